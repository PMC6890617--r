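#' Write genotypes as VCF v4.2
#'
#' Minimal biallelic VCF with a GT-only FORMAT field (`0/0`, `0/1`, `1/1`,
#' `./.`), one sample column per individual. Dosages count the ALT allele.
#'
#' @param genotypes a [genotype_matrix()] (integer dosages; mean-imputed
#'   real-valued dosages cannot be represented in GT and are rejected).
#' @param path output file path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosage
  if (any(!is.na(d) & d != round(d))) {
    stop("non-integer dosages cannot be written as GT calls")
  }
  map <- genotypes$map
  gt <- matrix(c("0/0", "0/1", "1/1")[t(d) + 1], nrow = ncol(d))
  gt[is.na(gt)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=drumgs",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(
      c(
        "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
        "FORMAT", rownames(d)
      ),
      collapse = "\t"
    )
  )
  body <- paste(
    map$chrom, map$pos, map$marker, map$ref, map$alt, ".", "PASS", ".", "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Reads a biallelic-SNP VCF via \pkg{vcfR} and converts GT calls to ALT
#' dosages. Multi-allelic records are rejected; phased separators are
#' accepted.
#'
#' @param path VCF file path (plain or gzipped).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt))) stop("multi-allelic records present; split or filter first")
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- c(
    "0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2,
    "0|0" = 0, "0|1" = 1, "1|0" = 1, "1|1" = 2
  )
  dosage <- matrix(code[gt], nrow = nrow(gt), dimnames = dimnames(gt))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  map <- data.frame(
    marker = ids, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = alt, stringsAsFactors = FALSE
  )
  d <- t(dosage)
  colnames(d) <- ids
  genotype_matrix(d, map)
}

#' Write / read a dosage matrix as TSV
#'
#' Rows are individuals (first column `id`), remaining columns one marker
#' each; missing calls written as `NA`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path file path.
#' @return `write_dosage_tsv` returns `path` invisibly; `read_dosage_tsv` a
#'   [genotype_matrix()].
#' @export
write_dosage_tsv <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosage
  df <- data.frame(id = rownames(d), d, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  d <- as.matrix(df[, -1, drop = FALSE])
  rownames(d) <- df[[1]]
  genotype_matrix(d)
}

#' Write / read a phenotype table as TSV
#'
#' Columns: `id`, `sex` (M/F), one column per trait.
#'
#' @param phenotypes phenotype data frame.
#' @param path file path.
#' @return `write_pheno_tsv` returns `path` invisibly; `read_pheno_tsv` the
#'   data frame.
#' @export
write_pheno_tsv <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pheno_tsv
#' @export
read_pheno_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
}
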
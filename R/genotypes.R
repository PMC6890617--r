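#' Genotype matrix container
#'
#' A light wrapper around an individuals x markers dosage matrix coded
#' 0/1/2 (count of the alternate allele; `NA` = missing call) together with
#' marker metadata. All pipeline stages consume and return this container.
#'
#' @param dosage numeric matrix, individuals in rows, markers in columns,
#'   entries in \{0, 1, 2, NA\}. Row and column names are used as individual
#'   and marker ids; defaults are generated when absent.
#' @param map optional data frame of marker metadata with columns
#'   `marker`, `chrom`, `pos`, `ref`, `alt`. A default single-chromosome map
#'   is generated when omitted.
#' @return an object of class `genotype_matrix` with elements `dosage` and
#'   `map`.
#' @export
genotype_matrix <- function(dosage, map = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  bad <- !is.na(dosage) & !(dosage %in% c(0, 1, 2))
  if (any(bad)) {
    stop("dosages must be 0, 1, 2 or NA; found ", dosage[which(bad)[1]])
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- sprintf("ind%0*d", nchar(nrow(dosage)), seq_len(nrow(dosage)))
  }
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("snp%0*d", nchar(ncol(dosage)), seq_len(ncol(dosage)))
  }
  if (is.null(map)) {
    map <- data.frame(
      marker = colnames(dosage),
      chrom = "1",
      pos = seq_len(ncol(dosage)) * 1000L,
      ref = "A",
      alt = "G",
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(map) == ncol(dosage))
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- x$dosage
  miss <- mean(is.na(d))
  cat(sprintf(
    "genotype_matrix: %d individuals x %d markers (%.2f%% missing)\n",
    nrow(d), ncol(d), 100 * miss
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by individuals and/or markers
#'
#' @param x a [genotype_matrix()].
#' @param individuals,markers index vectors (integer, logical or names);
#'   `NULL` keeps all.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(x, individuals = NULL, markers = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosage
  map <- x$map
  if (!is.null(individuals)) d <- d[individuals, , drop = FALSE]
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, colnames(d))
    d <- d[, markers, drop = FALSE]
    map <- map[markers, , drop = FALSE]
  }
  genotype_matrix(d, map)
}

#' Observed alternate-allele frequencies
#'
#' Per-marker frequency of the dosage-counted (alternate) allele, computed
#' from non-missing calls only.
#'
#' @param x a [genotype_matrix()] or a dosage matrix.
#' @return named numeric vector of frequencies in \[0, 1\].
#' @export
allele_freqs <- function(x) {
  d <- if (inherits(x, "genotype_matrix")) x$dosage else as.matrix(x)
  colMeans(d, na.rm = TRUE) / 2
}

# Column-center dosages at 2 * freq (the VanRaden centering). Errors on
# missing values: impute first.
center_dosages <- function(x, freqs = NULL) {
  d <- if (inherits(x, "genotype_matrix")) x$dosage else as.matrix(x)
  if (anyNA(d)) stop("dosage matrix contains missing calls; run impute_missing() first")
  if (is.null(freqs)) freqs <- colMeans(d) / 2
  stopifnot(length(freqs) == ncol(d))
  sweep(d, 2L, 2 * freqs, `-`)
}
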
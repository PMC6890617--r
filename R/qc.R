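#' Marker quality-control parameters
#'
#' Threshold set matching the conventional pre-analysis SNP filters for
#' genotyping-by-sequencing data: minimum minor allele frequency, maximum
#' per-marker missing-call fraction, and a Hardy-Weinberg exact-test p-value
#' floor.
#'
#' @param maf_min minimum minor allele frequency (computed on non-missing
#'   calls), default 0.01.
#' @param missing_max maximum fraction of missing calls, default 0.1.
#' @param hwe_p_min minimum Hardy-Weinberg exact-test p-value, default 1e-5.
#' @param biallelic_only logical; retained for interface completeness (the
#'   dosage container is biallelic by construction).
#' @return a `qc_params` list.
#' @export
qc_params <- function(maf_min = 0.01, missing_max = 0.1, hwe_p_min = 1e-5,
                      biallelic_only = TRUE) {
  stopifnot(
    maf_min >= 0, maf_min <= 1,
    missing_max >= 0, missing_max <= 1,
    hwe_p_min >= 0, hwe_p_min <= 1
  )
  structure(
    list(
      maf_min = maf_min, missing_max = missing_max,
      hwe_p_min = hwe_p_min, biallelic_only = isTRUE(biallelic_only)
    ),
    class = "qc_params"
  )
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test of Hardy-Weinberg proportions from genotype counts,
#' using the Levene-Haldane conditional distribution of the heterozygote
#' count given the allele counts. The p-value is the total probability of
#' all heterozygote configurations no more probable than the observed one
#' (plain exact test, no mid-p correction — the default of the standard QC
#' tooling).
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts (dosages 0, 1, 2).
#' @return p-value in (0, 1\].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("total genotype count is zero")
  n_a <- n_Aa + 2 * n_aa # minor-ish allele count (orientation-free test)
  rare <- min(n_a, 2 * n - n_a)
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(het = h | n, rare) up to a common constant:
  # P = C(n; nAA, nAa, naa) 2^h / C(2n, rare)
  homr <- (rare - hets) / 2
  homc <- n - hets - homr
  logp <- hets * log(2) - lfactorial(hets) - lfactorial(homr) - lfactorial(homc)
  logp <- logp - max(logp)
  prob <- exp(logp)
  prob <- prob / sum(prob)
  obs <- match(n_Aa, hets)
  if (is.na(obs)) stop("heterozygote count inconsistent with allele counts")
  # sum configurations with probability <= observed (with a tiny numerical
  # guard so ties are included despite floating-point noise)
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-10)]))
}

# Per-marker genotype counts, MAF and missingness from a dosage matrix.
marker_stats <- function(dosage) {
  markers <- colnames(dosage)
  if (is.null(markers)) markers <- paste0("m", seq_len(ncol(dosage)))
  n0 <- colSums(dosage == 0, na.rm = TRUE)
  n1 <- colSums(dosage == 1, na.rm = TRUE)
  n2 <- colSums(dosage == 2, na.rm = TRUE)
  n_obs <- n0 + n1 + n2
  freq <- ifelse(n_obs > 0, (n1 + 2 * n2) / (2 * n_obs), NA_real_)
  data.frame(
    marker = markers,
    n_obs = n_obs,
    n_hom_ref = n0, n_het = n1, n_hom_alt = n2,
    missing_rate = 1 - n_obs / nrow(dosage),
    freq = freq,
    maf = pmin(freq, 1 - freq),
    stringsAsFactors = FALSE
  )
}

#' Filter markers on MAF, missingness and Hardy-Weinberg equilibrium
#'
#' Applies, in order, the minor-allele-frequency, missing-call-rate and
#' Hardy-Weinberg exact-test rules of [qc_params()]. A removed marker is
#' attributed to the first rule it fails (MAF, then missingness, then HWE),
#' so the drop report is deterministic. MAF is computed from non-missing
#' calls only; the HWE test uses the observed genotype counts.
#'
#' @param genotypes a [genotype_matrix()].
#' @param params a [qc_params()].
#' @return list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report` (data frame with per-marker `maf`, `missing_rate`, `hwe_p`,
#'   `keep` and `reason` among `"maf"`, `"missing"`, `"hwe"`, `""`).
#' @export
filter_markers <- function(genotypes, params = qc_params()) {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(params, "qc_params"))
  d <- genotypes$dosage
  st <- marker_stats(d)
  hwe_p <- mapply(function(a, h, b) {
    if (a + h + b == 0) return(NA_real_)
    hwe_exact_test(a, h, b)
  }, st$n_hom_ref, st$n_het, st$n_hom_alt)
  reason <- rep("", ncol(d))
  fail_maf <- is.na(st$maf) | st$maf < params$maf_min
  fail_mis <- st$missing_rate > params$missing_max
  fail_hwe <- !is.na(hwe_p) & hwe_p < params$hwe_p_min
  reason[fail_hwe] <- "hwe"
  reason[fail_mis] <- "missing"
  reason[fail_maf] <- "maf"
  keep <- reason == ""
  if (!any(keep)) warning("all markers removed by QC filters")
  report <- data.frame(
    marker = st$marker, maf = st$maf, missing_rate = st$missing_rate,
    hwe_p = hwe_p, keep = keep, reason = reason, stringsAsFactors = FALSE
  )
  list(
    genotypes = subset_genotypes(genotypes, markers = which(keep)),
    report = report
  )
}

#' Impute missing genotype calls
#'
#' A naive single-marker imputation: `mean` fills each missing call with the
#' per-marker mean dosage (a real number, preserving the marker mean);
#' `mode` fills the most frequent observed dosage, breaking ties toward the
#' lower dosage.
#'
#' @param genotypes a [genotype_matrix()].
#' @param mode `"mean"` or `"mode"`.
#' @return a [genotype_matrix()] with no missing entries. Mean-imputed
#'   dosages are real-valued; the container check is bypassed for them.
#' @export
impute_missing <- function(genotypes, mode = c("mean", "mode")) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  mode <- match.arg(mode)
  d <- genotypes$dosage
  if (!anyNA(d)) return(genotypes)
  all_missing <- colSums(!is.na(d)) == 0
  if (any(all_missing)) {
    stop(
      "marker(s) with no observed calls: ",
      paste(colnames(d)[all_missing], collapse = ", ")
    )
  }
  fill <- if (mode == "mean") {
    colMeans(d, na.rm = TRUE)
  } else {
    apply(d, 2L, function(col) {
      tab <- table(factor(col, levels = c(0, 1, 2)))
      as.numeric(names(tab)[which.max(tab)]) # which.max takes the first max: lower dosage wins ties
    })
  }
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- fill[idx[, 2L]]
  out <- genotypes
  out$dosage <- d
  out
}
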
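#' VanRaden genomic relationship matrix
#'
#' Builds the realized additive relationship matrix from centered dosages:
#' `G = W W' / (2 sum p_j (1 - p_j))` with `W = B - 2P`, where `B` is the
#' dosage matrix (0/1/2 counts of the alternate allele) and `p_j` the
#' frequency of the counted allele at marker `j`. Frequencies default to the
#' observed sample frequencies; supplying base-population frequencies (e.g.
#' those of a training set when relating selection candidates to it) is
#' supported through `freqs`.
#'
#' `G` is invariant to flipping which allele a marker counts, provided the
#' frequency is flipped with it.
#'
#' @param genotypes a [genotype_matrix()] or dosage matrix with no missing
#'   calls.
#' @param freqs optional per-marker frequencies of the counted allele.
#' @return an object of class `grm`: list with `matrix` (n x n, dimnames =
#'   individual ids), `centering_freqs`, `denominator` = 2 sum p(1-p),
#'   `n_markers_used` and `blend_epsilon` (0 for a raw matrix).
#' @export
vanraden_grm <- function(genotypes, freqs = NULL) {
  d <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage else as.matrix(genotypes)
  if (anyNA(d)) stop("dosage matrix contains missing calls; impute first")
  if (ncol(d) < 1L) stop("no markers")
  if (is.null(freqs)) {
    freqs <- colMeans(d) / 2
    mono <- freqs <= 0 | freqs >= 1
    if (any(mono)) {
      stop(
        "monomorphic marker(s) with default frequencies (e.g. ",
        colnames(d)[which(mono)[1]],
        "); run filter_markers() first or supply freqs"
      )
    }
  }
  stopifnot(length(freqs) == ncol(d), all(freqs > 0), all(freqs < 1))
  denom <- 2 * sum(freqs * (1 - freqs))
  w <- sweep(d, 2L, 2 * freqs, `-`)
  g <- tcrossprod(w) / denom
  g <- (g + t(g)) / 2 # enforce exact symmetry against rounding
  structure(
    list(
      matrix = g, centering_freqs = freqs, denominator = denom,
      n_markers_used = ncol(d), blend_epsilon = 0
    ),
    class = "grm"
  )
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf(
    "grm: %d individuals, %d markers, mean diagonal %.3f%s\n",
    nrow(x$matrix), x$n_markers_used, mean(diag(x$matrix)),
    if (x$blend_epsilon > 0) sprintf(", blended (epsilon = %g)", x$blend_epsilon) else ""
  ))
  invisible(x)
}

#' Blend a GRM toward the identity
#'
#' Returns `(1 - epsilon) G + epsilon I`. Centering at observed frequencies
#' always leaves the raw cross-product matrix singular (the all-ones vector
#' is in its null space), so a small identity blend guarantees positive
#' definiteness before any inversion: every eigenvalue is shifted up by at
#' least `epsilon` on a positive semi-definite input.
#'
#' @param grm a `grm` from [vanraden_grm()].
#' @param epsilon blending weight in (0, 1), default 0.01.
#' @return a `grm` with updated `matrix` and `blend_epsilon`.
#' @export
blend_grm <- function(grm, epsilon = 0.01) {
  stopifnot(inherits(grm, "grm"))
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  out <- grm
  g <- (1 - epsilon) * grm$matrix
  diag(g) <- diag(g) + epsilon
  out$matrix <- g
  out$blend_epsilon <- grm$blend_epsilon + epsilon * (1 - grm$blend_epsilon)
  out
}

# Coerce grm-or-matrix to a plain matrix.
as_grm_matrix <- function(x) {
  if (inherits(x, "grm")) x$matrix else as.matrix(x)
}

#' Write / read a GRM as TSV
#'
#' Plain-text serialization: a square tab-separated matrix with individual
#' ids as header row and first column.
#'
#' @param grm a `grm` or square matrix.
#' @param path file path.
#' @return `write_grm_tsv` returns `path` invisibly; `read_grm_tsv` returns
#'   the matrix (class `grm` with centering metadata absent).
#' @export
write_grm_tsv <- function(grm, path) {
  g <- as_grm_matrix(grm)
  df <- data.frame(id = rownames(g), g, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grm_tsv
#' @export
read_grm_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  rownames(g) <- df[[1]]
  structure(
    list(
      matrix = g, centering_freqs = NULL,
      denominator = NA_real_, n_markers_used = NA_integer_, blend_epsilon = NA_real_
    ),
    class = "grm"
  )
}
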
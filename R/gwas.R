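#' Mixed-model single-marker association scan
#'
#' EMMAX-style scan: the variance components of the null model
#' `y ~ N(X alpha, G sigma_g2 + I sigma_e2)` are estimated once (or taken
#' from a supplied fit), the data are rotated by `V^{-1/2}`, and each
#' marker's additive dosage effect is tested by a Wald t-test against the
#' null-model covariance held fixed. Dosages are centered but not
#' standardized. With `G = I` the scan reduces exactly to the ordinary
#' fixed-effect regression t-test.
#'
#' @param mm a [model_matrices()] (phenotyped individuals only are used).
#' @param dosages complete [genotype_matrix()] or dosage matrix over the
#'   same individuals as `mm`.
#' @param vc optional `varcomp` from [reml_fit()] on the null model;
#'   estimated internally when omitted.
#' @return data frame with `marker`, `beta`, `se`, `stat` and two-sided `p`
#'   (markers collinear with the fixed effects get `p = 1` with a warning).
#' @export
mlm_scan <- function(mm, dosages, vc = NULL) {
  stopifnot(inherits(mm, "model_matrices"))
  d <- if (inherits(dosages, "genotype_matrix")) dosages$dosage else as.matrix(dosages)
  if (anyNA(d)) stop("dosages contain missing calls; impute first")
  stopifnot(nrow(d) == length(mm$y))
  obs <- !is.na(mm$y)
  y <- mm$y[obs]
  X <- mm$X[obs, , drop = FALSE]
  W <- center_dosages(d[obs, , drop = FALSE])
  if (is.null(vc)) vc <- reml_fit(mm)
  K <- as_grm_matrix(mm$grm)[obs, obs, drop = FALSE]
  eig <- eigen(K, symmetric = TRUE)
  dv <- pmax(eig$values, 0) * vc$sigma_g2 + vc$sigma_e2
  rot <- sweep(t(eig$vectors), 1L, sqrt(dv), `/`) # rows of U' scaled: V^{-1/2}
  ys <- drop(rot %*% y)
  Xs <- rot %*% X
  Ws <- rot %*% W
  # residualize against the rotated fixed effects
  qx <- qr(Xs)
  ry <- qr.resid(qx, ys)
  rw <- qr.resid(qx, Ws)
  p_fix <- ncol(Xs)
  df <- length(ys) - p_fix - 1L
  if (df < 1L) stop("not enough residual degrees of freedom for the scan")
  sxx <- colSums(rw^2)
  sxy <- drop(crossprod(rw, ry))
  syy <- sum(ry^2)
  collinear <- sxx <= max(sxx, 1) * 1e-12
  beta <- ifelse(collinear, NA_real_, sxy / sxx)
  rss <- pmax(syy - ifelse(collinear, 0, sxy^2 / sxx), 0)
  se <- sqrt(rss / df / sxx)
  stat <- beta / se
  p <- 2 * pt(abs(stat), df = df, lower.tail = FALSE)
  if (any(collinear)) {
    warning(sum(collinear), " marker(s) collinear with the fixed effects; p set to 1")
    p[collinear] <- 1
    stat[collinear] <- 0
    se[collinear] <- NA_real_
  }
  data.frame(
    marker = colnames(d), beta = beta, se = se, stat = stat, p = p,
    stringsAsFactors = FALSE
  )
}

#' Low-density SNP panel specification
#'
#' @param mode `"informative"` (smallest association p-values first) or
#'   `"random"` (uniform sample without replacement).
#' @param size panel size (>= 1).
#' @param source_pvalues per-marker p-values, named by marker or aligned
#'   with the marker ids handed to [select_panel()]; required in
#'   informative mode.
#' @param seed integer seed, required in random mode.
#' @return a `panel_spec` list.
#' @export
panel_spec <- function(mode = c("informative", "random"), size,
                       source_pvalues = NULL, seed = NULL) {
  mode <- match.arg(mode)
  size <- as.integer(size)
  if (size < 1L) stop("panel size must be at least 1")
  if (mode == "informative" && is.null(source_pvalues)) {
    stop("informative mode requires source_pvalues")
  }
  if (mode == "random" && is.null(seed)) stop("random mode requires a seed")
  structure(
    list(mode = mode, size = size, source_pvalues = source_pvalues, seed = seed),
    class = "panel_spec"
  )
}

#' Select a low-density marker panel
#'
#' Informative mode returns the `size` markers with the smallest source
#' p-values, ties broken by genome order (position in `marker_ids`), so
#' panels are nested across sizes. Random mode draws a uniform sample
#' without replacement under the spec's seed.
#'
#' @param spec a [panel_spec()].
#' @param marker_ids character vector of candidate marker ids in genome
#'   order.
#' @return character vector of selected marker ids (ordered by rank in
#'   informative mode).
#' @export
select_panel <- function(spec, marker_ids) {
  stopifnot(inherits(spec, "panel_spec"))
  n <- length(marker_ids)
  if (spec$size > n) stop("panel size exceeds marker count")
  if (spec$mode == "informative") {
    p <- spec$source_pvalues
    if (!is.null(names(p))) p <- p[marker_ids]
    if (length(p) != n || anyNA(p)) stop("source_pvalues must cover all marker_ids")
    ord <- order(p, seq_len(n))
    marker_ids[ord[seq_len(spec$size)]]
  } else {
    with_seed(spec$seed, marker_ids[sample.int(n, spec$size)])
  }
}
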
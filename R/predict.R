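#' Genomic BLUP prediction
#'
#' Solves the GBLUP mixed-model equations for `y ~ N(X alpha, G sigma_g2 +
#' I sigma_e2)` at shrinkage `lambda = sigma_e2/sigma_g2 = (1 - h2)/h2`.
#' Individuals with `NA` phenotypes are excluded from the records but kept
#' in the relationship matrix; their GEBVs come out of the joint solve,
#' which is computed in the equivalent covariance form
#' `alpha = GLS(y, X; G_tt + lambda I)`,
#' `g_hat = G[, train] (G_tt + lambda I)^{-1} (y - X alpha)`.
#' This is algebraically identical to the inverted-G mixed-model equations
#' but needs no `G` inverse, so it tolerates the exactly singular raw
#' cross-product matrix.
#'
#' @param mm a [model_matrices()]; `NA` entries of `mm$y` mark prediction
#'   individuals.
#' @param lambda shrinkage ratio, or a `varcomp` from [reml_fit()] (its
#'   `lambda` is used).
#' @param predict_ids ids to report GEBVs for; default all individuals in
#'   `mm`.
#' @param blend_epsilon identity blend applied to the GRM before solving
#'   (see [blend_grm()]); 0 disables blending, which is required for the
#'   exact GBLUP-RRBLUP equivalence.
#' @return object of class `gebv_result`: `gebv` (named vector),
#'   `fixed_effects`, `method`, `hyperparams`.
#' @export
gblup_predict <- function(mm, lambda, predict_ids = NULL, blend_epsilon = 0.01) {
  stopifnot(inherits(mm, "model_matrices"))
  if (inherits(lambda, "varcomp")) lambda <- lambda$lambda
  stopifnot(is.numeric(lambda), lambda >= 0)
  grm <- mm$grm
  if (blend_epsilon > 0) grm <- blend_grm(grm, blend_epsilon)
  G <- as_grm_matrix(grm)
  obs <- !is.na(mm$y)
  if (!any(obs)) stop("no phenotyped individuals to train on")
  y <- mm$y[obs]
  X <- mm$X[obs, , drop = FALSE]
  V0 <- G[obs, obs, drop = FALSE]
  diag(V0) <- diag(V0) + lambda
  Vi <- tryCatch(solve(V0), error = function(e) {
    stop("singular GBLUP coefficient matrix; increase blend_epsilon")
  })
  XtVi <- crossprod(X, Vi)
  alpha <- drop(solve(XtVi %*% X, XtVi %*% y))
  r <- drop(Vi %*% (y - X %*% alpha))
  gebv <- drop(G[, obs, drop = FALSE] %*% r)
  names(gebv) <- mm$ids
  names(alpha) <- colnames(mm$X)
  if (is.null(predict_ids)) predict_ids <- mm$ids
  structure(
    list(
      gebv = gebv[predict_ids], fixed_effects = alpha, method = "gblup",
      hyperparams = list(lambda = lambda, blend_epsilon = blend_epsilon)
    ),
    class = "gebv_result"
  )
}

#' @export
print.gebv_result <- function(x, ...) {
  cat(sprintf(
    "gebv_result (%s): %d individuals, gebv sd %.4f\n",
    x$method, length(x$gebv), sd(x$gebv)
  ))
  invisible(x)
}

#' Ridge-regression BLUP on marker effects
#'
#' Fits `y = X alpha + W beta + e` with an equal ridge penalty
#' `lambda_marker = sigma_e2 / sigma_beta2` on every marker effect and no
#' penalty on the fixed effects; `W` is the dosage matrix column-centered at
#' `2 * freqs`. With `sigma_beta2 = sigma_g2 / (2 sum p(1-p))` this is the
#' marker-effect formulation of GBLUP and yields identical GEBVs.
#'
#' Rows of `y` that are `NA` are excluded from the fit; GEBVs (`W beta_hat`)
#' are returned for all rows. The solver uses the augmented normal
#' equations when `p + m <= n` or `lambda_marker = 0`, and the equivalent
#' n-dimensional dual system otherwise.
#'
#' @param y response (named) vector, `NA` = predict-only.
#' @param X fixed-effects design matrix (same rows as `y`).
#' @param dosages [genotype_matrix()] or complete dosage matrix.
#' @param lambda_marker ridge penalty on marker effects (>= 0).
#' @param freqs centering frequencies; default observed frequencies over all
#'   rows of `dosages` (match the GRM's centering frequencies to reproduce
#'   GBLUP exactly).
#' @return object of class `gebv_result` with an additional `effects`
#'   element (named per-marker estimates).
#' @export
rrblup_fit <- function(y, X, dosages, lambda_marker, freqs = NULL) {
  d <- if (inherits(dosages, "genotype_matrix")) dosages$dosage else as.matrix(dosages)
  if (ncol(d) == 0L) stop("no markers")
  stopifnot(length(y) == nrow(d), nrow(X) == nrow(d), lambda_marker >= 0)
  W <- center_dosages(d, freqs)
  obs <- !is.na(y)
  yt <- y[obs]
  Xt <- X[obs, , drop = FALSE]
  Wt <- W[obs, , drop = FALSE]
  p <- ncol(Xt)
  m <- ncol(Wt)
  if (lambda_marker == 0 || p + m <= length(yt)) {
    Z <- cbind(Xt, Wt)
    A <- crossprod(Z)
    if (lambda_marker > 0) {
      idx <- (p + 1):(p + m)
      A[cbind(idx, idx)] <- A[cbind(idx, idx)] + lambda_marker
    }
    sol <- drop(solve(A, crossprod(Z, yt)))
    alpha <- sol[seq_len(p)]
    beta <- sol[-seq_len(p)]
  } else {
    H <- tcrossprod(Wt)
    diag(H) <- diag(H) + lambda_marker
    Hi <- solve(H)
    XtHi <- crossprod(Xt, Hi)
    alpha <- drop(solve(XtHi %*% Xt, XtHi %*% yt))
    beta <- drop(crossprod(Wt, Hi %*% (yt - Xt %*% alpha)))
  }
  names(alpha) <- colnames(X)
  names(beta) <- colnames(d)
  gebv <- drop(W %*% beta)
  names(gebv) <- if (!is.null(names(y))) names(y) else rownames(d)
  structure(
    list(
      gebv = gebv, fixed_effects = alpha, effects = beta, method = "rrblup",
      hyperparams = list(lambda_marker = lambda_marker)
    ),
    class = "gebv_result"
  )
}

#' Scale parameter of the scaled-inverse-chi-square marker-variance prior
#'
#' The Bayesian-alphabet samplers give each (included) marker an effect
#' variance with a scaled-inverse-chi-square prior with `v` degrees of
#' freedom. Its scale `s2` is chosen so the prior mean `v s2 / (v - 2)`
#' equals the per-marker variance implied by the genetic variance:
#' `sigma_beta2 = sigma_g2 / (pi * 2 sum p(1-p))`, giving
#' `s2 = sigma_beta2 (v - 2) / v`.
#'
#' @param sigma_g2 additive genetic variance of the trait.
#' @param v prior degrees of freedom (> 2, or the prior mean is undefined).
#' @param pi prior probability a marker is included in the model (1 for
#'   BayesA-type models where every marker has an effect).
#' @param sum2pq the GRM scaling denominator `2 sum p_j (1 - p_j)`.
#' @return the scale parameter `s2`.
#' @export
bayes_scale_param <- function(sigma_g2, v, pi, sum2pq) {
  if (v <= 2) stop("v must exceed 2 for the inverse-chi-square mean to exist")
  stopifnot(pi > 0, pi <= 1, sum2pq > 0, sigma_g2 >= 0)
  sigma_b2 <- sigma_g2 / (pi * sum2pq)
  sigma_b2 * (v - 2) / v
}

#' Bayesian-alphabet chain controls and hyperparameters
#'
#' @param pi prior inclusion probability (BayesB) or initial value
#'   (BayesCpi); ignored by BayesA.
#' @param v degrees of freedom of the scaled-inverse-chi-square
#'   marker-variance prior.
#' @param s2 its scale; `NULL` derives it in [bayes_sampler()] via
#'   [bayes_scale_param()].
#' @param n_iter,burn_in,thin chain length, burn-in discarded, thinning
#'   interval for stored samples.
#' @param variance_ratio MMixp large:small variance ratio (default 100).
#' @param seed integer seed for chain reproducibility (`NULL` = continue the
#'   session RNG stream).
#' @return a `bayes_hyper` list.
#' @export
bayes_hyper <- function(pi = 0.01, v = 4.2, s2 = NULL, n_iter = 10000L,
                        burn_in = 2000L, thin = 10L, variance_ratio = 100,
                        seed = NULL) {
  stopifnot(
    pi > 0, pi <= 1, v > 2, n_iter > burn_in, burn_in >= 0, thin >= 1,
    variance_ratio >= 1
  )
  structure(
    list(
      pi = pi, v = v, s2 = s2, n_iter = as.integer(n_iter),
      burn_in = as.integer(burn_in), thin = as.integer(thin),
      variance_ratio = variance_ratio, seed = seed
    ),
    class = "bayes_hyper"
  )
}

#' Whole-genome regression by single-site Gibbs sampling
#'
#' Bayesian-alphabet marker-effect models fitted by single-site Gibbs
#' sampling:
#' * `BayesA` — every marker has an effect; marker variances are iid
#'   scaled-inverse-chi-square(v, s2).
#' * `BayesB` — spike-and-slab: each marker is in the model with fixed prior
#'   probability `pi`; included markers get BayesA-type per-marker variances.
#' * `BayesCpi` — spike-and-slab with one common slab variance and `pi`
#'   sampled from its Beta posterior.
#' * `MMixp` — every marker has an effect drawn from a two-component normal
#'   scale mixture (large variance `tau2` or small variance
#'   `tau2 / variance_ratio`), with the large-class probability sampled.
#'
#' Fixed effects carry flat priors; the residual variance a weakly
#' informative scaled-inverse-chi-square prior (4 df, prior mean
#' `var(y)/2`). GEBVs are centered dosages times posterior-mean effects,
#' reported for all rows including `NA`-phenotype (prediction) individuals.
#'
#' @inheritParams rrblup_fit
#' @param model one of `"BayesA"`, `"BayesB"`, `"BayesCpi"`, `"MMixp"`.
#' @param hyper a [bayes_hyper()].
#' @param sigma_g2 genetic variance used to derive `s2` when `hyper$s2` is
#'   `NULL`; defaults to `var(y)/2` (a neutral half-heritability guess) —
#'   supply a REML estimate for better calibration.
#' @return list with `posterior` (class `marker_posterior`: `effect_mean`,
#'   `inclusion_prob`, `pi_posterior`, `chain_summaries`) and `result`
#'   (class `gebv_result`).
#' @export
bayes_sampler <- function(y, X, dosages, model = c("BayesA", "BayesB", "BayesCpi", "MMixp"),
                          hyper = bayes_hyper(), freqs = NULL, sigma_g2 = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(hyper, "bayes_hyper"))
  d <- if (inherits(dosages, "genotype_matrix")) dosages$dosage else as.matrix(dosages)
  stopifnot(length(y) == nrow(d), nrow(X) == nrow(d))
  if (is.null(freqs)) freqs <- colMeans(d) / 2
  W <- center_dosages(d, freqs)
  obs <- !is.na(y)
  yt <- y[obs]
  if (length(yt) < 10L) stop("need at least 10 phenotyped individuals")
  pi_eff <- if (model %in% c("BayesA", "MMixp")) 1 else hyper$pi
  s2 <- hyper$s2
  if (is.null(s2)) {
    if (is.null(sigma_g2)) sigma_g2 <- var(yt) / 2
    sum2pq <- 2 * sum(freqs * (1 - freqs))
    s2 <- bayes_scale_param(sigma_g2, hyper$v, pi_eff, sum2pq)
  }
  ve_df <- 4
  ve_scale <- (var(yt) / 2) * (ve_df - 2) / ve_df
  model_code <- match(model, c("BayesA", "BayesB", "BayesCpi", "MMixp")) - 1L
  fit <- with_seed(hyper$seed, {
    bayes_gibbs_cpp(
      yt, X[obs, , drop = FALSE], W[obs, , drop = FALSE],
      model_code, pi_eff, hyper$v, s2, ve_df, ve_scale,
      hyper$n_iter, hyper$burn_in, hyper$thin, hyper$variance_ratio
    )
  })
  effect_mean <- stats::setNames(drop(fit$effect_mean), colnames(d))
  gebv <- drop(W %*% effect_mean)
  names(gebv) <- if (!is.null(names(y))) names(y) else rownames(d)
  scalars <- data.frame(
    parameter = c("sigma_e2", "pi", "sigma_b2"),
    mean = c(mean(fit$sigma_e2_samples), mean(fit$pi_samples), mean(fit$sigma_b2_samples)),
    ess = c(
      effective_size(fit$sigma_e2_samples),
      effective_size(fit$pi_samples),
      effective_size(fit$sigma_b2_samples)
    )
  )
  posterior <- structure(
    list(
      effect_mean = effect_mean,
      inclusion_prob = stats::setNames(drop(fit$inclusion_prob), colnames(d)),
      pi_posterior = mean(fit$pi_samples),
      chain_summaries = scalars,
      n_samples = length(fit$sigma_e2_samples)
    ),
    class = "marker_posterior"
  )
  result <- structure(
    list(
      gebv = gebv,
      fixed_effects = stats::setNames(drop(fit$alpha_mean), colnames(X)),
      method = model,
      hyperparams = list(
        pi = pi_eff, v = hyper$v, s2 = s2, n_iter = hyper$n_iter,
        burn_in = hyper$burn_in, thin = hyper$thin,
        variance_ratio = hyper$variance_ratio
      )
    ),
    class = "gebv_result"
  )
  list(posterior = posterior, result = result)
}

#' @export
print.marker_posterior <- function(x, ...) {
  cat(sprintf(
    "marker_posterior: %d markers, posterior mean pi = %.4g, %d stored samples\n",
    length(x$effect_mean), x$pi_posterior, x$n_samples
  ))
  invisible(x)
}

# Effective sample size of a scalar chain via the AR spectral density at
# zero (the usual time-series estimator).
effective_size <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 10 || var(x) == 0) return(as.numeric(n))
  fit <- tryCatch(stats::ar(x, aic = TRUE), error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) == 0) return(as.numeric(n))
  spec0 <- fit$var.pred / (1 - sum(fit$ar))^2
  max(1, min(n, n * var(x) / spec0))
}
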
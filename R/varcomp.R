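#' Assemble mixed-model matrices
#'
#' Aligns a phenotype table with a GRM and builds the fixed-effect design
#' (intercept plus factor indicators). The random-effect incidence is the
#' identity — one record per individual — so it is implicit.
#'
#' @param phenotypes data frame with an `id` column, the fixed-effect
#'   columns and the trait column.
#' @param grm a `grm` covering at least the phenotyped individuals.
#' @param trait name of the trait column.
#' @param fixed character vector of fixed-effect column names (factors or
#'   numeric covariates); default `"sex"`. Use `character(0)` for an
#'   intercept-only model.
#' @return object of class `model_matrices`: list with `y` (named numeric,
#'   may contain `NA` for unphenotyped individuals), `X`, `ids`, `grm`.
#' @export
model_matrices <- function(phenotypes, grm, trait, fixed = "sex") {
  stopifnot(inherits(grm, "grm"), trait %in% names(phenotypes))
  ids <- phenotypes$id
  g_ids <- rownames(grm$matrix)
  if (!all(ids %in% g_ids)) stop("phenotyped individuals missing from the GRM")
  grm_sub <- grm
  grm_sub$matrix <- grm$matrix[ids, ids, drop = FALSE]
  fml <- if (length(fixed)) {
    stats::reformulate(fixed)
  } else {
    ~1
  }
  X <- stats::model.matrix(fml, data = phenotypes)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design matrix is rank deficient")
  y <- stats::setNames(phenotypes[[trait]], ids)
  structure(
    list(y = y, X = X, ids = ids, grm = grm_sub),
    class = "model_matrices"
  )
}

# Shared plumbing for the rotated (eigen-space) mixed model
# y ~ N(X alpha, sigma_g2 K + sigma_e2 I): returns P y, trace terms and the
# restricted log-likelihood for components theta = c(sigma_g2, sigma_e2).
reml_eval <- function(ys, Xs, d, theta) {
  v <- d * theta[1] + theta[2]
  a <- ys / v
  Xv <- Xs / v
  XtViX <- crossprod(Xs, Xv)
  C <- solve(XtViX)
  b <- crossprod(Xs, a)
  Py <- a - Xv %*% (C %*% b)
  Py <- drop(Py)
  ll <- -0.5 * (sum(log(v)) + determinant(XtViX, logarithm = TRUE)$modulus[1] + sum(ys * Py))
  list(v = v, C = C, Py = Py, Xv = Xv, loglik = as.numeric(ll))
}

# P f for an arbitrary vector f, reusing reml_eval pieces.
apply_P <- function(f, env) {
  fv <- f / env$v
  drop(fv - env$Xv %*% (env$C %*% crossprod(env$Xv * env$v, fv)))
}

#' REML variance components under the GBLUP model
#'
#' Estimates the additive genetic and residual variances of
#' `y ~ N(X alpha, G sigma_g2 + I sigma_e2)` by restricted maximum
#' likelihood. The default algorithm is average-information (AI) REML with
#' EM-REML fallback steps whenever an AI update would push a component
#' negative or decrease the restricted log-likelihood; `method = "em"` runs
#' pure EM (slower, monotone). Standard errors come from the inverse AI
#' matrix at the optimum and the heritability standard error by the delta
#' method.
#'
#' Components are floored at `1e-8 * var(y)`; an estimate at the floor is
#' flagged `boundary`. Convergence is declared when the maximum relative
#' parameter change drops below `tol`.
#'
#' @param mm a [model_matrices()] (records with `NA` phenotypes are
#'   excluded from the fit).
#' @param method `"ai"` (default) or `"em"`.
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap; non-convergence returns the current
#'   estimates with `converged = FALSE` and a warning.
#' @return object of class `varcomp`: `sigma_g2`, `sigma_e2`, `h2`,
#'   `se_sigma_g2`, `se_sigma_e2`, `se_h2`, `lambda` (= sigma_e2/sigma_g2),
#'   `loglik`, `loglik_trace`, `n_iterations`, `converged`, `boundary`, `n`.
#' @export
reml_fit <- function(mm, method = c("ai", "em"), tol = 1e-8, max_iter = 200L) {
  stopifnot(inherits(mm, "model_matrices"))
  method <- match.arg(method)
  obs <- !is.na(mm$y)
  y <- mm$y[obs]
  X <- mm$X[obs, , drop = FALSE]
  K <- as_grm_matrix(mm$grm)[obs, obs, drop = FALSE]
  n <- length(y)
  if (n < 10L) stop("need at least 10 phenotyped individuals for REML")
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect design")
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  ys <- drop(crossprod(U, y))
  Xs <- crossprod(U, X)
  vy <- var(y)
  floor_v <- 1e-8 * vy
  theta <- c(vy / 2, vy / 2)
  env <- reml_eval(ys, Xs, d, theta)
  trace <- env$loglik
  converged <- FALSE
  it <- 0L
  ai <- NULL
  em_step <- function(theta, env) {
    ypa1py <- sum(d * env$Py^2)
    ypa2py <- sum(env$Py^2)
    trP1 <- sum(d / env$v) - sum(env$C * crossprod(Xs, Xs * (d / env$v^2)))
    trP2 <- sum(1 / env$v) - sum(env$C * crossprod(Xs, Xs / env$v^2))
    c(
      theta[1] + theta[1]^2 / n * (ypa1py - trP1),
      theta[2] + theta[2]^2 / n * (ypa2py - trP2)
    )
  }
  while (it < max_iter) {
    it <- it + 1L
    if (method == "em") {
      theta_new <- em_step(theta, env)
    } else {
      # average-information update with EM fallback
      f1 <- d * env$Py
      f2 <- env$Py
      Pf1 <- apply_P(f1, env)
      Pf2 <- apply_P(f2, env)
      ai <- 0.5 * matrix(
        c(sum(f1 * Pf1), sum(f1 * Pf2), sum(f2 * Pf1), sum(f2 * Pf2)), 2, 2
      )
      ai <- (ai + t(ai)) / 2
      trP1 <- sum(d / env$v) - sum(env$C * crossprod(Xs, Xs * (d / env$v^2)))
      trP2 <- sum(1 / env$v) - sum(env$C * crossprod(Xs, Xs / env$v^2))
      score <- -0.5 * c(trP1 - sum(d * env$Py^2), trP2 - sum(env$Py^2))
      step <- tryCatch(solve(ai, score), error = function(e) NULL)
      theta_new <- if (is.null(step)) em_step(theta, env) else theta + drop(step)
      if (any(!is.finite(theta_new)) || any(theta_new <= floor_v)) {
        theta_new <- em_step(theta, env)
      }
    }
    theta_new <- pmax(theta_new, floor_v)
    env_new <- reml_eval(ys, Xs, d, theta_new)
    if (method == "ai" && env_new$loglik < env$loglik - 1e-10) {
      theta_new <- pmax(em_step(theta, env), floor_v)
      env_new <- reml_eval(ys, Xs, d, theta_new)
    }
    rel <- max(abs(theta_new - theta) / pmax(abs(theta), floor_v))
    theta <- theta_new
    env <- env_new
    trace <- c(trace, env$loglik)
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("REML did not converge in ", max_iter, " iterations")
  }
  # AI matrix at the optimum for standard errors
  f1 <- d * env$Py
  f2 <- env$Py
  Pf1 <- apply_P(f1, env)
  Pf2 <- apply_P(f2, env)
  ai <- 0.5 * matrix(
    c(sum(f1 * Pf1), sum(f1 * Pf2), sum(f2 * Pf1), sum(f2 * Pf2)), 2, 2
  )
  ai <- (ai + t(ai)) / 2
  cov_theta <- tryCatch(solve(ai), error = function(e) matrix(NA_real_, 2, 2))
  sg2 <- theta[1]
  se2 <- theta[2]
  h2 <- sg2 / (sg2 + se2)
  grad <- c(se2, -sg2) / (sg2 + se2)^2
  se_h2 <- sqrt(max(0, drop(t(grad) %*% cov_theta %*% grad)))
  structure(
    list(
      sigma_g2 = sg2, sigma_e2 = se2, h2 = h2,
      se_sigma_g2 = sqrt(max(0, cov_theta[1, 1])),
      se_sigma_e2 = sqrt(max(0, cov_theta[2, 2])),
      se_h2 = se_h2,
      lambda = if (h2 > 0 && h2 < 1) (1 - h2) / h2 else se2 / sg2,
      loglik = env$loglik, loglik_trace = trace,
      n_iterations = it, converged = converged,
      boundary = any(theta <= floor_v * (1 + 1e-12)),
      n = n, method = method
    ),
    class = "varcomp"
  )
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf(
    paste0(
      "REML variance components (%s, n = %d, %d iterations%s)\n",
      "  sigma_g2 = %.4f (SE %.4f)\n  sigma_e2 = %.4f (SE %.4f)\n",
      "  h2 = %.3f (SE %.3f), lambda = %.4f\n"
    ),
    x$method, x$n, x$n_iterations,
    if (x$converged) "" else ", NOT converged",
    x$sigma_g2, x$se_sigma_g2, x$sigma_e2, x$se_sigma_e2,
    x$h2, x$se_h2, x$lambda
  ))
  invisible(x)
}

#' Narrow-sense heritability from variance components
#'
#' `h2 = sigma_g2 / (sigma_g2 + sigma_e2)`.
#'
#' @param sigma_g2 additive genetic variance (>= 0).
#' @param sigma_e2 residual variance (>= 0).
#' @return heritability in \[0, 1\].
#' @export
h2_from_components <- function(sigma_g2, sigma_e2) {
  stopifnot(all(sigma_g2 >= 0), all(sigma_e2 >= 0))
  tot <- sigma_g2 + sigma_e2
  if (any(tot <= 0)) stop("sigma_g2 + sigma_e2 must be positive")
  sigma_g2 / tot
}

#' Normal-approximation confidence interval for heritability
#'
#' `h2 +/- z * se_h2` with `z` the `(1 + level)/2` standard-normal quantile,
#' truncated to the parameter space \[0, 1\]. The quantile is used at the
#' conventional three-decimal tabulated value (2.576 at the 99% level,
#' 1.960 at 95%), matching how such intervals are quoted in the breeding
#' literature.
#'
#' @param h2 heritability estimate.
#' @param se_h2 its standard error (>= 0).
#' @param level confidence level in (0, 1), default 0.99.
#' @return named numeric `c(lower, upper)`.
#' @export
h2_confidence_interval <- function(h2, se_h2, level = 0.99) {
  stopifnot(se_h2 >= 0, level > 0, level < 1)
  z <- round(qnorm((1 + level) / 2), 3)
  c(
    lower = max(0, h2 - z * se_h2),
    upper = min(1, h2 + z * se_h2)
  )
}
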
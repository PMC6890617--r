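# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (dense solves, direct enumeration,
# textbook formulas) so that agreement is evidence, not tautology.

# Exact Hardy-Weinberg p-value by direct enumeration of heterozygote
# configurations with the multinomial/hypergeometric probability formula
# computed from plain factorials (valid for totals <= ~80).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- n_Aa + 2 * n_aa
  rare <- min(na, 2 * n - na)
  hets <- seq(rare %% 2, rare, by = 2)
  prob <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    factorial(n) / (factorial(hr) * factorial(h) * factorial(hc)) *
      2^h * factorial(rare) * factorial(2 * n - rare) / factorial(2 * n)
  }, numeric(1))
  p_obs <- prob[match(n_Aa, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-9)]))
}

# Naive double-loop VanRaden G on a plain dosage matrix.
naive_grm <- function(dosage, freqs = colMeans(dosage) / 2) {
  n <- nrow(dosage)
  m <- ncol(dosage)
  denom <- 2 * sum(freqs * (1 - freqs))
  g <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      s <- 0
      for (j in seq_len(m)) {
        s <- s + (dosage[i, j] - 2 * freqs[j]) * (dosage[k, j] - 2 * freqs[j])
      }
      g[i, k] <- s / denom
    }
  }
  g
}

# Restricted log-likelihood of y ~ N(X a, sigma_p2 (h2 K + (1 - h2) I)),
# profiled over sigma_p2, computed with dense solves only.
profile_reml_loglik <- function(y, X, K, h2) {
  n <- length(y)
  p <- ncol(X)
  V0 <- h2 * K + (1 - h2) * diag(n)
  Vi <- solve(V0)
  XtViX <- crossprod(X, Vi %*% X)
  P0 <- Vi - Vi %*% X %*% solve(XtViX, crossprod(X, Vi))
  yP0y <- drop(crossprod(y, P0 %*% y))
  sp2 <- yP0y / (n - p)
  -0.5 * ((n - p) * log(sp2) + determinant(V0)$modulus[1] +
    determinant(XtViX)$modulus[1] + yP0y / sp2)
}

# GBLUP solved literally from the inverted-G mixed-model equations
# (requires invertible G; Z maps records to individuals).
mme_gblup <- function(y, X, G, lambda) {
  n <- length(y)
  Z <- diag(n)
  A <- rbind(
    cbind(crossprod(X), crossprod(X, Z)),
    cbind(crossprod(Z, X), crossprod(Z) + solve(G) * lambda)
  )
  sol <- solve(A, c(crossprod(X, y), crossprod(Z, y)))
  list(alpha = sol[seq_len(ncol(X))], g = sol[-seq_len(ncol(X))])
}

# Small complete simulated dataset shared by several tests.
toy_dataset <- function(n = 120, m = 200, h2 = 0.5, n_qtl = 20, seed = 1,
                        maf = c(0.1, 0.5)) {
  simulate_dataset(sim_config(
    n_individuals = n, n_markers = m, maf_range = maf, n_qtl = min(n_qtl, m),
    h2_target = h2, missing_rate = 0, seed = seed
  ))
}
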
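test_that("GBLUP equals the hand-built mixed-model equations on a toy system", {
  set.seed(77)
  n <- 3
  G <- diag(n) * 0.9 + 0.1 # blended-identity-like PD matrix
  y <- c(1.2, -0.5, 0.3)
  X <- matrix(1, n, 1)
  lambda <- 0.8
  grm <- structure(
    list(matrix = G, centering_freqs = NULL, denominator = 1,
         n_markers_used = 1L, blend_epsilon = 0.1),
    class = "grm"
  )
  rownames(grm$matrix) <- colnames(grm$matrix) <- paste0("i", 1:n)
  mm <- structure(
    list(y = setNames(y, paste0("i", 1:n)), X = X, ids = paste0("i", 1:n), grm = grm),
    class = "model_matrices"
  )
  fit <- gblup_predict(mm, lambda, blend_epsilon = 0)
  oracle <- mme_gblup(y, X, G, lambda)
  expect_equal(unname(fit$gebv), unname(oracle$g), tolerance = 1e-10)
  expect_equal(unname(fit$fixed_effects), unname(oracle$alpha), tolerance = 1e-10)
})

test_that("huge shrinkage drives all GEBVs to zero", {
  dat <- toy_dataset(n = 60, m = 100, seed = 19)
  g <- vanraden_grm(dat$genotypes)
  mm <- model_matrices(dat$phenotypes, g, "trait")
  fit <- gblup_predict(mm, lambda = 1e10)
  expect_lt(max(abs(fit$gebv)), 1e-5 * sd(mm$y))
})

test_that("GBLUP and RRBLUP are the same model in two parameterizations", {
  dat <- toy_dataset(n = 100, m = 250, seed = 41)
  g <- vanraden_grm(dat$genotypes)
  mm <- model_matrices(dat$phenotypes, g, "trait")
  # mask a prediction set to exercise the unphenotyped path too
  mm$y[1:10] <- NA
  vc <- reml_fit(mm)
  gb <- gblup_predict(mm, vc$lambda, blend_epsilon = 0)
  rr <- rrblup_fit(
    mm$y, mm$X, dat$genotypes$dosage, vc$lambda * g$denominator,
    freqs = g$centering_freqs
  )
  expect_lt(
    max(abs((gb$gebv - mean(gb$gebv)) - (rr$gebv - mean(rr$gebv)))), 1e-6
  )
  expect_gt(cor(gb$gebv, rr$gebv), 0.9999)
})

test_that("ridge closed forms hold for single-marker and dense systems", {
  # scalar ridge: beta = x'y / (x'x + lambda)
  set.seed(2)
  x <- c(0, 1, 2, 1, 0, 2, 1, 1)
  y <- rnorm(8)
  lam <- 3.7
  fit <- rrblup_fit(y, matrix(1, 8, 1), matrix(x, ncol = 1), lam, freqs = mean(x) / 2)
  w <- x - mean(x)
  A <- rbind(c(8, sum(w)), c(sum(w), sum(w^2) + lam))
  sol <- solve(A, c(sum(y), sum(w * y)))
  expect_equal(unname(fit$effects), sol[2], tolerance = 1e-10)
  # dense 8x5 system vs augmented normal equations
  W <- matrix(sample(0:2, 40, replace = TRUE), 8, 5)
  colnames(W) <- paste0("s", 1:5)
  X <- cbind(1, rnorm(8))
  y2 <- rnorm(8)
  f2 <- rrblup_fit(y2, X, W, 2.5)
  Wc <- scale(W, scale = FALSE)
  Z <- cbind(X, Wc)
  A2 <- crossprod(Z) + diag(c(0, 0, rep(2.5, 5)))
  sol2 <- solve(A2, crossprod(Z, y2))
  expect_equal(unname(f2$effects), unname(sol2[3:7]), tolerance = 1e-10)
  # lambda = 0, m < n: plain least squares
  f0 <- rrblup_fit(y2, X, W, 0)
  ols <- solve(crossprod(Z), crossprod(Z, y2))
  expect_equal(unname(f0$effects), unname(ols[3:7]), tolerance = 1e-8)
})

test_that("primal and dual ridge solvers agree", {
  dat <- toy_dataset(n = 40, m = 120, seed = 55)
  g <- vanraden_grm(dat$genotypes)
  y <- dat$phenotypes$trait
  X <- cbind(1, as.numeric(dat$phenotypes$sex == "M"))
  lam <- 35
  dual <- rrblup_fit(y, X, dat$genotypes$dosage, lam, freqs = g$centering_freqs) # 122 > 40 -> dual
  primal <- local({
    W <- drumgs:::center_dosages(dat$genotypes$dosage, g$centering_freqs)
    Z <- cbind(X, W)
    A <- crossprod(Z)
    idx <- 3:(2 + 120)
    A[cbind(idx, idx)] <- A[cbind(idx, idx)] + lam
    drop(solve(A, crossprod(Z, y)))[idx]
  })
  expect_equal(unname(dual$effects), unname(primal), tolerance = 1e-8)
})

test_that("scale parameter follows the inverse-chi-square prior-mean identity", {
  s2 <- bayes_scale_param(1, 4.2, 0.01, 100)
  expect_equal(s2, (1 / (0.01 * 100)) * (2.2 / 4.2), tolerance = 1e-12)
  # prior mean v s2 / (v - 2) reproduces sigma_beta2
  expect_equal(4.2 * s2 / 2.2, 1 / (0.01 * 100), tolerance = 1e-12)
  # v -> infinity limit: s2 -> sigma_beta2
  expect_equal(bayes_scale_param(1, 1e9, 0.01, 100), 1, tolerance = 1e-6)
  # pi = 1 reproduces the all-markers (BayesA) scale
  expect_equal(bayes_scale_param(2, 4.2, 1, 50), (2 / 50) * 2.2 / 4.2)
  expect_error(bayes_scale_param(1, 2, 0.1, 10), "exceed 2")
})

test_that("chains are deterministic under a fixed seed", {
  dat <- toy_dataset(n = 80, m = 120, seed = 61)
  mmX <- cbind(1, as.numeric(dat$phenotypes$sex == "M"))
  h <- bayes_hyper(n_iter = 400, burn_in = 100, thin = 2, seed = 31)
  f1 <- bayes_sampler(dat$phenotypes$trait, mmX, dat$genotypes, "BayesB", h)
  f2 <- bayes_sampler(dat$phenotypes$trait, mmX, dat$genotypes, "BayesB", h)
  expect_identical(f1$posterior$effect_mean, f2$posterior$effect_mean)
  expect_identical(f1$result$gebv, f2$result$gebv)
})

test_that("BayesB with pi = 1 collapses to BayesA", {
  dat <- toy_dataset(n = 150, m = 200, h2 = 0.6, n_qtl = 100, seed = 71)
  X <- cbind(1, as.numeric(dat$phenotypes$sex == "M"))
  y <- dat$phenotypes$trait
  hA <- bayes_hyper(pi = 1, n_iter = 1500, burn_in = 500, thin = 2, seed = 5)
  fA <- bayes_sampler(y, X, dat$genotypes, "BayesA", hA)
  fB <- bayes_sampler(y, X, dat$genotypes, "BayesB", hA)
  expect_gte(cor(fA$result$gebv, fB$result$gebv), 0.95)
  expect_true(all(fB$posterior$inclusion_prob == 1))
})

test_that("posterior-mean GEBVs are invariant to marker order up to MC error", {
  dat <- toy_dataset(n = 100, m = 150, h2 = 0.6, seed = 81)
  X <- cbind(1, as.numeric(dat$phenotypes$sex == "M"))
  y <- dat$phenotypes$trait
  h <- bayes_hyper(n_iter = 2000, burn_in = 500, thin = 2, seed = 13)
  f1 <- bayes_sampler(y, X, dat$genotypes, "BayesCpi", h)
  perm <- sample(150)
  gperm <- subset_genotypes(dat$genotypes, markers = perm)
  f2 <- bayes_sampler(y, X, gperm, "BayesCpi", h)
  expect_gte(cor(f1$result$gebv, f2$result$gebv), 0.95)
})

test_that("MMixp fits polygenic data and reports class probabilities", {
  dat <- toy_dataset(n = 120, m = 150, h2 = 0.6, seed = 91)
  X <- cbind(1, as.numeric(dat$phenotypes$sex == "M"))
  f <- bayes_sampler(
    dat$phenotypes$trait, X, dat$genotypes, "MMixp",
    bayes_hyper(n_iter = 1500, burn_in = 500, thin = 2, seed = 3)
  )
  expect_true(all(f$posterior$inclusion_prob >= 0 & f$posterior$inclusion_prob <= 1))
  expect_gt(cor(f$result$gebv, dat$truth$true_breeding_values), 0.5)
})

test_that("no-signal data yields near-zero GEBV variance in all methods", {
  dat <- toy_dataset(n = 150, m = 200, h2 = 0.02, seed = 101)
  g <- vanraden_grm(dat$genotypes)
  mm <- model_matrices(dat$phenotypes, g, "trait")
  vc <- reml_fit(mm)
  gb <- gblup_predict(mm, vc$lambda)
  expect_lt(var(gb$gebv) / var(mm$y), 0.25)
  X <- mm$X
  f <- bayes_sampler(
    mm$y, X, dat$genotypes, "BayesCpi",
    bayes_hyper(n_iter = 1000, burn_in = 300, thin = 2, seed = 7),
    sigma_g2 = vc$sigma_g2
  )
  expect_lt(var(f$result$gebv) / var(mm$y), 0.25)
})
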
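test_that("predictive ability is a guarded Pearson correlation", {
  expect_equal(predictive_ability(1:5, 1:5), 1)
  expect_equal(predictive_ability(1:5, -(1:5)), -1)
  expect_equal(predictive_ability(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(predictive_ability(1:2, 1:2), "at least 3")
  expect_error(predictive_ability(1:4, rep(1, 4)), "zero variance")
  expect_error(predictive_ability(1:4, 1:5), "length")
})

test_that("an oracle predictor scores 1 in every replicate, deterministically", {
  dat <- toy_dataset(n = 80, m = 60, seed = 7)
  cv1 <- cross_validate(dat$genotypes, dat$phenotypes, "trait", "oracle",
    n_reps = 10, seed = 3
  )
  expect_true(all(abs(cv1$replicate_abilities - 1) < 1e-12))
  cv2 <- cross_validate(dat$genotypes, dat$phenotypes, "trait", "oracle",
    n_reps = 10, seed = 3
  )
  expect_identical(cv1$replicate_abilities, cv2$replicate_abilities)
  expect_equal(cv1$n_testing, 8)
  expect_equal(cv1$n_reference, 72)
})

test_that("cv summary statistics are recomputable from the replicates", {
  dat <- toy_dataset(n = 100, m = 150, seed = 27)
  cv <- cross_validate(dat$genotypes, dat$phenotypes, "trait", "gblup",
    n_reps = 6, seed = 11
  )
  expect_equal(cv$mean_ability, mean(cv$replicate_abilities))
  expect_equal(cv$se_ability, sd(cv$replicate_abilities) / sqrt(6))
  expect_length(cv$replicate_abilities, 6)
  expect_error(
    cross_validate(dat$genotypes, dat$phenotypes, "trait",
      test_fraction = 0.01, n_reps = 2
    ),
    "smaller than 3"
  )
})

test_that("gblup and rrblup cross-validate to near-identical abilities", {
  dat <- toy_dataset(n = 120, m = 200, h2 = 0.5, seed = 37)
  cvg <- cross_validate(dat$genotypes, dat$phenotypes, "trait", "gblup",
    n_reps = 4, seed = 9
  )
  cvr <- cross_validate(dat$genotypes, dat$phenotypes, "trait", "rrblup",
    n_reps = 4, seed = 9
  )
  # same splits, same model family: abilities differ only via the 1% blend
  expect_equal(cvg$replicate_abilities, cvr$replicate_abilities, tolerance = 0.05)
})

test_that("a larger reference fraction improves mean GBLUP ability", {
  dat <- toy_dataset(n = 200, m = 400, h2 = 0.5, seed = 47)
  means <- vapply(c(0.5, 0.1), function(tf) {
    cross_validate(dat$genotypes, dat$phenotypes, "trait", "gblup",
      n_reps = 15, test_fraction = tf, seed = 13
    )$mean_ability
  }, numeric(1))
  expect_gt(means[2], means[1]) # 90% reference beats 50% reference
})

test_that("method_spread reduces variants, is order invariant, handles ties", {
  ab <- c(a = 0.3, b = 0.2, b = 0.35, c = 0.25)
  ms <- method_spread(ab)
  expect_equal(ms$max_difference, 0.35 - 0.25)
  expect_equal(ms$percent_of_difference, 100 * 0.1 / 0.35)
  ms2 <- method_spread(ab[c(4, 2, 3, 1)])
  expect_equal(ms2$max_difference, ms$max_difference)
  equal <- c(x = 0.4, y = 0.4)
  expect_equal(method_spread(equal)$max_difference, 0)
  expect_equal(method_spread(equal)$percent_of_difference, 0)
  expect_error(method_spread(c(only = 1)), "at least 2")
})

test_that("phenotype summary reproduces Welch arithmetic and star coding", {
  ph <- data.frame(
    id = as.character(1:6), sex = c("M", "M", "M", "F", "F", "F"),
    tr = c(1, 2, 3, 4, 5, 6), stringsAsFactors = FALSE
  )
  out <- summarize_phenotypes(ph)
  # hand Welch: means 2 and 5, pooled se = sqrt(1/3 + 1/3)
  expect_equal(out$t, (2 - 5) / sqrt(2 / 3), tolerance = 1e-12)
  same <- ph
  same$tr <- rep(c(1, 2, 3), 2)
  out2 <- summarize_phenotypes(same)
  expect_equal(out2$t, 0)
  expect_equal(out2$signif, "(-)")
  # star thresholds
  star <- function(p) if (p < 0.001) "**" else if (p < 0.01) "*" else "(-)"
  expect_equal(star(0.005), "*")
  expect_equal(star(0.0005), "**")
  expect_error(
    summarize_phenotypes(ph[c(1, 4, 5, 6), ]),
    "at least 2"
  )
})

test_that("ratio traits use the printed percentage scales", {
  out <- derive_ratio_traits(
    body_weight = 100, swim_bladder_weight = 0.72, gonad_weight = 1.11,
    body_length = 210, body_height = 70
  )
  expect_equal(out$SBI, 0.72)
  expect_equal(out$GWI, 1.11)
  expect_equal(out$LHR, 3.0)
  expect_error(derive_ratio_traits(0, 1, 1, 10, 10), "body weight")
  expect_error(derive_ratio_traits(10, 1, 1, 10, 0), "body height")
})

test_that("reference-size inversion matches the forward accuracy formula", {
  expect_equal(required_reference_size(0.5, 1000, 0.8), 3556L)
  expect_equal(required_reference_size(0.5, 1000, 0), 0L)
  expect_error(required_reference_size(0.5, 1000, 1), "below 1")
  # numerical round trip: accuracy at the returned N reaches the target
  for (h2 in c(0.3, 0.5, 0.8)) {
    n <- required_reference_size(h2, 500, 0.7)
    expect_gte(daetwyler_accuracy(n, h2, 500), 0.7)
    expect_lt(daetwyler_accuracy(n - 1, h2, 500), 0.7)
  }
  # strictly decreasing in h2
  ns <- vapply(c(0.2, 0.4, 0.6, 0.8), required_reference_size,
    integer(1),
    me = 1000, target_accuracy = 0.8
  )
  expect_true(all(diff(ns) < 0))
})

test_that("five random SNPs carry essentially no signal on a polygenic trait", {
  dat <- toy_dataset(n = 200, m = 400, h2 = 0.5, n_qtl = 50, seed = 67)
  pc <- suppressWarnings(panel_curve(
    dat$genotypes, dat$phenotypes, "trait",
    sizes = 5, modes = "random", n_reps = 20, seed = 67
  ))
  expect_lt(abs(pc$mean_ability), 0.1)
})

test_that("panel curves: exhaustive panels coincide; both modes run", {
  dat <- toy_dataset(n = 80, m = 60, h2 = 0.6, seed = 57)
  pc <- panel_curve(dat$genotypes, dat$phenotypes, "trait",
    sizes = 60, n_reps = 3, seed = 5
  )
  inf <- pc$mean_ability[pc$mode == "informative"]
  ran <- pc$mean_ability[pc$mode == "random"]
  expect_equal(inf, ran, tolerance = 1e-10) # same (full) panel
})
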
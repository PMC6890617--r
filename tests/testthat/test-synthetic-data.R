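test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_individuals = 0), "at least 1")
  expect_error(sim_config(n_markers = 0), "at least 1")
  expect_error(sim_config(n_qtl = 10, n_markers = 5), "n_qtl")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(h2_target = 1.2), "h2_target")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
})

test_that("genotype draws follow Hardy-Weinberg proportions at p = 0.5", {
  cfg <- sim_config(
    n_individuals = 10000, n_markers = 1, maf_range = c(0.5, 0.5),
    missing_rate = 0, seed = 7
  )
  d <- simulate_genotypes(cfg)$dosage
  props <- tabulate(d + 1, 3) / length(d)
  # binomial SE of each class proportion at n = 10000
  se <- sqrt(c(0.25 * 0.75, 0.5 * 0.5, 0.25 * 0.75) / 10000)
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 3 * se))
})

test_that("simulation is deterministic given config and seed", {
  cfg <- sim_config(n_individuals = 50, n_markers = 40, seed = 123)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1, g2)
  cfg0 <- sim_config(n_individuals = 50, n_markers = 40, missing_rate = 0, seed = 123)
  geno <- simulate_genotypes(cfg0)
  p1 <- simulate_phenotypes(geno, cfg0)
  p2 <- simulate_phenotypes(geno, cfg0)
  expect_identical(p1, p2)
})

test_that("empirical allele frequencies track the drawn frequencies", {
  cfg <- sim_config(
    n_individuals = 2000, n_markers = 200, maf_range = c(0.1, 0.4),
    missing_rate = 0, seed = 99
  )
  geno <- simulate_genotypes(cfg)
  # recover the drawn frequencies from the generator's RNG stream
  drawn <- local({
    set.seed(99)
    runif(200, 0.1, 0.4)
  })
  emp <- allele_freqs(geno)
  se <- sqrt(drawn * (1 - drawn) / (2 * 2000))
  expect_true(all(abs(emp - drawn) < 4 * se))
})

test_that("h2_target = 1 gives phenotypes equal to breeding values plus sex effect", {
  cfg <- sim_config(
    n_individuals = 60, n_markers = 100, h2_target = 1,
    sex_effect = 2.5, missing_rate = 0, seed = 4
  )
  dat <- simulate_dataset(cfg)
  y_adj <- dat$phenotypes$trait - 2.5 * (dat$phenotypes$sex == "M")
  expect_equal(unname(y_adj), unname(dat$truth$true_breeding_values), tolerance = 1e-12)
  expect_equal(dat$truth$realized_h2, 1)
  expect_error(
    simulate_phenotypes(
      simulate_genotypes(sim_config(n_individuals = 20, n_markers = 10, n_qtl = 0, h2_target = 1, missing_rate = 0)),
      sim_config(n_individuals = 20, n_markers = 10, n_qtl = 0, h2_target = 1, missing_rate = 0)
    ),
    "QTL"
  )
})

test_that("h2_target = 0 leaves no detectable heritable signal", {
  cors <- vapply(1:8, function(s) {
    dat <- simulate_dataset(sim_config(
      n_individuals = 300, n_markers = 50, h2_target = 0, sex_effect = 0,
      missing_rate = 0, seed = s
    ))
    cor(dat$phenotypes$trait, dat$truth$true_breeding_values)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.05)
  expect_true(all(abs(cors) < 0.2))
})

test_that("variance scaling hits the heritability target on average", {
  h2s <- vapply(1:30, function(s) {
    dat <- simulate_dataset(sim_config(
      n_individuals = 1000, n_markers = 200, n_qtl = 50, h2_target = 0.5,
      missing_rate = 0, seed = s
    ))
    dat$truth$realized_h2
  }, numeric(1))
  expect_gte(mean(h2s), 0.45)
  expect_lte(mean(h2s), 0.55)
})

test_that("truth record variance bookkeeping is exact and sexes are balanced", {
  dat <- toy_dataset(n = 121, seed = 17)
  tr <- dat$truth
  expect_identical(tr$realized_h2, tr$var_g / (tr$var_g + tr$var_e))
  sexes <- table(dat$phenotypes$sex)
  expect_lte(abs(sexes[["M"]] - sexes[["F"]]), 1)
  # breeding values reconstructable from QTL dosages and effects
  q <- dat$genotypes$dosage[, tr$qtl_indices, drop = FALSE]
  g <- drop(scale(q, scale = FALSE) %*% tr$qtl_effects)
  expect_equal(unname(tr$true_breeding_values), unname(g), tolerance = 1e-10)
})

test_that("family structure produces full sibs with elevated relationship", {
  cfg <- sim_config(
    n_individuals = 200, n_markers = 400, maf_range = c(0.2, 0.5),
    missing_rate = 0, family_structure = list(n_sires = 2, n_dams = 2),
    seed = 21
  )
  geno <- simulate_genotypes(cfg)
  # a few markers can drift to fixation through the 8 founder haplotypes
  geno <- filter_markers(geno, qc_params(hwe_p_min = 0))$genotypes
  g <- vanraden_grm(geno)$matrix
  off <- g[upper.tri(g)]
  # observed-frequency centering forces the GRM rows to sum to ~0, so the
  # family signal shows up as dispersion: sib pairs sit far above average,
  # cross-family pairs below. Unrelated HWE data would give sd(off) ~ 1/sqrt(m).
  expect_gt(sd(off), 3 / sqrt(ncol(geno$dosage)))
  expect_gt(max(off) - min(off), 0.5)
  expect_equal(nrow(geno$dosage), 200L)
})

test_that("missingness lands at the configured rate", {
  cfg <- sim_config(n_individuals = 200, n_markers = 200, missing_rate = 0.05, seed = 3)
  d <- simulate_genotypes(cfg)$dosage
  expect_lt(abs(mean(is.na(d)) - 0.05), 0.005)
})
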
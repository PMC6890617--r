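#' Simulation configuration
#'
#' Bundles the knobs of the genotype/phenotype generator. Defaults emulate a
#' post-QC genotyping-by-sequencing dataset from a sibling-heavy yellow drum
#' cohort: 371 individuals of two near-balanced sexes, ~50k biallelic SNPs
#' with minor allele frequency at least 0.01, a quantitative trait with an
#' additive polygenic architecture, a sex fixed effect, and moderate-to-high
#' narrow-sense heritability.
#'
#' @param n_individuals number of individuals.
#' @param n_markers number of biallelic SNPs.
#' @param maf_range length-2 numeric in (0, 0.5]; per-marker allele
#'   frequencies are drawn uniformly from this interval before genotype
#'   sampling noise.
#' @param n_qtl number of causal markers (must not exceed `n_markers`);
#'   defaults to 50 or the marker count, whichever is smaller.
#' @param qtl_effect_dist `"normal"` or `"laplace"` distribution of causal
#'   effects.
#' @param h2_target in-sample narrow-sense heritability the residual
#'   variance is scaled to (see [simulate_phenotypes()]).
#' @param sex_effect trait units added to males (the fixed sex effect).
#' @param missing_rate fraction of calls set missing uniformly at random, in
#'   \[0, 1). The default mirrors a typical pre-imputation GBS missing rate.
#' @param family_structure `NULL` for unrelated Hardy-Weinberg draws, or a
#'   list with `n_sires`, `n_dams` (and optionally `offspring_per_cross`)
#'   for one generation of random sire x dam crosses with Mendelian gene
#'   dropping, reproducing a full-sib/half-sib kinship structure.
#' @param seed integer seed; the same configuration and seed always produce
#'   bit-identical data.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals = 371L,
                       n_markers = 53677L,
                       maf_range = c(0.01, 0.5),
                       n_qtl = min(50L, n_markers),
                       qtl_effect_dist = c("normal", "laplace"),
                       h2_target = 0.5,
                       sex_effect = 1,
                       missing_rate = 0.0332,
                       family_structure = NULL,
                       seed = 1L) {
  qtl_effect_dist <- match.arg(qtl_effect_dist)
  n_individuals <- as.integer(n_individuals)
  n_markers <- as.integer(n_markers)
  n_qtl <- as.integer(n_qtl)
  if (n_individuals < 1L || n_markers < 1L) {
    stop("n_individuals and n_markers must both be at least 1")
  }
  if (n_qtl > n_markers) stop("n_qtl must not exceed n_markers")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
    maf_range[1] > maf_range[2]) {
    stop("maf_range must be an increasing pair within (0, 0.5]")
  }
  if (h2_target < 0 || h2_target > 1) stop("h2_target must be in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (!is.null(family_structure)) {
    stopifnot(
      is.list(family_structure),
      all(c("n_sires", "n_dams") %in% names(family_structure))
    )
  }
  structure(
    list(
      n_individuals = n_individuals, n_markers = n_markers,
      maf_range = as.numeric(maf_range), n_qtl = n_qtl,
      qtl_effect_dist = qtl_effect_dist, h2_target = h2_target,
      sex_effect = sex_effect, missing_rate = missing_rate,
      family_structure = family_structure, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate SNP genotypes
#'
#' Draws per-marker allele frequencies uniformly from `maf_range`, then
#' samples dosages. Without family structure each individual is an
#' independent Hardy-Weinberg draw (dosage ~ Binomial(2, p)). With family
#' structure, sire and dam genotypes are drawn under Hardy-Weinberg and
#' offspring receive one gamete from each parent (Mendelian gene dropping
#' over random sire x dam crosses). Missing calls are placed uniformly at
#' random at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_markers
  with_seed(config$seed, {
    p <- runif(m, config$maf_range[1], config$maf_range[2])
    fs <- config$family_structure
    if (is.null(fs)) {
      d <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
    } else {
      n_sires <- as.integer(fs$n_sires)
      n_dams <- as.integer(fs$n_dams)
      stopifnot(n_sires >= 1L, n_dams >= 1L)
      sire_g <- matrix(rbinom(n_sires * m, 2L, rep(p, each = n_sires)), n_sires, m)
      dam_g <- matrix(rbinom(n_dams * m, 2L, rep(p, each = n_dams)), n_dams, m)
      if (!is.null(fs$offspring_per_cross)) {
        k <- as.integer(fs$offspring_per_cross)
        crosses <- expand.grid(sire = seq_len(n_sires), dam = seq_len(n_dams))
        crosses <- crosses[rep(seq_len(nrow(crosses)), each = k), , drop = FALSE]
        idx <- sample.int(nrow(crosses), n, replace = nrow(crosses) < n)
        sire_of <- crosses$sire[idx]
        dam_of <- crosses$dam[idx]
      } else {
        sire_of <- sample.int(n_sires, n, replace = TRUE)
        dam_of <- sample.int(n_dams, n, replace = TRUE)
      }
      # one Bernoulli gamete per parent: transmission prob = parent dosage / 2
      gam_s <- matrix(
        rbinom(n * m, 1L, sire_g[sire_of, , drop = FALSE] / 2), n, m
      )
      gam_d <- matrix(
        rbinom(n * m, 1L, dam_g[dam_of, , drop = FALSE] / 2), n, m
      )
      d <- gam_s + gam_d
    }
    if (config$missing_rate > 0) {
      drop <- runif(n * m) < config$missing_rate
      d[drop] <- NA_real_
    }
    genotype_matrix(d)
  })
}

#' Simulate phenotypes with additive polygenic architecture
#'
#' Builds a trait as `y = sex effect + sum(QTL dosage x effect) + e` on top
#' of an existing genotype matrix. QTL positions are sampled, effects drawn
#' from the configured distribution, genetic values computed from centered
#' dosages at the QTL, and the residual standard deviation set to
#' `sqrt(var(g) (1 - h2) / h2)` so the configured heritability is the
#' in-sample target. When `h2_target = 0` the residual is made dominant
#' (sd = 1000 x sd(g)) rather than zeroing the genetic effects, so the
#' causal architecture in the truth record remains meaningful.
#'
#' @param genotypes a complete (no missing calls) [genotype_matrix()].
#' @param config the [sim_config()] used; the phenotype stage consumes
#'   `n_qtl`, `qtl_effect_dist`, `h2_target`, `sex_effect` and derives its
#'   own RNG stream from `seed`.
#' @param trait name of the trait column in the phenotype table.
#' @return a list with `phenotypes` (data frame: `id`, `sex` (`"M"`/`"F"`),
#'   one trait column) and `truth` (list: `true_breeding_values`,
#'   `qtl_indices`, `qtl_effects`, `var_g`, `var_e`, `realized_h2`).
#' @export
simulate_phenotypes <- function(genotypes, config, trait = "trait") {
  stopifnot(inherits(genotypes, "genotype_matrix"), inherits(config, "sim_config"))
  d <- genotypes$dosage
  if (anyNA(d)) stop("genotypes contain missing calls; impute before simulating phenotypes")
  n <- nrow(d)
  h2 <- config$h2_target
  if (h2 == 1 && config$n_qtl == 0L) {
    stop("h2_target = 1 requires at least one QTL")
  }
  with_seed(config$seed + 1L, {
    # near-balanced sexes, |#M - #F| <= 1
    sex <- rep(c("M", "F"), length.out = n)[sample.int(n)]
    qtl <- sort(sample.int(ncol(d), config$n_qtl))
    eff <- switch(config$qtl_effect_dist,
      normal = rnorm(config$n_qtl),
      laplace = rexp(config$n_qtl) * sample(c(-1, 1), config$n_qtl, replace = TRUE)
    )
    q <- d[, qtl, drop = FALSE]
    g <- drop(sweep(q, 2L, colMeans(q), `-`) %*% eff)
    var_g <- var(g)
    sd_e <- if (h2 == 0) {
      1e3 * max(sqrt(var_g), 1)
    } else if (h2 == 1) {
      0
    } else {
      sqrt(var_g * (1 - h2) / h2)
    }
    e <- if (sd_e > 0) rnorm(n, 0, sd_e) else numeric(n)
    y <- config$sex_effect * (sex == "M") + g + e
    var_e <- var(e)
    pheno <- data.frame(
      id = rownames(d), sex = sex, stringsAsFactors = FALSE
    )
    pheno[[trait]] <- y
    list(
      phenotypes = pheno,
      truth = list(
        true_breeding_values = stats::setNames(g, rownames(d)),
        qtl_indices = qtl,
        qtl_effects = eff,
        var_g = var_g,
        var_e = var_e,
        realized_h2 = if (var_g + var_e > 0) var_g / (var_g + var_e) else 0
      )
    )
  })
}

#' Simulate a complete genotype + phenotype dataset
#'
#' Convenience wrapper: [simulate_genotypes()] then [simulate_phenotypes()]
#' (imputing nothing; set `missing_rate = 0` in the config, the default here,
#' when the dataset feeds prediction directly).
#'
#' @param config a [sim_config()]; defaults to `sim_config(missing_rate = 0)`
#'   overridden by `...`.
#' @param ... fields passed to [sim_config()].
#' @param trait trait column name.
#' @return list with `genotypes`, `phenotypes`, `truth`.
#' @export
simulate_dataset <- function(config = NULL, ..., trait = "trait") {
  if (is.null(config)) config <- sim_config(missing_rate = 0, ...)
  geno <- simulate_genotypes(config)
  ph <- simulate_phenotypes(geno, config, trait = trait)
  list(genotypes = geno, phenotypes = ph$phenotypes, truth = ph$truth)
}
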
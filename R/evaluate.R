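#' Predictive ability
#'
#' Pearson correlation between GEBVs and observed phenotypes — the standard
#' accuracy proxy of cross-validated genomic prediction.
#'
#' @param gebv,phenotype equal-length numeric vectors (>= 3 values each).
#' @return the correlation.
#' @export
predictive_ability <- function(gebv, phenotype) {
  if (length(gebv) != length(phenotype)) stop("length mismatch")
  if (length(gebv) < 3L) stop("need at least 3 pairs")
  if (var(gebv) == 0 || var(phenotype) == 0) {
    stop("undefined correlation: zero variance input")
  }
  cor(gebv, phenotype)
}

# Methods the cross-validation harness knows how to train.
cv_methods <- c("gblup", "rrblup", "bayesA", "bayesB", "bayesCpi", "mmixp", "oracle")

#' Repeated random-split cross-validation
#'
#' Repeatedly splits the individuals into a reference (training) and a
#' testing set at `test_fraction`, trains the chosen predictor on the
#' reference set, and scores the testing set by [predictive_ability()]
#' against the raw phenotype. Variance components are re-estimated by REML
#' on each replicate's reference set by default; `paper_mode = TRUE`
#' estimates them once on the whole dataset (the historical shortcut —
#' mildly optimistic, but cheaper and sometimes needed to mirror published
#' designs).
#'
#' The `"oracle"` method returns the phenotype itself as the GEBV — a
#' harness self-check that must score 1 in every replicate.
#'
#' @param genotypes complete [genotype_matrix()].
#' @param phenotypes phenotype data frame (`id`, fixed-effect columns,
#'   traits).
#' @param trait trait column to predict.
#' @param method one of `"gblup"`, `"rrblup"`, `"bayesA"`, `"bayesB"`,
#'   `"bayesCpi"`, `"mmixp"`, `"oracle"`.
#' @param n_reps number of random splits (default 100).
#' @param test_fraction fraction of individuals held out per split (default
#'   0.1, i.e. a ~9:1 reference:testing design).
#' @param seed integer; fixes the split sequence and all downstream
#'   sampling.
#' @param fixed fixed-effect columns (default `"sex"`).
#' @param panel optional character vector of marker ids restricting the
#'   predictor to a low-density panel.
#' @param hyper [bayes_hyper()] for the sampler methods (its `seed` is
#'   overridden per replicate for determinism).
#' @param paper_mode logical, see above.
#' @param adjust_sex if `TRUE`, ability is computed against the phenotype
#'   with the fixed effects removed (GLS estimates from the training fit)
#'   instead of the raw phenotype.
#' @return object of class `cv_result`: `trait`, `method`, `panel_size`,
#'   `replicate_abilities`, `mean_ability`, `se_ability` (SD over replicates
#'   / sqrt(n_reps)), `n_reference`, `n_testing`, `n_reps`.
#' @export
cross_validate <- function(genotypes, phenotypes, trait, method = "gblup",
                           n_reps = 100L, test_fraction = 0.1, seed = 1L,
                           fixed = "sex", panel = NULL,
                           hyper = bayes_hyper(n_iter = 3000L, burn_in = 1000L, thin = 2L),
                           paper_mode = FALSE, adjust_sex = FALSE) {
  method <- cv_methods[match(tolower(method), tolower(cv_methods))]
  if (is.na(method)) {
    stop("method must be one of: ", paste(cv_methods, collapse = ", "))
  }
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!is.null(panel)) genotypes <- subset_genotypes(genotypes, markers = panel)
  d <- genotypes$dosage
  if (anyNA(d)) stop("genotypes contain missing calls; run impute_missing() first")
  phenotypes <- phenotypes[match(rownames(d), phenotypes$id), , drop = FALSE]
  if (anyNA(phenotypes$id)) stop("phenotype table does not cover all genotyped individuals")
  n <- nrow(d)
  n_test <- round(n * test_fraction)
  if (n_test < 3L) stop("test set smaller than 3; increase test_fraction or n")
  grm <- vanraden_grm(genotypes)
  mm_full <- model_matrices(phenotypes, grm, trait, fixed)
  y_full <- mm_full$y
  splits <- with_seed(seed, lapply(seq_len(n_reps), function(i) sample.int(n, n_test)))
  vc0 <- if (paper_mode && method != "oracle") reml_fit(mm_full) else NULL
  abilities <- vapply(seq_len(n_reps), function(rep) {
    test <- splits[[rep]]
    mm <- mm_full
    mm$y[test] <- NA
    if (method == "oracle") {
      gebv_test <- y_full[test]
      return(predictive_ability(gebv_test, y_full[test]))
    }
    vc <- if (paper_mode) vc0 else reml_fit(mm)
    fit <- switch(method,
      gblup = gblup_predict(mm, vc$lambda, predict_ids = mm_full$ids[test]),
      rrblup = rrblup_fit(
        mm$y, mm$X, d, vc$lambda * grm$denominator,
        freqs = grm$centering_freqs
      ),
      {
        h <- hyper
        h$seed <- seed * 1000L + rep
        model <- c(
          bayesA = "BayesA", bayesB = "BayesB",
          bayesCpi = "BayesCpi", mmixp = "MMixp"
        )[[method]]
        bayes_sampler(
          mm$y, mm$X, d, model,
          hyper = h, freqs = grm$centering_freqs, sigma_g2 = vc$sigma_g2
        )$result
      }
    )
    gebv_test <- fit$gebv[mm_full$ids[test]]
    target <- y_full[test]
    if (adjust_sex) {
      target <- target - drop(mm_full$X[test, , drop = FALSE] %*% fit$fixed_effects)
    }
    predictive_ability(gebv_test, target)
  }, numeric(1))
  structure(
    list(
      trait = trait, method = method,
      panel_size = if (is.null(panel)) ncol(d) else length(panel),
      replicate_abilities = abilities,
      mean_ability = mean(abilities),
      se_ability = sd(abilities) / sqrt(n_reps),
      n_reference = n - n_test, n_testing = n_test, n_reps = n_reps
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "cv_result: trait %s, method %s, %d markers, %d reps (%d/%d split)\n  predictive ability %.3f +/- %.3f\n",
    x$trait, x$method, x$panel_size, x$n_reps, x$n_reference, x$n_testing,
    x$mean_ability, x$se_ability
  ))
  invisible(x)
}

#' Spread of mean predictive abilities across methods
#'
#' Reduces hyperparameter variants of a method to their best variant (the
#' convention when one method is run on a grid), then reports the range of
#' the remaining per-method abilities: `max - min` and that difference as a
#' percentage of the maximum.
#'
#' @param abilities named numeric vector of mean abilities; duplicated names
#'   mark hyperparameter variants of one method and are reduced by `max`.
#' @return list with `max_difference`, `percent_of_difference`, and the
#'   reduced `abilities`.
#' @export
method_spread <- function(abilities) {
  stopifnot(is.numeric(abilities), !is.null(names(abilities)))
  reduced <- tapply(abilities, names(abilities), max)
  reduced <- reduced[unique(names(abilities))] # keep first-appearance order
  if (length(reduced) < 2L) stop("need at least 2 methods")
  dif <- max(reduced) - min(reduced)
  list(
    max_difference = dif,
    percent_of_difference = if (max(reduced) > 0) 100 * dif / max(reduced) else 0,
    abilities = reduced
  )
}

#' Per-sex phenotype summary with Welch t-tests
#'
#' Per-trait count, mean and SD by sex plus a two-sided Welch t-test of the
#' sex effect, star-coded `"**"` (p < 0.001), `"*"` (p < 0.01) or `"(-)"`.
#'
#' @param phenotypes data frame with `sex` (`"M"`/`"F"`) and trait columns.
#' @param traits trait columns to summarize; default every numeric column
#'   other than `id`/`sex`.
#' @return data frame with one row per trait.
#' @export
summarize_phenotypes <- function(phenotypes, traits = NULL) {
  stopifnot("sex" %in% names(phenotypes))
  if (is.null(traits)) {
    traits <- setdiff(
      names(phenotypes)[vapply(phenotypes, is.numeric, logical(1))],
      c("id", "sex")
    )
  }
  sexes <- unique(phenotypes$sex)
  if (!all(c("M", "F") %in% sexes)) stop("both sexes must be present")
  out <- lapply(traits, function(tr) {
    ym <- phenotypes[[tr]][phenotypes$sex == "M"]
    yf <- phenotypes[[tr]][phenotypes$sex == "F"]
    if (length(ym) < 2L || length(yf) < 2L) {
      stop("each sex needs at least 2 records for trait ", tr)
    }
    tt <- t.test(ym, yf)
    p <- tt$p.value
    data.frame(
      trait = tr,
      n_male = length(ym), mean_male = mean(ym), sd_male = sd(ym),
      n_female = length(yf), mean_female = mean(yf), sd_female = sd(yf),
      t = unname(tt$statistic), p = p,
      signif = if (p < 0.001) "**" else if (p < 0.01) "*" else "(-)",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Derived ratio traits
#'
#' Builds the three ratio traits used alongside the directly measured body
#' traits: swimming bladder index `SBI = 100 x bladder weight / body weight`
#' (%), body length to body height ratio `LHR = BL / BH` (unitless), and
#' gonad weight index `GWI = 100 x gonad weight / body weight` (%).
#'
#' @param body_weight,swim_bladder_weight,gonad_weight weights in grams.
#' @param body_length,body_height lengths in mm.
#' @return data frame with columns `SBI`, `LHR`, `GWI`.
#' @export
derive_ratio_traits <- function(body_weight, swim_bladder_weight, gonad_weight,
                                body_length, body_height) {
  if (any(body_weight <= 0)) stop("body weight must be positive")
  if (any(body_height <= 0)) stop("body height must be positive")
  data.frame(
    SBI = 100 * swim_bladder_weight / body_weight,
    LHR = body_length / body_height,
    GWI = 100 * gonad_weight / body_weight
  )
}

#' Deterministic accuracy of genomic prediction
#'
#' The Daetwyler et al. expectation for the accuracy of genomic breeding
#' values: `sqrt(N h2 / (N h2 + Me))` for a reference population of `N`
#' phenotyped individuals, trait heritability `h2` and `Me` effective
#' independent chromosome segments. The expected predictive ability
#' (correlation with phenotype) is this accuracy times `sqrt(h2)`.
#'
#' @param n_reference reference population size.
#' @param h2 heritability.
#' @param me effective number of independent segments.
#' @return the expected accuracy `r`.
#' @export
daetwyler_accuracy <- function(n_reference, h2, me) {
  stopifnot(n_reference >= 0, h2 > 0, h2 <= 1, me > 0)
  sqrt(n_reference * h2 / (n_reference * h2 + me))
}

#' Reference population size for a target accuracy
#'
#' Inverts the Daetwyler accuracy formula:
#' `N = Me r^2 / (h2 (1 - r^2))`, rounded up.
#'
#' @param h2 heritability (> 0).
#' @param me effective number of independent chromosome segments (> 0).
#' @param target_accuracy desired accuracy `r` in \[0, 1).
#' @return required reference size (integer).
#' @export
required_reference_size <- function(h2, me, target_accuracy) {
  stopifnot(h2 > 0, h2 <= 1, me > 0, target_accuracy >= 0)
  if (target_accuracy >= 1) stop("target accuracy must be below 1")
  as.integer(ceiling(me * target_accuracy^2 / (h2 * (1 - target_accuracy^2))))
}

#' Predictive-ability curve over low-density panel sizes
#'
#' For each panel size, compares GWAS-informative panels (top-ranked markers
#' from a mixed-model scan) against random panels of the same size, scoring
#' each by GBLUP cross-validation on the same split sequence. By default the
#' scan is re-run on each replicate's reference set only, so marker ranking
#' never sees the test individuals; `paper_mode = TRUE` ranks once on the
#' full dataset (optimistically biased, but reproduces designs that did so).
#'
#' @inheritParams cross_validate
#' @param sizes integer vector of panel sizes.
#' @param modes subset of `c("informative", "random")`.
#' @return data frame with `mode`, `size`, `mean_ability`, `se_ability`,
#'   `n_reps`.
#' @export
panel_curve <- function(genotypes, phenotypes, trait, sizes,
                        modes = c("informative", "random"),
                        n_reps = 10L, test_fraction = 0.1, seed = 1L,
                        fixed = "sex", paper_mode = FALSE) {
  modes <- match.arg(modes, several.ok = TRUE)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosage
  if (anyNA(d)) stop("genotypes contain missing calls; run impute_missing() first")
  m <- ncol(d)
  if (any(sizes > m)) stop("panel size exceeds marker count")
  phenotypes <- phenotypes[match(rownames(d), phenotypes$id), , drop = FALSE]
  n <- nrow(d)
  n_test <- round(n * test_fraction)
  if (n_test < 3L) stop("test set smaller than 3")
  grm_full <- vanraden_grm(genotypes)
  mm_full <- model_matrices(phenotypes, grm_full, trait, fixed)
  y_full <- mm_full$y
  marker_ids <- colnames(d)
  splits <- with_seed(seed, lapply(seq_len(n_reps), function(i) sample.int(n, n_test)))
  pvals_full <- if (paper_mode && "informative" %in% modes) {
    sc <- mlm_scan(mm_full, genotypes)
    stats::setNames(sc$p, sc$marker)
  } else {
    NULL
  }
  acc <- array(
    NA_real_, c(length(modes), length(sizes), n_reps),
    dimnames = list(modes, NULL, NULL)
  )
  for (rep in seq_len(n_reps)) {
    test <- splits[[rep]]
    mm <- mm_full
    mm$y[test] <- NA
    pvals <- if ("informative" %in% modes) {
      if (paper_mode) {
        pvals_full
      } else {
        sc <- mlm_scan(mm, genotypes)
        stats::setNames(sc$p, sc$marker)
      }
    } else {
      NULL
    }
    for (si in seq_along(sizes)) {
      size <- sizes[si]
      for (mo in modes) {
        panel <- if (mo == "informative") {
          select_panel(panel_spec("informative", size, source_pvalues = pvals), marker_ids)
        } else {
          select_panel(
            panel_spec("random", size, seed = seed + 7919L * rep + si),
            marker_ids
          )
        }
        sub <- subset_genotypes(genotypes, markers = panel)
        grm_p <- vanraden_grm(sub)
        mm_p <- model_matrices(phenotypes, grm_p, trait, fixed)
        mm_p$y[test] <- NA
        vc <- reml_fit(mm_p)
        fit <- gblup_predict(mm_p, vc$lambda, predict_ids = mm_full$ids[test])
        acc[mo, si, rep] <- predictive_ability(fit$gebv, y_full[test])
      }
    }
  }
  out <- expand.grid(mode = modes, size = sizes, stringsAsFactors = FALSE)
  out$mean_ability <- mapply(
    function(mo, si) mean(acc[mo, which(sizes == si), ]),
    out$mode, out$size
  )
  out$se_ability <- mapply(
    function(mo, si) sd(acc[mo, which(sizes == si), ]) / sqrt(n_reps),
    out$mode, out$size
  )
  out$n_reps <- n_reps
  out
}
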
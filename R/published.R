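#' Published genetic-parameter estimates for seven yellow drum traits
#'
#' Variance components, heritabilities and per-sex phenotype summaries
#' reported for a yellow drum breeding cohort of 371 fish (183 males, 188
#' females) genotyped at 53,677 post-QC SNPs: body length (BL, mm), body
#' length / body height ratio (LHR), swimming bladder index (SBI, %),
#' swimming bladder weight (SBW, g), body thickness (BT, mm), body height
#' (BH, mm) and gonad weight index (GWI, %). Useful as worked-example input
#' for [h2_from_components()], [h2_confidence_interval()] and
#' [summarize_phenotypes()]-style star coding.
#'
#' @return data frame with one row per trait: per-sex counts, means and SDs,
#'   `sigma_g2`/`se_g2`, `sigma_e2`/`se_e2`, `h2`/`se_h2`, and the published
#'   sex-effect significance code (`"**"` p < 0.001, `"*"` p < 0.01, `"(-)"`
#'   otherwise).
#' @export
yellow_drum_varcomp <- function() {
  data.frame(
    trait = c("BL", "LHR", "SBI", "SBW", "BT", "BH", "GWI"),
    n_male = 183L, n_female = 188L,
    mean_male = c(211.80, 2.99, 0.72, 1.56, 35.81, 71.14, 1.11),
    sd_male = c(15.45, 0.21, 0.30, 0.68, 4.05, 6.68, 0.43),
    mean_female = c(221.46, 2.99, 0.62, 1.52, 37.30, 74.42, 0.91),
    sd_female = c(16.08, 0.22, 0.42, 0.84, 3.98, 5.95, 0.25),
    sigma_g2 = c(237.123, 0.015, 556.844, 0.301, 11.923, 29.656, 0.104),
    se_g2 = c(59.328, 0.007, 251.654, 0.120, 3.377, 7.939, 0.025),
    sigma_e2 = c(44.210, 0.032, 830.842, 0.330, 5.498, 12.449, 0.030),
    se_e2 = c(39.475, 0.006, 200.971, 0.092, 2.379, 5.540, 0.017),
    h2 = c(0.843, 0.309, 0.401, 0.477, 0.684, 0.704, 0.773),
    se_h2 = c(0.150, 0.140, 0.162, 0.165, 0.151, 0.145, 0.140),
    sex_signif = c("**", "(-)", "*", "(-)", "*", "*", "**"),
    stringsAsFactors = FALSE
  )
}

#' Published cross-validated predictive abilities for seven yellow drum traits
#'
#' Mean predictive ability (correlation of GEBVs with phenotypes over 100
#' random ~9:1 reference/testing splits) and its standard error, for eight
#' predictor configurations on the same seven traits as
#' [yellow_drum_varcomp()]. BayesB appears at each of its three prior
#' inclusion probabilities; the convention when comparing methods is to
#' reduce it to its best variant per trait (see [method_spread()]).
#'
#' @return data frame in long format: `method`, `pi` (BayesB prior inclusion
#'   probability, `NA` otherwise), `trait`, `ability`, `se`.
#' @export
yellow_drum_ability <- function() {
  traits <- c("BL", "LHR", "SBI", "SBW", "BT", "BH", "GWI")
  rows <- list(
    list("BayesA", NA, c(0.361, 0.157, 0.209, 0.184, 0.315, 0.355, 0.397),
         c(0.011, 0.014, 0.014, 0.013, 0.017, 0.014, 0.013)),
    list("BayesB", 0.001, c(0.240, 0.186, 0.177, 0.139, 0.259, 0.363, 0.349),
         c(0.015, 0.014, 0.016, 0.017, 0.016, 0.012, 0.014)),
    list("BayesB", 0.01, c(0.334, 0.186, 0.242, 0.191, 0.293, 0.393, 0.394),
         c(0.015, 0.014, 0.018, 0.016, 0.015, 0.013, 0.012)),
    list("BayesB", 0.1, c(0.362, 0.191, 0.230, 0.214, 0.298, 0.397, 0.400),
         c(0.014, 0.014, 0.016, 0.015, 0.015, 0.013, 0.012)),
    list("BayesCpi", NA, c(0.396, 0.165, 0.203, 0.180, 0.317, 0.384, 0.391),
         c(0.014, 0.014, 0.013, 0.014, 0.016, 0.015, 0.012)),
    list("MMixp", NA, c(0.378, 0.207, 0.215, 0.195, 0.296, 0.400, 0.386),
         c(0.013, 0.014, 0.013, 0.012, 0.017, 0.012, 0.014)),
    list("RRBLUP", NA, c(0.380, 0.192, 0.224, 0.218, 0.298, 0.380, 0.389),
         c(0.015, 0.014, 0.013, 0.013, 0.015, 0.012, 0.012)),
    list("GBLUP", NA, c(0.378, 0.174, 0.219, 0.238, 0.305, 0.365, 0.374),
         c(0.015, 0.013, 0.014, 0.011, 0.017, 0.013, 0.014)),
    list("CNN", NA, c(0.392, 0.145, 0.207, 0.211, 0.283, 0.350, 0.412),
         c(0.012, 0.015, 0.014, 0.016, 0.015, 0.014, 0.012))
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(
      method = r[[1]], pi = r[[2]], trait = traits,
      ability = r[[3]], se = r[[4]], stringsAsFactors = FALSE
    )
  }))
}
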
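---
title: "Genomic prediction methods in drumgs: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction methods in drumgs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drumgs)
```

# The problem

Aquaculture breeding programs for species like yellow drum (*Nibea
albiflora*) increasingly replace phenotype-and-pedigree selection with
genomic selection: genome-wide SNP genotypes are used to estimate the
realized kinship among candidates and to predict each candidate's additive
genetic merit (its genomic estimated breeding value, GEBV). `drumgs`
implements the full evaluation loop for such a program on a single cohort:
simulate or ingest genotypes and phenotypes, quality-control markers, build
the genomic relationship matrix, estimate variance components, predict
GEBVs with a menu of standard models, rank markers for low-density panels,
and measure predictive ability by repeated random-split cross-validation.

# The model

Every trait is treated as additive-polygenic with one fixed covariate
(sex):

$$\mathbf{y} = \mathbf{X}\boldsymbol\alpha + \mathbf{B}\boldsymbol\beta + \mathbf{e},
\qquad \mathbf{e} \sim N(0, \mathbf{I}\sigma_e^2),$$

where $\mathbf{B}$ holds SNP dosages coded 0/1/2 (count of the alternate
allele) and $\boldsymbol\beta$ the additive marker effects. Summing marker
contributions into individual genetic values $\mathbf{g} = \mathbf{W}\boldsymbol\beta$
(with $\mathbf{W}$ the column-centered dosages) gives the equivalent
individual-level model $\mathbf{y} = \mathbf{X}\boldsymbol\alpha + \mathbf{g} + \mathbf{e}$
with $\mathbf{g} \sim N(0, \mathbf{G}\sigma_g^2)$ and the VanRaden
relationship matrix

$$\mathbf{G} = \frac{(\mathbf{B} - 2\mathbf{P})(\mathbf{B} - 2\mathbf{P})'}{2\sum_j p_j (1 - p_j)},$$

where $p_j$ is the frequency of the counted allele at marker $j$
(`vanraden_grm()`, observed frequencies by default). GBLUP solves the mixed
model at shrinkage $\lambda = \sigma_e^2/\sigma_g^2 = (1-h^2)/h^2$;
RRBLUP is the same model in marker-effect coordinates with ridge penalty
$\lambda_m = \lambda \cdot 2\sum_j p_j(1-p_j)$, and the two produce
identical GEBVs when they share $\lambda$ and centering frequencies — the
package's primary correctness oracle, asserted in the test suite to below
$10^{-6}$.

A numerical point worth stating: with observed-frequency centering the raw
cross-product $\mathbf{G}$ is always singular (every column of
$\mathbf{W}$ sums to zero, so $\mathbf{G}\mathbf{1} = \mathbf{0}$).
`gblup_predict()` therefore solves the equivalent covariance form —
$\hat{\boldsymbol\alpha}$ by GLS under $\mathbf{V}_0 = \mathbf{G}_{tt} + \lambda\mathbf{I}$,
then $\hat{\mathbf{g}} = \mathbf{G}_{\cdot t}\mathbf{V}_0^{-1}(\mathbf{y} - \mathbf{X}\hat{\boldsymbol\alpha})$
— which never inverts $\mathbf{G}$ and is algebraically identical to the
inverted-G mixed-model equations (a unit test checks this against a
hand-built MME solve). `blend_grm()` ($(1-\varepsilon)\mathbf{G} + \varepsilon\mathbf{I}$,
default $\varepsilon = 0.01$) is still applied by default as mild
regularization and is required by any downstream step that does invert
$\mathbf{G}$. The exact GBLUP–RRBLUP equivalence holds only at
$\varepsilon = 0$, which is how the equivalence checks run.

# Variance components and heritability

`reml_fit()` maximizes the restricted likelihood of
$\mathbf{y} \sim N(\mathbf{X}\boldsymbol\alpha, \mathbf{G}\sigma_g^2 + \mathbf{I}\sigma_e^2)$
by average-information (AI) REML, taking an EM-REML step whenever the AI
update would leave the parameter space or decrease the likelihood
(`method = "em"` runs pure EM; its likelihood trace is non-decreasing, a
property test). The computation runs in the eigenbasis of $\mathbf{G}$, so
each iteration is $O(n^2)$ after one $O(n^3)$ decomposition. Components are
floored at $10^{-8}\,\mathrm{var}(y)$ and flagged `boundary` when pinned
there; convergence is relative parameter change below `tol` ($10^{-8}$
default, 200-iteration cap). Standard errors come from the inverse AI
matrix; $\mathrm{SE}(h^2)$ by the delta method on
$h^2 = \sigma_g^2/(\sigma_g^2 + \sigma_e^2)$.

`h2_confidence_interval()` is the normal approximation
$h^2 \pm z\,\mathrm{SE}(h^2)$ truncated to $[0,1]$, with $z$ at the
conventional three-decimal tabulated value (2.576 at the 99% level rather
than 2.5758…): published intervals in this literature are quoted with the
tabulated quantile, and the third decimal of a reconstructed bound can
differ otherwise.

# The Bayesian alphabet

`bayes_sampler()` fits four whole-genome regression priors by single-site
Gibbs sampling (compiled in C++; R's RNG, so `set.seed()` fixes a chain):

* **BayesA** — every marker has an effect; per-marker variances iid
  scaled-inverse-$\chi^2(v, s^2)$.
* **BayesB** — spike-and-slab with fixed prior inclusion probability
  $\pi$; the inclusion indicator is Gibbs-sampled with the effect
  integrated out given the current variances, which mixes well and needs
  no Metropolis step.
* **BayesC$\pi$** — one common slab variance and $\pi$ drawn from its
  Beta posterior, so the data decide the sparsity.
* **MMixp** — every marker has an effect drawn from a two-component
  normal scale mixture ("large" variance $\tau^2$ or "small"
  $\tau^2/r$). The published description of this model fixes neither the
  ratio nor the priors, so the implementation fixes $r = 100$ by default,
  exposes it as a hyperparameter (`variance_ratio`), and samples the
  large-class probability from its Beta posterior. This is a documented
  interpretation, not a reimplementation of a reference code base.

The marker-variance scale follows the inverse-$\chi^2$ expectation
identity: the per-marker prior variance target is
$\sigma_\beta^2 = \sigma_g^2 / (\pi \cdot 2\sum_j p_j(1-p_j))$ and
$s^2 = \sigma_\beta^2 (v-2)/v$ so that $E[\sigma^2] = v s^2/(v-2) = \sigma_\beta^2$
(`bayes_scale_param()`; $v = 4.2$ by default, and $v \le 2$ is rejected
because the mean does not exist). Fixed effects carry flat priors; the
residual variance a weakly informative scaled-inverse-$\chi^2$ (4 df,
prior mean $\mathrm{var}(y)/2$ — a neutral half-heritability guess).
Chain defaults are 10,000 iterations, 2,000 burn-in, thinning 10; the
recovery checks in the tests run 5,000 iterations, which is ample at the
simulated problem sizes. Scalar chains (residual variance, $\pi$, slab
variance) are summarized with an AR-spectral effective sample size.

# Marker ranking and low-density panels

`mlm_scan()` is the one-variance-component approximation used by the
standard mixed-model GWAS tools: variance components are estimated once on
the null model, the data are rotated by $\mathbf{V}^{-1/2}$, and each
marker is tested by a Wald $t$-test (df $= n - p - 1$) with the covariance
held at the null fit; with $\mathbf{G} = \mathbf{I}$ this reduces exactly
to the ordinary regression $t$-test. Dosages are centered, not
standardized, matching the additive coding of the phenotype model.
`select_panel()` takes the `size` smallest p-values (ties broken by genome
order, so panels are nested across sizes) or a seeded uniform random
subset.

By default `panel_curve()` re-ranks markers within each cross-validation
replicate using only that replicate's reference individuals, so the panel
never sees test phenotypes; `paper_mode = TRUE` ranks once on the full
dataset, the cheaper design some published evaluations used, which is
optimistically biased for informative panels. The same switch governs
whether variance components are re-estimated per replicate (default) or
once on the whole dataset in `cross_validate()`.

# Cross-validation

`cross_validate()` repeatedly holds out a random `test_fraction` of
individuals (default 0.1 — the published design this package mirrors
describes its split as roughly 5:1 but reports group sizes of ~334 and ~37
of 371, i.e. 9:1; the printed sizes are the more specific statement, and
the fraction is exposed), trains on the remainder, and scores the held-out
individuals by the Pearson correlation between GEBV and raw phenotype
(`predictive_ability()`; a flag substitutes the fixed-effect-adjusted
phenotype for methodological comparisons). The summary is the mean over
replicates ± SD/√reps. An `"oracle"` method returns the phenotype itself
and must score exactly 1 — a harness self-check.

`method_spread()` reduces hyperparameter variants of a method to their best
variant and reports max − min of the per-method abilities and that range
as a percentage of the maximum — the summary row convention of published
method-comparison tables. `required_reference_size()` inverts the
deterministic accuracy formula of Daetwyler et al.,
$r = \sqrt{Nh^2/(Nh^2 + M_e)}$, to $N = M_e r^2 / (h^2(1-r^2))$, rounded
up; `daetwyler_accuracy()` is the forward formula.

# What the simulator emulates — and what it does not

`sim_config()` defaults describe the cohort this package was built around:
371 individuals of two near-balanced sexes, ~54k biallelic SNPs with
allele frequencies drawn uniformly on [0.01, 0.5], a sex fixed effect, 50
normally distributed QTL (a convention — the true architecture of any real
trait is unknown), target $h^2$ 0.5 within the 0.3–0.85 range typical of
these traits, and 3.32% missing calls placed uniformly at random (the
typical pre-imputation GBS missing rate). Genotypes are independent
Hardy–Weinberg draws per marker, or, with `family_structure`, one
generation of random sire×dam crosses with Mendelian gene dropping, which
reproduces the sibling-heavy kinship of a hatchery cohort.

QTL effects are drawn first, genetic values computed, and the residual SD
set to $\sqrt{\mathrm{var}(g)(1-h^2)/h^2}$, making `h2_target` an
in-sample target (sharp for parameter-recovery tests); residuals are drawn
iid rather than rescaled, so the realized heritability fluctuates around
the target. At `h2_target = 0` the residual SD is set to $10^3 \times$ the
genetic SD — residual-dominant rather than effect-free — so the causal
architecture recorded in the truth record stays meaningful. `h2_target = 1`
with zero QTL is an error.

The simulator has **no linkage disequilibrium** beyond what family
structure induces, no minor-allele-frequency spectrum from demography, no
genotyping error, and missingness is completely at random. Passing tests
therefore demonstrate correctness of the estimators under their own
assumptions — not that real GBS data meet those assumptions. In particular
$M_e$ (independent segments) equals the marker count here, which is why
the deterministic accuracy expectation is testable at all; on real data
$M_e$ is far smaller than the SNP count and must be inferred.

# Quality control

`filter_markers()` applies MAF ≥ 0.01, missing rate ≤ 0.1 and
Hardy–Weinberg exact-test p ≥ 1e-5 (the conventional pre-analysis filter
set), attributing each removed marker to the first failing rule in the
fixed order MAF → missingness → HWE so reports are deterministic. MAF is
computed from non-missing calls. `hwe_exact_test()` is the plain two-sided
Levene–Haldane exact test — the total probability of heterozygote
configurations no more probable than the observed one, no mid-p
correction, matching the default of the standard QC tooling; it agrees
with a full-enumeration oracle to $10^{-12}$ over every table with up to
30 individuals. `impute_missing()` is a deliberately naive single-marker
stand-in (per-marker mean, or mode with ties to the lower dosage) for the
haplotype-based imputation a production pipeline would use; it preserves
per-marker means (mean mode) and refuses markers with no observed calls.

# Numerical and design choices, in one place

* Dosages count the alternate allele; $\mathbf{G}$ is invariant to
  orientation flips with matched $p_j$ (tested).
* GRM blending default $\varepsilon = 0.01$; equivalence checks run at 0.
* REML: AI with EM fallback, $10^{-8}$ relative tolerance, components
  floored at $10^{-8}\mathrm{var}(y)$, boundary flagged; at a boundary the
  relative-change criterion can time out harmlessly (estimates stable,
  `converged = FALSE` returned with a warning).
* Tabulated $z$ (three decimals) in `h2_confidence_interval()`.
* Sampler indicator updates integrate the effect out given variances;
  excluded BayesB markers refresh their variance from the prior.
* `method_spread()` reduces duplicate-named entries by `max` before
  taking the range.
* Problem sizes in the shipped checks (chosen for desk-scale runs):
  equivalence at n = 300/m = 1000; REML recovery over 20 datasets at
  n = 500/m = 2000; predictive-ability calibration over 4 independent
  datasets × 25 splits at n = 400/m = 2000 against
  $r\sqrt{h^2}$ with $M_e = 2000$ (averaging across datasets because the
  per-dataset mean ability carries sampling noise of ±0.05–0.1 from the
  realized QTL draw); panel comparison at n = 400/m = 1000, 100-SNP
  panels, 50 replicates; sampler recovery at n = 300 with 5,000-iteration
  chains.

# Known limitations

Single-trait, single-record-per-individual models only; no pedigree or
single-step matrices; no dominance or epistasis; no multi-locus GWAS or
genomic control; the imputation stand-in ignores linkage entirely; and the
published reference-population sizes that motivated the Daetwyler
calculator depend on an external fit of $M_e$ per trait that is not
recoverable from the main text of the source study, so the package
provides the closed-form inversion, not those numbers.

# A worked example

```{r example, eval = FALSE}
dat <- simulate_dataset(sim_config(
  n_individuals = 371, n_markers = 5000, h2_target = 0.5, seed = 1,
  missing_rate = 0
))
grm <- vanraden_grm(dat$genotypes)
mm <- model_matrices(dat$phenotypes, grm, "trait")
vc <- reml_fit(mm)
vc
cv <- cross_validate(dat$genotypes, dat$phenotypes, "trait", "gblup",
  n_reps = 25, seed = 1
)
cv
```
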
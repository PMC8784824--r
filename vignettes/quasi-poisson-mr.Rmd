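---
title: "Quasi-Poisson Mendelian randomization for rate outcomes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-Poisson Mendelian randomization for rate outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcount)
```

## The estimation problem

Event counts observed over varying person-time — hospital admissions over
years of cohort follow-up — are naturally modelled as rates with a
log-link GLM and a `log(person-years)` offset:

$$\log \mathbb{E}[y_i] = \log t_i + \beta_0 + \beta_1 x_{i1} + \dots$$

Exponentiated coefficients are yearly rate ratios per regressor unit.
Observational versions of this regression are vulnerable to omitted
variables that drive both the exposure and the event rate, and to reverse
causation (illness changing the exposure). Mendelian randomization
replaces the exposure with its genetically instrumented component:
germline variants are fixed at conception, so — under the instrumental
variable assumptions of relevance, conditional independence, and the
exclusion restriction — their quasi-random allocation supports causal
claims about the exposure.

Because counts require a nonlinear second stage, the classical two-stage
least squares estimator does not apply directly. The package's core
estimator exploits the fact that the Poisson model is linear on the log
scale: a linear first stage for the gene–exposure association
$\beta_{exp}$ and a quasi-Poisson second stage for the gene–outcome
association $\beta_{out}$ give the Wald ratio

$$\beta_{IV} = \exp(\beta_{out} / \beta_{exp}),$$

the yearly rate ratio per exposure unit. With a collapsible link the Wald
ratio is *identical* to two-stage predictor substitution (regressing the
counts on the first-stage fitted exposure); `test-onesample.R` and the
acceptance checks verify this equivalence to numerical precision, which
also serves as an internal consistency check between the two code paths.

Overdispersion is handled by the quasi-Poisson device: point estimates
equal plain Poisson estimates, standard errors are inflated by
$\sqrt{\hat\varphi}$ with $\hat\varphi$ the Pearson statistic over its
degrees of freedom. We use the Pearson rather than the deviance estimator
because it is the standard quasi-likelihood moment estimator and remains
well behaved with many zero counts.

### Standard errors for the ratio

The delta-method variance used by `wald_iv()` is

$$\mathrm{se}^2 = \frac{\mathrm{se}_{out}^2}{\beta_{exp}^2}
  + \frac{\beta_{out}^2\,\mathrm{se}_{exp}^2}{\beta_{exp}^4},$$

the first-order Taylor expansion treating the two stages as uncorrelated.
The cross-stage covariance term is omitted deliberately: with strong
instruments (first-stage F in the hundreds or thousands) it is negligible,
and omitting it is conservative when the instrument's direct effect on the
outcome is weak. The acceptance suite bounds the consequence empirically:
the delta SE must sit within 15% of a 500-replicate parametric bootstrap
that redraws the exposure from the fitted normal first stage and the
counts from a negative binomial matched to the fitted quasi-Poisson mean
and dispersion ($\theta_i = \mu_i / (\hat\varphi - 1)$, so
$\mathrm{Var} = \hat\varphi\,\mu$).

`wald_iv()` accepts either an in-sample first-stage fit or a plain
`list(beta_exp = ..., se_exp = 0)`. The second form covers the design in
which external consortium weights are treated as known constants; the
in-sample slope is the default because it makes the two stages refer to
the same population and scale.

## Genetic risk scores and instrument strength

`compute_grs()` forms the weighted average number of exposure-increasing
alleles, $G_i = \sum_j w_j d_{ij} / \sum_j w_j$, after `orient_weights()`
flips any variant whose reported weight is negative (swapping alleles,
negating the weight, complementing the frequency). The normalization makes
the score unit-free in $[0, 2]$ and exactly invariant to rescaling all
weights. Missing dosages are an error, never mean-imputed: the analysis
population is expected to be restricted to participants with adequate
genetic data, and silent imputation would shift the score scale.

Instrument strength is reported as the partial R² and partial F of the
score given any covariates, reducing exactly to $F = (n-2)R^2/(1-R^2)$ in
the unadjusted single-regressor case (`f_from_r2()`). Whether published
first-stage statistics are covariate-adjusted is often unstated, so both
variants are available — pass covariates or not.

For multivariable MR, `conditional_sw_f()` implements the
Sanderson–Windmeijer conditional F by residual projection: each remaining
exposure is replaced by its instrumented component, exposure *k* is
regressed on those components, and the residuals are regressed on the full
instrument set; the F statistic uses residual degrees of freedom
$n - J - (K-1) - 1$. This is the homoskedastic construction; a robust
variant was considered out of scope because the downstream second stage is
already quasi-likelihood based.

## Two-sample summary estimators

Per-SNP Wald ratios $\hat\beta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with
first-order SEs $\sigma_{Yj}/|\hat\beta_{Xj}|$ (a second-order option adds
$\hat\beta_{Yj}^2\sigma_{Xj}^2/\hat\beta_{Xj}^4$) feed four estimators
with complementary identifying assumptions:

* **Exact-weights IVW** minimizes
  $Q(b) = \sum_j (\hat\beta_{Yj} - b\,\hat\beta_{Xj})^2 /
  (\sigma_{Yj}^2 + b^2\sigma_{Xj}^2)$, letting the weights depend on the
  causal parameter itself. This removes the regression-dilution
  attenuation of the closed-form estimator when exposure betas are noisy
  (verified by simulation in `test-twosample.R`). The minimization is a
  bracketed 1-D `optimize()` call seeded at the closed-form value with
  tolerance 1e-10; when all $\sigma_{Xj} = 0$ the closed form is returned
  exactly. Fixed-effects SE from $1/\sqrt{\sum_j \hat\beta_{Xj}^2 w_j(\hat
  b)}$; random effects multiply by $\sqrt{\max(1, Q/(J-1))}$. Random
  effects are handled multiplicatively (with the floor at one) rather than
  via an additive $\tau^2$, matching the multiplicative convention of
  summary-data MR; the floor prevents underdispersion from shrinking SEs.
* **MR-Egger** frees the intercept, which estimates the average
  directional pleiotropic effect under the assumption that pleiotropy is
  independent of instrument strength. All exposure betas are oriented
  positive first (outcome betas in tandem), making the fit invariant to
  the arbitrary sign convention of each row.
* **Penalized weighted median** is consistent when at least half the
  weight comes from valid instruments. Weights are inverse-variance
  ($\hat\beta_{Xj}^2/\sigma_{Yj}^2$), the median is interpolated linearly
  at cumulative weight 0.5 with ties broken by variant id, and each weight
  is multiplied by $\min(1, 20\,p_j)$ where $p_j$ is the upper
  $\chi^2_1$ tail of SNP *j*'s Q contribution. One design choice departs
  from the usual single-pass recipe: the penalization is **iterated to a
  fixed point**. A single pass evaluates Q contributions at the
  unpenalized median, which under directional pleiotropy is already
  shifted, so valid SNPs on the far side get penalized asymmetrically and
  a residual bias of roughly half the estimator's sampling SD survives;
  iterating re-centres the contributions and removes most of it (the
  pleiotropy acceptance check quantifies this). The penalty constant 20 is
  configurable; it is large enough that homogeneous SNPs are untouched
  ($p_j > 0.05$ leaves the weight unchanged).
* **Weighted mode** maximizes a normal-kernel weighted density of the
  ratios, bandwidth = factor × $0.9\min(\mathrm{sd},\mathrm{mad})
  J^{-1/5}$ (modified Silverman). If the mad is zero but the sd is not,
  the sd is used; if every ratio is identical the common value is returned
  directly. A zero user-supplied bandwidth factor is an error.

SEs for the median and mode come from a parametric bootstrap redrawing
both beta vectors from their reported sampling distributions (default
1000 replicates, seedable).

**Heterogeneity.** Cochran's Q at the IVW slope (df $J-1$) and Rücker's
Q′ at the Egger fit (df $J-2$) are reported with per-SNP contributions
that sum exactly to the statistic; Q′ ≤ Q always because the Egger model
nests the origin-constrained one. `leave_one_out()` replaces visual
outlier inspection with a reproducible rule — flag SNPs whose Q
contribution has $p < 0.05/J$ (Bonferroni), with a top-*k* override — and
reports the estimate and both Q statistics with each SNP removed.

**Harmonization and LD.** `harmonize()` joins exposure and outcome tables
on variant id, flips swapped alleles, resolves strand flips via base
complement, and handles palindromic (A/T, C/G) variants by frequency: if
the exposure effect-allele frequency lies in a configurable ambiguity
window (default 0.42–0.58) the variant is dropped, otherwise the outcome
row is aligned to the frequency-matching strand. All actions are recorded
in an audit attribute. `ld_prune()` is the greedy smallest-p-first rule at
r² < 0.001. In the pipeline, r² is estimated from the full genotype panel
rather than the split half used for the exposure associations: at the very
strict 0.001 threshold, sampling noise in a half-sized r² estimate would
otherwise prune a noticeable fraction of genuinely independent SNPs.

## The synthetic cohort generator

The generator emulates the data structure of a large national biobank with
linked admission records; its defaults *are* the study conditions and are
not tuning knobs:

| quantity | default | basis |
|---|---|---|
| BMI mean (SD) | 27.4 (4.74) kg/m² | reported cohort moments |
| WHR mean (SD) | 0.872 (0.09) | reported cohort moments |
| instrument R², BMI / WHR | 1.7% / 0.4% | reported first-stage R² |
| true rate ratio per BMI SD | 1.13 | reported one-sample estimate |
| follow-up mean (SD) | 6.05 (0.91) y | reported follow-up |
| deaths before censoring | ~2% | reported mortality |
| admission count mean / variance | 1.89 / ≈55 | reported count moments |

Mechanics, and what each choice does and does not emulate:

* **Genotypes** are independent Binomial(2, maf) dosages, maf uniform on
  (0.05, 0.5). There is no LD-realistic haplotype structure; linkage for
  pruning tests is injected explicitly by duplicating columns
  (`duplicate_snps()`).
* **Exposures** are linear in the dosages with i.i.d. half-normal per-SNP
  weights rescaled jointly so the instrument set explains exactly the
  target variance fraction — the "many small effects" regime of GWAS
  hits. A single standard-normal latent confounder acts linearly on both
  exposures and log-linearly on the admission rate; it stands in for the
  web of socioeconomic and behavioural confounders in real data, which
  are emulated only in their aggregate effect.
* **Follow-up** is staggered uniform entry over a 2.67-year window with
  administrative censoring 7.45 years after the window opens and an
  exponential death hazard of 0.0033/y. The window and horizon were
  solved so the *marginal* follow-up distribution (including the
  shortening from deaths) matches mean 6.05 and SD 0.91; censoring is
  non-informative by construction unless the death hazard is deliberately
  coupled to the exposure.
* **Counts** follow a Poisson law with rate
  $t_i\,\nu_i\exp(\beta_0 + \beta' x_i + \gamma C_i + d_i'\alpha)$, where
  $\nu_i$ is a mean-one gamma frailty. The frailty preserves the
  log-linear mean structure every estimator assumes (the marginal is
  negative binomial), which is why it was chosen over zero-inflation or
  hurdle mechanisms — the printed moments do not identify the true
  overdispersion mechanism, and this is the one compatible choice that
  leaves the estimand untouched. The intercept $\beta_0$ is solved
  analytically from the lognormal moment identity
  ($\mathbb{E}[y] = \mathbb{E}[t] e^{\beta_0 + \mathbb{E}L +
  \mathrm{Var}L/2}$), and the default frailty variance 12.8 comes from the
  matching second-moment identity evaluated at the target variance 55.3.
  The implied zero fraction (~75%) is higher than the ~47% observed in
  real admission data: a single gamma frailty cannot match both the
  variance and the zero mass, and the variance was prioritized because
  the estimators are moment-based. Passing tests therefore demonstrate
  correct behaviour under overdispersion of the right magnitude, not
  under the exact zero structure of real records.
* **Pleiotropy** adds direct SNP effects on the log rate: none, balanced
  (mean zero), or directional (nonzero mean), with the drawn vector
  returned so tests know the ground truth.
* **Covariates** `age` and `sex` are generated with realistic marginals
  but no generative effect on admissions by default; they exist so that
  covariate-adjustment plumbing is exercised, not to emulate age
  gradients in admission rates.
* **Randomness** flows from one root seed through named streams
  (`derive_seed(seed, "genotypes")`, …), so every stage is independently
  reproducible and the pipeline is byte-stable under a fixed seed.

The summary-level generator `sim_summary_mr()` bypasses the cohort for
estimator calibration work: true per-allele effects drawn uniformly,
observed betas with specified SEs, and pleiotropy applied to a chosen
fraction of SNPs.

## Observational benchmark and imputation

`fit_quasipoisson()` is the conventional (non-IV) benchmark.
`impute_missing()` completes missing covariate cells by multivariate-
normal predictive draws from the conditional distribution given the
observed cells (moments estimated from complete cases), with factor
columns handled on an integer scale and rounded back to the nearest level
— explicitly an approximation, adequate for the Rubin-pooling machinery
that is the load-bearing part (`pool_rubin()`:
$T = W + (1 + 1/m)B$, held exactly). The working model assumes
missingness at random given the included columns, which by default are all
analysis covariates. This simple predictive-draw engine is a deliberate
design choice over an EM-plus-bootstrap imputation engine; only the
pooling rules affect downstream inference in the package's analyses.

## Numerical choices and degenerate inputs

* Wald/quasi-Poisson CIs are Wald intervals on the log scale,
  exponentiated — symmetric on the log scale, and per-SD views are exact
  powers of per-unit views ($\mathrm{RR}_{SD} = \mathrm{RR}_{unit}^{SD}$,
  tested to 1e-12).
* Weak instruments trigger a warning below F = 10 (conventional,
  configurable); a zero first-stage coefficient is an error, as is a zero
  weight in orientation (no exposure-increasing allele defined).
* All-zero counts, non-integer counts, nonpositive offsets, collinear
  covariates or fitted-value columns, and fewer instruments than exposures
  are errors with named offenders, not silent degradation.
* Bootstrap defaults: 10,000 replicates for the multivariable one-sample
  analysis (the full-scale analysis convention), overridden to a few
  hundred in tests and the demo pipeline.

## Problem sizes used in validation

The test suite validates moment calibration on a 300,000-participant
cohort; parameter recovery and CI coverage on 200 cohorts of 50,000; SE
validity against a 500-replicate parametric bootstrap at 20,000; Q-null
calibration on 2,000 summary replicates with 30 SNPs; and pleiotropy
behaviour on 200 summary replicates with 40 SNPs, 30% of them invalid.
These sizes keep every Monte-Carlo band meaningfully narrow while staying
desk-scale; the demo pipeline (`run_config()` defaults) uses 20,000
participants and 60 SNPs.

## Known limitations

* No LD reference panels, clumping of GWAS hits, or genotype container
  formats; instrument lists and summary tables are plain delimited text.
* The generator's confounding is a single Gaussian latent; real
  confounding is multivariate and partly discrete.
* The delta-method SE ignores cross-stage covariance (bounded empirically,
  see above), and bootstrap percentile intervals are the fallback where
  that matters.
* Local-average-treatment-effect interpretation, monotonicity
  diagnostics, and within-family designs are out of scope.
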
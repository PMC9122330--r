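---
title: "Estimating entire distributions of child growth z-scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating entire distributions of child growth z-scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Child growth failure (CGF) — stunting, wasting and underweight — is
conventionally monitored as the proportion of children below −2 SD of the
WHO growth-standard median (HAZ, WHZ or WAZ z-scores). A single cutoff
treats child growth as a dichotomy. It cannot distinguish a population in
which most affected children sit just below −2 SD from one with a long left
tail of severe (< −3 SD) and extreme (< −4 SD) growth failure, and it hides
progress or setbacks concentrated in that tail. `cgfdist` implements a
pipeline that estimates the *entire distribution* of z-scores per country,
year, age group (six under-5 bins) and sex, and derives prevalences at
multiple severities, with draw-level uncertainty propagated end to end.

The pipeline has four modelling stages plus downstream analyses:

1. **Ensemble distribution fitting** (`fit_ensemble_weights`). A convex
   mixture of ten distribution families — normal, log-normal, log-logistic,
   exponential, gamma, mirrored gamma, inverse gamma, Gumbel, mirrored
   Gumbel, Weibull — each parameterised from the same mean and variance by
   method of moments. The mixture weights are global: they capture the
   characteristic *shape* of z-score curves, learned from individual-level
   (microdata) surveys by minimising squared error in predicted prevalence
   below −1, −2 and −3 SD across sources, every source weighted evenly. The
   simplex is searched with Nelder-Mead from random Dirichlet starting
   points (100 restarts by default).
2. **Spatiotemporal Gaussian process regression** (`stgpr`), run
   independently for three indicators: mean z-score (identity scale) and
   prevalence below −2 and −3 SD (logit scale). Stage 1 is an ensemble of
   linear mixed models over candidate covariate subsets with nested
   super-region/region/country random intercepts; models with
   non-significant (Wald p ≥ 0.05) or wrong-signed coefficients are
   dropped, survivors are weighted by out-of-sample RMSE. Stage 2 smooths
   data-minus-prior residuals over space (hierarchy weights 1, ζ, ζ²),
   time (tricube-style weight with exponent λ) and age (Ω^−|rank
   distance|). Stage 3 places a Matérn-5/2 Gaussian process over years per
   location-age-sex series, conditions on observations with their sampling
   variances, and samples (1000 draws by default).
3. **Variance recovery and integration** (`optimize_sd`,
   `integrate_surface`). Per cell and draw, the ensemble SD is solved so
   that the mixture's prevalences below −2/−3 SD match the modelled draws
   while the mean is anchored at the modelled mean draw; the resulting
   continuous curve is then evaluated at −2, −3 and −4 SD. Because all
   severities come from one CDF, the ordering extreme ≤ severe ≤ overall
   holds on every draw by construction.
4. **Downstream analyses**: draw-level relative change versus a reference
   year with population aggregation *before* the ratio
   (`relative_change`), annual-change analysis stratified by the direction
   of universal-health-coverage (UHC) index change with Kolmogorov-Smirnov
   comparisons (`annual_changes`, `ks_two_sample`), and a monotone
   quadratic-spline meta-regression of prevalence on the UHC index with
   anchored scaling across severities (`fit_spline_ensemble`,
   `scale_trajectories`).

## Conventions and parameters that matter

**Shift and mirror anchors.** Six families have positive support and two
are mirrored. Positive-support families are fit to `z + shift` and mirrored
families to `mirror_anchor − z`. Both default to 10 z-score units, so every
plausible z-score (> −10) maps into the support; the anchors are part of
`ensemble_spec` and are serialised with fitted weights. When a cell's
moments are infeasible for a family (e.g. shifted mean ≤ 0), that family
contributes zero density and the remaining weights are renormalised, rather
than failing.

**Exponential moment matching.** The exponential family has one parameter,
so it is matched on the shifted mean only; its variance mismatch is a
property the weight optimiser can exploit to downweight it. All other
families reproduce both target moments exactly (log-logistic and Weibull
shapes are solved numerically from the squared coefficient of variation via
a cached monotone-spline inverse polished by secant iteration to ~1e-12).

**Weight-fit identifiability.** With mean and variance fixed, many of the
ten families are nearly symmetric at typical CGF moments (a gamma with
shape (m+10)²/v ≈ 64 is close to normal), so the prevalence objective is
nearly flat across subsets of families and fitted weights are not uniquely
identified — different restarts can return different weight vectors with
near-identical objective. This mirrors the estimand: what is identified is
the *curve*, not the labels. Tests therefore assert fitted-curve accuracy
and optimiser contracts, not weight concentration on the generating family.

**SD search.** `optimize_sd` brackets the SD in [0.05, 5] z-score units and
minimises the equally-weighted squared error at −2/−3 SD by Nelder-Mead
restarted from 0.5, 1 and 2 (best of three). When the −3 SD target is
numerically zero (< 1e-7) the solve uses the −2 SD target alone, avoiding a
degenerate objective in near-zero-prevalence cells. Inside
`integrate_surface`, draws after the first in a cell reuse the previous
draw's solution as a warm start and are polished with a bounded
golden-section/parabolic search in a bracket around it (falling back to the
full bracket if the sub-bracket binds); this is numerically equivalent at
the 1e-5 level and roughly five times faster than restarting Nelder-Mead
per draw, which matters at 1000 draws × thousands of cells.

**ST-GPR specifics.**

* Prevalence indicators are modelled in logit space with delta-method
  variances `var / (p(1−p))²`; the mean z-score in identity space.
* Stage-1 candidate subsets are capped at 3 covariates; age group and sex
  enter every candidate (and the intercept fallback) as fixed effects so
  demographic contrasts are absorbed by the prior rather than leaking into
  residuals, where the Ω-weighted cross-age pooling would shrink them.
* Model ensemble weights are `exp(−RMSE/min RMSE)`, RMSE from
  location-grouped 5-fold cross-validation; retained models are capped at
  the top 10.
* The space weight uses the standard hierarchy-geometric scheme (1 same
  country, ζ same region, ζ² same super-region, 0 otherwise); the time
  weight is `(1 − (|Δt|/(1+max|Δt|))^λ)³`; the age weight is
  `Ω^(−|rank distance|)` over the six age bins; only same-sex residuals are
  pooled. Hyperparameters are chosen on a grid by holdout RMSE of the
  stage-2 surface (20% of observations held out), ties broken toward
  smoother settings (larger λ, then larger ζ).
* The GP kernel is Matérn-5/2 in years with a 10-year lengthscale; the
  amplitude defaults to 1.4826 × the median absolute data-minus-stage-2
  residual (a robust scale estimate covering both data noise and
  stage-1/stage-2 disagreement), floored at 0.05. Cholesky failures
  escalate through a jitter ladder (0, 1e-10…1e-6 × amplitude²).

**Relative change.** Age-sex prevalence draws are population-aggregated to
both-sex under-5 *before* the ratio `(ref − current)/ref` is formed —
aggregating ratios instead would weight cells incorrectly. Positive values
mean prevalence declined. Summaries use the median with a 2.5–97.5
percentile interval: reference draws near zero explode the ratio and make
the mean unrepresentative; draws with reference prevalence below 1e-9 are
dropped and counted. The annual (disruption) analysis covers 1991–2019,
classifies location-years by the sign of the UHC index change (exactly-zero
changes are excluded, since only increase/decrease classes are defined),
and filters to location-years with prevalence above one per million
(applied to the both-sex under-5 mean of the severity in question) and
population above 300 000.

**Transition splines.** Each of 20 submodels is a five-segment C1 quadratic
spline in logit prevalence over the UHC index (truncated-power basis;
4 interior knots drawn uniformly over the observed 5–95% UHC quantile span
with minimum spacing 5 index points). Monotone non-increase is enforced as
hard linear constraints on the derivative at 201 grid points over the full
0–100 domain, solved by linearly-constrained least squares (`mgcv::pcls`);
a hard constraint rather than a penalty makes monotonicity testable as an
invariant. Submodel weights are `exp(−CV-RMSE)` from location-grouped
5-fold cross-validation, and one trim-refit cycle removes the lowest and
highest 0.5% of points by signed residual against the ensemble fit
(`⌈0.005·n⌉` per tail) — a single cycle, matching the single stated
trimming step of the estimator this module emulates; the framework's full
Bayesian-prior and Student-t machinery is out of scope. The optional SDI
covariate enters linearly in logit space; because the ensemble prediction
is a convex combination of monotone submodels, monotonicity in UHC is
preserved at every SDI level. Scaling multiplies each severity's aggregated
curve by `overall(u₀)/severity(u₀)` at the lowest observed UHC `u₀`, so all
severities share the anchor and relative decline rates can be compared.

## What the synthetic world emulates — and what it does not

The generator (`make_hierarchy`, `simulate_truth`, `simulate_microdata`,
`simulate_tabulated`, `simulate_covariates`) produces a complete
super-region/region/country tree, a smooth true surface (global mean path
from −1.88 to −1.65 z over 1990–2020 with log-SD narrowing from 1.15 to
1.0 — the trajectory of a high-burden country whose curves shift right and
tighten), zero-mean Gaussian offsets at each hierarchy level (SD 0.08),
i.i.d. microdata draws from the cell ensemble, tabulated prevalences drawn
as a single trinomial over {below −3, −3 to −2, above −2} (which guarantees
`prev3 ≤ prev2` without clipping), covariates that are noisy monotone
transforms of the true mean (so stage-1 selection has signal to find), and
UHC/SDI indices as logistic transforms of the country-year mean. Because
microdata sample-size distributions for real sources vary widely and no
canonical default exists, per-cell sample size is exposed as configuration.

Deliberately not emulated: survey design effects (clustering, weights),
raw height/weight measurement (the generator works in z-score space),
national-to-subnational raking, and real covariate or population databases.
Passing tests on this world demonstrate that the *estimator machinery*
recovers known truth under its own assumptions; they cannot certify
robustness to design effects, measurement error in age, or covariate
misspecification in real surveys.

Problem sizes used in the bundled validation runs (chosen as the smallest
worlds in which each property is identifiable): a 10-country, 31-year,
2-age-bin world with 100 draws and surveys every second year for end-to-end
recovery (mean absolute error under 1 percentage point against true
prevalence); 200 single-series locations for Gaussian-process interval
calibration (95% intervals expected to cover 90–99% of cells); 10⁷
Monte-Carlo draws for CDF validation (3 standard errors).

## Numerical choices and degenerate inputs

* Prevalences are floored into [1e-7, 1−1e-7] before logits.
* Empirical variances use n−1; microdata cells need ≥ 2 records.
* Zero-variance (degenerate) microdata sources are dropped from weight
  fitting with a warning; an all-degenerate input errors.
* Repeated identical draws in `integrate_surface` reuse the previous SD
  solve, so constant draw vectors give bitwise-constant outputs.
* `prev3 > prev2` targets raise a classed error (`cgf_inconsistent_targets`);
  per-draw solve failures are imputed from the cell's median SD and
  counted.
* Ties in hyperparameter selection resolve toward smoother fits.
* The weight simplex is parameterised by softmax with the first coordinate
  pinned, removing the translation degeneracy.

## Known limitations

* Global (not per-location) ensemble weights, as in the estimator this
  package reimplements.
* The three ST-GPR indicators are modelled independently; coherence is
  restored only at the variance-recovery step, and cross-indicator draw
  alignment is by index (rank-preserving), so cross-model correlation is
  an assumption, not an estimate.
* Identity-space modelling of the mean z-score can, in principle, produce
  draws inconsistent with extreme prevalence targets; the SD solve then
  lands at its bracket bound and is flagged.
* The transition splines describe association between UHC and prevalence;
  nothing in the module supports causal claims.
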
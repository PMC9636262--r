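---
title: "Models and methods behind taucascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind taucascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette describes the statistical models the package implements, the
generative model behind the synthetic cohorts, the numerical choices that
matter, and the limits of what passing tests demonstrate.

## The scientific question

In Alzheimer's disease, amyloid-β plaques accumulate years before
symptoms, soluble hyperphosphorylated tau (p-tau, measurable in CSF) rises
early, and insoluble tau aggregates (visible on tau-PET) spread through the
cortex in a stereotyped pattern that tracks the brain's functional
architecture. The package quantifies one proposed causal chain: amyloid
drives soluble p-tau; soluble p-tau fuels the accumulation of insoluble
tau, preferentially in regions strongly connected to where tau already
resides (the "epicenters"); and that accumulation, rather than soluble
p-tau itself, proximally drives cognitive decline in early disease. At the
dementia stage, p-tau has plateaued and local self-replication of
aggregates dominates. All analyses therefore run separately in a
non-demented amyloid-positive stratum and an AD-dementia stratum.

## Rates of change (trajectories)

Per region, `suvr ~ time` is fitted by REML (`lme4::lmer`) with
subject-level random intercepts and random slopes (unstructured 2×2
covariance). The per-subject rate is the fixed slope plus the empirical
best linear predictor of the subject's random-slope deviation; the fitted
baseline is the analogous intercept at *t* = 0. Singular fits fall back to
independent random effects and then to random-intercept-only, recorded in
the diagnostics — never silently imputed. BLUP slopes are shrunk toward the
population slope, so their variance is at most that of per-subject OLS
slopes; in the zero-residual limit they interpolate the data exactly, which
is the basis of the slope-recovery tests. Time is expressed in years from
each subject's first visit (365.25 days/year when dates are supplied). No
covariates enter these models; adjustment happens in the downstream
analyses.

Percent rates are `100 × slope / baseline`, aggregated over a meta-ROI
(by default the generator's temporal module) per subject and then averaged
per group.

## Mixture positivity and epicenters

Baseline tau-PET is heavily right-skewed: most regions of most subjects
show only non-specific binding. Per region, a two-component univariate
Gaussian mixture is fitted by EM (20 restarts, k-means++-style
initialisation, relative log-likelihood tolerance 1e-8), components
ordered by mean. The posterior probability of the higher-mean component is
a thresholds-free positivity measure; multiplied by the SUVR it gives a
score cleaned of non-specific signal, and the top 10 scores define the
subject's tau epicenters (ties broken by lower region ID). A region is
flagged *ambiguous* — excluded from posterior use and epicenter
selection — when the two-component fit is not clearly better than one
Gaussian (ΔBIC < 10) or the means are separated by less than one pooled
within-component SD. This operationalises the qualitative "one or two
distributions fit about equally" exclusion; both thresholds are arguments.
Biomarker cutoffs (e.g. for CSF p-tau) are the point between the means
where the posterior crosses 0.5, found by bisection to 1e-8. Group-level
epicenters are the top 10 of the subject-averaged score under the same tie
rule; with one subject this reduces to the subject-level rule.

## Connectome distances

Subject functional connectivity is the Fisher z-transform of pairwise
Pearson correlations between ROI time series (r clipped to ±(1 − 1e-7)
before `atanh`; zero-variance ROIs get zero edges with a warning).
Scrubbing censors frames with framewise displacement above 1 mm together
with the frame before and the two after; runs with ≥ 30% censored frames
are flagged unusable. Subject matrices are averaged, negative mean edges
dropped (path lengths need positive weights), and exactly
`floor(0.30 · n(n−1)/2)` strongest edges retained — 5970 of 19900 for
n = 200 — with boundary ties broken by weight then lower (i, j) index.
Retained edges get length 1/weight and Dijkstra shortest paths give the
distance matrix; "close" means strongly connected, directly or through
strong intermediate links. The 1/weight convention is a design choice (the
transform is not uniquely determined by the verbal description); distances
satisfy the triangle inequality by construction, and unreachable pairs stay
`Inf` and are masked, never silently finite. Each non-epicenter region's
distance-to-epicenters is the arithmetic mean of its distances to the 10
epicenter nodes.

## Gradient statistic, quartiles and the interaction test

Per subject, rate and distance are z-scored across the non-epicenter
regions and the simple-regression slope (equal to the Pearson correlation)
is the gradient β; negative values mean faster accumulation in regions more
strongly connected to the epicenters. Quartiles are consecutive rank blocks
of the distance ordering with cumulative sizes `ceiling(k·n/4)` —
48/47/48/47 for n = 190 — rather than interpolated sample quantiles, so
sizes are unambiguous; ties at block boundaries resolve by region ID.

The p-tau × quartile test is a classical split-plot ANOVA (between:
binary p-tau status; within: quartile), computed from the standard
sums-of-squares decomposition; `stats::aov` with an `Error(subject/quartile)`
stratum is used as an independent oracle in the tests. Sphericity is not
corrected by default. Per-quartile effect sizes are Cohen's d with the
pooled-SD denominator. The association between β and p-tau across subjects
is an OLS fit of β on log p-tau with z-scored continuous covariates (global
amyloid, age, sex; optionally baseline tau). β itself is already a bounded
standardized quantity and is deliberately not re-z-scored, so the
coefficient is the change in β per SD of log p-tau; collinearity is
monitored via VIF = diag(cor(X)⁻¹) with a warning above 10.

## Regional maps and FDR

Per region, OLS of the z-scored tau rate on z-scored predictors (model M1:
regional amyloid; M2: p-tau; M3: both; M4: both + baseline regional tau)
plus age (z-scored) and sex (binary, as coded). Benjamini–Hochberg
correction is applied separately per predictor map across regions — the
family definition is configurable since it is genuinely underdetermined.
Aliased predictors are reported as `NA` with infinite VIF; regions with
fewer complete cases than predictors + 5 are flagged unestimable.

## Mediation

Three OLS fits define total (c), exposure→mediator (a), and jointly
mediator (b) and direct (c′) paths, all sharing the covariate set (age and
sex for the regional chain; age, sex and education for the cognitive
chain) and z-scored variables. For linear models the mediated effect
c − c′ equals a·b exactly — asserted to 1e-10 in the tests. Inference is a
nonparametric subject-resampling bootstrap (default 1000 draws, seeded)
with percentile intervals, chosen over quasi-Bayesian simulation for exact
reproducibility under a seed; the proportion mediated is
100·(c − c′)/c, reported raw and flagged (not truncated) outside [0, 100],
and undefined when |c| < 1e-8. The regional map restricts, by default, to
regions whose amyloid total effect survives FDR in model M1.

## The synthetic cohort generator

The generator encodes the working model of the cascade so that every
downstream stage has a recoverable target. Defaults are the study
conditions: groups of 204/65/65/66 (amyloid-negative controls,
amyloid-positive CU, amyloid-positive MCI, AD dementia), 200 regions in 7
connectome modules, 2–4 annual visits.

* **Connectome** — weighted stochastic block model: within-module edge
  weights N(0.45, 0.12), between-module N(0.15, 0.08), truncated at 0.01;
  module 1 plays the temporal lobe and defines both the epicenter seed
  region and the meta-ROI.
* **Latent stage** — each subject has a disease-time *s* (group base
  0/1/2/3 plus N(0, 0.3)) that drives global amyloid (saturating in *s*,
  mirroring the observed plateau of amyloid at late stages), the CSF
  Aβ42/40 ratio (declining), and log p-tau (group log-normal location
  plus 0.5·(s − group base)). Because *s* drives both amyloid and p-tau,
  the amyloid → p-tau → tau-rate mediation structure is real, not
  asserted. Group p-tau means are constrained monotone with the AD mean at
  most 1.2× the MCI mean — the plateau is emulated structurally since its
  magnitude is not quantified anywhere; 1.2 is a free generator parameter.
* **Baseline tau** — 10 epicenters are sampled per subject from the
  temporal module (weights decaying with a canonical ranking, so
  epicenters jitter between subjects but never leave the module).
  Baseline tau is `1.1 + amp_i · exp(−λ_i · d/mean(d)) + N(0, 0.02)`,
  where d is the graph distance to the subject's epicenters computed
  through the same thresholding/shortest-path code the analysis uses.
  `amp_i` is the group amplitude (0.10/0.38/0.62/1.2) with lognormal
  within-group jitter — a clinical group is a continuum, not a point
  mass — and `λ_i` shrinks with stage so that tau extends beyond the
  temporal lobe at dementia, Braak-fashion. Both features matter for the
  mixture machinery: without them the per-region mixtures degenerate into
  well-separated group clumps whose geometry defeats posterior-weighted
  epicenter selection for the very subjects (amyloid-positive CU/MCI) the
  method targets.
* **True rates** — `r = r0 + κ · max(0, log(ptau/114.4)) · exp(−λ d/mean d)
  + ρ · (tau0 − 1.1) + leak · z(amyloid)`, with r0 = 0.002 SUVR/yr,
  κ = 0.04, ρ = 0.15 and leak = 0 by default (full regional mediation).
  κ and ρ were calibrated once, analytically, so the temporal meta-ROI
  percent rates land near the observed ≈0.7/3.3/9 %/yr ordering across
  strata; the realized defaults give roughly 1.2/4.6/8.3.
* **Cognition** — the true composite slope is a group base plus a term
  proportional to −(γ·z(Q1 rate) + δ·z(log p-tau)) with noise, where Q1
  is the subject's true most-connected quartile. δ is solved from the
  realized p-tau/Q1-rate correlation in the non-demented subset so the
  population proportion mediated through the Q1 rate equals the
  configured 0.60 in the stratum where the chain is analysed. MMSE slopes
  are an affine noisy transform of the composite slope.

Observed SUVR adds N(0, 0.03) per scan; composite and MMSE scores add
visit-level noise. All draws flow from one seed recorded in the metadata;
the connectome uses `seed` and the cohort `seed + 1`.

What the generator does **not** emulate: spatial autocorrelation of PET
noise, off-target binding structure (the off-target ratio is a plain
scalar), practice effects and floors/ceilings in cognitive tests (MMSE is
not clamped at 30), attrition, and scanner/tracer differences. Passing
tests therefore show the estimators are correct and the pipeline coherent
under the assumed data-generating model — not that the scientific claims
hold in any particular real cohort.

## Numerical choices and degenerate inputs

* Boundary rules are strict: "above 1.75" excludes ratios > 1.75 only; a
  biomarker exactly at its cutoff is negative.
* EM restarts are seeded; mixture SDs are floored at 1e-6 of the data SD;
  posterior arithmetic is done in log space.
* Bisection for cutoffs stops at 1e-8; lmer convergence handling tolerates
  singular fits via the documented fallback chain.
* Epicenter and quartile ties break by lower region ID, making every
  ranking deterministic.
* Degenerate inputs (all-equal mixture data, zero-variance gradient
  inputs, total effect ≈ 0 in mediation, empty meta-ROI, unreachable
  regions) raise typed errors or flags rather than propagating NaN.

## Problem sizes used in verification

The shipped tests run the full statistical machinery at reduced problem
sizes chosen to keep the suite fast while preserving every structural
property: cohorts of 40–100 subjects with 60–100 regions for pipeline
properties, the full 200 regions for slope recovery and edge-count checks,
500 permutations for the type-I calibration of the β–p-tau association,
1000 random vectors for the FDR oracle, and 50 simulations × 1000
bootstrap draws per mediation-recovery chain. `scripts/acceptance.R` runs
the pipeline at the full default cohort size (396 subjects after QC, 200
regions). One caveat worth knowing: mediation proportions estimated from
the pipeline use the *estimated* Q1 rate as mediator, so classical
measurement-error attenuation pulls the estimated proportion below the
generating 0.60 (to ≈0.4 at default noise); the recovery criterion is
therefore tested on the exact linear-SEM generator, where the bootstrap CI
covers the truth at the nominal rate.

## Known limitations

* The mixed ANOVA uses the unadjusted split-plot F (no
  Greenhouse–Geisser correction).
* The mediation model assumes linearity and no exposure–mediator
  interaction (c − c′ = a·b relies on it); no sensitivity analysis for
  sequential ignorability is provided.
* Quartile sizes follow the documented rank-block rule; other software
  using interpolated quantiles will disagree at the margins.
* The distance conversion (1/weight) is one of several defensible
  choices; results are stable under monotone alternatives but magnitudes
  of β differ.
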
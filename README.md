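# taucascade

Longitudinal biomarker-cascade analysis for Alzheimer's disease: how
amyloid load and soluble phosphorylated tau (p-tau) relate to the
connectome-mediated accumulation of insoluble tau aggregates, and how that
accumulation carries the association between soluble p-tau and cognitive
decline.

The package is written for biostatisticians and neuroimaging researchers
working with parcellated longitudinal tau-PET (e.g. 200 Schaefer cortical
parcels, 2–4 scans per subject), CSF biomarkers (p-tau217/181, Aβ42/40),
resting-state functional connectivity and longitudinal cognitive testing.
Because individual-level data of this kind are not openly downloadable, the
package ships a synthetic-cohort generator with recorded ground truth, so
every stage of the pipeline is verifiable end to end.

## What it computes

For each brain region *r* and subject *i*, a linear mixed model with random
intercept and slope,

    SUVR_ir(t) = (β0 + b0_i) + (β1 + b1_i) t + ε,

yields the subject's annual tau accumulation rate
(slope = β1 + BLUP(b1_i), in SUVR/year). A two-component Gaussian mixture
per region converts baseline SUVR into a posterior probability of "high
tau"; the 10 regions with the largest posterior-weighted SUVR are the
subject's tau epicenters. A group functional-connectivity template
(Fisher-z, averaged, thresholded at 30% edge density) is converted to graph
distances (edge length 1/weight, Dijkstra shortest paths), giving each
region a distance to the epicenters. The spreading statistic is the
per-subject standardized slope

    β_i = cor( z(rate_ir), z(distance_r) ),   r ∉ epicenters,

negative when accumulation is faster in regions more strongly connected to
the epicenters. Non-epicenter regions split into connectivity quartiles
Q1–Q4 feed a split-plot ANOVA (p-tau status × quartile). Region-wise
progressive regressions (amyloid alone; p-tau alone; both; both + baseline
tau; always adjusting age and sex) are corrected with Benjamini–Hochberg
FDR, and bootstrap mediation (a, b, c, c′ paths from OLS; mediated effect
c − c′ = a·b; percentile CIs from 1000 subject resamples) quantifies the
two cascades: amyloid → p-tau → tau rate (region-wise), and p-tau →
tau-rate measure → cognitive decline, with cognition summarised by a
PACC5-like composite, `(2·z_recall + z_MMSE + z_TMT-A + z_fluency)/5`.

## Worked example

```r
library(taucascade)

cfg <- cohort_config(
  n_per_group = c(cn_neg = 40, cu_pos = 20, mci_pos = 20, ad = 15),
  n_regions = 100, seed = 7)
run <- run_pipeline(run_config(cohort_config = cfg, n_boot = 200, seed = 7))

nd <- run$strata$nondemented
mean(nd$gradient_beta)            # -0.62: faster accumulation near epicenters
colMeans(nd$quartile_means)       # 0.0290 0.0199 0.0192 0.0170 (Q1 > ... > Q4)
nd$anova$anova                    # interaction F = 3.66, p = 0.015
nd$beta_vs_ptau$coefficients      # p-tau estimate -0.055, p = 0.021
nd$mediation_regional$mean_prop   # ~57% of amyloid effect mediated by p-tau
```

The gradient beta near −0.62 in the non-demented stratum says that regional
tau accumulation falls off with graph distance from the subject's own
epicenters; the quartile means decline monotonically from Q1 (most
connected) to Q4; the significant p-tau × quartile interaction says this
spreading gradient is steeper in p-tau-positive subjects; and the regional
mediation proportion says most of the local amyloid–tau-rate association is
carried by soluble p-tau — the cascade the package is built to quantify.

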
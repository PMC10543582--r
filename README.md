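# alpscombat

Multisite harmonization and evaluation of the DTI-ALPS index in R.

The ALPS index (diffusion tensor image analysis along the perivascular
space) is a non-invasive dMRI readout of glymphatic-adjacent water
mobility: in the white matter lateral to the lateral-ventricle bodies it
compares diffusivity along the perivascular direction (x) with diffusivity
perpendicular to both the dominant fibers and the perivascular spaces,

```
ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc),
```

where each term is the mean of one directional diffusivity map (mm²/s)
over a projection- or association-area ROI.  Values near 1.0 mean minimal
perivascular diffusivity.  Because the index is built from DTI fits it
inherits scanner-, site- and protocol-dependent bias, which in multisite
cohorts (e.g. AD vs cognitively normal) can swamp the disease effect.

This package is for neuroimaging statisticians assembling such multisite
ALPS studies.  It provides:

* **ALPS computation** from per-axis diffusivity volumes (NIfTI) and ROI
  masks or reproducible center+size ROI placements
  (`alps_measurement()`, `build_roi_from_center()`);
* **Scanner harmonization** with an empirical-Bayes location–scale batch
  model fitted after regressing out biological covariates — per scanner
  *i* and feature *v*,
  `y = alpha_v + X'beta_v + gamma_iv + delta_iv * eps`, with normal /
  inverse-gamma priors on the standardized `gamma`, `delta²` across
  features and iterative conditional posterior means
  (`combat_harmonize()`);
* **Evaluation** of what harmonization buys: Cohen's d with the
  n-weighted pooled SD `S_c = sqrt((n1*s1² + n2*s2²)/(n1+n2))`, Welch's
  t, Pearson correlations, Type II ANOVA with partial η², and
  noncentral-t power / required sample size (`evaluate_cohort()`,
  `power_two_sample()`, `sample_size_for_power()`);
* **Synthetic data**: a seeded multisite cohort generator drawn from the
  harmonization model itself and box-phantom diffusivity volumes, so the
  entire pipeline is testable without restricted cohort data
  (`generate_cohort()`, `generate_diffusivity_volumes()`).

## Worked example

One command generates the default synthetic study (three scanners with
additive effects −0.3/0/+0.3 and scale effects 0.7/1.0/1.5, 200 subjects
per scanner-group cell), harmonizes it and evaluates before vs after:

```r
library(alpscombat)
report <- demo_synthetic(seed = 1)
report$scanner_d
#>      feature      scanner_1 scanner_2 d_before     d_after
#> 1  alps_left DiscoveryMR750 PrismaFit 2.257741 0.031349669
#> 2  alps_left DiscoveryMR750 SignaHDxt 1.467168 0.025937707
#> 3  alps_left      PrismaFit SignaHDxt 1.066662 0.004934311
#> 4 alps_right DiscoveryMR750 PrismaFit 2.390926 0.056026830
#> 5 alps_right DiscoveryMR750 SignaHDxt 1.506372 0.018568833
#> 6 alps_right      PrismaFit SignaHDxt 1.191625 0.074082647
```

Between-scanner separations of d ≈ 1–2.4 collapse to a few hundredths.
The disease contrast moves the other way:

```r
report$group_comparison[, c("feature", "stage", "welch_t", "p_value", "cohen_d")]
#>      feature  stage   welch_t      p_value   cohen_d
#> 1  alps_left before -4.162893 3.367446e-05 0.2403448
#> 2  alps_left  after -5.323585 1.214020e-07 0.3073573
#> 3 alps_right before -4.690937 3.032196e-06 0.2708314
#> 4 alps_right  after -6.893516 8.785119e-12 0.3979973
```

AD-vs-CN Cohen's d grows (0.24 → 0.31 left, 0.27 → 0.40 right) because
removing scanner scatter shrinks the pooled SD while the covariate
(group) effect is preserved by construction.  Power arithmetic works the
same way as a standalone calculator:

```r
power_two_sample(0.438, 45, 82)
#>       d n1 n2 alpha     power
#> 1 0.438 45 82  0.05 0.6490777
```

`run_pipeline()` drives the same loop from a YAML config over real
inputs — either NIfTI diffusivity volumes plus ROI definitions or a
precomputed cohort table — writing every intermediate (ALPS table,
serialized fit, harmonized table, report) as plain delimited text.  A
thin command-line wrapper lives at `inst/cli/alpscombat.R`.

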
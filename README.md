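# frocdwi

Simulation and analysis of multi-b-value breast diffusion-weighted MRI
with the fractional-order calculus (FROC) diffusion model.

Benign and malignant breast lesions differ in how water diffuses through
them. Over a wide b-value range (here 14 b-values up to 3000 s/mm²) the
signal decay is visibly non-exponential, and the FROC model

S_b/S_0 = exp[ −D · µ^{2(β−1)} · (γG_dδ)^{2β} · (Δ − ((2β−1)/(2β+1))·δ) ]

describes it with an anomalous diffusion coefficient D (µm²/ms), an
intravoxel heterogeneity index β (0 < β ≤ 1, lower = more heterogeneous)
and a spatial constant µ (µm), alongside the classical mono-exponential
ADC. This package provides, for people who study such protocols without
access to patient images:

* the forward signal models and the Stejskal–Tanner b→q mapping;
* digital phantoms (ellipsoidal lesions, air slab, Rician noise at the
  protocol's averaging schedule) and two-group lesion cohort generators
  with bundled reference moments (73 benign / 105 malignant, two
  sequences per lesion);
* voxel-wise bounded Levenberg–Marquardt fitting of ADC and of (D, β, µ)
  with convergence QC, VOI statistics, and per-b SNR/CNR tables;
* the full diagnostic statistics stage: normality-gated group tests,
  Spearman/ICC agreement with category labels, Bland–Altman limits,
  ROC with Youden cutoffs and DeLong comparisons, multivariate logistic
  modelling with single-pass selection, nomogram construction,
  Hosmer–Lemeshow and bootstrap-corrected calibration, and decision-curve
  analysis.

A word on identifiability: with fixed gradient timings, D and µ act on
the signal only through the product D·µ^{2(β−1)}. The package fits the
conventional three-parameter model for literature comparability, but all
recovery guarantees are stated on the identifiable quantities (β, the
decay product, ADC); see the methods vignette
(`vignettes/froc-dwi-methods.Rmd`) for the full discussion.

## Worked example

```r
library(frocdwi)

protocol <- protocol_14b()           # 14 b-values, delta 25.66 / Delta 30.13 ms
lesion   <- froc_params(D = 0.85, beta = 0.73, mu = 3.5)
signal   <- froc_signal(lesion, protocol$b_values, protocol)
fit_froc(signal, protocol)
#> FROC parameters: D = 0.7941 um2/ms, beta = 0.73, mu = 3.086 um
#>   SSR = 0, converged = TRUE, iterations = 11
```

β is recovered exactly and the fit reproduces the curve with zero
residual; D and µ land elsewhere on the zero-residual ridge
(D·µ^{2(β−1)} = 0.432 in both cases — the quantity the data determine).

```r
cohort <- simulate_cohort(cohort_spec(seed = 42))
cs <- cohort[cohort$sequence == "SSEPI", ]
roc_analysis(cs$D, cs$group, direction = "lower")
#> ROC: AUC 0.889 (95% CI 0.828-0.950), cutoff 0.91 (<= cutoff predicts malignant)
#>   sens 89.52%, spec 80.82%, accuracy 85.96% (n = 178)

fit_logistic_with_selection(cs)       # single-pass Wald selection
#> Logistic model (malignant = 1)
#>   retained: D, beta
#> (Intercept)           D        beta
#>     24.4846     -6.5978    -22.1712
```

The numbers mean: a simulated 178-lesion cohort at the bundled group
moments separates benign from malignant lesions with AUC ≈ 0.89 on D
alone, lower D values indicating malignancy with the Youden-optimal
threshold near 0.91 µm²/ms; in the multivariate model µ fails the Wald
test at this seed and the D + β model remains.

The `analysis/` directory holds the numbered drivers that run the whole
study on synthetic data — `01_simulate.R` (phantom + cohort),
`02_fit_phantom.R` (voxel-wise maps, recovery, SNR/CNR),
`03_group_statistics.R` (group tests, agreement) and `04_diagnostics.R`
(ROC table, logistic model, nomogram, calibration, decision curves) —
writing their tables under `results/`.

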
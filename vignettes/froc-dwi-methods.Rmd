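---
title: "Methods: FROC modelling of multi-b-value breast DWI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FROC modelling of multi-b-value breast DWI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frocdwi)
```

## The signal models

Diffusion-weighted MRI probes water mobility by attenuating the signal with
a diffusion weighting $b$ (s/mm²). The classical description is
mono-exponential,

$$S_b/S_0 = \exp(-b\cdot\mathrm{ADC}),$$

but tumour tissue is heterogeneous at the voxel scale and its decay over a
wide b-range (here 0–3000 s/mm²) is visibly non-exponential. The
fractional-order calculus (FROC) model generalises the Bloch–Torrey
solution to

$$S_b/S_0 = \exp\!\left[-D\,\mu^{2(\beta-1)}\,(\gamma G_d\delta)^{2\beta}
\Bigl(\Delta-\tfrac{2\beta-1}{2\beta+1}\,\delta\Bigr)\right],$$

with $D$ an anomalous diffusion coefficient (µm²/ms), $\beta\in(0,1]$ the
intravoxel diffusion heterogeneity (lower = more heterogeneous) and $\mu$
(µm) a spatial constant that preserves the units of $D$. $\delta$ and
$\Delta$ are the gradient pulse width and interval; the bundled protocol
(`protocol_14b()`) uses 14 b-values with $\delta = 25.66$ ms and
$\Delta = 30.13$ ms and 1–3 averages per b.

Scanners export nominal b-values rather than per-b gradient amplitudes, so
the gradient factor $q=\gamma G_d\delta$ is recovered by inverting the
Stejskal–Tanner relation $b=q^2(\Delta-\delta/3)$
(`b_to_gradient_factor()`). This is the conventional practical choice; it
also makes the FROC model collapse *exactly* to the mono-exponential at
$\beta=1$, which the test suite asserts to $10^{-12}$. Units follow the
breast-DWI convention: $b$ is accepted in s/mm² at every interface and
converted internally (1000 s/mm² = 1 ms/µm²); $D$ and ADC are reported in
µm²/ms, numerically equal to $10^{-3}$ mm²/s.

## Identifiability: what a fixed-timing protocol can and cannot measure

With $\delta$ and $\Delta$ fixed across b-values, $D$ and $\mu$ enter the
exponent only through the product $D\,\mu^{2(\beta-1)}$ (the *decay
coefficient*, `froc_decay_coefficient()`): the two Jacobian columns are
exactly parallel at every b-value, and the data determine only the pair
$(\beta,\;D\,\mu^{2(\beta-1)})$. No estimator can recover $D$ and $\mu$
separately from such data — the forward map is many-to-one — and any
solver simply returns one point on a zero-residual ridge selected by its
initialisation. The ridge degenerates further at $\beta=1$, where $\mu$
vanishes from the model entirely and only there $D$ becomes fully
identifiable.

The package is explicit about this. `fit_froc()` performs the
field-standard joint three-parameter fit (so that its $D$ and $\mu$ maps
are comparable with the literature, where the same ridge is implicitly
resolved by the optimiser), but every `fit_result` also carries the decay
coefficient, and all recovery claims in the test suite are made on the
identifiable quantities: $\beta$, the decay coefficient, the ADC, and the
predicted curve itself. Reported $D$ and $\mu$ values from any single
diffusion-time acquisition should be read as convention-dependent
coordinates on that ridge; this is a plausible mechanism for the
inconsistent $\mu$ findings across published FROC studies and for the
known instability of $\mu$ as $\beta\to 1$.

## Fitting

Both models are fitted by bounded Levenberg–Marquardt (minpack.lm) on the
signal normalised by the measured $b=0$ volume, rather than fitting $S_0$
as an extra parameter, because the model is written on $S_b/S_0$. The
mono-exponential fit uses all 14 b-values nonlinearly (not log-linearised)
so that low-signal high-b points are weighted consistently with the FROC
fit.

* **Bounds:** $D\in[10^{-4},4]$ µm²/ms, $\beta\in[0.05,1]$,
  $\mu\in[0.1,20]$ µm — the model constrains only $0<\beta\le 1$; the
  rest bracket physiological plausibility.
* **Initialisation:** $D_0$ = the voxel's mono-exponential ADC (clamped
  into bounds), $\beta_0=0.9$, $\mu_0=5$ µm — an interior warm start.
* **Convergence:** relative parameter tolerance $10^{-8}$, at most 500
  iterations (with an evaluation budget large enough that the iteration
  and tolerance criteria, not the evaluation cap, terminate the fit).
* **Multi-start:** if the first solution touches a bound, one restart
  from $(D_0, 0.6, 2.5)$ is tried and the lower-residual fit kept.
* **QC:** voxels that fail either fit are flagged and excluded from VOI
  statistics (`voi_statistics()` uses converged voxels only; sample SD).

On noiseless data the fit recovers $\beta$ and the decay coefficient to
better than $10^{-3}$ relative (property-tested over random parameter sets
with $\beta \le 0.95$); under 1\% Rician noise the non-converged fraction
stays below 1\% and replicate-voxel medians centre on the generating curve.

## The phantom generator

`phantom_spec()` describes what the simulated study needs and nothing
more: ellipsoidal lesions with known FROC parameters inside homogeneous
background tissue, plus a signal-free air slab so the SNR definition
(lesion mean / air SD) has a place to measure noise. Noise is Rician —
the magnitude of the complex signal plus independent Gaussian noise of SD
$\sigma$ in both channels — because clinical DWI magnitudes are
Rician-distributed, with Rayleigh statistics in air. Each b-volume is the
mean of that b-value's `n_averages` independent magnitudes
(magnitude-then-average, as scanners combine repeats), so tripling the
averages shrinks the noise SD by $\sqrt 3$, which is property-tested.
The default demonstration phantom uses $\sigma = 1$–2\% of the lesion
$S_0$, matching the b=0 SNR range of breast DWI at 3 T.

What the phantom does *not* emulate: anatomical texture, coil-sensitivity
profiles, parallel-imaging artifacts, eddy currents, motion or geometric
distortion. Passing phantom tests therefore validates the estimation and
statistics chain, not robustness to acquisition artifacts.

## The cohort generator

`simulate_cohort()` draws per-lesion parameter values directly (skipping
the image level) for two sequences — a conventional single-shot EPI
("SSEPI") and a simultaneous-multi-slice accelerated variant ("SMS") — in
a benign and a malignant group of 73 and 105 lesions, the reference group
sizes bundled with the package. Marginals are truncated normals at the
bundled group means/SDs (`default_cohort_moments()`); $\beta$ is capped at
1 and all parameters at their physical domains, with joint redraws so the
within-domain moments stay close to the nominal ones. Because the
agreement stage consumes *paired* sequences, the two sequences of a lesion
are coupled through a Gaussian copula whose correlations default to the
published between-sequence Spearman values for D, β, µ and ADC
(0.956/0.732/0.640/0.983), converted to Pearson via $2\sin(\pi r/6)$.
The generator is unimodal by design; it does not attempt to reproduce the
bimodal µ distribution reported for accelerated acquisitions in malignant
lesions, for which no generative mechanism is established.

## Statistical conventions

* **Normality gate:** a Lilliefors-type Kolmogorov–Smirnov test against a
  normal with estimated mean/SD at $\alpha=0.05$ routes each two-group
  comparison to the t-test (both groups normal) or Mann–Whitney U.
  Zero-variance samples are classed non-normal.
* **Correlation/agreement categories** are applied to the estimate rounded
  to two decimals with closed printed endpoints: Spearman $\le 0.24$
  little/none, 0.25–0.49 fair, 0.50–0.74 moderate, 0.75–1.00 good; ICC
  $\le 0.20$ poor up to 0.81–1.00 excellent.
* **ICC form:** two-way random effects, absolute agreement, single
  measure — ICC(2,1) — the common inter-reader choice; the CI follows
  McGraw & Wong. This is an assumption: the source convention is not
  stated in the application domain.
* **Bland–Altman** uses the conventional $\pm 1.96$ SD limits.
* **ROC:** malignant is the positive class. For D, β and ADC lower values
  indicate malignancy, so scores are negated internally and cutoffs
  reported with the "≤ cutoff ⇒ malignant" rule; µ uses "≥ cutoff".
  Youden-optimal cutoffs are scanned at observed-value midpoints with
  ties broken toward higher specificity (clinically conservative). AUC
  CIs and paired AUC comparisons use DeLong's covariance (pROC).
* **Logistic model:** maximum likelihood with one selection pass —
  features with Wald $p \ge 0.05$ dropped, survivors refit. Perfect
  separation or collinearity falls back to a weak ridge penalty
  ($\lambda=10^{-4}$, intercept unpenalised) with Wald p from the
  penalised information matrix. No multiplicity correction is applied;
  $\alpha=0.05$ throughout.
* **Nomogram:** the retained feature with the largest
  $|\hat\beta_j|\times$range spans 0–100 points, others scale
  proportionally, and total points map to probability through the inverse
  logit of the reassembled linear predictor — the construction is exact,
  so tabulated probabilities agree with the model to machine precision.
* **Calibration:** Hosmer–Lemeshow over deciles of risk ($g-2$ df; empty
  bins merged with a warning) and a bootstrap optimism correction of the
  per-decile calibration curve (refit on each resample, apparent-minus-
  original calibration averaged over $B\ge100$ replicates).
* **Decision curves:** net benefit
  $\mathrm{NB}(p_t)=\mathrm{TP}/n-\mathrm{FP}/n\cdot p_t/(1-p_t)$ on the
  grid 0.01–0.99 (step 0.01), against treat-all and treat-none.

## Problem sizes and determinism

The shipped analyses use a 24×16×6 phantom (≈1700 fitted voxels), the
73/105 cohort, 200-replicate binormal ROC summaries and $B=200$ bootstrap
calibration; these sizes make every stage reproducible on a laptop in
minutes while keeping Monte-Carlo error well inside the stated tolerances.
Every random stage takes an explicit seed, a single pipeline seed fans out
to per-stage sub-seeds, and reruns of `run_pipeline()` with the same
config are byte-identical.

## Known limitations

* $D$ and $\mu$ are reported for literature comparability but are not
  separately identifiable from fixed-timing data (see above); only
  $\beta$, the decay coefficient and ADC have acquisition-independent
  meaning here.
* The cohort generator reproduces first and second moments and a pairwise
  copula, not the full joint distribution of real lesions (e.g. no
  D–β within-lesion correlation is imposed, and µ stays unimodal).
* The Lilliefors p-value uses the standard analytic approximation rather
  than Monte-Carlo simulation.
* Image-quality scoring by human readers, acquisition physics and image
  reconstruction are out of scope; SNR/CNR are computed on simulated
  magnitudes only.
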
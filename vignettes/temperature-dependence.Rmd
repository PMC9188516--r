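---
title: "Modelling and correcting the temperature dependence of post mortem brain qMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and correcting the temperature dependence of post mortem brain qMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmqmri)
```

## The problem

In situ post mortem MRI (PMMRI) scans the intact brain of a deceased
subject and is a key route to validating in vivo quantitative MRI
against histology. But the quantitative parameters — the relaxation
times T1, T2 and T2\*, the mean diffusivity (MD) and the fractional
anisotropy (FA) — all depend on tissue temperature, and a cooled body
(algor mortis) can sit anywhere between refrigerator and living brain
temperature. Comparing post mortem maps with in vivo references
therefore requires a temperature model and a correction.

Over a span of a few tens of degrees the activation-energy relaxation
models linearise well, so each region/parameter pair is described by a
straight line in brain temperature \(x\):

\[ y = a + b\,x , \]

fitted once over all subjects (*with in vivo*) and once over the
deceased only (*without in vivo*). Two percentage statistics summarise
each pair of fits:

* **Δ\***: the percentage difference between the measured mean in vivo
  value and the post-mortem-only line extrapolated to 36.5 °C, with the
  in vivo mean as 100 %. A large Δ\* flags physiology that temperature
  cannot explain — for MD, chiefly the loss of perfusion and active
  diffusion after death (Δ\* ≈ −50 %).
* **Δ\*\***: the percentage difference between the line's values at
  4 °C and 36.5 °C, with the 36.5 °C value as 100 %, computed on the
  post-mortem-only fit. It isolates the pure temperature effect.

The package ships the published coefficient table
(`temperature_coefficients()`: 7 regions × 5 parameters × 2 variants),
fits the same models on data (`fit_linear_model()`,
`fit_cohort_models()`), derives the Δ statistics (`delta_star()`,
`delta_double_star()`), and corrects measured values along a fitted
line (`correct_to_temperature()`).

## Signal models and voxel-wise fitting

Three forward models generate and fit the signals.

**Inversion-recovery spin echo (T1).** With equilibrium magnetisation
\(M_0\), inversion-efficiency factor \(p\) and the sequence times TI,
TE, TR:

\[ S = M_0\, e^{-\mathrm{TE}/T_2}\,\bigl(1 - p\,e^{-\mathrm{TI}/T_1} +
     e^{-\mathrm{TR}/T_1}\bigr). \]

The factor \(p\) absorbs B1 errors of the 180° pulse; \(p = 2\) is a
perfect inversion. The fit (`fit_t1_ir()`) holds TE, TR and the voxel's
previously fitted T2 fixed and estimates \((M_0, p, T_1)\) by
Levenberg–Marquardt least squares. Scanner images are magnitudes, so
the sign of the recovery curve is lost; the fit restores polarity by
negating the first \(k\) inversion times for every \(k = 0..n\),
fitting each candidate and keeping the lowest residual. (Whether signed
or magnitude data were fitted in the original analysis is not stated;
polarity restoration is this package's choice and, on signed data, the
two routes agree exactly.)

**Mono-exponential decay (T2, T2\*).** `fit_monoexp()` fits
\(s_0 e^{-\mathrm{TE}/T_2}\), initialised from the log-linear
regression of log-signal on TE. T2 and T2\* share the implementation
and differ only in echo list.

**Diffusion tensor (MD, FA).** `fit_tensor()` is the standard
unweighted log-linear OLS fit of the six tensor components plus
\(\log s_0\); the b = 0 volumes are averaged before fitting. MD is the
eigenvalue mean, FA the normalised eigenvalue dispersion with negative
eigenvalues clamped to zero and a per-voxel flag. Weighted or nonlinear
tensor variants are out of scope; the external tool the original
analysis used does not document its internal variant, so the unweighted
fit is the documented choice here.

Numerical settings: relative tolerances of 1e-8 (`ptol`/`ftol` 1e-10)
with a 500-iteration cap; T1 initialised from the zero-crossing TI as
\(T_1 \approx \mathrm{TI}_\mathrm{null}/\ln 2\), \(p\) at 2, \(M_0\)
from the largest magnitude. Voxels that cannot be fitted (all-zero or
non-decaying signal, missing T2, \(p \le 0\) or \(p > 2.5\),
non-positive T1) are recorded as `NA` sentinels and excluded from every
downstream statistic. The validity slack above the physical bound
\(p \le 2\) is deliberate: noise scatters \(\hat p\) around 2, and a
hard bound would invalidate half of all well-behaved voxels.

## Region aggregation

Partial-volume voxels bias region means, and two exclusions guard
against them, mirroring the study pipeline:

1. `exclude_partial_volume()` keeps only voxels whose partial-volume
   fraction reaches 1 (threshold configurable).
2. `apply_otsu_exclusion()` thresholds each region's parameter values
   with the Otsu method — the bin-edge threshold maximising the
   between-class variance \(w_0 w_1 (\mu_0-\mu_1)^2\) over 256
   candidate edges — and drops the voxels on the discarded side.

Class statistics are computed exactly from the values in each bin, so
the result provably equals an exhaustive search over the same edges;
exact ties across an empty inter-mode gap resolve to the centre of the
tying edges. Which side to keep is configurable (`keep_rule`), keeping
the majority class by default, since the side retained per map is not
documented in the source. Two guards handle maps without real
contamination, where a forced binary split would discard valid tissue:
if the optimal split explains less than 75 % of the total variance
(η² < 0.75) the values are treated as unimodal and the full mask kept,
and a split discarding more than half the region is rejected with a
warning. The η² guard is this package's addition: a
discard-fraction rule alone still removes about half of a unimodal
region.

`summarize_subject()` applies both steps per elementary region and
parameter map; the deep-gray-matter aggregate reuses the union of its
four subregions' refined masks rather than pooling their distinct value
ranges, which would make the mixture itself look like contamination.

## The synthetic study

No raw scans of the original cohort are public, so the package
generates its own data at two levels.

**Voxel level.** `generate_phantom()` builds a labelled volume of
nested spherical compartments — a cortical shell around white matter
containing four deep-gray spheres (globus pallidus, putamen, caudate
nucleus, thalamus) and a central CSF cavity. The geometry is
deliberately schematic; realistic anatomy contributes nothing to
testing the estimators. Every labelled voxel carries the ground-truth
parameter values of its region's published line at the subject's brain
temperature, plus multiplicative Gaussian within-region variation
(default CV 3 %, a plausible tissue heterogeneity; the source reports
region spreads only graphically, so this magnitude is configurable
rather than asserted). Boundary voxels receive partial-volume fractions
of 0.5, giving the exclusion steps something to exclude. CSF, absent
from the coefficient table, uses fixed long relaxation times and the
known strong temperature dependence of free-water diffusivity (about
1.0×10⁻³ mm²/s near 5 °C to 3.0×10⁻³ mm²/s at body temperature).
Diffusion tensors are axially symmetric with region-specific principal
axes, built to match the MD/FA ground truth exactly.
`simulate_subject_signals()` evaluates the three signal equations at
the acquisition protocol — six inversion times, twelve SE echoes
(the third echo is 29.4 ms, continuing the list's 9.8 ms spacing),
twelve GRE echoes, and b = 2000 s/mm² over 64 directions plus three
b = 0 — and applies Rician noise (magnitude of the complex signal after
independent Gaussian perturbations of both channels).

**Cohort level.** `generate_cohort()` emulates the study cohort: 16
post mortem subjects with brain temperatures from a truncated normal,
12.7 ± 5.7 °C on [5.6, 28.1] °C (matching all published descriptives;
a uniform alternative can be had by widening the SD), plus 4 in vivo
subjects at exactly 36.5 °C. Region means are the line value plus a
Gaussian residual. The published tables print no residual SDs, so the
default inverts the printed slope CI half-width,
\(\mathrm{ci}_b = t_{0.975,n-2}\, s/\sqrt{S_{xx}}\), under the nominal
design (n = 16, temperature SD 5.7 °C) — a residual scale consistent
with the printed uncertainty (`residual_sd_from_ci()`). An
`invivo_scale` factor can multiply the in vivo model value to inject a
variant discrepancy; scaling MD by 2 reproduces the −50 % Δ\* signature
of perfusion loss. For that detection scenario the examples use a
smaller, measurement-level residual SD (5×10⁻⁶ mm²/s, about 2 % of a
typical MD): with the CI-derived SD the sampling scatter of Δ\* itself
(≈ 6 pp at n = 16) would dominate what is being demonstrated, which is
the detection machinery, not estimator noise.

All randomness derives from user seeds; per-subject seeds are derived
deterministically, so cohorts are bit-reproducible and invariant to
subject ordering.

## Temperature correction

`correct_to_temperature()` transports a measured value along a fitted
line, \(v' = v + b\,(T_\mathrm{ref} - T_\mathrm{meas})\); it is exactly
invertible and composes additively in temperature. For post mortem
data the post-mortem-only slope is the default recommendation: the
with-invivo line absorbs non-temperature effects wherever Δ\* is large
(MD and FA especially). Corrections outside 0–40 °C warn, since the
linearisation is only supported over the span the models were built
for. p values across the many region/parameter fits are reported
unadjusted, mirroring the source analysis; treat marginal significances
accordingly.

## What passing tests do and do not show

The test-suite and the acceptance script establish: (i) the printed
Δ\*\* values are reproduced from the printed coefficients wherever the
printed precision pins them down to 0.5 pp (coarser rows are flagged
rounding-limited, with the propagated half-ulp bound reported);
(ii) noiseless signals at the printed protocol refit to ground truth to
better than 1e-6 relative in all five parameters; (iii) the Otsu and
OLS estimators equal their brute-force oracles; (iv) across replicate
cohorts the 95 % slope CI covers the generating slope at nominal rate,
the correction collapses the temperature–value correlation, and an
injected in vivo MD offset is recovered as Δ\* ≈ −50 %.

Problem sizes are chosen to keep the full suite inside a half-hour on
one CPU: 16³ phantoms, per-region voxel subsamples of 8–100 in the
map-level tests (the region mean is then estimated from the subsample),
500 cohort replicates for coverage, 1000 for noise robustness. None of
this certifies behaviour on real scanner data: the phantom has
schematic geometry, no B0 inhomogeneity, no motion, no slice profile,
no autolysis biophysics, and region means in the cohort generator are
drawn directly from the generating lines rather than aggregated from
contaminated voxels. What the synthetic route does certify is the
estimation chain itself — forward model, inversion, exclusion,
aggregation, regression, correction — under exactly known truth.

## Worked example

```{r example}
tab <- temperature_coefficients()
subset(tab, region == "putamen" & parameter == "T1",
       select = c(variant, a, ci_a, b, ci_b, r2_adj, p_value))

# pure temperature effect on putamen T1 across the post mortem span
m <- as_linear_temp_model(a = 500.6, b = 6.5,
                          region = "putamen", parameter = "T1")
delta_double_star(m)

# correct a putamen T1 measured at 8 degrees to living brain temperature
correct_to_temperature(550, measured_temp = 8, reference_temp = 36.5, m)

# a small synthetic cohort, refit and compared
coh <- generate_cohort(regions = "putamen", parameters = "T1", seed = 1)
fit_cohort_models(coh$summaries)[, c("variant", "a", "b", "ci_b",
                                     "r2_adj", "p_value")]
```
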
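---
title: "Quantifying renal blood flow from ASL and DCE-MRI: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying renal blood flow from ASL and DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renperf)
```

# The problem

Renal cortical perfusion (renal blood flow, RBF, in ml per 100 g of tissue
per minute) is a sensitive marker of kidney function: unilateral
ischaemia-reperfusion injury can halve cortical perfusion within days. Two
MRI modalities measure it without biopsy. Arterial spin labelling (ASL) uses
magnetically inverted arterial water as an endogenous tracer; dynamic
contrast-enhanced (DCE) MRI follows a gadolinium bolus through the tissue.
`renperf` implements both quantification chains, the region-of-interest
statistics used to compare them in a unilateral-injury setting, and a
synthetic two-kidney phantom that gives every stage a known ground truth.

# The FAIR ASL model

A FAIR (flow-sensitive alternating inversion recovery) experiment interleaves
three magnetic preparations: unprepared equilibrium frames (`M0`),
slice-selective inversion (`ssIR`, the control), and non-selective global
inversion (`nsIR`, the tag). After averaging each preparation, the
perfusion-weighted difference image is

$$\Delta M = \overline{ssIR} - \overline{nsIR},$$

positive in perfused tissue. Under the single-compartment model with
immediate blood–tissue water exchange and transit delays neglected, the
pixelwise perfusion is

$$f = \frac{6000\,\lambda\,\Delta M\,e^{TI/T_1}}{2\,M_0\,TI}
\quad [\mathrm{ml}/100\,\mathrm{g}/\mathrm{min}],$$

with the blood–tissue water partition coefficient $\lambda = 0.8$ ml/g, the
tissue longitudinal relaxation time $T_1 = 1.14$ s, the inflow (inversion)
time $TI = 1.2$ s, and the factor 6000 converting ml/g/s to ml/100 g/min
(`quantify_fair()`). The simulator (`simulate_asl()`) emits frames whose
tag/control difference is exactly the algebraic inverse of this expression at
the phantom's ground-truth perfusion, which is what makes the noise-free
round trip exact rather than approximate: quantification applied to a
simulated series reproduces the truth to floating precision (the test suite
asserts $<10^{-9}$ relative error on a 128×128 phantom).

Two conventions to be aware of:

* **Sign.** `ssIR` is the control and `nsIR` the tag; the subtraction is
  control minus tag so that cortical $\Delta M > 0$.
* **Masking.** Pixels whose equilibrium signal is at or below `m0_floor`
  (default 5 % of the 99th-percentile $M_0$, a robust maximum) are excluded —
  the ratio diverges over background air. Negative perfusion values on the
  mask are kept; no statistic clips them.

# The DCE deconvolution model

With a linear signal-to-concentration relationship (the proportionality
constant cancels between tissue and blood, so it is fixed at 1), the tissue
concentration is the convolution of the arterial input function (AIF)
$C_A(t)$ with the tissue impulse response $h(t) = f\,R(t)$:

$$C_T(t) = \int_0^t C_A(\tau)\, f R(t-\tau)\, d\tau,$$

where the residue function $R$ satisfies $R(0) = 1$ and is non-increasing.
Perfusion is read off as the maximum of the deconvolved impulse response,
$f = 6000 \cdot \max_t h(t)$.

The chain (`dce_quantify()`) is: subtract the mean of the 15 pre-contrast
baseline volumes (`normalize_baseline()`); keep only the first-pass window —
50 volumes by default, 60 for slower boluses (`truncate_first_pass()`),
which excludes errors from tracer clearance through the medulla; average the
aortic voxels into the AIF (`extract_aif()`); and solve the discrete
convolution system pixel by pixel (`rbf_map()`).

## Deconvolution and regularisation

Discretised by the rectangle rule at the volume spacing $dt = 0.9$ s, the
convolution becomes a lower-triangular Toeplitz system
$A\,h = c_T$ with $A_{ij} = dt\,c_A[i-j+1]$. `deconvolve()` solves it by
truncated SVD: singular values below `threshold_fraction` times the largest
are zeroed. The simulator discretises its forward model with the same
rectangle rule, so noise-free recovery is exact up to the truncation (the
suite checks cortical ROI recovery within 5 % and a forward re-convolution
residual $\le 10^{-6}$ at `threshold_fraction = 1e-12`).

The cutoff trades bias for variance, and the trade-off is strong:

* Near zero (`1e-12`) the solution is exact on noise-free data but amplifies
  noise through the small singular values of the smooth AIF kernel.
* The default `0.15` — the usual choice for noisy first-pass data —
  suppresses that amplification at the cost of a systematic underestimation
  of the impulse-response peak (on the default phantom with realistic noise,
  the pixelwise cortical map comes out roughly 20 % low). Left/right ratios
  are essentially unaffected, because the bias is common to both kidneys.

Because the in-vivo processing this package models does not document its
regularisation, absolute agreement of DCE maps with any particular software
is not promised; the printed per-animal ROI tables (which feed the
statistics stage) and synthetic recovery are the reproducible surface.

## ROI summaries under noise: average first, then take the maximum

`rbf_map()` takes the per-pixel maximum of a noisy $h$; averaging those
maxima over an ROI is biased upward (a maximum of noisy samples). The
deconvolution is linear, so deconvolving the ROI-averaged concentration
curve gives the ROI mean of the impulse responses — and taking the maximum
after averaging removes that bias. `dce_roi_rbf()` implements this and is
the estimator used for ROI summaries of noisy series, with a weak default
cutoff (`1e-3`) since the averaging itself suppresses most noise. The
Monte-Carlo tests show it is unbiased to within two Monte-Carlo standard
errors at 100 replicates; the result is insensitive to the exact weak
cutoff (`1e-4` gives the same estimates).

# The synthetic phantom

`phantom_spec()` describes a single 128×128 axial slice (0.5 mm pixels)
containing both kidneys as ellipses — a cortical ring around a medullary
core — plus a small circular aorta cross-section. Defaults emulate a
left-sided injury: cortical perfusion 316 (diseased) vs 416 (healthy)
ml/100 g/min, the representative cortical means of the two conditions;
medullary perfusion is set to 150 ml/100 g/min (low relative to cortex, as
in vivo) and the equilibrium signal to 100 arbitrary units. The DCE series
replicates the slice over three slices to exercise the three-slice ROI
averaging rule (`multislice_roi_mean()`).

The forward models are deliberately simple in ways that matter for
interpreting the tests:

* The ASL series is generated from the inverse of the implemented
  quantification formula, not from a Bloch simulation of the readout. The
  round-trip tests therefore validate the quantification algebra and
  pipeline plumbing, not the MR physics of the acquisition.
* The AIF is a gamma-variate bolus,
  $c(t) = a\,((t-t_0)/\beta)^\alpha e^{-(t-t_0)/\beta}$, with shape
  $\alpha = 3$ and scale $\beta = 2$ s (peak 6 s after arrival — a fast,
  rat-like first pass that fits inside the 35 post-baseline volumes). Bolus
  arrival defaults to the first post-baseline volume,
  $t_0 = n_{baseline} \cdot dt = 13.5$ s. The default amplitude makes the
  peak arterial concentration equal to the baseline tissue signal, giving a
  realistic enhancement-to-noise ratio; all estimates are invariant to this
  constant.
* The residue function is a single-exponential washout with mean transit
  time 3 s (consistent with cortical blood volume over flow); a plug-flow
  boxcar is available as an alternative.
* Noise is additive Gaussian per frame, not Rician: the difference and
  enhancement signals simulated here sit far from the magnitude-image noise
  floor, where the Gaussian approximation is standard.
* No respiratory motion, inversion-slab imperfections, or view-sharing
  artefacts are simulated. Passing tests therefore demonstrate correctness
  of the quantification chains under the stated models — not robustness to
  the confounds a live acquisition adds.

For noisy studies the frame noise is set by the perfusion signal: an ASL
difference-signal noise of ~1 % corresponds to
$\sigma = 0.01\,\Delta M_{cortex}\sqrt{n_{pairs}/2}$, and the matched DCE
level is 1 % of the peak cortical enhancement. At these levels the
within-subject repeat-scan coefficient of variation is ~0.1 %, comfortably
inside the few-percent repeatability observed in vivo. Monte-Carlo checks
use a 64×64 grid (100 replicates); exact noise-free checks use the full
128×128 grid.

# Statistics

The comparison stage works on per-subject (left, right) cortical RBF pairs
(`paired_comparison()`):

* **Groups.** The diseased group collects the injured-side values; the
  healthy group collects the contralateral values plus *both* kidneys of any
  all-healthy subject. Group summaries use the sample SD (ddof 1).
* **Paired differences** (healthy minus diseased, diseased subjects only)
  feed a two-sided one-sample t-test (`paired_t_test()`, delegating to
  `stats::t.test`) and a Bland–Altman summary (`bland_altman()`): mean
  difference, population SD (ddof 0) and limits of agreement
  $\mathrm{mean} \pm 1.96\,\mathrm{SD}$.
* **Ratios.** `lr_ratio()` reports left/right cortical RBF to two decimals —
  the scale-free diagnostic that survives intermethod calibration offsets.
* **Repeatability.** `repeatability_summary()` gives per-kidney mean and
  population SD across repeated scans.

The ddof conventions are deliberate and asymmetric: re-computation from the
packaged per-animal tables reproduces the printed group summaries only with
the sample SD, and the printed difference and repeatability summaries only
with the population SD. Both are exposed via `group_summary(..., ddof =)`;
the report generator (`table_report()`) applies the convention above.
Reporting rounds RBF to integers, ratios to 2 decimals and p-values to
percent with 2 decimals; computation is never rounded.

Null calibration is verified empirically: under a zero-difference null with
n = 5 pairs the t-test rejects at the nominal 5 % (±1.5 % over 1000
replicates), and the Bland–Altman limits cover 95 % (±0.5 %) of 10⁴ normal
differences.

# Numerical and design choices

* **Pseudo-inverse convention.** Singular values that are numerically zero
  (below $n\,\varepsilon\,s_{max}$) are always dropped, so
  `threshold_fraction = 0` means "unregularised", never "divide by zero".
  This matters because a bolus arriving after the baseline makes the leading
  AIF samples exactly zero and the Toeplitz matrix exactly rank-deficient.
* **Delay handling.** AIF and tissue share one time axis; no delay fitting
  is applied (none was applied in the workflow this reproduces). Shifting
  both curves by a whole number of samples changes the recovered maximum by
  under 1 %.
* **Coordinates.** Arrays are indexed (row, column, slice, time); masks
  share their series' in-plane grid exactly, with no resampling. Series
  travel as 4-D NIfTI with a CSV frame-label sidecar (ASL) or YAML-supplied
  timing (DCE) — volume timing is taken from configuration, not trusted from
  NIfTI headers.
* **Determinism.** Every simulation takes an explicit seed and restores the
  caller's RNG state; `run_pipeline()` output is bit-identical for a fixed
  configuration and seed.

# Known limitations

* ASL quantification uses a single global $T_1$; per-pixel $T_1$ mapping
  (which would sharpen diseased-cortex estimates) is out of scope.
* No motion correction or registration stage is provided (a hook exists in
  the pipeline configuration); the phantom generates co-registered data.
* The DCE stage stops at model-free deconvolution: no pharmacokinetic
  compartment modelling, no relaxivity-based signal-to-concentration
  conversion, no hematocrit correction.
* Absolute DCE values depend on the regularisation choice (see above);
  between-method comparisons should lean on differences and ratios, which is
  precisely what the statistics stage does.
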
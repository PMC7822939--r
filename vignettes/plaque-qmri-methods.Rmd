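---
title: "Quantitative MRI plaque characterization: models, simulation and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MRI plaque characterization: models, simulation and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaquemap)
```

## The problem

Carotid endarterectomy specimens imaged ex vivo at high field can be
characterized non-destructively by quantitative relaxometry: voxel-wise maps
of the longitudinal relaxation time T1 and the effective transverse
relaxation time T2\*. Small regions of interest (ROIs) drawn where histology
identifies a tissue component — fibrous tissue, lipids, inflammation, or
hemorrhage — yield feature vectors of relaxation statistics, and quadratic
discriminant analysis (QDA) on those features classifies plaque components,
reporting a per-plaque misclassification rate. Because the original specimen
data are not publicly available, `plaquemap` pairs the analysis chain with a
first-class synthetic-data module: digital plaque phantoms with known
ground truth take the place of histology-labeled specimens, so every stage
is testable end to end.

## Signal models

The simulated acquisition is a spoiled 3D gradient-echo sequence. Its
steady-state magnitude signal at flip angle $\alpha$ and repetition time
$TR$ is

$$S = M_0\,\frac{1 - E}{1 - E\cos\alpha}\,\sin(\alpha)\,A,
  \qquad E = e^{-TR/T_1},\qquad A = e^{-TE/T_2^*}.$$

T1 mapping uses the variable flip angle (VFA) method: with signals at
several flip angles, the substitution $Y = S/\sin\alpha$,
$X = S/\tan\alpha$ linearizes the model to $Y = E\,X + M_0(1-E)\,A$, an
ordinary least-squares line per voxel. T1 comes from the slope
($T_1 = -TR/\ln E$). Note that any factor constant across flip angles —
including $A$ — multiplies both $X$ and $Y$ and therefore cancels in the
slope: ignoring $A$ when $TE \ll T_2^*$ biases only the fitted $M_0$, never
T1. The simulator deliberately *includes* $A$ (computed from the true T2\*
and the fixed $TE = 2$ ms of the VFA protocol) so this cancellation is a
testable property rather than an assumption; `use_a_factor = FALSE`
restores the idealized $A = 1$ regime.

T2\* mapping uses the mono-exponential decay $S = S_0 e^{-TE/T_2^*}$ over a
multi-echo series, fitted as unweighted least squares of $\ln S$ on $TE$.
An $S^2$-weighted variant (the first-order variance correction for
log-transformed noisy magnitudes) is available via `weighted = TRUE` but is
not the default, because the default estimator should be the simplest one
consistent with the stated model.

## Acquisition protocols

The two default protocols reproduce the published ex vivo settings:

* VFA (T1): $TR = 10$ ms, $TE = 2$ ms, flip angles $5, 10, 20, 30, 40^\circ$;
* multi-echo (T2\*): $TR = 22$ ms, $TE = 4, 8, 12, 16, 20$ ms, flip angle
  $10^\circ$;
* voxel size $120\,\mu m$ isotropic; Fourier zero-filling (`zero_fill()`)
  doubles the display grid to $60\,\mu m$.

For the multi-echo series the zero-echo amplitude $S_0$ is the spoiled-GRE
steady-state signal at the protocol's own flip angle and TR, keeping the two
simulated series physically consistent for the same phantom.

## The phantom generator: what it emulates, what it does not

A phantom is a 3D label volume (regions painted in order over a background
class) plus ground-truth T1, T2\* and M0 fields. Per-voxel values are drawn
from **normal distributions truncated at the class min/max**. The class
parameters default to the published per-class ROI statistics (mean, SD,
min, max of ROI-mean T1 and T2\* for fibrous tissue, lipids, inflammation
and hemorrhage); the truncated normal is the simplest distribution that
respects all four printed quantities. Choices the source leaves open, fixed
here once:

* **Background (fixative) class**: T1 = 2000 ms, T2\* = 40 ms, M0 = 0.05.
  The fixative bath's signal is unreported; a near-void M0 keeps background
  maskable while still exercising the invalid-voxel paths.
* **M0 of tissue classes**: mean 1, SD 0.05 (arbitrary units); the analysis
  is insensitive to the absolute M0 scale.
* **Noise**: Rician by construction (magnitude MRI), with
  $\sigma$ expressed as a fraction of the maximum noiseless signal.
  The source reports no SNR; the packaged default configuration uses
  $\sigma = 0.5\%$, consistent with a heavily averaged high-field ex vivo
  acquisition. Gaussian noise and $\sigma = 0$ are available.

Important caveat: the generator draws voxels independently, so within-class
spatial correlation, partial-volume mixing at interfaces, B1
inhomogeneity, susceptibility artefacts and chemical shift are all absent.
Consequently a green end-to-end test establishes the correctness of the
estimators and the classification bookkeeping — not that real plaques would
classify at any particular rate. In particular the synthetic cohort's
misclassification rates are systematically lower than the published ~16%,
because ROI means concentrate around class means (SE shrinks with ROI size)
when voxels are independent; no attempt is made to tune the generator
toward the published rate.

## Numerical choices

* **Invalid voxels**: fits never raise mid-volume; voxels fail into `NaN`
  plus a `valid_mask`. A T1 voxel is invalid when the slope leaves $(0,1)$,
  any signal is at or below `signal_floor`, or the regressor variance is
  degenerate; a T2\* voxel when any signal is at or below the floor, the
  slope is non-negative, or the fitted T2\* exceeds `t2s_cap` (default
  200 ms, beyond any plausible plaque value).
* **`signal_floor`**: defaults to 0 at the function level; the pipeline
  passes $3\sigma S_{max}$ when the protocol declares noise — in simulation
  the noise level is known exactly, standing in for "3x the estimated
  background SD".
* **Zero-filling** pads the centered spectrum symmetrically, splitting the
  Nyquist bin of even-length axes half-and-half; the inverse transform is
  then exactly real and the interpolant is the periodic-sinc (Dirichlet)
  kernel, which the tests verify against direct Fourier summation. The real
  part is returned (the imaginary part is zero to rounding), preserving the
  sign of interpolated values.
* **ROIs** are 4-connected, within one axial slice, 4-9 voxels, and
  homogeneous in the ground-truth label; "pixel" is interpreted on the
  fitted-map grid (the acquisition grid), not the zero-filled display grid.
  ROI statistics use the sample SD ($n-1$); an ROI retaining fewer than 4
  valid voxels is dropped and reported, preserving the 4-pixel floor.
* **QDA**: class means and sample covariances with shrinkage
  $(1-\lambda)\Sigma + \lambda\,\mathrm{diag}(\Sigma)$, default
  $\lambda = 0.1$ — with 7 predictors and sometimes ~10 ROIs per class per
  plaque, raw covariances are near-singular. Zero-variance diagonal entries
  of the shrinkage target are floored at $10^{-6}\times$ the largest
  variance ($10^{-12}$ if all are zero) so $\lambda = 1$ is always proper.
  Priors default to empirical class frequencies (uniform available). Scores
  are the usual log-discriminants
  $\delta_k(x) = -\tfrac12\ln|\Sigma_k| - \tfrac12 (x-\mu_k)^\top
  \Sigma_k^{-1}(x-\mu_k) + \ln\pi_k$; ties break to the first class in
  sorted order, deterministically.
* **Training scope** defaults to per-plaque, because the reference analysis
  reports per-plaque rates and declares QDA "not applicable" on
  single-tissue plaques; a plaque needs at least two classes with at least
  two ROIs each, classes below that are dropped from that plaque's model,
  and inapplicable plaques are excluded from the mean with their reason
  recorded. Evaluation is resubstitution (fit and score the same labeled
  ROIs) — the reference analysis claims no cross-validation.
* **Confidence interval**: Student-t on per-plaque rates at 95%. The
  construction behind the published interval is unstated, so it is treated
  as a design choice, recorded in the report metadata, and never used as a
  test oracle. Single-plaque or zero-variance inputs give a degenerate
  interval.
* **Seeds**: a master seed deterministically derives per-stage seeds (all
  within 32-bit range); identical configurations reproduce byte-identical
  CSV/JSON outputs.

## The synthetic cohort

The packaged default configuration (`default_run_config()`,
`inst/extdata/default_config.yaml`) builds 12 plaques matching the
composition pattern of the reference cohort: fibrous tissue in all 12,
lipids in 10, inflammation in 9, hemorrhage in 5, with two predominantly
fibrous plaques on which QDA is not applicable. Each plaque is an outer
fibrous ellipsoid with inner component pockets on a small grid
(default $8\times36\times36$ voxels), kept deliberately modest so a full
run completes in seconds on one CPU.

## Known limitations

* No B1/slice-profile/susceptibility modeling; no fat suppression, no
  calcification class (deliberately out of scope).
* The NIfTI reader/writer covers only this package's own single-file,
  little-endian subset of NIfTI-1.
* Independent-voxel phantoms understate real between-ROI variance (see
  above); the class-summary tables, not the misclassification rate, are the
  quantities anchored to published values.
* The linearized VFA estimator is exact on noiseless data but noise-biased
  at low SNR; the tests quantify this only at the 0.5% noise level.
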
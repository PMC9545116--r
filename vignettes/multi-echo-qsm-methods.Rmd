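---
title: "Multi-echo combination for QSM: models, pipelines and noise theory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-echo combination for QSM: models, pipelines and noise theory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(qsmme)
```

## The problem

Quantitative susceptibility mapping (QSM) estimates the spatial
distribution of tissue magnetic susceptibility $\chi$ (in ppm) from the
phase of gradient-recalled-echo (GRE) MRI. The measured phase at position
$r$ and echo time $TE$ follows

$$\varphi(r, TE) = \gamma\,\Delta B_{tot}(r)\,TE + \varphi_0(r),$$

with $\gamma$ the proton gyromagnetic ratio (angular,
$2\pi \cdot 42.577478518\,$MHz/T) and $\varphi_0$ a TE-independent offset.
The total field splits into a background part $\Delta B_{bg}$ (exterior
sources; harmonic inside the brain) and a local part $\Delta B_{loc}$,
which relates to $\chi$ through a convolution with the unit dipole field.
In k-space the dipole kernel is $D(k) = 1/3 - (k\cdot\hat b)^2/|k|^2$;
its zero cone at the magic angle makes the $\Delta B_{loc}\!\to\!\chi$
inversion ill-posed.

A multi-echo acquisition samples $\varphi$ at several echo times, and the
echoes must be combined somewhere along the processing chain. This package
implements the four combination strategies in common use, as complete
pipelines over one shared numerical backbone, so that accuracy and noise
can be compared like for like:

* **NLFit** — complex-domain nonlinear fitting of $(\Delta B_{tot},
  \varphi_0)$ across echoes (Gauss-Newton on the phase parameters with the
  measured magnitudes as weights), then SHARP background removal and
  Tikhonov inversion. Combination happens *before* any Laplacian-based
  processing, and the Gaussian noise model on the complex channels is
  respected.
* **TE-wAvg** — per-echo Laplacian phase unwrapping, then a TE-weighted
  average $\Delta B_{tot} = \frac{1}{\gamma}\sum_i w_i \varphi_i / TE_i$
  with $w_i = TE_i / \sum_j TE_j$, then SHARP and inversion. $\varphi_0$ is
  not modelled and biases the estimate by $n\varphi_0/(\gamma\sum TE_j)$.
* **SNR-wAvg** — per-echo SHARP (simultaneous unwrapping and background
  removal), an $R_2^*$ map from the magnitude decay, then the
  $R_2^*$-dependent weights $w_i(r) \propto TE_i e^{-TE_i R_2^*(r)}$,
  which track the echo of optimal phase SNR per tissue, then inversion.
* **Susc-wAvg** — per-echo SHARP and per-echo inversion, then a
  magnitude-weighted average of the susceptibility maps with
  $w_i(r) \propto M^2(r, TE_i)\,TE_i^2$. A hook (`external_chi` in
  `pipeline_config()`) accepts per-echo $\chi$ maps from any external
  single-step reconstruction in place of the internal per-echo inversions.

## Numerical backbone and its conventions

**Discrete Laplacian.** All Laplacian-based steps use the minimum-size
3-voxel 7-point stencil (centre $-6$, face neighbours $+1$), diagonalised
by the FFT with periodic boundaries. The trigonometric identity
$\nabla^2\varphi = \cos\varphi\,\nabla^2\sin\varphi -
\sin\varphi\,\nabla^2\cos\varphi$ makes wrapped input admissible; for
smooth small-magnitude inputs (e.g. fields in Tesla) it reduces to the
plain Laplacian, so the same code path serves both.

**Truncation threshold.** The regularised inverse Laplacian zeroes k-space
components with $|\tilde L(k)| \le$ threshold. The threshold is compared
against the stencil eigenvalues themselves, which span the fixed range
$[-12, 0]$, so the values are scale-free for this kernel: $10^{-10}$
(unwrapping) truncates only the DC null space, while $0.05$ (SHARP)
truncates spatial wavelengths longer than about 28 voxels. We considered
normalising the threshold to the spectral maximum instead; at 0.05 that
removes everything below ~8-voxel wavelengths and annihilates
anatomical-scale local fields (interior-source recovery errors above 90%),
so the absolute convention — which is also what the standard MATLAB QSM
implementations apply — is used. The practical consequence of either
convention is that SHARP behaves as a high-pass filter and *shrinks*
large-scale susceptibility structure; this is the origin of the
susceptibility underestimation that the inversion step corrects.

**SHARP.** Forward Laplacian via the trig identity, restriction to the
mask eroded by 5 voxels (cubic structuring element, applied once per
radius unit), truncated deconvolution, mean-zero over the eroded mask.
Voxels outside the eroded mask never influence the output (mask-locality
is tested). All pipelines report $\chi$ on the eroded mask only, and
regional statistics intersect ROIs with it, so comparisons share support.

**Tikhonov inversion and the L-curve.** The closed form
$\chi = \mathrm{IFFT}[D/(D^2+\alpha)\,\mathrm{FFT}(\Delta B_{loc}^{ppm})]$
is used, with $\alpha$ selected at the corner (maximum curvature) of the
log-log L-curve over 30 log-spaced values in $[10^{-4}, 1]$. Two details
matter on real curves: curvature is estimated on monotone (Hyman) spline
interpolants to avoid finite-difference noise, and when several curvature
maxima exist the corner at the *largest* $\alpha$ among significant maxima
is taken — the dipole cone produces a second, spurious bend at very small
$\alpha$ where the solution norm grows only slowly, and the
noise-balancing corner is always the right-hand one. Degenerate
non-monotone curves fall back to the grid midpoint with a warning.

**Underestimation correction.** The truncation and regularisation shrink
recovered contrast. The correction is calibrated, per pipeline context
(grid, $\alpha$, SHARP settings), by running the identical chain on a
synthetic sphere of known susceptibility and dividing by the recovered
contrast ratio; the factor is recorded in every output and never applied
silently elsewhere. Because the kernel truncation acts at a fixed voxel
scale, the shrinkage depends on absolute structure size; the calibration
sphere therefore has a fixed 4-voxel radius, representing the smallest
structures of interest (deep grey nuclei, veins). This keeps the factor
mild and grid-stable; larger structures remain under-corrected, mirroring
the residual underestimation expected of truncation-regularised QSM.

## The synthetic study

`phantom_spec()` defines the study conditions: a 96³ grid (1 mm voxels,
3 T, field along the third axis), a piece-wise-regional head phantom
(cortical GM shell, WM core, paired CSF ventricles, caudate, putamen,
globus pallidus, thalamus, and a venous arc bent through the sagittal
plane as a superior-sagittal-sinus analogue), five echoes at
3/8.4/13.8/19.2/24.6 ms, and complex Gaussian channel noise of SD 0.07
regenerated per echo and per repeat. Repeats share the ground truth and
differ only in noise, standing in for back-to-back scans of the same
subject. Per-voxel tissue values are drawn as mean + SD·z from the tissue
table; the default table (χ in ppm: GM 0.02, WM −0.03, CSF 0, CN 0.06,
PU 0.09, GP 0.18, TH 0.02, vein 0.45; T2* 20–500 ms; GM-normalised M0) is
configuration chosen within literature ranges for 3 T brain tissue, and a
user-supplied table reproduces any other parameterisation.
`phantom_from_labels()` ingests an externally obtained voxelised head
model (e.g. a Zubal volume) with nearest-neighbour resampling for users
who have one.

Deliberate simplifications: the venous arc sits at 0.24 of the grid
dimension rather than on the brain surface, so that the venous ROI
survives the 5-voxel SHARP erosion at desk-scale grids; air susceptibility
defaults to 0 (the phantom is self-referenced; `air_chi_ppm` enables an
air-tissue offset for strong background fields); there is no flow,
anisotropy, microstructure or coil/SENSE spatial structure. The phantom is
smooth and piece-wise constant, which flatters piece-wise-constant priors
and makes ground-truth decompositions exact — passing tests demonstrate
correctness of the operators and propagation on such data, not performance
on pathology or textured tissue.

The ground-truth field decomposition uses the reference-scan method: the
local field is re-simulated from the source distribution with everything
outside the brain removed and the mask-mean χ subtracted; the background
is the remainder. This makes `total = background + local` exact by
construction, and the background harmonic inside the mask.

## Noise theory and its validation

Per-echo phase noise is the reciprocal image SNR,
$\sigma_\varphi = c\,\sigma_M / M$, with $c \equiv 1$ for simulated data
and estimated from two-scan ROI statistics
($\sqrt{R/2}\,\mathrm{SD}(M_1-M_2)$, SENSE factor $R$) for measured data.
The combined-field noise is, per pipeline: the weighted-least-squares
slope variance (NLFit; also its a-priori noise), quadrature propagation
through the TE weights (TE-wAvg), and through the $R_2^*$ weights
(SNR-wAvg). Where the background-removal noise attenuation is unknown the
worst case $\sigma(\Delta B_{loc}) = \sigma(\Delta B_{tot})$ is applied.

Propagation through the inversion treats the Tikhonov step as the linear
convolution it is: the variance map is convolved with the squared impulse
response $h^2$, $h = \mathrm{IFFT}[D/(D^2+\alpha)]$, evaluated by FFT.
For spatially uniform variance this reduces to the Parseval closed form
$\sigma/B_0\sqrt{\sum_k (D/(D^2+\alpha))^2 / N}$. A formulation that
filters the variance spectrum directly by the squared k-space kernel was
rejected: it returns exactly zero for uniform variance (the kernel's DC
is zero), contradicting both the closed form and Monte-Carlo. For the
susceptibility-averaging pipeline, first-order propagation covers both
the per-echo $\chi_i$ uncertainties and the magnitude dependence of the
weights, with the analytic sensitivity
$\partial\chi/\partial M_i = (2 M_i TE_i^2/\textstyle\sum_j M_j^2 TE_j^2)
(\chi_i - \chi)$; printed forms of these propagation equations elsewhere
carry spurious $1/n$ factors, so the implementation derives everything
from the combination formulas and lets the Monte-Carlo oracle arbitrate.

`monte_carlo_sigma()` is that oracle: it reruns a full pipeline on
independent noise realisations and returns empirical SD maps. At the
tested conditions (48³ phantom, 200 repeats, fixed $\alpha$ and
correction) the analytic maps agree with the empirical SDs to within a
few percent on a mid-volume line profile, and the single-voxel formulas
agree to ~1% over $10^4$ draws.

One documented tension: with the same $\sigma_\varphi$ maps feeding every
pipeline and a common $\alpha$, the fit-based field noise exceeds the
TE-weighted-average field noise at every voxel (a two-parameter estimator
against an offset-blind one; the ratio is ~1.6–1.8 for five evenly spaced
echoes at tissue $R_2^*$, crossing over only above roughly 120 s⁻¹). The
empirical Monte-Carlo SDs follow the same order. A reported ordering in
which the fit-based pipeline has the *lowest* susceptibility-noise
profile can therefore only arise when the pipelines' L-curves select
different $\alpha$; on the default phantom they do not, and the
corresponding acceptance assertion fails by design rather than being
weakened — the noise validation itself is green.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use a 96³ phantom for the
simulation study (six subjects, shared per-pipeline $\alpha$ and
correction calibrated on the first), 48³ with 200 repeats for Monte-Carlo
noise validation, and 24³–64³ grids for operator round trips; these sizes
were chosen as the smallest at which every structure of interest
comfortably survives the 5-voxel erosion and the truncation scale.
Gauss-Newton fits stop at relative updates below $10^{-6}$ (field/offset)
or $10^{-8}$ ($R_2^*$), capped at 30/25 iterations; $R_2^*$ is bounded to
$[0, 2000]$ s⁻¹ and initialised from the closed-form log-linear fit;
zero-magnitude voxels are excluded and flagged rather than fitted. Wrapped
phase is always reduced to $(-\pi, \pi]$ with the half-open convention;
ties at $\pi$ stay at $\pi$. Variance maps clip tiny negative FFT
round-trip values at zero before square roots. All randomness flows from
one master seed through fixed per-(echo, repeat) sub-streams, so studies
are bit-reproducible.

## Known limitations

Single field strength and single orientation per run (no tensor or
orientation-dependent modelling of white matter); no path-following
unwrapping or SMV-kernel SHARP variants; no iterative (e.g. TGV)
inversion — external per-echo maps can be combined through the
`external_chi` hook instead; scalar SENSE factor only (no g-factor maps);
the underestimation correction is a single global scale per pipeline
context and cannot restore structure-size-dependent shrinkage exactly.
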
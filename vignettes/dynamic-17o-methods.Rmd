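---
title: "Dynamic oxygen-17 brain MRI at desk scale: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic oxygen-17 brain MRI at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The experiment this package models

Dynamic oxygen-17 MRI measures cerebral oxygen metabolism directly: a subject
breathes room air, then 70% ^17^O~2~-enriched gas for about six minutes, then
room air again, while the brain is imaged continuously at the ^17^O frequency.
Inhaled ^17^O~2~ gas is MR-invisible; only after oxidative phosphorylation
converts it to ^17^O water (H~2~^17^O) does it contribute signal. The slope of
the regional H~2~^17^O signal during inhalation is therefore a proxy for the
regional metabolic rate of oxygen consumption (CMRO~2~), and a stroke lesion
is expected to show a reduced signal rise relative to mirrored healthy tissue.

Because no raw patient data are publicly available for this kind of
experiment, the package pairs every analysis stage with a synthetic-data
stage. The phantom and acquisition simulator define the study conditions; the
reconstruction, PSF, partial-volume-correction (PVC) and region-of-interest
(ROI) statistics implement the analysis exactly as it would run on real 4D
NIfTI data plus label masks.

## Signal model

**Kinetics.** Each tissue's H~2~^17^O concentration follows a three-phase
piecewise-linear course: constant at the baseline level until the first gas
switch at `t1` (default 5 min), rising linearly at the tissue's uptake rate
until the second switch at `t2` (default 11 min), then evolving linearly at a
post-inhalation rate until the end of imaging (default 30 min), continuous at
both switches and clipped at zero. The published kinetic models for this
experiment are compartmental, but their printed outputs at this time scale
are well approximated by the piecewise-linear form, which has the great
advantage that every rate is directly interpretable and configurable. Whether
tissue signal keeps rising or washes out after the second switch is left to
the sign of the post-inhalation rate; the default is a slow continued
accumulation (+0.012 per unit baseline per min for brain tissue), consistent
with metabolized water persisting in tissue.

**Default rates.** Baseline levels scale with water content (GM 0.83,
WM 0.70, CSF 1.00, lesion/control 0.80 in arbitrary concentration units).
Uptake rates are 0.030/min per unit baseline for brain tissue and 0.0225/min
for CSF, with post-switch rates 0.012 and 0.010. These four numbers are the
package's calibration: with 1-min frames and the five-frame switch-window
average defined below, they place healthy tissue at a relative level of
about 1.18 and CSF (as a tissue) at about 1.135 — the plateau levels the
methodology is anchored to. The stroke label defaults to healthy kinetics;
experiments impose a deficit by scaling its rates
(`default_tissue_table(stroke_uptake_scale = 0.7)` for a 30% deficit).

**Relaxation and steady state.** ^17^O relaxation in brain is fast
(T1 = 5 ms; T2* = 2.8 ms WM, 2.5 ms GM, 5 ms CSF). With TR = 20 ms,
longitudinal magnetization recovers almost completely between excitations
(`E1 = exp(-4)`), so T1 enters the forward model only through the spoiled
steady-state amplitude `sin(a)(1 - E1)/(1 - cos(a) E1)` — a uniform scale
factor — and not through the kernel shape. T2* decay during the 5.5 ms
readout, by contrast, attenuates high spatial frequencies and is the main
tissue-dependent determinant of the point spread function.

## Phantom geometry

The head is an ellipsoid (default semi-axes 67 x 82 x 62 mm) split into a WM
core (0.68 of the brain semi-axes) and a GM shell; the lateral ventricles are
a pair of paramedian CSF slabs inside the core; the stroke lesion is a sphere
(default radius 15 mm) pushed against one ventricle so the two masks share a
face — the topology of a basal-ganglia infarct next to the ventricle. The
mirrored control label is the exact left-right reflection of the lesion.
Labels are mutually exclusive; the ventricle label wins over the lesion on
overlap (CSF is unambiguous on real segmentations), and the lesion/control
labels win over GM/WM. The midsagittal plane is the central voxel plane of
the left-right axis (0-based index `x -> N-1-x`), and all Fourier operations
use coordinates centred on that same point, so a symmetric phantom
reconstructs to an exactly symmetric image (see below). Real data would have
to be registered to this convention first; registration itself is out of
scope.

The default grid is 32^3 voxels at (7.5 mm)^3 (240 mm field of view). Matrix
sizes are configurable and the test suite mostly uses 24^3 (180 mm FOV),
which still covers an adult head at this resolution.

## Acquisition

The density-adapted 3D radial readout starts every spoke at the k-space
centre with a linear ramp for the first `t0_fraction` (default 0.3) of the
5.5 ms readout, then follows a cube-root law `k(t) = (k0^3 + c(t-t0))^(1/3)`
with `c` fixed by gradient continuity. Beyond `k0` this makes the sample
density per spherical shell constant (`k^2 dk/dt` constant), which is the
defining property of the design and the one the PSF depends on; with
`t0_fraction = 0.3`, `k0 = k_max/2` exactly. Spokes end at the Nyquist radius
`k_max = 1/(2 x 7.5 mm)`.

Spoke directions come from the 3D golden-means spherical scheme
(low-discrepancy increments 0.4656/0.6823 in `cos(polar)` and azimuth), with
one refinement: directions are generated in left-right mirror pairs. Any
even-length contiguous block is then exactly mirror-symmetric as a point set,
so every sliding-window frame of a left-right-symmetric object is itself
symmetric to floating-point precision — which is what makes the
stroke-vs-mirrored-control contrast of a symmetric phantom exactly zero
rather than zero-ish. Blocks of 3000 consecutive spokes have mean resultant
length around 0.01 (tested bound 0.05), so each 1-min frame sees a
near-uniform sphere.

Samples are the exact (non-uniform) discrete Fourier transform of the
per-tissue concentration maps, weighted per tissue by the steady-state
amplitude and `exp(-(TE + t)/T2*)` along the readout, with the phantom held
piecewise-constant over 1-min blocks (matching the frame rate; the
granularity is configurable). Noise is circular complex Gaussian with a
single seed per run. B0/B1 inhomogeneity and flow are not modeled — the
analysis being reproduced does not model them either.

## Reconstruction

Frames are reconstructed by convolution gridding: analytic density
compensation (`min(k, k0)^2`, the closed-form inverse of the trajectory's
sample density), scattering onto a 2x-oversampled Cartesian k-grid with a
width-4 Kaiser-Bessel kernel (Beatty shape parameter), an optional radial
Hamming window `0.54 + 0.46 cos(pi |k|/k_max)`, inverse FFT, and closed-form
deapodization. Two implementation details matter for exactness:

* the oversampled grid has an odd size `2N + 1`, so every spatial frequency
  has a paired negative and mirror symmetry survives gridding exactly;
* the inverse transform is evaluated at the voxel-centre coordinates
  `j - (N-1)/2` through a half-voxel phase ramp, so image indices line up
  with phantom voxels for any matrix parity.

The gridding path is validated against `direct_reconstruct()`, an exact
(slow) density-compensated adjoint DFT evaluated at every voxel centre; the
two agree to well below 1% RMS on normalized point-source kernels. "Sliding
window" frames use stride = window (3000 projections = 1 min per image),
which is what the printed frame counts imply (90000/3000 = 30 images,
120000/3000 = 40); leftover spokes are discarded with a warning.
Zero-filling pads the discrete spectrum symmetrically (with Nyquist-plane
splitting for even sizes), which sinc-interpolates the frame onto a
`factor`-times finer grid while reproducing the original samples exactly.

## PSF, effective resolution, and T2* bias

The PSF is the reconstruction of a unit point source whose samples carry the
same steady-state and T2* weighting as the data, through the same gridding
and Hamming filter. The kernel is refined 8x by zero-filling and its FWHM
measured by linear interpolation on the three axis profiles through the peak,
then averaged (the radial trajectory makes the kernel near-isotropic, so the
axis choice is immaterial). With the default protocol this yields about
2.29 voxels for WM (T2* 2.8 ms), 2.33 for GM (2.5 ms) and 2.15 for CSF
(5 ms); times the 7.5 mm voxel these give effective resolutions of about
17.2, 17.5 and 16.1 mm. Effective resolution is defined as FWHM x nominal
voxel size, and both numbers are reported independently rather than forcing
one rounding convention onto the other. The T2* signal bias at the echo time
is the closed form `exp(-TE/T2*)`, reported relative to CSF: WM 92%, GM 89%.

## GTM partial-volume correction

With regions `r_1..r_R` and per-region PSFs, the observed regional mean is
modeled as `obs_i = sum_j G[i,j] true_j` with
`G[i,j] = mean over mask_i of (mask_j convolved with PSF_j)`; the corrected
values are `G^{-1} obs`, frame by frame. Kernels are normalized to unit DC
gain (smearing conserves signal), truncated at the radius enclosing 99.9% of
their energy, and applied by circular FFT convolution. The PVC region set is
GM, WM, CSF and stroke; the mirrored control is analyzed only in the
uncorrected pathway, mirroring the described procedure. The solve is guarded
by a condition-number ceiling (default 1e6) and fails with advice to merge
regions rather than returning a degraded inversion. No nonnegativity
constraint is applied to corrected values. On a noise-free forward smear the
round trip recovers true regional values to ~1e-15 relative; under iid noise
on the observed means the correction amplifies variance, and the
amplification grows as a region shrinks relative to the PSF — the package's
reproduction of the finding that PV-corrected curves from a small stroke ROI
are too noisy to interpret.

## ROI statistics

All time courses are normalized to the mean of the first five 1-min frames
(the 5-min baseline). The post-inhalation level is the mean of five frames
centred on the frame whose mid-time is nearest the second switch (two before,
the centre, two after); when the switch falls exactly between two mid-times
the later frame is taken — the symmetric reading of "around the switch".
Baseline variability is the sample (n-1) standard deviation of the first
five frames relative to their mean. The stroke-vs-control contrast is the
ratio form `(1 - A/B) x 100`; the printed means 1.158/1.168 give 0.9% under
this definition, which is why it was adopted over the
difference-of-increases reading. ROIs near the ventricles are shrunk by
subtracting the ventricle mask dilated twice with the 6-connected structuring
element — the most conservative one-voxel-per-step margin. Relative
signal-increase maps divide (end-of-inhalation minus baseline) by baseline on
Hamming-filtered, 8x zero-filled condition images (three 1-min frames each),
masking voxels whose baseline falls below 10% of the in-brain median to avoid
division blow-up outside the head (both thresholds configurable).

## What the synthetic data does and does not show

The generator emulates the geometry, timing, sampling and relaxation physics
of the experiment, so tests against it validate the *machinery*:
trajectories, weighting, gridding accuracy, PSF widths, GTM algebra, ROI
bookkeeping, and the power structure of the lesion contrast. It does not
emulate anatomical detail, perfusion or arterial input, isotope
recirculation, B0/B1 maps, or physiological drift — so passing tests say
nothing about those aspects of real data. Two desk-scale effects are worth
knowing about. First, the phantom's ventricles are only one to two voxels
wide, so the *measured* CSF ROI curve sits visibly above the CSF tissue
curve (about 1.16 vs 1.135 at the switch window) due to spillover from
surrounding tissue — the very effect GTM PVC corrects, and a useful reminder
that uncorrected small-ROI values are mixtures. Second, with the PSF at
2.2-2.3 voxels, a lesion a few voxels across retains only part of its true
contrast (about 0.4 of it at the default lesion size): on the synthetic
patient conditions a 30% uptake deficit in the ventricle-adjacent lesion
measures about 1.8%, below the 2.2% baseline variability — reproducing the
null finding — while a four-times-larger cortical lesion measures about
2.5%, above the baseline variability but still PSF-limited. Chasing deficits
much smaller than the baseline CV at this resolution is not realistic, and
the package makes that quantitative.

## Problem sizes and numerical choices

The full-scale protocol (90000 spokes of 32 samples onto a 32^3 grid) runs in
minutes; the test suite and examples mostly use a scaled variant chosen as a
package default for iteration speed: a 24^3 grid, 30 one-minute frames of
300-1000 spokes with TR scaled up to keep the 30-min protocol timing, and
24 samples per spoke (the radial Nyquist count for that matrix). Frame
bookkeeping checks use the full 90000/120000-spoke acquisitions with a small
brain and few samples per spoke, which leaves the arithmetic identical. The
noise level has no canonical published value; it is calibrated per experiment
with `calibrate_noise_sd()` so the control-ROI baseline CV matches the
volunteer-level 2.2%, exploiting the linearity of the reconstruction (ROI
scatter is proportional to k-space noise at high SNR). Monte-Carlo properties
add independent noise realizations to a single noise-free simulation, which
is exact because the forward model is additive.

Numerical tie-breaks and tolerances: `fwhm()` accepts flat-topped profiles
and measures the maximal run edge to edge; the switch-window centre prefers
the later frame on ties; gridding exactness is enforced against the direct
DFT rather than assumed from kernel theory; the GTM kernel truncation is
validated against the untruncated convolution; and dilation is 6-connected
throughout. All protocol constants live in the `sequence_params()`,
`inhalation_protocol()`, `grid_spec()` and `default_tissue_table()`
constructors and appear nowhere else.

## Known limitations

Piecewise-linear kinetics cannot represent the curvature of compartmental
uptake near the switches; the frame counts and window sizes assume the
1-min frame structure; the phantom's mirror symmetry is exact, unlike real
heads, so the zero-contrast property is a machinery check, not a claim about
anatomy; and absolute image scale is arbitrary (everything downstream is
baseline-relative). Voxel-wise PVC, iterative reconstruction, off-resonance
correction, registration and segmentation are out of scope.
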
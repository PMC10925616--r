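---
title: "Methods: qualifying a Lu-177 SPECT/CT chain on digital phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: qualifying a Lu-177 SPECT/CT chain on digital phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(luquant)
```

`luquant` re-creates, on digital phantoms, the chain of physics tests a
clinic performs before trusting a SPECT/CT system for Lu-177 dosimetry. This
vignette is the package's account of the models behind each stage: what is
assumed, which knobs matter, what the synthetic data do and do not emulate,
and where genuinely open design choices were settled.

## Decay bookkeeping and calibrator QA

All decay arithmetic uses
$A(t) = A_0 \, 2^{-(t - t_0)/T_{1/2}}$ with the half-life taken as exactly
6.6500 d — the value recorded on the calibrator QA sheet the package
reproduces, rather than the evaluated 6.647 d, so that sheet arithmetic
round-trips. Timestamps are naive local times in `"MM/DD/YY HH:MM"`; no
timezone or DST handling is attempted because the ledger dialect has none.
The bundled ledger's final row (10/31) deviates from pure 6.65-d decay by
about 0.10%, roughly twice the other rows; this is consistent with a rounded
timestamp at transcription, and the package reports rather than forces it.

Constancy is the signed percent difference
$100\,(A_\text{meas} - A_\text{calc})/A_\text{calc}$, computed against the
decay value by default or against a transcribed `calculated_mCi` column when
verifying an existing sheet (the sheet rounds its decay column to two
decimals, which propagates into the printed percent differences). No numeric
action level is mandated by the programme this mirrors; the `warn_pct = 5`
flag is an institutional convention and configurable. Linearity is an
ordinary least-squares line of measured on expected activity — activities,
not log-activities, because the QA plot is response versus activity — with
the Pearson correlation kept at full precision and rounded to one decimal
only for display.

Activity units convert by the exact definition 1 mCi = 37 MBq.

## Digital phantoms

Three generators replace the physical phantoms:

- **NEMA-style body**: a water-filled elliptical cylinder (semi-axes
  110 × 85 mm, height 180 mm) holding three hot spheres of 22/28/37 mm
  diameter filled with 0.13/0.27/0.63 mCi. Sphere centres are not a measured
  quantity anywhere; the defaults place them 120° apart on a 55-mm-radius
  circle in the central plane, the usual arrangement, and are configurable.
  The exact IEC body contour and cold inserts are not modelled — nothing
  downstream uses them quantitatively.
- **Uniform cylinder** (Jaszczak-style, 216 mm diameter × 186 mm interior)
  with a default fill of 18 mCi, inside the 15–20 mCi range used for Lu-177
  calibration scans.
- **Point-source jigs** for registration QA, deposited with trilinear
  weights so the intensity-weighted centroid equals the requested position
  to machine precision.

Voxelisation uses partial-volume weighting: voxels wholly inside an object
get the full concentration, boundary voxels get the volume fraction
estimated by 3×3×3 subsampling (cylinder slice ends are handled
analytically). On the 4.42-mm grid this reconstitutes each sphere's activity
to well under 1%, and refining the grid shrinks the error further. The
attenuation map is single-energy water, $\mu = 0.0137\,\text{mm}^{-1}$ at
208 keV from standard attenuation tables (no value is measured in a
commissioning report; it is configurable); bone and air are not modelled.

## Acquisition model

A view at gantry angle $\theta$ is produced by (1) blurring the activity
with a separable, distance-independent Gaussian PSF, (2) rotating the
volume by $-\theta$ about the axial axis, (3) weighting every voxel by its
attenuation survival $\exp(-\int \mu\, dl)$ integrated along $+y$ to the
volume edge (half-voxel self-attenuation at the source voxel), and
(4) summing along $+y$ and scaling by system sensitivity and view duration.
Rotation is a sparse bilinear *splat* operator (the transpose of the gather
interpolator), chosen because splatting conserves counts exactly — a vacuum
point source projects to sensitivity × activity in every view — while its
transpose serves as the exact adjoint for reconstruction.

Scatter is modelled in projection space: the primary sinogram is broadened
by a wide Gaussian (default σ = 20 mm) and scaled by a scatter-to-primary
fraction (default 0.3, a typical photopeak scatter fraction for Lu-177 in a
water phantom). The scattered counts are split across the three protocol
energy windows in proportion to their widths (41.6 / 17.8 / 24 keV), i.e. a
flat Compton plateau across 168.9–252 keV; photopeak counts land only in
the main window. The window bounds are carried verbatim from the protocol
(187.6–229.2, 168.9–186.7, 228–252 keV) rather than recomputed from
"208 keV ± 10%", which would give 187.2–228.8. Poisson noise is applied per
window with a config-held seed; the simulation is bit-reproducible.

Tunables, with defaults and rationale:

| parameter | default | why |
|---|---|---|
| `n_angles` | 60 over 360° | typical body SPECT protocol |
| `duration_s` | 30 s/view | typical clinical value; not printed in any report |
| `psf_sigma_mm` | 4.25 mm (≈10 mm FWHM) | medium-energy collimator resolution class |
| `scatter_fraction` | 0.3 | Lu-177 photopeak scatter fraction in water |
| `scatter_sigma_mm` | 20 mm | scatter is much broader than primary |
| `sensitivity_cps_per_MBq` | 5 | the magnitude such systems calibrate to |
| detector grid | 64 × 64 at 4.42 mm | matches the NM voxel; desk scale |

What the generator does **not** emulate: distance-dependent collimator
response, septal penetration, spectral transport (the window split is a
fixed fraction, not a physics simulation), detector dead time, CT
beam-hardening, and patient anatomy. Consequently, passing tests demonstrate
that the *software chain* — windows, TEW, reconstruction, calibration,
registration, dose conversion — is self-consistent and accurate under a
known forward model (an "inverse crime" by construction); they do not
certify a physical scanner, whose measured calibration factors and offsets
remain facts about hardware.

## Scatter correction and reconstruction

TEW estimates main-window scatter per pixel as
$\hat{S} = (C_l/W_l + C_u/W_u)\, W_m/2$ and clamps the corrected counts at
zero — negative counts are unphysical, and the clamp is exercised only where
the estimate exceeds the (noisy) main window. Under the simulator's
width-proportional window split, TEW is exact in expectation, so residual
scatter error in the closed loop is noise-driven.

Reconstruction is MLEM with optional ordered subsets over interleaved angle
sets. The system matrix matches the simulator (attenuation from the CT-grid
μ map resampled to the NM grid, Gaussian resolution modelling), and forward
and back projector are exact transposes, so full-data MLEM retains its
monotone-likelihood guarantee (verified in the tests). Defaults are 5
iterations × 8 subsets = 40 MLEM-equivalent updates — enough for count
conservation within 1% on the phantoms used here; no vendor discloses its
iteration budget, so this is a package choice. Data are normalised to cps
before reconstruction; the reconstructed image is therefore in cps per
voxel, and doubling the acquisition duration changes only the noise, not the
scale. Voxels with zero sensitivity (outside the field of view at all
angles) are fixed at zero.

## Calibration and sphere recovery

The volume-sensitivity calibration factor is
$CF = \sum_\text{VOI} \text{cps} \,/\, A_\text{VOI}\,[\text{MBq}]$ from the
uniform-cylinder scan, with the VOI taken as the cylinder mask dilated by
the same 10-mm margin used for spheres so that resolution spill-out is
recaptured. In the closed loop the CF recovers the configured sensitivity
within a few percent; on a real system its value is a hardware fact, which
is why the package tests *recovery of a known truth* rather than any
particular printed number.

Sphere recovery aggregates reconstructed cps over VOIs built from CT-grid
contours: each contour is resampled to the NM grid as a *covering* mask
(any voxel the contour touches), then dilated by a metric 10-mm margin —
dilation thresholds the Euclidean distance, not voxel counts, because the
two grids have different spacings. The covering choice makes zero-margin
recovery exact on a perfectly reconstructed image; a volume-unbiased
0.5-fraction threshold (used by the generic mask resampler) would lose the
partially filled boundary voxels of a 22-mm sphere, about 16% of its
activity at 4.42 mm. Dilated VOIs must stay disjoint; overlap is an error
naming the spheres. Estimates convert as
$A\,[\text{mCi}] = \text{cps}/CF/37$ and percent differences are reported
against the injected activity. No recovery-coefficient correction is
applied — the commissioning procedure this mirrors applies none.

One bookkeeping note: the commissioning measurements bundled with the
package (251.6/109.5/51.5 cps converting to 1.33/0.58/0.27 mCi) are not
arithmetically consistent with their printed percent differences against
0.63/0.27/0.13 mCi; a common factor near 2 suggests an unrecorded
assay-reference correction upstream of the published table. The package
reproduces the count→activity conversions exactly and reports percent
differences by its stated convention; it does not attempt to reproduce
those particular percentages.

## Registration QA and centre of rotation

The offset estimator is the difference of intensity-weighted centroids
(NM − CT, the CT-to-NM difference convention) per source, summarised as a
signed per-axis mean ± SD over sources — centroids rather than Gaussian
fits for robustness at 4.42-mm voxels, which is also why point sources are
deposited with sub-voxel trilinear weighting. Means are kept signed (a QA
sheet may print magnitudes, but the *correction* needs the sign); the gate
is $|\text{mean}| \le 2.2$ mm per axis, the vendor limit spec, with the
alternative one-pixel criterion reported informationally. Five sources per
study is the default (the number behind a printed mean ± SD is not
recorded anywhere; it is configurable). The correction shift is the negated
mean vector; verification re-runs the estimator after shifting the NM
volumes, so the residual measures estimator self-consistency (sub-0.1 mm
noise-free) while accuracy against truth is tested separately by parameter
recovery (±0.3 mm at the default noise level).

COR analysis fits the per-angle lateral centroid of an off-axis point
source to $x(\theta) = r\cos(\theta - \varphi) + c$ via the linear basis
$a\cos\theta + b\sin\theta + c$ — ordinary least squares, no iteration —
and recovers offsets to < 0.1 mm noise-free (cross-checked against a
grid-search oracle in the tests).

## Dosimetry

For a phantom there is no biological clearance, so single-time-point
cumulated activity is $\tilde{A} = A/\lambda$ with
$\lambda = \ln 2 / T_{1/2}$ (an effective half-life can be supplied to fold
in washout). Dose uses the local deposition method:
$D = \tilde{A} \cdot 10^{6} \cdot E_\text{decay} / m_\text{voxel}$ Gy, with
$E_\text{decay} = 147.9$ keV $= 2.3696\times10^{-14}$ J — the mean beta
plus conversion/Auger electron energy per Lu-177 decay from standard
evaluated decay data (a package constant, not a commissioning measurement)
— and voxel mass defaulting to water density × voxel volume. LDM is a good
approximation at SPECT voxel sizes because the Lu-177 beta range (~0.6 mm
mean) is far below 4.42 mm. Kernel-convolution (voxel-S-value) dosimetry is
exposed only as a `kernel_fun` hook: no validated Lu-177 kernel ships with
the package, and fabricating one was out of scope. Energy conservation
(`sum(D·m) = decays × E`) holds to 1e-9 relative by construction and is
asserted in the tests.

## Numerical choices and degenerate inputs

- Rotation operators are sparse matrices built once per geometry; square
  in-plane voxels are required (asserted).
- Gaussian blur matrices are symmetric and truncated at 4σ; edge rows lose
  a little mass, which is irrelevant for centred phantoms and identical
  between simulation and reconstruction.
- MLEM divides by the subset sensitivity only where it is positive; empty
  projections yield zero images rather than NaNs.
- Zero-activity phantoms, empty contour lists, all-zero sinograms and
  zero-margin VOIs all return well-defined empty/zero results; geometry
  violations (sphere outside body, disjoint fields of view, overlapping
  VOIs, out-of-grid sources) raise classed errors.
- Double trilinear resampling (shift + unshift) smooths by a tent-kernel
  convolution; the package guarantees exact centroid restoration — the
  property registration relies on — rather than voxelwise identity.

## Problem sizes

The package computes everything at desk scale: the default end-to-end run
uses a 64 × 64 × 48 emission grid, 60 views, and 40 reconstruction updates
per phantom (about half a minute on one CPU), and the test suite exercises
the same code paths on 16–24-voxel grids with 8–24 views. These sizes were
chosen so that the complete qualification chain, including both
reconstructions, runs interactively; all tolerances quoted above were
measured at these sizes.
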
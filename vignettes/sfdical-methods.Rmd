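---
title: "Model-based SFDI calibration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based SFDI calibration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfdical)
```

This vignette explains the models behind `sfdical`, the conventions the
implementation commits to where the underlying physics literature is
ambiguous, the study conditions encoded in the digital twin, and the known
limitations. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## 1. Imaging model

Both the camera and the projector are pinhole devices: a 3D point `P` in
global coordinates maps to a pixel `p = (u, v)` through

```
s p~ = A [R | t] P~,     A = [[fx, 0, cx], [0, fy, cy], [0, 0, 1]]
```

with radial distortion `delta_r = u (k1 r^2 + k2 r^4 + k3 r^6)` and
tangential distortion `(2 p1 u v + p2 (r^2 + 2u^2), p1 (r^2 + 2v^2) + 2 p2 u v)`
applied in *normalized image coordinates* (after the perspective divide,
before the intrinsic mapping) — the convention of the standard
computer-vision calibration model, which the source equations do not state.
Pixels are 0-based, `(u, v) = (column, row)`, centers at integer coordinates.
Up to three radial terms are accepted; more raise a configuration error.
Undistortion is a damped fixed-point iteration (tolerance 1e-10, at most 50
iterations) that reports its residual on failure.

The camera pose is the identity and defines the global frame; the projector
pose is the projector-to-camera transform obtained during calibration.

## 2. Geometric calibration

Planar circle-grid poses give 3D–2D correspondences. For the projector the
image points are obtained indirectly: patterns along the DMD columns and rows
encode the chip coordinates in their phase, and the unwrapped phase sampled
(bilinearly) at each detected marker centroid decodes to
`u_DLP = phi_u / (f_col 4 pi / N_col)`. Detection thresholds the DC image,
extracts blobs with EBImage, takes *darkness-weighted* sub-pixel centroids,
identifies the three enlarged corner markers by blob area (origin largest,
then the x- and y-axis markers), and orders all centroids by an affine
estimate from the markers refined by a full homography. The perspective bias
of circle centroids (an ellipse's centroid is not the projected circle
center) is ignored: for millimeter circles at a third of a meter it is far
below the centroid noise.

The solver is Zhang-style: normalized-DLT homographies per pose, closed-form
intrinsics from the homography constraints, extrinsics per pose, then a
Levenberg–Marquardt bundle refinement (via `minpack.lm`) of intrinsics,
radial distortion and all poses against the reprojection error. No
R-ecosystem package provides this solver, so it is implemented in-package and
validated against exact synthetic correspondences, where it recovers every
parameter to well below 0.1%.

Two properties of the default (telephoto, 21.6 mm field at 320 mm) geometry
matter for interpretation:

* **Focal-length/distance ambiguity.** At a 3.9 degree field of view, `fx`
  and the working distance are almost degenerate. With mathematically exact
  correspondences the solver recovers the truth to machine precision, but
  0.05 px of centroid bias already moves the virtual projector center by
  millimeters. The virtual device centers are therefore not characteristic
  points of the physical setup; only the full parameter set is meaningful.
* **Unobservable distortion terms.** Tangential terms and `k2` displace
  pixels by less than 0.01 px over this chip, so the twin's ground-truth
  devices carry a single `k1` term per device and the calibration tests fit
  one radial term. The model itself supports `k1..k3` plus tangential terms.

Per-pose projector-to-camera transforms are averaged (quaternion mean for the
rotation, arithmetic for the translation) and their spread is reported. The
reference plane passes through the calibrated-volume center, normal to the
camera optical axis. Predistorted DMD patterns are generated by intersecting
each DMD pixel ray with the reference plane and sampling the target metric
fringe field there.

## 3. Phase handling and 3D reconstruction

Phase-shift demodulation solves the linear model
`I_i = DC + AC cos(phase + delta_i)` by least squares over the shift set,
which equals the classic three-step closed form for shifts {0, 2pi/3, 4pi/3}
and is exact on noise-free sinusoids for any three or more distinct shifts.
Pixels with `i_ac <= max(1e-6, 0.01 * median(i_ac))` are masked.

Absolute phase is obtained *temporally*: every acquisition includes a
low-frequency anchor pattern (default 0.01/mm, less than half a period across
the field, so its wrapped phase is already absolute) and each higher
frequency takes the 2pi branch closest to the frequency-scaled previous map.
A quality-guided flood-fill spatial unwrapper (quality = AC amplitude,
independent components flagged) is provided for stacks without an anchor;
the specific unwrapping algorithm of the original hardware system is not
reproduced, and behavior on steep phase discontinuities is
implementation-defined.

Phase-to-distance conversion is parameterized per pixel: each camera ray is
sampled at its intersections with 10 virtual planes spanning the calibrated
volume in z (uniform spacing; 10 planes follow the published protocol), every
sample is mapped through the projector model to its global phase, and a cubic
polynomial `l(phi)` is fitted by least squares after per-pixel centering and
scaling of the phase (for conditioning). Monotonicity of the cubic over the
sampled range is asserted at fit time; the fit residual is below a
micrometer over the volume, and out-of-range phases at evaluation time are
masked and counted. The cubic is evaluated directly per pixel (a cited
fast-evaluation scheme is not reproduced; results agree within float
precision). `P = e_cam * l` then gives the 3D point.

Normals come from a local-plane PCA over the valid 3D points in the
surrounding window (default `k_neighbors = 16`, a 5x5 window on the pixel
grid — organized-cloud estimation, much faster than a k-d tree and equivalent
on grid data), oriented toward the camera (`n . e_cam < 0`). All downstream
cosines take absolute values consistently with this orientation convention.

## 4. Angles and the frequency correction

For every surface point a local frame is built from the normal (`e_z`), the
fringe (constant-phase) direction projected along the projector ray onto the
tangent plane (`e_x`), and `e_y = e_z x e_x`. Rays are expressed in this
frame and converted to a **polar angle** `phi` (from the normal; stored as
`phi_pro`, `phi_cam`) and an **azimuth** `theta` measured from the in-plane
pattern propagation direction `e_y` (stored as `theta_pro`, `theta_cam`).
The published equations are internally inconsistent about which symbol is the
polar angle (their reported flat-phantom means — incidence 35 degrees called
`phi`, near-zero azimuth called `theta` — contradict the arccos/arctan forms
as typeset), so the package commits to the convention above, which reproduces
those reported means on the twin's flat phantom: that check is part of the
acceptance suite.

The angular fringe-scaling factors are

```
scaling_parallel(tilt, azimuth)      = sqrt(cos^2 tilt + sin^2 azimuth * sin^2 tilt)
scaling_perpendicular(tilt, azimuth) = sqrt(cos^2 tilt + cos^2 azimuth * sin^2 tilt)
```

and the corrected local frequency is `f_corr = f_ref * S_z * S_ang` with the
magnification `S_z = |P_ref| / |P|` (reference point on the same camera ray).

**Normalization (a genuinely open design point).** Applied literally, the
angular factor is not 1 at the reference configuration (oblique incidence
makes it `cos 35deg`), although the predistorted patterns *define* `f_ref`
there. The package therefore normalizes each angular factor by its value for
a *reference-oriented flat patch at the same surface position*
(`normalize = TRUE`, the default). This choice

* leaves a flat sample at the reference plane with all factors exactly 1,
* attributes pure height shifts entirely to `S_z` (a plane moved −10 mm gets
  exactly `f_ref * 320/310` everywhere), and
* tracks the true local fringe frequency — computed independently from the
  gradient of the projected phase field — to about 1% on a 40 mm spherical
  cap.

`normalize = FALSE` gives the literal printed composition; it is what the
acceptance script uses when reproducing the published hemisphere numbers,
because the published gradient (down to ~0.28/mm for a 0.45/mm pattern, with
the map never exceeding the nominal frequency) is only consistent with the
unnormalized form. On the same scene the normalized physical variant yields a
smaller mean deviation (~8.5%) and the printed form a larger one (~18%),
bracketing the published "about 15%"; the discrepancy is inherited from the
source's angle-convention ambiguity and is left visible rather than tuned
away. A second open point — whether tilts perpendicular to the fringes should
also rescale the frequency — is implemented as printed (parallel factor only)
with the alternative behind `include_perpendicular = TRUE`.

## 5. Intensity correction, MTF look-up and reflectance

The Lambert factor `cos(phi_cam) * S_perp * S_par` models the cosine-law
signal attenuation of a Lambertian patch relative to normal incidence and
detection. Measured intensities are **divided** by it: the source's equations
multiply, but a factor that is at most 1 must be divided out to remove the
orientation dependence — multiplying would square it in the reference ratio
and make "corrected" strictly worse than uncorrected, contradicting the
method's own validation. The acceptance suite asserts the corrected-error <
uncorrected-error ordering that this choice guarantees.

The reference standard, measured at 6 positions spanning the calibrated
volume and 9 frequencies in 0–1/mm (the published protocol), yields per
camera pixel a node grid of Lambert-corrected intensities over
(distance l, corrected frequency f): the DC row at f = 0, AC rows elsewhere.
Nodes are sorted per pixel by l (duplicates averaged and flagged); queries
interpolate bilinearly along l and f and return NA outside the node hull by
default (`policy = "clamp"` is available). Node queries are exact by
construction. Because both the look-up table and later measurements key their
frequency axis by the *same* corrected-frequency definition, the reference
ratio

```
R_SFD(f) = (I_AC / S_Lambert) / MTF_ref(l, f_corr) * R_SFD,ref(f_corr)
```

is self-consistent under either normalization convention; the DC channel
averages `(I_DC / S_Lambert) / MTF_ref(l, 0) * R_SFD,ref(0)` over all
acquired frequencies. The unwrapping-anchor frequency is excluded from the
reflectance (it exists for geometry only); whether the DC average should run
over all frequencies was open and is implemented over all of them.

Reference surfaces for the look-up table are reconstructed from a mid-range
frequency (the one closest to the phase-distance model frequency), not the
highest: defocus crushes the modulation of high-frequency patterns at the
volume edges and would poison the geometry there.

## 6. Forward model and inversion

The semi-infinite forward reflectance is the standard diffusion
approximation in the spatial frequency domain:

```
mu_tr = mu_a + mu_s',  mu_eff'(f) = sqrt(3 mu_a mu_tr + (2 pi f)^2),
a' = mu_s'/mu_tr,      R(f) = 3 A a' / ((mu_eff'/mu_tr + 1)(mu_eff'/mu_tr + 3A))
```

with `A = (1 + r_eff)/(1 - r_eff)` and `r_eff` from the Groenhuis-style
polynomial in the refractive index. This deliberately replaces the original
order-11 analytical radiative-transfer solution, which is out of scope along
with the surface-roughness parameter it supports; the model sits behind a
single `forward(f, mu_a, mu_s_prime, n)` interface so a higher-order solution
can be dropped in. The digital twin uses the *same* model, so end-to-end
recovery tests are closed: they validate the calibration and correction
chain, not the radiative-transfer physics.

Inversion is bounded Levenberg–Marquardt least squares per 16x16-binned cell
(binning is mask-aware; cells under half-valid are masked), started from the
best cell of a log-spaced 8x8 (mu_a, mu_s') grid to avoid local minima, with
bounds mu_a in [1e-5, 10], mu_s' in [1e-3, 20] 1/mm. Fits are invariant to
frequency ordering and duplicated points; degenerate inputs (all-zero R,
fewer than two frequencies) are flagged, not fitted.

## 7. The digital twin and its study conditions

The twin renders, per camera pixel: ray–surface intersection (analytic for
planes and spherical caps; no mesh tracing), the pattern phase at the hit
point through the ground-truth projector (for predistorted metric patterns
this is the fringe field at the reference-plane piercing point of the
projector ray, which is exact and distortion-consistent), and intensity

```
I = gain * V(u,v) * S_Lambert * (R_dc + m * MTF_defocus * R_ac(f_local) * cos(phase + shift))
```

with radial vignetting V, modulation depth m = 0.8, gain 0.5 (keeps
intensities in TIFF range), Gaussian defocus
`MTF = exp(-2 pi^2 f^2 (0.027 |l - 316| mm)^2)` — blur growing linearly away
from a 316 mm focal plane, chosen so high frequencies are resolvable only
within roughly ±8 mm, qualitatively matching the published depth-of-field
behavior; the real hardware MTF and noise levels are unknown and not
claimed. `R_ac` is evaluated at the *model-corrected* local frequency, so the
twin embodies the geometric frequency-scaling model itself; a physical
surface additionally chirps the fringes continuously (the model tracks that
true field to ~1–3% here). Additive Gaussian, multiplicative Gaussian and
Poisson shot noise are available and seeded explicitly; identical seeds give
bit-identical fixtures.

Defaults mirror the published setup: a 2048 px camera viewing 21.6 mm at
z = 320 mm (fx about 30341 px, k1 = -0.2), a 1920x1080 DMD projector at 35
degree oblique incidence aimed at the field center from 361 mm (the distance
implied by the published device centers — the published center coordinates
themselves imply a 30.4 degree incidence, inconsistent with the stated and
reported 35 degrees, so 35 degrees wins), an illuminated area of
56.8 x 27.9 mm, a calibrated volume of 21.6 x 21.6 x 25 mm, three phase
shifts of 0, 2pi/3, 4pi/3, measurement frequencies 0.01–0.45/mm and reference
frequencies 0–1/mm. The reference standard is a turbid plate with
mu_s' = 2.5/mm, mu_a = 0.01/mm, n = 1.5; its reflectance table is the forward
model evaluated on a fine frequency grid. The nine wavelength-analogue
phantom pairs (`twin_phantom_pairs()`) span mu_s' 1.48–2.40/mm and mu_a
0.08–0.30/mm with the 521 nm analogue fixed at the published
integrating-sphere values (1.98, 0.18)/mm, n = 1.52, g = 0.6.

One published condition cannot be reproduced literally: a 40x40 circle grid
at 2 mm spacing spans ~80 mm, four times the stated 21.6 mm field, so
full-grid visibility (which detection requires) is impossible at that size.
`calibration_target()` defaults to the published target; the calibration
tests use a 13x13 grid at 1.4 mm spacing that fits the field.

**Problem sizes.** Tests and the acceptance script run the twin at reduced
camera resolutions — 256 px for calibration imagery and the deterministic
frequency-map statistics, 128 px for topography and angle recovery, 96 px
(binning 12) for the 27-run multispectral experiment, 64 px for shared unit
fixtures — sizes at which every reported statistic is resolution-converged
(field means and medians, not per-pixel extremes). The full 2048 px default
remains available.

## 8. What passing tests do and do not show

The twin exercises geometry, radiometry, noise propagation and the entire
correction chain with known ground truth, and the suite checks printed-value
reproductions (hand-evaluated projections, distortion displacements, phase
decodings), solver recovery against exact correspondences, sub-micrometer
noise-free closure, published-protocol analogues (35 degree mean incidence,
≤15 um flat-target residual at AC/sigma = 100, ≤5%/12% recovery of mu_s' and
mu_a under 1% intensity noise) and the corrected-vs-uncorrected ordering.
It does not show: radiative-transfer fidelity beyond the diffusion
approximation (shared by twin and inversion), robustness to specular
reflections, non-Lambertian references, subsurface-scattering blur of the
fringes, real sensor artifacts (gamma, fixed-pattern noise, saturation), or
phase unwrapping across steep discontinuities. Multi-view fusion, meshing,
machine-learning inversion and hardware control are out of scope.
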
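---
title: "Methods: simulating and reconstructing dual-focal-spot CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and reconstructing dual-focal-spot CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dfsct)
```

This vignette is the package's own account of its models and the design
choices behind them. Numbers quoted here are either definitions or values
that the test suite and `scripts/acceptance.R` compute.

## 1. The geometric question

A circular-orbit cone-beam scan only measures the central slice exactly;
every off-plane slice is reconstructed from rays that leave the axial plane
by their *cone angle* $\kappa$, and filtered backprojection degrades as
$\kappa$ grows. Wide single-source detectors buy z-coverage with large cone
angles: a 140 mm collimation reaches $\kappa = \arctan(70/541) = 7.4^\circ$
at its edge rows. A dual-focal-spot single-detector (DFSSD) system instead
places two spots at $z = \pm 45$ mm over one 100 mm detector. Each spot
illuminates an iso-plane interval of 100 mm shifted by
$\pm 45 \cdot D/(R+D)$, so the union covers
$W + d\,D/(R+D) = 138.7 \approx 140$ mm while the *effective* cone angle
(the smallest $|\kappa|$ over the spots covering a slice,
`min_cone_angle_at_z()`) peaks at $\arctan(45/541)=4.8^\circ$ on the
mid-plane and vanishes on the two spot planes. All geometric arithmetic
uses the shared constants $R = 541$ mm (source-to-iso), $D = 408$ mm
(iso-to-detector), 888 channels of 0.58 mm at iso (fan angle
$\Gamma = 888\cdot 0.58/541 = 54.5^\circ$), and 0.625 mm rows at iso.

The detector element size is quoted as $0.58 \times 0.62$ mm at iso while
the slice thickness is 0.625 mm; we treat the row pitch as exactly
0.625 mm (64/224/160 rows for 40/140/100 mm collimation) so that rows tile
the collimation without remainder.

Coordinates: z along the rotation axis, iso-center at the origin, gantry
angle $\beta$ counter-clockwise seen from $+z$ with the source at $+y$ for
$\beta = 0$; the channel angle $\gamma$ increases along
$-(\cos\beta, \sin\beta, 0)$, which makes the conjugate of a ray
$(\beta, \gamma)$ the pose $(\beta + \pi - 2\gamma, -\gamma)$. The shared
detector is a cylinder of radius $R + D$ around the source's xy-position
(the two spots differ only in z, so one curved detector is exactly focused
for both), with rows flat in z and centered on the gantry plane.

### View schedules

Axial full scans use one rotation of 984 views per spot; axial half scans
use the minimal complete short-scan range $180^\circ + \Gamma = 234.5^\circ$
with the same angular spacing; helical scans advance the table by
`pitch × collimation` per rotation (the pitch factor is normalized to
collimation for every geometry, including DFSSD). The two DFSSD spots fire
in strict alternation, the second offset by half a view period, so one
rotation holds 1968 views; each view carries half the single-source
per-view tube load, keeping the rotation total at 240 mAs (120 mAs per
spot). Whether the real system alternates or fires simultaneously is not
public; alternation is the natural reading of a doubled projection count on
a single shared detector.

## 2. The phantom generator

`helical_body_phantom()` emulates an oval body phantom built to provoke
cone-beam artifacts: a water elliptic cylinder (semi-axes
$225 \times 150$ mm, 160 mm long, $\mu_w = 0.0193$ mm$^{-1}$ at a 70 keV
effective energy) with

* 12 Teflon rods (+900 HU, radius 6 mm, length 120 mm) on a ring at 80% of
  the torso semi-axes, axes along the local ellipse tangent tilted out of
  plane by angles drawn once from $U(10^\circ, 35^\circ)$ with a fixed
  seed, and rod centers staggered along z over $\pm 38$ mm like a rib
  cage — the stagger keeps high-contrast longitudinal gradients present
  throughout the volume, and its span is the largest for which the
  steepest-tilted rod still fits inside the torso;
* two lung-equivalent cone frusta (−700 HU, base radius 45 mm, apex 5 mm,
  height 120 mm) at $x = \pm 70$ mm straddling the mid-plane, giving
  low-contrast structure whose cross-section changes continuously in z.

The exact insert layout of the original physical phantom is not published;
these are declared emulation parameters (every one is an argument), chosen
so that the features that matter — tilted high-contrast rods and z-varying
low-contrast structure — exist at every evaluation slice. Attenuation is
*additive* over primitives (no overwrite priority), which keeps every line
integral an order-independent closed form: the chord of each quadric
(ellipsoid, elliptic cylinder, capped circular rod, plane-capped cone
frustum) solves a quadratic, and the integral is
$\sum_i \Delta\mu_i \cdot \text{chord}_i$. The unit tests verify this
against midpoint sampling at 0.05 mm steps on 1000 random rays (within
0.1% relative), additivity over ray partitions ($10^{-9}$), and mirror
symmetry for symmetric layouts.

What the generator does *not* emulate: anthropomorphic texture, motion,
polychromatic materials. Passing tests therefore demonstrate the
geometry-driven artifact and noise behavior of the three systems, not
absolute clinical image quality.

## 3. Forward model

Projections are exact line integrals $p$ degraded by a monoenergetic
Poisson model:

$$\lambda = N_0\, \mathrm{mAs}_\mathrm{view}\, b(\gamma)\, e^{-p},\qquad
N \sim \mathrm{Poisson}(\lambda),\qquad
\hat p = -\ln\frac{\max(N, 0.5)}{N_0\,\mathrm{mAs}_\mathrm{view}\,b(\gamma)}.$$

* $N_0 = 2\times10^5$ photons/mAs per element at iso — a calibration
  constant chosen to put body-phantom noise in the tens of HU at 240 mAs;
  only *relative* noise comparisons across geometries are meaningful, since
  the absolute calibration of any particular scanner simulator is unknown.
* $b(\gamma) = \exp(-\mu_w\,[L(0)-L(\gamma)])$ with $L$ the chord of a
  300 mm water cylinder: an idealized body bowtie that exactly flattens
  detected flux for a centered 300 mm water load; $b(0)=1$, even in
  $\gamma$.
* The photon floor of 0.5 counts before the log is the standard guard
  against $\ln 0$ in photon-starved rays.
* Detector elements are point-sampled at their centers; spatial resolution
  is out of scope, so no aperture integration, focal-spot blur, scatter,
  cross-talk or electronic noise is modeled, and the monoenergetic beam
  deliberately omits beam hardening (orthogonal to the cone-angle
  question).

The noiseless path is bit-exact: $\hat p \equiv p$, tested to $10^{-12}$.
Noise obeys the delta-method variance $1/\lambda$ (tested within 3
standard errors over 200 repeats) and reconstructed noise scales as
$1/\sqrt{\mathrm{mAs}}$ across 60/240/960 mAs (20 replicates).

## 4. Reconstruction

The chain is the equiangular Feldkamp-type weighted cone-beam FBP:

1. **Pre-weight** each element by $R\cos\gamma\cos\kappa$.
2. **In-plane redundancy weights, applied before filtering.** This is the
   package's central numerical design decision. Redundancy weights that
   vary across the fan must multiply the *projections*, not the filtered
   values: the ramp filter is nonlocal, and in a short scan roughly 40% of
   views lie in the Parker ramp regions where the weight swings from 0
   to 1 across the detector. Applying those weights after filtering
   (pixel-wise, at $\gamma$ of the voxel) produced a measured −62 HU
   off-center bias in a water cylinder; applying them before filtering
   restores the textbook short-scan identity and the water test holds to
   a fraction of an HU everywhere. Concretely:
   * axial full scan: factor 1/2 (every line is measured twice);
   * axial half scan: Parker weights
     (pair sums $w(\beta,\gamma) + w(\beta+\pi-2\gamma,-\gamma) = 1$,
     verified to $10^{-9}$ over $10^4$ random rays);
   * helical: per-slice generalized redundancy weights (below).
3. **Ramp filter** along channels with the equiangular kernel
   ($g(0) = 1/(8\Delta\gamma^2)$,
   $g(m) = -1/(2\pi^2\sin^2 m\Delta\gamma)$ for odd $m$), zero-padded to
   twice the row length; the shared "standard" kernel multiplies the ramp
   by a Hann window rolled off at 80% of Nyquist. All geometries use the
   same kernel, so noise comparisons are kernel-fair.
4. **Voxel-driven backprojection** with bilinear detector interpolation,
   inverse-square distance weight $1/L^2$ ($L$ the in-plane source–voxel
   distance), and the exact short-scan scaling
   $\mu = 2\Delta\beta \sum_v w_v q_v / L_v^2$.

### Cone-angle-dependent pixel-wise weighting

The published functional form of the 3D weighting used by the original
study is not public; the package adopts $\cos^k\kappa$ with $k = 2$ as the
documented stand-in ($k$ configurable, $k = 0$ giving a bit-identical
plain-FDK control path). Where the two DFSSD beams measure the same pose,
each view's contribution to a voxel is $\cos^k\kappa_{\text{spot}}$
normalized over the covering spots — unit effective redundancy per pose,
verified to $10^{-6}$. At CT cone angles ($\le 8^\circ$)
$\cos^2\kappa \ge 0.98$, so with the default exponent the blend is close
to an even split: it preserves noise averaging where beams overlap rather
than aggressively selecting the less oblique beam. That trade-off is
deliberate and documented; a much larger $k$ would reduce cone artifacts
in overlap zones at the cost of noise uniformity.

### Detector truncation

At edge slices most of the field of view is only partially covered: the
voxel's ray exits the collimation for part of the rotation. Dropped rays
destroy those slices entirely, so the backprojector extrapolates with the
nearest detector row (standard FDK practice). For the dual-spot geometry a
pose is extrapolated only when *no* spot genuinely covers it, from the
spot whose detector edge is nearest (exact ties split evenly — the tie
handling matters: taking both spots at full weight biased the air region
by over 100 HU in an early version of the air calibration check).

### Helical weighting

Helical reconstruction is per-slice: every measurement of an in-plane line
through the slice — multi-turn repeats $\beta + 2\pi n$, conjugates
$\beta + \pi - 2\gamma + 2\pi n$, and the other spot's poses — shares unit
weight, each measurement scored by a raised-cosine apodization of the
slice's detector-track position (1 at the detector center, 0 at the
physical z-edge) times $\cos^k$ of the iso-reference cone angle. This
replaces a fixed tapered $180^\circ+\Gamma$ window for three measured
reasons: a per-voxel window weight applied post-filter carried the same
bias mechanism as post-filter Parker (±46 HU off-center); with two spots
whose windows are disjoint in $\beta$ the window formulation double-counted
the data (watchable as a doubled water value); and at pitch 0.5 a single
short-scan window discards half of the acquired data, while the
per-line normalization uses all of it — which is what makes helical noise
lower than axial half-scan noise at the same tube load. The weights are
exactly DC-calibrated: water reconstructs to well under 1 HU for all three
geometries at pitch 0.5–1.0, on and off center (see the calibration
tests). The weight construction is validated against a brute-force
enumeration of each line's measurement set.

A consequence worth knowing: each DFSSD spot sits 45 mm from the shared
detector's center, so in helical mode no measurement of a slice is
simultaneously near the detector-track center *and* in-plane — the
geometry carries a $\approx 2.7^\circ$ cone-angle floor in helical scans,
and its helical artifact scores sit closer to the wide single-source
system than to the narrow one. The axial comparisons, where the dual-spot
design pays off, are unaffected.

## 5. Image-quality metrics

* `roi_noise()` — standard deviation of HU inside a 40 mm circle centered
  60 mm above the phantom center (a uniform water region; the function
  rejects ROIs that touch an insert), after subtracting the matched
  noiseless reconstruction. Differencing separates stochastic noise from
  deterministic artifact texture; both conventions are computable but the
  differenced one is the default and the one reported.
* `artifact_score()` — RMSE of the noiseless reconstruction against the
  voxelized truth inside the torso (outline shrunk to 80%) with inserts
  dilated by 2 voxels masked out, so insert-edge band-limiting does not
  dominate the score.
* `line_profile()` — horizontal profiles smoothed by a 5-voxel moving
  average with symmetrically shrinking end windows.
* `percent_deviation()` / `max_noise_deviation()` — the comparison-table
  arithmetic: $100\,(v - r)/r$ to one decimal, maximized over evaluation
  slices (the dual-spot edge contributes one value per coverage end).

Evaluation slices per geometry: center (zero cone angle), intermediate
(quarter collimation), and edge (outermost row center — the geometric
boundary voxels are only half-sampled) for single-source systems; for the
dual-spot system the mid-plane (its largest effective cone angle),
$\pm 22.5$ mm, and the two coverage ends. Helical comparisons use a fixed
absolute-z slice set shared by all geometries (0, ±35, ±55 mm — inside the
phantom's structured region and far enough from its physical ends that
oblique rays do not exit the object, which would otherwise add an
object-end truncation deficit unrelated to the geometry comparison).

## 6. Scale, problem sizes and determinism

The study conditions are preserved at reduced cost by decimating channels
and views per rotation by `scale` (default 0.25: 222 channels, 246
views/rotation/spot) and detector rows by `sqrt(scale)` — rows carry the
longitudinal gradients that drive cone artifacts, so they are decimated
more gently. Fan angle, collimation, coverage, cone angles and the 2×
dual-spot view ratio are invariant under scaling. Reconstruction grids are
128–256² over the 500 mm display FOV; ground truth uses 2× supersampled
voxelization. The study-level tests run at scale 0.1–0.25 on 128–192²
grids; the acceptance script uses scale 0.25 and 256². Gantry rotation
time is recorded as metadata only — the phantom is static, so it is
physically inert.

Every stochastic step is seed-controlled (`withr::with_seed`), so
identical seeds give bit-identical sinograms, volumes and reports; the
pipeline writes a manifest with seeds and file checksums.

## 7. Numerical details and degenerate inputs

* Quadratic chord solvers switch to the linear/contained cases below
  $|A| < 10^{-14}$; cone frusta with steep rays ($A < 0$) take the
  exterior-interval branch.
* Parker weights at the measure-zero corner $\gamma = \pm\Gamma/2$,
  $\beta$ at the scan end are never evaluated by the backprojector
  (channel bounds keep $|\gamma|$ strictly inside the fan).
* Bilinear interpolation clamps the last channel/row index pair; rays
  outside the channel range contribute nothing and rows are extrapolated
  as described above.
* Empty grids, out-of-coverage slices (reported with the offending z),
  helical ranges shorter than one collimation, inserts escaping the torso
  (reported with the primitive index), ROIs touching inserts, zero
  references in percent deviations, and even window widths all raise
  informative errors.
* The half-scan view count is pro-rated at fixed angular spacing
  ($2\pi/984$ per spot), so the sampled range can fall one view short of
  $180^\circ + \Gamma$; the Parker ramp makes the missing sliver's weight
  negligible.

## 8. Known limitations

* Monoenergetic beam: no beam hardening; Teflon/lung contrasts are fixed
  effective-energy surrogates (+900/−700 HU).
* Absolute noise magnitudes depend on the $N_0$ calibration; only relative
  comparisons across geometries at matched total mAs are meaningful. In
  particular, at matched 240 mAs total the dual-spot coverage ends are
  covered by a single 120 mAs beam, and their differenced ROI noise sits
  roughly $\sqrt 2$ above the double-covered baseline — the acceptance
  script reports the resulting maximum slice-noise deviation as computed.
* The $\cos^k$ cone weight with the default $k = 2$ is nearly inert below
  $8^\circ$; it is a documented stand-in for an unpublished weighting
  function, not a reconstruction of it.
* Helical artifact ratios between geometries are sensitive to the
  near-artifact-free narrow-detector baseline (a few HU RMSE); absolute
  helical artifact levels are low for all three systems.
* No iterative or learned reconstruction, no exact helical inversion, no
  MTF/resolution characterization, no dose metrics, no motion.
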
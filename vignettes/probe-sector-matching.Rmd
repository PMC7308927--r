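---
title: "Probe sector matching: model, feedback compensation, and the ring-phantom simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe sector matching: model, feedback compensation, and the ring-phantom simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psm3d)
```

## The problem

Freehand 3D ultrasound sweeps a conventional 2D linear-array probe around a
target by hand while sensors track the probe's position, attitude and
contact pressure; the tracked 2D frames are then compounded into a 3D
volume. Free 6-DOF placement of every frame is expensive and fragile:
pressing the probe squeezes the surface (moving the target), and changes in
the coupling medium stretch the echo travel time, so naively placed frames
produce a distorted volume.

Probe sector matching exploits a geometric constraint: if the imaging
target P is fixed and the probe always aims at an axis L through P, then
every frame plane belongs to the pencil of planes through L. The
reconstruction therefore becomes three steps:

1. **Sector database** — precompute `delta_v` candidate half-planes
   ("sectors") through L at uniform azimuths; `delta_v` half-planes pair
   into `delta_v / 2` full planes (8 sectors = 4 planes dividing the
   surrounding cylinder into 8 equal parts).
2. **Matching** — identify, for each acquired frame, which database sector
   its plane coincides with, using the three-point dual-space form of the
   3D Hough transform.
3. **Compensation and placement** — correct the echo depths with the
   pressure, pose and medium feedback, then paint the frame's pixels into
   the matched plane.

## Plane parameterization and the two Hough routes

All matching happens in the Hesse normal form: a plane is
$(\theta, \varphi, \rho)$ with

$$x\sin\theta\cos\varphi + y\sin\theta\sin\varphi + z\cos\theta = \rho,$$

$\theta \in [0, \pi]$, $\varphi \in [-\pi, \pi]$, $\rho \ge 0$ (mm).
Because the sign of the normal is free, we canonicalize: $\rho \ge 0$
always, and for planes through the origin $\theta \le \pi/2$ (with
$\varphi \in (-\pi/2, \pi/2]$ on the equator). This makes plane equality a
numeric comparison, which the matcher and the tests rely on.

The *accumulator route* (`hough_accumulate()`, `hough_detect_plane()`)
votes every point into each $(\theta, \varphi)$ bin at the $\rho$ bin
containing its dual value, and takes the global peak. Defaults are 1° bins
in both angles and 0.5 mm in $\rho$ — fine enough to separate database
sectors at `delta_v = 128` (2.8125° spacing). Two numerical caveats are
worth stating:

* The accumulator's *angular* discrimination is roughly
  $\rho$-bin / cloud-extent. A cloud only a few mm across cannot pin the
  normal to 1°; clouds spanning tens of mm can. Tests use wide planar
  clouds for exactly this reason.
* Peak ties are broken by the smallest
  $(\theta, \varphi, \rho)$-bin lexicographic index, so detection is
  deterministic.

The *three-point route* (`solve_three_points()`) is the inverse reading:
three non-collinear points determine one parameter-space point, found by
solving the linear system $M m = \mathbf{1}$ with $m = \hat n / \rho$ (an
SVD nullspace handles planes through the origin). This is deliberately a
different algorithm from `plane_from_three_points()` (cross-product
construction); the suite enforces their equivalence on 1000 random triples
to below $10^{-6}$ in the canonical parameters, so the dual-space test used
in matching is cross-checked against elementary geometry.

`match_sector()` implements the matching decision as a point–plane
distance test: the frame contributes two points (the probe contact point
and the deepest point of the contact scanline — both on the frame plane by
construction), and a sector is accepted when the worst of their distances
to its full plane is below `tol` (default `working_radius * 1e-3`; a
scale-free choice, since three non-collinear points always define *some*
plane and the operative question is coincidence with a stored one).
Candidates are tried in order of azimuthal proximity to the probe pose,
which both makes the search near-constant-time and resolves the half-plane
ambiguity (a full plane serves two opposite sectors; the one on the
probe's side wins). Exact ties — a probe exactly on a bisector — go to the
lower sector id, with distances quantized at 1 nrad so float noise cannot
flip the policy. An unmatched frame is skipped and counted, and the
no-match signal carries the advice to rebuild with a larger `delta_v`; we
do not auto-rebuild.

## Sensor models

**Echo time.** Times are *one-way*: $T = 1000\,D/c$ µs for $D$ in mm and
$c$ in m/s, rounded to the 0.1 µs readout. At the reference distance
$n = 4$ mm and $c = 1500$ m/s this gives the 2.7 µs reference time, and
all echo-time errors are $\Delta t = T - 2.7$. The calibration tables
(`surface_change_table()`, `tmc_table()`) are reproduced exactly by this
arithmetic, which only works with the one-way convention even though
physical echoes travel round-trip — we follow the calibrated convention.

**Medium (TMC).** The transmission medium coefficient has no closed-form
relation to echo time; `tmc_echo_time()` interpolates the eight calibrated
control pairs with a monotone (Fritsch–Carlson) cubic, exact at the
controls and refusing extrapolation outside TMC $\in [0.75, 2.77]$. The
medium *distortion* is modeled as an additive time offset
$\Delta t_{\mathrm{TMC}} = T(\mathrm{TMC}) - T_{\mathrm{ref}}$, not a
multiplicative ratio: the calibration defines $\Delta t$ relative to
2.7 µs, and the additive form reproduces the tabulated
displacement-equals-$\Delta t \times c$ relation exactly, whereas a ratio
against the rounded 2.7 µs reference would miss it by up to 0.2 mm. For
targets near the reference distance the two forms are equivalent to first
order.

**Pressure.** The paper's hardware concept gives feedback but no formula,
so the gain is an explicit linear model: squeezing with force $F$
displaces the target toward the probe by $k_p F$ mm (`k_pressure`, default
0.5 mm/N, configurable). The simulator uses the exact inverse
($F = (n - D)/k_p$, clamped at 0), so a closed-loop test can verify the
round trip to $10^{-9}$.

**Edge error.** When the probe face does not sit flush, the effective
working radius of edge elements shrinks. The per-element profile is a
symmetric quadratic bow — zero at the array center, `delta_r_max` at the
edges — the minimal model consistent with the center-flush/edge-lifted
contact picture. It is a modeling choice, exposed as
`edge_error_profile()` and combined with the pressure term in
`corrected_radius()`; the simulator defaults to a flush probe.

## The ring-phantom simulator

The generator reproduces the two numerical experiments: a ring target in
the XY plane imaged at `delta_v` uniform azimuths, once with a surface
perturbation and once with a medium perturbation.

* **Phantom**: a thin-wire torus, centerline radius 10 mm, tube radius
  0.05 mm — the wire-target construction of ultrasound QA phantoms. The
  thin wire matters: echoes arise at the tube *surface*, so a thick tube
  would bias every reconstructed point outward by its radius and no
  reconstruction could approach the centerline closer than that.
* **Frames**: 128 scanlines (one per array element) at 0.3 mm pitch, 512
  depth samples over a 20 mm working radius (0.039 mm/sample). Scanline
  lateral offsets are `(i - ceiling((n+1)/2)) * delta_h`, which puts the
  contact ray *on* a scanline for any element count; a strictly
  element-symmetric even array has no scanline through the contact ray and
  would never insonify a thin wire.
* **Echo rendering** is geometric time of flight: each scanline's ray is
  marched against the torus (0.01 mm grid, bisection-refined to
  $10^{-6}$ mm), the hit distance becomes a one-way time, the medium
  offset is added, and the time is mapped back to a depth sample under the
  *nominal* model — so surface and medium changes appear as pure depth
  displacements, which is exactly what the calibration tables quantify. A
  full-wave simulation would add nothing testable to this arithmetic.
* **Perturbation curves** interpolate the eight calibrated controls
  periodically over azimuth (shape-preserving PCHIP: exact at controls,
  bounded by the control range, periodic by knot replication). Controls
  are placed in cyclic table order *anchored so the reference row
  (D = 4 mm / TMC = 1) sits at azimuth 0*: the reference sector must be
  undistorted because it normalizes everything else. The knot positions
  themselves are not specified by the calibration, so uniform spacing is a
  choice, recorded in the configuration.
* **Sensing semantics**: elevation ($D > n$) moves the probe outward and
  is visible to the pose sensor; squeeze ($D < n$) displaces the *target*
  while the probe stays on its nominal radius, so the pose is blind to it
  and only the pressure reading ($F = (n - D)/k_p$, hence the clamp at 0)
  carries the information. This division is what makes both feedback
  channels necessary rather than redundant.
* **Noise**: Gaussian, SD 0.1 mm on position, 0.2° on attitude angle,
  0.05 N on pressure, all configurable, all driven by the mandatory seed;
  a fixed seed reproduces the acquisition bit-exactly.

What the generator does **not** emulate: speckle, beamforming and aperture
effects, frequency-dependent attenuation or gain compensation, refraction,
tissue deformation beyond the rigid target shift, and pose-sensor drift.
Passing tests therefore demonstrate the geometric and feedback logic of
the method under calibrated perturbations, not performance on real tissue.
(The recorded ultrasound frequency is carried in the configuration but
unused by the geometric model.)

## Compensation and placement

`compensate_frame()` corrects each detected echo depth by three terms:

$$d_{\mathrm{corr}} = d_{\mathrm{meas}}
  - \Delta t_{\mathrm{TMC}}(\alpha)\, c
  - (R_{\mathrm{pose}} - R_{\mathrm{ref}})
  + k_p F,$$

where $\alpha$ is the pose azimuth, $R_{\mathrm{pose}}$ the pose's
distance from the axis and $R_{\mathrm{ref}}$ the nominal contact radius
of the reference sector. The medium profile TMC$(\alpha)$ is part of the
calibration (`calibration_map(tmc_curve = ...)`): the frames themselves
carry no per-frame medium measurement, so the azimuthal medium map is
treated as calibrated knowledge, mirroring how the perturbation itself is
defined by calibration controls. $R_{\mathrm{ref}}$ likewise lives in the
calibration and, when absent, is inferred from the pose of the frame
nearest the reference azimuth.

Placement anchors every frame at $R_{\mathrm{ref}}$ on its matched plane:
a point at corrected depth $d$ on the scanline with lateral offset $z$
lands at radius $R_{\mathrm{ref}} - d$ in the sector's azimuth direction,
offset $z$ along the axis. Anchoring at the *nominal* radius (not the
per-frame pose) is what makes the uncompensated runs show the distortion
the method is designed to remove; with compensation on, the same anchor
recovers the target. Every placed point lies on its matched plane to
better than $10^{-6}$ mm by construction, and the per-frame feedback
magnitude (the net applied shift) is reported alongside the points — large
feedback flags azimuths where the raw data were most distorted.

`error_report()` scores a reconstruction by the deviation of each point's
in-plane radius from the ring centerline radius (RMSE and maximum);
`target_curve()` produces the cumulative-X/cumulative-Y-versus-azimuth
signature curve used to compare runs. Cumulative sums over azimuth order
are one reading of that comparison curve; the operation is isolated so an
alternative reading is a one-line change.

## Problem sizes and observed behavior

The test suite and the acceptance script run the full pipeline at
`delta_v = 8` and `delta_v = 128` with sensor noise disabled for the
geometric checks (the numerical experiments are noise-free by
construction; the determinism checks run with noise enabled). At these
sizes the undistorted reconstruction is discretization-limited (radial
RMSE below 0.1 mm, set by the 0.039 mm depth sample, the 0.05 mm wire and
the echo-grid rounding). With the surface curve enabled and no
compensation the radial RMSE equals the commanded $|D(\alpha) - 4|$
pattern (order 1.6 mm RMS); with the medium curve it reaches about 4 mm;
compensation returns both to the discretization floor, better than 0.1 mm
— a 30-to-80-fold reduction. These are properties the suite computes at
run time, not stored constants.

## Known limitations

* The axis L is general in the API (any line through the target), but the
  acquisition geometry assumes the probe aims at the axis; oblique
  insonification is not modeled.
* The matching tolerance trades noise robustness against sector
  discrimination; with the default `r * 1e-3` tolerance, realistic pose
  noise (0.1 mm) will reject frames, which is the designed behavior
  (escalate `delta_v` or widen `tol`), not a silent degradation.
* The pressure–displacement gain is linear; real tissue is not. The gain
  is a single calibration constant precisely so it can be re-fitted.
* Frames are rectangles (parallel scanlines of a linear array), not fan
  sectors; curved arrays would need a different pixel-to-plane map.
* The cumulative target curve is one of several possible readings of the
  comparison-curve construction (see above).
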
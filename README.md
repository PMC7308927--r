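# psm3d — probe sector matching for freehand 3D ultrasound reconstruction

Freehand 3D ultrasound sweeps a hand-held 2D linear-array probe around a
target while sensors record the probe's position, attitude and contact
pressure, then compounds the tracked 2D frames into a 3D volume. Two
effects distort the naive compounding: pressing the probe squeezes the
surface and shifts the target, and changes in the coupling medium stretch
the echo travel time. `psm3d` implements **probe sector matching (PSM)**
for this setting, aimed at people building or evaluating tracked-probe
reconstruction pipelines:

1. **Sector database.** With the target P as origin and an axis L through
   it, every frame plane the probe can occupy belongs to the pencil of
   planes through L. `build_sector_database()` precomputes `Δv` candidate
   half-plane *sectors* at uniform azimuths (`Δv` half-planes = `Δv/2`
   full planes; 8 sectors are 4 planes cutting the surrounding cylinder
   into 8 equal parts).
2. **Matching by the 3D Hough transform.** Planes live in Hesse normal
   form, `x sinθ cosφ + y sinθ sinφ + z cosθ = ρ`. The classical route
   (`hough_accumulate()` / `hough_detect_plane()`) votes points into a
   `(θ, φ, ρ)` accumulator and takes the peak. The improved three-point
   route (`solve_three_points()`, used by `match_sector()`) skips the
   accumulator: two points from the current frame plus a stored sector
   point determine the parameter-space intersection directly, and a frame
   matches the sector whose plane passes through its points within a
   tolerance.
3. **Feedback compensation and placement.** Echo depths are corrected by
   the pressure channel (squeeze, `Δr = k_p·F`), the pose channel
   (surface elevation relative to the reference sector) and the
   calibrated medium channel (`Δt = T(TMC) − 2.7 µs`, converted to depth),
   then the pixels are painted into the matched plane
   (`psm_reconstruct()`).

A seeded simulator (`simulate_acquisition()`) reproduces the validation
setup: a thin-wire ring phantom imaged at `Δv` azimuths, with periodic
surface-distance and transmission-medium-coefficient (TMC) perturbation
curves built from the calibrated tables (`surface_change_table()`,
`tmc_table()`). Echo times are one-way (`T = 1000·D/c` µs; 4 mm at
1500 m/s → 2.7 µs, the reference time).

## Worked example

```r
library(psm3d)

phantom <- ring_phantom()                      # 10 mm wire ring
cal     <- calibration_map()                   # k_p = 0.5 mm/N + TMC table
db      <- build_sector_database(r = 20, delta_v = 128)

# surface-perturbed acquisition (no sensor noise, seed 1)
sc  <- curve_from_controls(kind = "surface")   # D: 1.75 .. 7 mm over azimuth
cfg <- sim_config(delta_v = 128, seed = 1, surface_curve = sc,
                  noise_pos_sd = 0, noise_angle_sd = 0, noise_pressure_sd = 0)
frames <- simulate_acquisition(phantom, cfg, cal)

raw <- psm_reconstruct(frames, db, cal, compensate = FALSE)
psm <- psm_reconstruct(frames, db, cal, compensate = TRUE)
error_report(raw, phantom)
#> radial RMSE 1.615 mm, max 2.942 mm over 128 points
error_report(psm, phantom)
#> radial RMSE 0.05116 mm, max 0.06825 mm over 128 points
```

Every frame matched its generating sector (`raw$skipped == 0`). Without
compensation the reconstructed ring is distorted by exactly the commanded
surface pattern `|D(α) − 4|` (RMSE 1.6 mm, worst 2.9 mm at the D = 7 mm
control); with the pressure + pose feedback the error returns to the
discretization floor (~0.05 mm: the 0.039 mm depth sample and the 0.05 mm
wire radius). The same structure with the TMC curve
(`tmc_curve = curve_from_controls(kind = "tmc")` and
`calibration_map(tmc_curve = ...)`) gives 4.16 mm uncompensated vs
0.051 mm compensated. `write_ply()` exports the point cloud;
`target_curve()` produces the cumulative-coordinate comparison curve.

## Command line

```sh
Rscript inst/cli/psm3d.R demo --seed 1 --out demo_out
```

Subcommands: `build-db`, `simulate`, `match`, `reconstruct`, `evaluate`,
`demo` (the full numerical experiment: both resolutions, both
perturbations, with/without compensation). Flags: `--config FILE` (YAML,
degrees at this surface), `--seed N`, `--out`, `--db`, `--frames`,
`--no-compensate`, `--verbose`. On-disk formats: JSON sector databases
(17-digit floats, bit-exact round trip), PNG frame stacks with a JSON
sidecar and a pose CSV (`t_s, x_mm, y_mm, z_mm, ax, ay, az, angle_rad,
force_N`), ASCII PLY point clouds (`x y z intensity`), CSV reports.

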
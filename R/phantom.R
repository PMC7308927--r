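# Synthetic ring-phantom acquisition simulator.
#
# The phantom is a thin-wire ring (torus) of centerline radius l in the XY
# plane; the probe orbits it at delta_v evenly spaced azimuths with the
# transducer face pointing at the axis. Echoes are rendered by geometric
# time of flight: the first ray/torus intersection distance is converted to
# a one-way echo time and back to an image depth sample under the nominal
# sound speed, so surface and medium perturbations appear as pure depth
# displacements of the target echo. Two perturbation models reproduce the
# calibrated experiments: a periodic surface-distance curve D(azimuth)
# (squeeze for D < n, elevation for D > n) and a periodic medium curve
# TMC(azimuth) that offsets the echo time by the calibrated
# tmc_echo_time(TMC) - T_ref.

#' Ring (thin-wire torus) phantom
#'
#' @param center Ring center, mm (default the origin = the target P).
#' @param ring_radius Distance l from the axis to the wire centerline, mm.
#' @param tube_radius Wire half-thickness, mm; must satisfy
#'   `0 < tube_radius < ring_radius`. The default 0.05 mm models the
#'   thin-wire targets of ultrasound QA phantoms.
#' @param plane_normal Unit normal of the ring plane (default Z: ring in
#'   the XY plane).
#' @return An object of class `"ring_phantom"`.
#' @export
ring_phantom <- function(center = c(0, 0, 0), ring_radius = 10,
                         tube_radius = 0.05, plane_normal = c(0, 0, 1)) {
  center <- .vec3(center, "center")
  plane_normal <- .vec3(plane_normal, "plane_normal")
  plane_normal <- plane_normal / sqrt(sum(plane_normal^2))
  if (!is.finite(ring_radius) || !is.finite(tube_radius) ||
      tube_radius <= 0 || ring_radius <= tube_radius)
    stop("need ring_radius > tube_radius > 0")
  structure(list(center = center, ring_radius = ring_radius,
                 tube_radius = tube_radius, plane_normal = plane_normal),
            class = "ring_phantom")
}

#' @export
print.ring_phantom <- function(x, ...) {
  cat(sprintf("Ring phantom: centerline radius %g mm, tube radius %g mm\n",
              x$ring_radius, x$tube_radius))
  invisible(x)
}

# distance from points (n x 3) to the ring centerline circle
.ring_circle_distance <- function(pts, phantom) {
  v <- sweep(pts, 2L, phantom$center)
  par <- drop(v %*% phantom$plane_normal)
  perp2 <- rowSums(v^2) - par^2
  sqrt((sqrt(pmax(perp2, 0)) - phantom$ring_radius)^2 + par^2)
}

#' Periodic calibration curve from control values
#'
#' Places the control values at evenly spaced azimuths over `[0, 2*pi)` in
#' cyclic table order, anchored so the reference control (the value closest
#' to the undistorted reference: D = reference n for `kind = "surface"`,
#' TMC = 1 for `kind = "tmc"`) sits at azimuth 0, where the reference
#' sector is. Evaluation is monotone (Fritsch-Carlson) piecewise-cubic
#' between knots, exact at the controls, periodic, and bounded by the
#' control range.
#'
#' @param values Ordered control values (>= 2): probe-target distances in
#'   mm for a surface curve, dimensionless TMC for a medium curve.
#'   Defaults: the printed calibration tables ([surface_change_table()]
#'   column `D_mm`, [tmc_table()] column `TMC`).
#' @param kind `"surface"` or `"tmc"`.
#' @param anchor Index (1-based) of the control to place at azimuth 0;
#'   default: the control nearest the reference value (4 mm / TMC 1).
#' @param reference Reference value used to pick the default anchor.
#' @return An object of class `"psm_curve"` with fields `kind`,
#'   `control_radians`, `control_values` and evaluator `value(azimuth)`.
#' @export
curve_from_controls <- function(values = NULL,
                                kind = c("surface", "tmc"),
                                anchor = NULL, reference = NULL) {
  kind <- match.arg(kind)
  if (is.null(values))
    values <- if (kind == "surface") surface_change_table()$D_mm
              else tmc_table()$TMC
  values <- as.numeric(values)
  if (length(values) < 2L || any(!is.finite(values)))
    stop("need at least 2 finite control values")
  if (is.null(reference)) reference <- if (kind == "surface") 4 else 1
  if (is.null(anchor)) anchor <- which.min(abs(values - reference))
  m <- length(values)
  vals <- values[((seq_len(m) - 1L + (anchor - 1L)) %% m) + 1L]
  ang <- 2 * pi * (seq_len(m) - 1L) / m
  # periodic shape-preserving interpolation: replicate one full period on
  # each side and evaluate a PCHIP (piecewise cubic Hermite) fit on the
  # middle period. PCHIP derivatives depend only on the two neighboring
  # slopes (zero at local extrema), so the middle period is exactly
  # periodic and the evaluator never overshoots the control range.
  xx <- c(ang - 2 * pi, ang, ang + 2 * pi)
  yy <- rep(vals, 3L)
  structure(list(kind = kind,
                 control_radians = ang, control_values = vals,
                 value = function(azimuth)
                   pracma::pchip(xx, yy, azimuth %% (2 * pi))),
            class = "psm_curve")
}

#' @export
print.psm_curve <- function(x, ...) {
  cat(sprintf("%s curve: %d controls in [%g, %g]\n", x$kind,
              length(x$control_values), min(x$control_values),
              max(x$control_values)))
  invisible(x)
}

#' First ray/ring intersection distance
#'
#' Marches each ray on a coarse grid (default 0.01 mm) until the distance
#' to the wire centerline first drops below `tube_radius`, then refines the
#' entry point by bisection to 1e-6 mm. `NA` for rays that miss within
#' `t_max`.
#'
#' @param origin Ray origin(s): length-3 vector or `n x 3` matrix, mm.
#' @param direction Unit ray direction(s), same shape as `origin`.
#' @param phantom A [ring_phantom()].
#' @param t_max March limit, mm (default `2 * (ring_radius + tube_radius +
#'   |origin|)` bound via 4 * ring_radius + 40).
#' @param coarse Coarse grid step, mm.
#' @param tol Bisection tolerance, mm.
#' @return Distance(s) `t >= 0` in mm, or `NA` on a miss.
#' @export
ray_ring_distance <- function(origin, direction, phantom, t_max = NULL,
                              coarse = 0.01, tol = 1e-6) {
  stopifnot(inherits(phantom, "ring_phantom"))
  O <- .points_matrix(origin)
  Dm <- .points_matrix(direction)
  if (nrow(Dm) == 1L && nrow(O) > 1L)
    Dm <- matrix(Dm, nrow(O), 3L, byrow = TRUE)
  stopifnot(nrow(Dm) == nrow(O))
  nrm <- sqrt(rowSums(Dm^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("direction must be a unit vector")
  if (is.null(t_max))
    t_max <- 2 * (phantom$ring_radius + phantom$tube_radius +
                    max(sqrt(rowSums(sweep(O, 2L, phantom$center)^2))))
  tt <- seq(0, t_max, by = coarse)
  out <- rep(NA_real_, nrow(O))
  for (i in seq_len(nrow(O))) {
    pts <- O[rep(i, length(tt)), , drop = FALSE] + outer(tt, Dm[i, ])
    f <- .ring_circle_distance(pts, phantom) - phantom$tube_radius
    k <- which(f <= 0)
    if (!length(k)) next
    k <- k[1L]
    if (k == 1L) { out[i] <- 0; next }
    lo <- tt[k - 1L]; hi <- tt[k]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      fm <- .ring_circle_distance(O[i, , drop = FALSE] +
                                    matrix(mid * Dm[i, ], 1L), phantom) -
        phantom$tube_radius
      if (fm <= 0) hi <- mid else lo <- mid
    }
    out[i] <- (lo + hi) / 2
  }
  if (length(out) == 1L) out[[1L]] else out
}

#' Simulation configuration
#'
#' @param delta_v Number of acquisition azimuths (= database vertical
#'   resolution); even, default 8.
#' @param working_radius Probe imaging depth r, mm (default 20).
#' @param n_lines Scanlines per frame (default 128, a 128-element linear
#'   array).
#' @param n_depth Depth samples per scanline (default 512).
#' @param delta_h Scanline pitch, mm (default 0.3).
#' @param seed Mandatory RNG seed; the same seed reproduces the
#'   acquisition bit-exactly.
#' @param noise_pos_sd Gaussian pose position noise SD, mm (default 0.1).
#' @param noise_angle_sd Attitude angle noise SD, radians (default 0.2
#'   degrees).
#' @param noise_pressure_sd Pressure noise SD, newtons (default 0.05).
#' @param surface_curve `NULL` (surface unchanged) or a `"psm_curve"` of
#'   kind `"surface"`.
#' @param tmc_curve `NULL` (homogeneous medium) or a `"psm_curve"` of kind
#'   `"tmc"`.
#' @param reference_azimuth Azimuth of the undistorted reference sector,
#'   radians (default 0).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(delta_v = 8, working_radius = 20, n_lines = 128,
                       n_depth = 512, delta_h = 0.3, seed,
                       noise_pos_sd = 0.1, noise_angle_sd = 0.2 * pi / 180,
                       noise_pressure_sd = 0.05,
                       surface_curve = NULL, tmc_curve = NULL,
                       reference_azimuth = 0) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("config error: a seed is mandatory")
  delta_v <- as.integer(delta_v)
  if (delta_v < 2L || delta_v %% 2L != 0L)
    stop("config error: delta_v must be even and >= 2")
  stopifnot(working_radius > 0, n_lines >= 1, n_depth >= 1, delta_h > 0,
            noise_pos_sd >= 0, noise_angle_sd >= 0, noise_pressure_sd >= 0)
  for (cv in list(surface_curve, tmc_curve))
    if (!is.null(cv) && !inherits(cv, "psm_curve"))
      stop("config error: curves must be psm_curve objects or NULL")
  structure(list(delta_v = delta_v, working_radius = working_radius,
                 n_lines = as.integer(n_lines), n_depth = as.integer(n_depth),
                 delta_h = delta_h, seed = as.integer(seed),
                 noise_pos_sd = noise_pos_sd, noise_angle_sd = noise_angle_sd,
                 noise_pressure_sd = noise_pressure_sd,
                 surface_curve = surface_curve, tmc_curve = tmc_curve,
                 reference_azimuth = reference_azimuth),
            class = "sim_config")
}

#' One acquired frame
#'
#' @param image `n_lines x n_depth` intensity matrix in `[0, 1]`
#'   (quantized to 1/255 steps so PNG round trips are exact).
#' @param pose A [probe_pose()].
#' @param pressure A [pressure_reading()].
#' @param true_azimuth,true_distance Simulator ground truth (radians, mm).
#' @param working_radius,delta_h Frame geometry, mm.
#' @return An object of class `"acquisition_frame"` with derived fields
#'   `n_lines`, `n_depth`, `depth_spacing`.
#' @export
acquisition_frame <- function(image, pose, pressure, true_azimuth = NA_real_,
                              true_distance = NA_real_, working_radius,
                              delta_h) {
  stopifnot(is.matrix(image), inherits(pose, "probe_pose"),
            is.null(pressure) || inherits(pressure, "pressure_reading"))
  if (any(image < 0) || any(image > 1))
    stop("image intensities must lie in [0, 1]")
  image <- round(image * 255) / 255   # 8-bit quantization, lossless on disk
  structure(list(image = image, pose = pose, pressure = pressure,
                 true_azimuth = true_azimuth, true_distance = true_distance,
                 working_radius = working_radius, delta_h = delta_h,
                 n_lines = nrow(image), n_depth = ncol(image),
                 depth_spacing = working_radius / ncol(image)),
            class = "acquisition_frame")
}

#' Simulate a freehand acquisition around a ring phantom
#'
#' Produces exactly `delta_v` frames at azimuths `2*pi*k/delta_v`. At
#' azimuth `a` the probe-target distance is `D(a)` (surface curve if
#' enabled, else the reference distance n): elevation (`D > n`) moves the
#' probe contact outward and is visible to the pose sensor; squeeze
#' (`D < n`) displaces the target toward the probe and is sensed only by
#' the pressure reading `force = (n - D) / k_pressure` (clamped at 0).
#' Per-scanline ray/torus echo distances are converted to one-way times,
#' offset by the calibrated medium delay `tmc_echo_time(TMC(a)) - T_ref`
#' when the TMC curve is enabled, and mapped back to image depth under the
#' nominal sound speed, so both perturbations appear as depth
#' displacements of the echo. Seeded Gaussian noise is added to pose and
#' pressure; the same seed yields bit-identical output.
#'
#' @param phantom A [ring_phantom()].
#' @param cfg A [sim_config()].
#' @param cal A [calibration_map()].
#' @param model An [echo_model()].
#' @return A list of [acquisition_frame()] objects with attributes
#'   `config`, `phantom`.
#' @export
simulate_acquisition <- function(phantom, cfg, cal = calibration_map(),
                                 model = echo_model()) {
  stopifnot(inherits(phantom, "ring_phantom"), inherits(cfg, "sim_config"),
            inherits(cal, "calibration_map"), inherits(model, "echo_model"))
  set.seed(cfg$seed)
  n_ref <- model$reference_distance
  az <- (2 * pi * (seq_len(cfg$delta_v) - 1L) / cfg$delta_v +
           cfg$reference_azimuth) %% (2 * pi)
  D <- if (!is.null(cfg$surface_curve)) cfg$surface_curve$value(az)
       else rep(n_ref, cfg$delta_v)
  tmc <- if (!is.null(cfg$tmc_curve)) cfg$tmc_curve$value(az)
         else rep(1, cfg$delta_v)
  dt_tmc <- tmc_echo_time(tmc, cal) - model$reference_time   # us
  elev <- pmax(0, D - n_ref)
  squeeze <- pmax(0, n_ref - D)
  force <- squeeze / cal$k_pressure
  r_outer <- phantom$ring_radius + phantom$tube_radius
  dz <- (seq_len(cfg$n_lines) - ceiling((cfg$n_lines + 1L) / 2)) *
    cfg$delta_h
  sp <- cfg$working_radius / cfg$n_depth
  frames <- vector("list", cfg$delta_v)
  for (k in seq_len(cfg$delta_v)) {
    a <- az[k]
    u <- c(cos(a), sin(a), 0)
    contact <- phantom$center + u * (r_outer + n_ref + elev[k])
    origins <- matrix(contact, cfg$n_lines, 3L, byrow = TRUE) +
      outer(dz, c(0, 0, 1))
    hit <- ray_ring_distance(origins, matrix(-u, 1L), phantom,
                             t_max = cfg$working_radius +
                               phantom$tube_radius)
    img <- matrix(0, cfg$n_lines, cfg$n_depth)
    for (i in which(!is.na(hit))) {
      dist_eff <- hit[i] - squeeze[k]     # target displaced toward probe
      if (dist_eff < 0) next
      t_us <- echo_time(dist_eff, model$speed_of_sound) + dt_tmc[k]
      s <- round(t_us * model$mm_per_us / sp)
      if (s >= 1 && s <= cfg$n_depth) img[i, s] <- 1
    }
    pos <- contact + stats::rnorm(3L, 0, cfg$noise_pos_sd)
    ang <- a + stats::rnorm(1L, 0, cfg$noise_angle_sd)
    f <- max(0, force[k] + stats::rnorm(1L, 0, cfg$noise_pressure_sd))
    ts <- (k - 1L) / 18    # 18 frames/s acquisition rate
    frames[[k]] <- acquisition_frame(
      image = img,
      pose = probe_pose(pos, c(0, 0, 1), ang, ts),
      pressure = pressure_reading(f, ts),
      true_azimuth = a, true_distance = D[k],
      working_radius = cfg$working_radius, delta_h = cfg$delta_h)
  }
  attr(frames, "config") <- cfg
  attr(frames, "phantom") <- phantom
  frames
}
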
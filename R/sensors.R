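# Echo time-of-flight model, pressure and transmission-medium feedback,
# and the sector edge-error profile.
#
# Conventions: distances mm, times microseconds, speed of sound m/s.
# Times are ONE-WAY: at c = 1500 m/s a 4 mm probe-target distance gives
# 1000 * 4 / 1500 = 2.667 us, i.e. 2.7 us at the 0.1 us readout
# resolution, which is the reference time all echo-time errors are
# relative to.

#' Echo time-of-flight model
#'
#' @param speed_of_sound Speed of sound c in m/s (default 1500).
#' @param reference_distance Probe-target distance n on the reference
#'   sector, mm (default 4).
#' @param reference_time Reference echo time T_ref in microseconds
#'   (default 2.7, i.e. `echo_time(n)` rounded to 0.1 us; the constructor
#'   enforces that consistency).
#' @return An object of class `"echo_model"`.
#' @export
echo_model <- function(speed_of_sound = 1500, reference_distance = 4,
                       reference_time = 2.7) {
  stopifnot(speed_of_sound > 0, reference_distance >= 0)
  if (abs(round(echo_time(reference_distance, speed_of_sound), 1) -
          reference_time) > 1e-9)
    stop("inconsistent echo model: reference_time must equal ",
         "echo_time(reference_distance) rounded to 0.1 us")
  structure(list(speed_of_sound = speed_of_sound,
                 reference_distance = reference_distance,
                 reference_time = reference_time,
                 mm_per_us = speed_of_sound / 1000),
            class = "echo_model")
}

#' One-way echo time for a distance
#'
#' @param distance Distance(s) in mm, `>= 0`.
#' @param speed_of_sound Speed of sound in m/s.
#' @return Time(s) in microseconds (`1000 * distance / c`).
#' @export
echo_time <- function(distance, speed_of_sound = 1500) {
  if (any(!is.finite(distance)) || any(distance < 0))
    stop("distance must be nonnegative")
  stopifnot(speed_of_sound > 0)
  1000 * distance / speed_of_sound
}

#' Echo time rounded to the 0.1 us readout resolution
#'
#' @inheritParams echo_time
#' @return Rounded time(s) in microseconds.
#' @export
echo_time_rounded <- function(distance, speed_of_sound = 1500) {
  round(echo_time(distance, speed_of_sound), 1)
}

#' Echo time error relative to the reference time
#'
#' @param t Measured echo time(s), microseconds.
#' @param model An [echo_model()].
#' @return `t - reference_time` in microseconds.
#' @export
echo_time_error <- function(t, model = echo_model()) {
  stopifnot(inherits(model, "echo_model"))
  t - model$reference_time
}

#' Printed surface-change calibration table
#'
#' The eight (D, T, dt) rows used to seed the surface-change experiment:
#' probe-target distance D in mm, one-way echo time T in us (0.1 us
#' readout), echo-time error dt relative to the 2.7 us reference.
#'
#' @return A data frame with columns `D_mm`, `T_us`, `dt_us`.
#' @export
surface_change_table <- function() {
  data.frame(D_mm = c(1.75, 2.5, 3.25, 4, 4.75, 5.5, 6.25, 7),
             T_us = c(1.2, 1.7, 2.2, 2.7, 3.2, 3.7, 4.2, 4.7),
             dt_us = c(-1.5, -1, -0.5, 0, 0.5, 1, 1.5, 2))
}

#' Printed transmission-medium calibration table
#'
#' The eight (TMC, T, dt) rows of the medium-change experiment: a larger
#' transmission medium coefficient means a weaker medium and a longer echo
#' time. TMC = 1 is the reference medium (T = 2.7 us, dt = 0).
#'
#' @return A data frame with columns `TMC`, `T_us`, `dt_us`, sorted by
#'   decreasing TMC as printed.
#' @export
tmc_table <- function() {
  data.frame(TMC = c(2.77, 2.04, 1.28, 1, 0.85, 0.82, 0.81, 0.75),
             T_us = c(11.2, 7.7, 4, 2.7, 2, 1.8, 1.7, 1.5),
             dt_us = c(8.5, 5, 1.3, 0, -0.7, -0.9, -1, -1.2))
}

#' Calibration map: pressure gain, TMC lookup, optional medium profile
#'
#' @param k_pressure Linear pressure-to-displacement gain, mm per newton
#'   (`>= 0`).
#' @param tmc_controls Data frame with columns `TMC` and `T_us` giving the
#'   empirical TMC to echo-time control points; must be strictly monotone
#'   in TMC. Defaults to [tmc_table()].
#' @param tmc_curve Optional azimuthal medium profile (a
#'   `"psm_curve"` of kind `"tmc"` from [curve_from_controls()]): the
#'   calibrated TMC as a function of azimuth, used by
#'   [compensate_frame()]. `NULL` means a homogeneous reference medium.
#' @param r_contact_ref Optional nominal probe contact radius (mm):
#'   distance from the axis to the probe face on the reference sector.
#'   Used to turn pose radii into surface-elevation feedback; inferred
#'   from the reference frame by [psm_reconstruct()] when `NULL`.
#' @return An object of class `"calibration_map"`.
#' @export
calibration_map <- function(k_pressure = 0.5, tmc_controls = tmc_table(),
                            tmc_curve = NULL, r_contact_ref = NULL) {
  if (!is.finite(k_pressure) || k_pressure < 0)
    stop("k_pressure must be a nonnegative gain in mm/N")
  stopifnot(is.data.frame(tmc_controls),
            all(c("TMC", "T_us") %in% names(tmc_controls)))
  tc <- tmc_controls[order(tmc_controls$TMC), c("TMC", "T_us")]
  if (nrow(tc) < 2L || any(diff(tc$TMC) <= 0) || any(diff(tc$T_us) <= 0))
    stop("tmc_controls must be strictly monotone in TMC (and in time)")
  if (!is.null(tmc_curve) && !inherits(tmc_curve, "psm_curve"))
    stop("tmc_curve must be a psm_curve (see curve_from_controls)")
  structure(list(k_pressure = k_pressure, tmc_controls = tc,
                 tmc_fun = stats::splinefun(tc$TMC, tc$T_us,
                                            method = "monoH.FC"),
                 tmc_curve = tmc_curve, r_contact_ref = r_contact_ref),
            class = "calibration_map")
}

#' Echo time implied by a transmission medium coefficient
#'
#' Monotone (Fritsch-Carlson) interpolation through the calibration
#' control points; exact at the controls; extrapolation is refused.
#'
#' @param tmc TMC value(s), dimensionless, within the control range.
#' @param cal A [calibration_map()].
#' @return Echo time(s) in microseconds.
#' @export
tmc_echo_time <- function(tmc, cal = calibration_map()) {
  stopifnot(inherits(cal, "calibration_map"))
  rng <- range(cal$tmc_controls$TMC)
  if (any(!is.finite(tmc)) || any(tmc < rng[1] - 1e-12) ||
      any(tmc > rng[2] + 1e-12))
    stop(sprintf("TMC out of calibrated range [%g, %g]", rng[1], rng[2]))
  cal$tmc_fun(pmin(pmax(tmc, rng[1]), rng[2]))
}

#' Pressure reading
#'
#' @param force Contact force in newtons, `>= 0`.
#' @param timestamp Acquisition time in seconds.
#' @return An object of class `"pressure_reading"`.
#' @export
pressure_reading <- function(force, timestamp = 0) {
  if (!is.finite(force) || force < 0) stop("force must be >= 0 newtons")
  structure(list(force = force, timestamp = timestamp),
            class = "pressure_reading")
}

#' Probe pose (position + attitude + timestamp)
#'
#' @param position Probe contact position, mm.
#' @param axis Rotation axis of the attitude (normalized internally).
#' @param angle Rotation angle, radians.
#' @param timestamp Seconds.
#' @return An object of class `"probe_pose"`.
#' @export
probe_pose <- function(position, axis = c(0, 0, 1), angle = 0,
                       timestamp = 0) {
  position <- .vec3(position, "position")
  axis <- .vec3(axis, "attitude axis")
  len <- sqrt(sum(axis^2))
  if (len < 1e-12) stop("attitude axis must be nonzero")
  structure(list(position = position, axis = axis / len, angle = angle,
                 timestamp = timestamp),
            class = "probe_pose")
}

#' Working-radius correction from a pressure reading
#'
#' Linear feedback model: squeezing the surface with force F displaces the
#' target toward the probe by `k_pressure * F` mm, so the working radius is
#' increased by the same amount (positive correction widens the radius).
#'
#' @param p A [pressure_reading()] or a nonnegative force in newtons.
#' @param cal A [calibration_map()].
#' @return Correction in mm.
#' @export
pressure_to_radius_correction <- function(p, cal = calibration_map()) {
  force <- if (inherits(p, "pressure_reading")) p$force else p
  if (any(!is.finite(force)) || any(force < 0))
    stop("force must be >= 0 newtons")
  cal$k_pressure * force
}

#' Per-element sector edge-error profile
#'
#' When the probe face does not sit flush on the surface, the working
#' radius of the edge elements is reduced by `delta_r_i`. The bow is
#' modeled as a symmetric quadratic: zero at the array center, rising to
#' `delta_r_max` at the two edges.
#'
#' @param n_elements Number of transducer elements (>= 1).
#' @param delta_r_max Edge error at the outermost elements, mm (>= 0).
#' @param flush If `TRUE` the probe fits the surface and the profile is
#'   all zeros.
#' @return An object of class `"edge_error_profile"` with fields
#'   `n_elements` and `delta_r` (length `n_elements`).
#' @export
edge_error_profile <- function(n_elements, delta_r_max = 0, flush = FALSE) {
  n_elements <- as.integer(n_elements)
  stopifnot(n_elements >= 1L, is.finite(delta_r_max), delta_r_max >= 0)
  if (flush || n_elements == 1L) {
    dr <- rep(0, n_elements)
  } else {
    i <- seq_len(n_elements)
    dr <- delta_r_max * ((2 * i - n_elements - 1) / (n_elements - 1))^2
  }
  structure(list(n_elements = n_elements, delta_r = dr),
            class = "edge_error_profile")
}

#' Corrected working radius for one element
#'
#' Combines the pressure feedback and the edge-error profile:
#' `r + delta_r_pressure - delta_r[element]`, clamped at 0 (with a
#' warning) if the combination is pathological.
#'
#' @param r Nominal working radius, mm.
#' @param dr_pressure Pressure correction, mm (see
#'   [pressure_to_radius_correction()]).
#' @param profile An [edge_error_profile()].
#' @param element Element index in `1..n_elements`.
#' @return Corrected radius in mm.
#' @export
corrected_radius <- function(r, dr_pressure, profile, element) {
  stopifnot(inherits(profile, "edge_error_profile"))
  element <- as.integer(element)
  if (any(is.na(element)) || any(element < 1L) ||
      any(element > profile$n_elements))
    stop("element index out of range 1..", profile$n_elements)
  out <- r + dr_pressure - profile$delta_r[element]
  if (any(out < 0)) {
    warning("corrected radius fell below 0 mm; clamped")
    out <- pmax(out, 0)
  }
  out
}

#' Write a pose/pressure stream as CSV
#'
#' Columns: `t_s, x_mm, y_mm, z_mm, ax, ay, az, angle_rad, force_N`
#' (header required, UTF-8, '.' decimal).
#'
#' @param poses List of [probe_pose()] objects.
#' @param pressures List of [pressure_reading()] objects (same length).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pose_csv <- function(poses, pressures, path) {
  stopifnot(length(poses) == length(pressures))
  df <- do.call(rbind, lapply(seq_along(poses), function(i) {
    p <- poses[[i]]; f <- pressures[[i]]
    data.frame(t_s = p$timestamp, x_mm = p$position[1], y_mm = p$position[2],
               z_mm = p$position[3], ax = p$axis[1], ay = p$axis[2],
               az = p$axis[3], angle_rad = p$angle, force_N = f$force)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pose/pressure stream written by [write_pose_csv()]
#'
#' @param path CSV path.
#' @return A list with elements `poses` and `pressures`.
#' @export
read_pose_csv <- function(path) {
  if (!file.exists(path)) stop("pose CSV not found: ", path)
  df <- utils::read.csv(path)
  need <- c("t_s", "x_mm", "y_mm", "z_mm", "ax", "ay", "az", "angle_rad",
            "force_N")
  if (!all(need %in% names(df)))
    stop("pose CSV is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad))
    stop("malformed pose CSV row(s): line ",
         paste(bad + 1L, collapse = ", "))
  list(poses = lapply(seq_len(nrow(df)), function(i)
         probe_pose(c(df$x_mm[i], df$y_mm[i], df$z_mm[i]),
                    c(df$ax[i], df$ay[i], df$az[i]),
                    df$angle_rad[i], df$t_s[i])),
       pressures = lapply(seq_len(nrow(df)), function(i)
         pressure_reading(df$force_N[i], df$t_s[i])))
}
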
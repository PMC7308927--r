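# Run configuration and frame-stack round-tripping.
#
# The run configuration is one YAML document of validated key/value pairs;
# angles are degrees at this surface only (radians everywhere inside).
# Frame stacks live in a directory of 8-bit grayscale PNGs
# (frame_0000.png, ...) plus a JSON sidecar (poses, pressures, ground
# truth, config echo, seed) and a pose CSV in the sensor dialect.

.config_defaults <- function() {
  list(
    delta_v = 8L,
    working_radius_mm = 20,
    n_lines = 128L,
    n_depth = 512L,
    delta_h_mm = 0.3,
    seed = 1L,
    speed_of_sound_m_s = 1500,
    reference_distance_mm = 4,
    reference_time_us = 2.7,
    ultrasound_frequency_khz = 1,   # recorded; unused by the geometric model
    k_pressure_mm_per_N = 0.5,
    ring_radius_mm = 10,
    tube_radius_mm = 0.05,
    noise_pos_sd_mm = 0.1,
    noise_angle_sd_deg = 0.2,
    noise_pressure_sd_N = 0.05,
    surface_curve = FALSE,
    tmc_curve = FALSE,
    reference_azimuth_deg = 0,
    match_tol_mm = NA_real_,
    detect_threshold = 0.5)
}

#' Load and validate a run configuration
#'
#' Reads a YAML key/value document, fills defaults, normalizes units
#' (degrees to radians happens when objects are built), and rejects
#' unknown keys by name. `surface_curve` / `tmc_curve` may be `false`
#' (off), `true` (the printed calibration table controls) or an explicit
#' numeric list of control values.
#'
#' @param path YAML file path.
#' @return A named list of class `"psm_config"` in canonical key order.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  defaults <- .config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(raw)] <- raw
  .validate_config(cfg)
  structure(cfg[names(defaults)], class = "psm_config")
}

.validate_config <- function(cfg) {
  num1 <- function(key, min = -Inf, allow_na = FALSE) {
    v <- cfg[[key]]
    if (allow_na && (is.null(v) || (length(v) == 1L && is.na(v)))) return()
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < min)
      stop(sprintf("config key '%s' must be a number >= %g", key, min))
  }
  num1("delta_v", 2); num1("working_radius_mm", 1e-9)
  num1("n_lines", 1); num1("n_depth", 1); num1("delta_h_mm", 1e-9)
  num1("seed"); num1("speed_of_sound_m_s", 1e-9)
  num1("reference_distance_mm", 0); num1("reference_time_us", 0)
  num1("k_pressure_mm_per_N", 0); num1("ring_radius_mm", 1e-9)
  num1("tube_radius_mm", 1e-9); num1("noise_pos_sd_mm", 0)
  num1("noise_angle_sd_deg", 0); num1("noise_pressure_sd_N", 0)
  num1("reference_azimuth_deg"); num1("match_tol_mm", 0, allow_na = TRUE)
  num1("detect_threshold", 1e-9)
  if (cfg$delta_v %% 2 != 0)
    stop("config key 'delta_v' must be an even integer")
  for (key in c("surface_curve", "tmc_curve")) {
    v <- cfg[[key]]
    ok <- (is.logical(v) && length(v) == 1L) ||
      (is.numeric(v) && length(v) >= 2L && all(is.finite(v)))
    if (!ok)
      stop(sprintf(paste0("config key '%s' must be true, false, or a list ",
                          "of >= 2 numeric control values"), key))
  }
  invisible(cfg)
}

#' Write a configuration document
#'
#' @param cfg A `"psm_config"` list.
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "psm_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build model objects from a configuration
#'
#' @param cfg A `"psm_config"`.
#' @return A list with `phantom`, `sim` (a [sim_config()]), `cal`, `model`,
#'   and `db_args` (arguments for [build_sector_database()]).
#' @export
config_objects <- function(cfg) {
  stopifnot(inherits(cfg, "psm_config"))
  model <- echo_model(cfg$speed_of_sound_m_s, cfg$reference_distance_mm,
                      cfg$reference_time_us)
  curve_of <- function(v, kind) {
    if (isTRUE(v)) curve_from_controls(kind = kind)
    else if (is.numeric(v)) curve_from_controls(v, kind = kind)
    else NULL
  }
  surface <- curve_of(cfg$surface_curve, "surface")
  tmc <- curve_of(cfg$tmc_curve, "tmc")
  cal <- calibration_map(cfg$k_pressure_mm_per_N, tmc_curve = tmc)
  sim <- sim_config(delta_v = cfg$delta_v,
                    working_radius = cfg$working_radius_mm,
                    n_lines = cfg$n_lines, n_depth = cfg$n_depth,
                    delta_h = cfg$delta_h_mm, seed = cfg$seed,
                    noise_pos_sd = cfg$noise_pos_sd_mm,
                    noise_angle_sd = cfg$noise_angle_sd_deg * pi / 180,
                    noise_pressure_sd = cfg$noise_pressure_sd_N,
                    surface_curve = surface, tmc_curve = tmc,
                    reference_azimuth = cfg$reference_azimuth_deg * pi / 180)
  phantom <- ring_phantom(ring_radius = cfg$ring_radius_mm,
                          tube_radius = cfg$tube_radius_mm)
  list(phantom = phantom, sim = sim, cal = cal, model = model,
       db_args = list(r = cfg$working_radius_mm, delta_v = cfg$delta_v,
                      delta_h = cfg$delta_h_mm))
}

#' Write a frame stack to a directory
#'
#' Per-frame 8-bit grayscale PNGs `frame_0000.png, ...`, one JSON sidecar
#' `frames.json` (poses, pressures, ground truth, geometry, 17-digit
#' floats), and a pose CSV `poses.csv`. Frame intensities are already
#' quantized to 1/255 steps, so the write/read round trip is bit-exact.
#'
#' @param frames List of [acquisition_frame()] objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    stopifnot(inherits(f, "acquisition_frame"))
    png::writePNG(t(f$image),
                  file.path(dir, sprintf("frame_%04d.png", i - 1L)))
    meta[[i]] <- list(
      index = i - 1L,
      pose = list(position = f$pose$position, axis = f$pose$axis,
                  angle = f$pose$angle, timestamp = f$pose$timestamp),
      pressure = if (is.null(f$pressure)) NULL
                 else list(force = f$pressure$force,
                           timestamp = f$pressure$timestamp),
      true_azimuth = f$true_azimuth, true_distance = f$true_distance,
      n_lines = f$n_lines, n_depth = f$n_depth,
      working_radius = f$working_radius, delta_h = f$delta_h)
  }
  doc <- list(schema = "psm3d/frame-stack/1", n_frames = length(frames),
              frames = meta)
  cfg <- attr(frames, "config")
  if (!is.null(cfg)) doc$seed <- cfg$seed
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              always_decimal = TRUE, pretty = TRUE,
                              null = "null"),
             file.path(dir, "frames.json"))
  write_pose_csv(lapply(frames, `[[`, "pose"),
                 lapply(frames, `[[`, "pressure"),
                 file.path(dir, "poses.csv"))
  invisible(dir)
}

#' Read a frame stack written by [write_frames()]
#'
#' @param dir Stack directory.
#' @return A list of [acquisition_frame()] objects.
#' @export
read_frames <- function(dir) {
  sidecar <- file.path(dir, "frames.json")
  if (!file.exists(sidecar))
    stop("missing frame-stack sidecar: ", sidecar)
  doc <- tryCatch(jsonlite::fromJSON(sidecar, simplifyDataFrame = FALSE,
                                     simplifyMatrix = FALSE),
                  error = function(e)
                    stop("malformed sidecar ", sidecar, ": ",
                         conditionMessage(e)))
  if (!identical(doc$schema, "psm3d/frame-stack/1"))
    stop("unrecognized frame-stack schema in ", sidecar)
  pngs <- sort(list.files(dir, pattern = "^frame_[0-9]+\\.png$"))
  if (length(pngs) != doc$n_frames || length(doc$frames) != doc$n_frames)
    stop(sprintf("frame-stack inconsistency in %s: %d PNG file(s) but %d ",
                 dir, length(pngs), doc$n_frames),
         "metadata entries")
  lapply(seq_len(doc$n_frames), function(i) {
    m <- doc$frames[[i]]
    img <- t(png::readPNG(file.path(dir, pngs[i])))
    if (nrow(img) != m$n_lines || ncol(img) != m$n_depth)
      stop(sprintf("frame %d image is %d x %d but metadata says %d x %d",
                   i - 1L, nrow(img), ncol(img), m$n_lines, m$n_depth))
    acquisition_frame(
      image = img,
      pose = probe_pose(unlist(m$pose$position), unlist(m$pose$axis),
                        m$pose$angle, m$pose$timestamp),
      pressure = if (is.null(m$pressure)) NULL
                 else pressure_reading(m$pressure$force,
                                       m$pressure$timestamp),
      true_azimuth = if (is.null(m$true_azimuth)) NA_real_
                     else m$true_azimuth,
      true_distance = if (is.null(m$true_distance)) NA_real_
                      else m$true_distance,
      working_radius = m$working_radius, delta_h = m$delta_h)
  })
}
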
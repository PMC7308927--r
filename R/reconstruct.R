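# The probe sector matching reconstruction pipeline:
# match each frame's plane to the sector database (three-point dual-space
# test), compensate echo depths using the pose / pressure / medium
# feedback, and place the detected echo pixels into the matched plane.
# Placement is anchored at the nominal contact radius of the reference
# sector, so uncompensated surface or medium changes show up directly as
# radial distortion of the reconstructed target, which the evaluation
# metrics quantify.

#' Per-scanline first-crossing echo depth
#'
#' For each scanline, the shallowest sample with intensity `>= threshold`,
#' converted to mm via the depth spacing.
#'
#' @param frame An [acquisition_frame()], or a plain `n_lines x n_depth`
#'   intensity matrix (then `depth_spacing` is required).
#' @param threshold Detection threshold in `(0, 1)` (default 0.5;
#'   synthetic frames are high-contrast).
#' @param depth_spacing Depth sample spacing in mm (taken from the frame
#'   when omitted).
#' @return Numeric vector of depths (mm), `NA` for scanlines with no
#'   crossing.
#' @export
detect_target_depth <- function(frame, threshold = 0.5,
                                depth_spacing = NULL) {
  if (inherits(frame, "acquisition_frame")) {
    img <- frame$image
    if (is.null(depth_spacing)) depth_spacing <- frame$depth_spacing
  } else {
    img <- frame
    if (is.null(depth_spacing))
      stop("depth_spacing is required for a bare image matrix")
  }
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  apply(img, 1L, function(row) {
    k <- which(row >= threshold)
    if (!length(k)) NA_real_ else k[1L] * depth_spacing
  })
}

#' Feedback-compensated depth map of one frame
#'
#' When enabled, three feedback channels correct each detected depth:
#' the medium delay `tmc_echo_time(TMC(azimuth)) - T_ref` (converted to mm
#' at the nominal sound speed) from the calibrated medium profile, the
#' surface elevation read from the pose (`pose radius - r_contact_ref`),
#' and the squeeze read from the pressure
#' ([pressure_to_radius_correction()], which widens the working radius).
#' The azimuth is taken from the pose. `correction_mm` reports the
#' magnitude of the net applied shift. With `enabled = FALSE` (or a
#' missing pressure reading, with a warning) the depths pass through
#' unchanged and the correction is 0.
#'
#' @param frame An [acquisition_frame()].
#' @param cal A [calibration_map()]; its `r_contact_ref` and `tmc_curve`
#'   fields drive the pose and medium channels (each skipped when `NULL`).
#' @param model An [echo_model()].
#' @param enabled Master switch.
#' @param threshold Echo detection threshold (see
#'   [detect_target_depth()]).
#' @param frame_index Bookkeeping index stored in the feedback record.
#' @return A list with `depths` (corrected per-scanline depths, mm) and
#'   `feedback` (a one-row data frame `frame_index, correction_mm,
#'   azimuth`).
#' @export
compensate_frame <- function(frame, cal = calibration_map(),
                             model = echo_model(), enabled = TRUE,
                             threshold = 0.5, frame_index = NA_integer_) {
  stopifnot(inherits(frame, "acquisition_frame"),
            inherits(cal, "calibration_map"), inherits(model, "echo_model"))
  depths <- detect_target_depth(frame, threshold)
  pos <- frame$pose$position
  azimuth <- atan2(pos[2L], pos[1L]) %% (2 * pi)
  if (enabled && is.null(frame$pressure)) {
    warning("frame has no pressure reading; compensation disabled")
    enabled <- FALSE
  }
  shift <- 0
  if (enabled) {
    if (!is.null(cal$tmc_curve)) {
      dt <- tmc_echo_time(cal$tmc_curve$value(azimuth), cal) -
        model$reference_time
      shift <- shift + dt * model$mm_per_us
    }
    if (!is.null(cal$r_contact_ref))
      shift <- shift + (sqrt(pos[1L]^2 + pos[2L]^2) - cal$r_contact_ref)
    shift <- shift - pressure_to_radius_correction(frame$pressure, cal)
    depths <- depths - shift
  }
  list(depths = depths,
       feedback = data.frame(frame_index = frame_index,
                             correction_mm = abs(shift),
                             azimuth = azimuth))
}

#' Reconstruct a 3D target by probe sector matching
#'
#' Per frame: two in-plane points are derived from the pose (B = the
#' contact point, C = the deepest point of the contact scanline, one
#' working radius inward); [match_sector()] finds the database plane;
#' [compensate_frame()] corrects the detected echo depths; and each
#' detected echo is placed into the matched plane at its scanline's
#' lateral offset and corrected depth from the nominal contact radius.
#' Unmatched frames are skipped and counted. The nominal contact radius
#' (`cal$r_contact_ref`) is inferred, when absent, from the pose of the
#' frame nearest the reference azimuth (sector 0).
#'
#' @param frames List of [acquisition_frame()] objects.
#' @param db A [build_sector_database()] result (same target frame as the
#'   poses).
#' @param cal A [calibration_map()].
#' @param model An [echo_model()].
#' @param compensate Apply the feedback compensation (default `TRUE`).
#' @param tol Matching tolerance in mm (default `working_radius * 1e-3`).
#' @param threshold Echo detection threshold.
#' @return An object of class `"psm_reconstruction"`: `points` (n x 3
#'   matrix, mm), `intensity`, `sector_id` and `azimuth` per point,
#'   `feedback` (data frame), `skipped` (count of unmatched frames),
#'   `r_contact_ref`.
#' @export
psm_reconstruct <- function(frames, db, cal = calibration_map(),
                            model = echo_model(), compensate = TRUE,
                            tol = NULL, threshold = 0.5) {
  stopifnot(inherits(db, "sector_database"))
  if (is.null(tol)) tol <- db$working_radius * 1e-3
  E <- db$basis
  to_db <- function(p) drop(crossprod(E, p - db$target))
  if (length(frames) == 0L)
    return(structure(list(points = matrix(numeric(0), 0L, 3L),
                          intensity = numeric(0), sector_id = integer(0),
                          azimuth = numeric(0),
                          feedback = data.frame(frame_index = integer(0),
                                                correction_mm = numeric(0),
                                                azimuth = numeric(0)),
                          skipped = 0L, r_contact_ref = cal$r_contact_ref),
                     class = "psm_reconstruction"))
  ref_az <- db$sectors[[1L]]$azimuth
  pose_xy <- t(vapply(frames, function(f) to_db(f$pose$position)[1:2],
                      numeric(2)))
  pose_az <- atan2(pose_xy[, 2L], pose_xy[, 1L]) %% (2 * pi)
  if (is.null(cal$r_contact_ref)) {
    iref <- which.min(.circ_dist(pose_az, ref_az))
    cal$r_contact_ref <- sqrt(sum(pose_xy[iref, ]^2))
  }
  r_ref <- cal$r_contact_ref
  pts <- list(); inten <- list(); sect <- list(); fb <- list()
  skipped <- 0L
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    p_db <- to_db(f$pose$position)
    a <- pose_az[i]
    u <- c(cos(a), sin(a), 0)
    B <- p_db
    C <- p_db - db$working_radius * u
    m <- match_sector(B, C, db, tol, a)
    if (is.na(m$sector_id)) {
      skipped <- skipped + 1L
      next
    }
    comp <- compensate_frame(f, cal, model, enabled = compensate,
                             threshold = threshold, frame_index = i)
    fb[[length(fb) + 1L]] <- comp$feedback
    sec <- db$sectors[[m$sector_id + 1L]]
    us <- c(cos(sec$azimuth), sin(sec$azimuth), 0)
    dz <- (seq_len(f$n_lines) - ceiling((f$n_lines + 1L) / 2)) * f$delta_h
    hit <- which(!is.na(comp$depths))
    if (length(hit)) {
      d <- comp$depths[hit]
      loc <- outer(r_ref - d, us) + outer(dz[hit], c(0, 0, 1))
      # back to world coordinates
      world <- sweep(loc %*% t(E), 2L, db$target, `+`)
      pts[[length(pts) + 1L]] <- world
      inten[[length(inten) + 1L]] <-
        vapply(hit, function(l) max(f$image[l, ]), numeric(1))
      sect[[length(sect) + 1L]] <- rep(m$sector_id, length(hit))
    }
  }
  if (skipped == length(frames))
    stop("no frame matched any database sector; rebuild the database ",
         "with a larger vertical resolution delta_v")
  points <- if (length(pts)) do.call(rbind, pts) else matrix(numeric(0), 0L, 3L)
  structure(list(points = points,
                 intensity = if (length(inten)) unlist(inten) else numeric(0),
                 sector_id = if (length(sect)) unlist(sect) else integer(0),
                 azimuth = if (nrow(points))
                   atan2(points[, 2L], points[, 1L]) %% (2 * pi)
                 else numeric(0),
                 feedback = if (length(fb)) do.call(rbind, fb)
                 else data.frame(frame_index = integer(0),
                                 correction_mm = numeric(0),
                                 azimuth = numeric(0)),
                 skipped = skipped, r_contact_ref = r_ref),
            class = "psm_reconstruction")
}

#' @export
print.psm_reconstruction <- function(x, ...) {
  cat(sprintf(paste0("PSM reconstruction: %d points, %d frame(s) skipped, ",
                     "mean feedback %.3g mm\n"),
              nrow(x$points), x$skipped,
              if (nrow(x$feedback)) mean(x$feedback$correction_mm) else 0))
  invisible(x)
}

#' Cumulative-coordinate target curve
#'
#' Orders the reconstructed points by azimuth and accumulates their X and
#' Y coordinates: the curve of running sums against azimuth is a compact
#' signature of the reconstructed ring used to compare a distorted or
#' compensated run with the ideal one.
#'
#' @param recon A `"psm_reconstruction"`.
#' @return An object of class `"target_curve"`: `radians` (sorted),
#'   `cum_x`, `cum_y`.
#' @export
target_curve <- function(recon) {
  stopifnot(inherits(recon, "psm_reconstruction"))
  if (nrow(recon$points) == 0L)
    return(structure(list(radians = numeric(0), cum_x = numeric(0),
                          cum_y = numeric(0)), class = "target_curve"))
  ord <- order(recon$azimuth)
  structure(list(radians = recon$azimuth[ord],
                 cum_x = cumsum(recon$points[ord, 1L]),
                 cum_y = cumsum(recon$points[ord, 2L])),
            class = "target_curve")
}

#' Radial error report against the ring ground truth
#'
#' The radial error of each reconstructed point is the deviation of its
#' in-plane radius `sqrt(x^2 + y^2)` (about the phantom center, in the
#' ring plane frame) from the ring centerline radius.
#'
#' @param recon A `"psm_reconstruction"`.
#' @param phantom The ground-truth [ring_phantom()].
#' @return An object of class `"psm_error_report"`: `radial_rmse`,
#'   `max_radial_error` (mm; `NaN` with `degenerate = TRUE` when empty),
#'   `n_points`, and the per-point `errors`.
#' @export
error_report <- function(recon, phantom) {
  stopifnot(inherits(recon, "psm_reconstruction"),
            inherits(phantom, "ring_phantom"))
  if (nrow(recon$points) == 0L)
    return(structure(list(radial_rmse = NaN, max_radial_error = NaN,
                          n_points = 0L, errors = numeric(0),
                          degenerate = TRUE), class = "psm_error_report"))
  v <- sweep(recon$points, 2L, phantom$center)
  par <- drop(v %*% phantom$plane_normal)
  rin <- sqrt(pmax(rowSums(v^2) - par^2, 0))
  err <- abs(rin - phantom$ring_radius)
  structure(list(radial_rmse = sqrt(mean(err^2)),
                 max_radial_error = max(err),
                 n_points = nrow(recon$points), errors = err,
                 degenerate = FALSE),
            class = "psm_error_report")
}

#' @export
print.psm_error_report <- function(x, ...) {
  cat(sprintf("radial RMSE %.4g mm, max %.4g mm over %d points\n",
              x$radial_rmse, x$max_radial_error, x$n_points))
  invisible(x)
}

#' Write a reconstruction as an ASCII PLY point cloud
#'
#' Vertices carry `x, y, z` (mm) and `intensity`.
#'
#' @param recon A `"psm_reconstruction"` (or an `n x 3` matrix plus
#'   `intensity`).
#' @param path Output path.
#' @param intensity Per-point intensities when `recon` is a bare matrix.
#' @return The path, invisibly.
#' @export
write_ply <- function(recon, path, intensity = NULL) {
  if (inherits(recon, "psm_reconstruction")) {
    pts <- recon$points; intensity <- recon$intensity
  } else {
    pts <- .points_matrix(recon)
    if (is.null(intensity)) intensity <- rep(1, nrow(pts))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(pts)),
               "property float x", "property float y", "property float z",
               "property float intensity", "end_header"), con)
  if (nrow(pts))
    writeLines(sprintf("%.9g %.9g %.9g %.9g",
                       pts[, 1L], pts[, 2L], pts[, 3L], intensity), con)
  invisible(path)
}

#' Read an ASCII PLY point cloud written by [write_ply()]
#'
#' @param path PLY path.
#' @return A list with `points` (n x 3) and `intensity`.
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) stop("PLY file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L || lines[1L] != "ply" ||
      !grepl("ascii", lines[2L]))
    stop("not an ASCII PLY file: ", path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)[1L]))
  start <- which(lines == "end_header")[1L]
  if (is.na(nv) || is.na(start)) stop("malformed PLY header in ", path)
  if (nv == 0L)
    return(list(points = matrix(numeric(0), 0L, 3L), intensity = numeric(0)))
  dat <- utils::read.table(text = lines[(start + 1L):(start + nv)])
  list(points = as.matrix(dat[, 1:3]), intensity = dat[, 4L])
}
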
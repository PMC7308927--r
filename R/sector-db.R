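# The space plane inverse operation: precompute the database of candidate
# sector half-planes around the imaging target.
#
# Sectors are HALF-planes bounded by the axis L: delta_v sectors at azimuths
# 2*pi*k/delta_v are delta_v/2 distinct full planes, each full plane serving
# two opposite sectors (so delta_v = 8 gives 4 planes dividing the
# surrounding cylinder into 8 equal angular parts). All planes contain the
# axis; a frame acquired anywhere around the target must lie in (near) one
# of them, which is what makes the later matching a lookup instead of a
# free 6-DOF registration.

# Orthonormal basis (e1, e2, e3) with e3 = axis direction. Deterministic:
# for an axis within 1e-9 of +/-Z the world X axis is used as e1.
.axis_basis <- function(axis_dir) {
  e3 <- axis_dir / sqrt(sum(axis_dir^2))
  ref <- if (abs(e3[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * e3) * e3
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- .cross3(e3, e1)
  cbind(e1, e2, e3)
}

#' Build the sector database around a target
#'
#' Places `delta_v` sector half-planes through the axis at azimuths
#' `2*pi*k/delta_v`, `k = 0 .. delta_v - 1`. Each sector stores its full
#' containing plane (Hesse form, world coordinates), the side of the axis
#' it occupies, and a representative point at distance `r/2` from the axis
#' along the sector's in-plane azimuth direction (used as point A in the
#' matching step). The build is deterministic and O(delta_v).
#'
#' @param target The imaging target point P (mm); default the origin.
#' @param axis A `"line_param"` giving the axis L; default the Z axis
#'   through the target. A general axis is handled by rotating the internal
#'   frame so the axis becomes Z.
#' @param r Working radius of the probe, mm (> 0).
#' @param delta_v Vertical resolution: number of sector half-planes; must
#'   be even and >= 2.
#' @param delta_h Horizontal resolution (scanline pitch of the linear
#'   array), mm (> 0).
#' @return An object of class `"sector_database"`.
#' @export
build_sector_database <- function(target = c(0, 0, 0),
                                  axis = line_param(target, c(0, 0, 1)),
                                  r, delta_v, delta_h = 0.3) {
  target <- .vec3(target, "target")
  stopifnot(inherits(axis, "line_param"))
  if (!is.finite(r) || r <= 0) stop("config error: working radius must be > 0")
  if (!is.finite(delta_h) || delta_h <= 0)
    stop("config error: delta_h must be > 0")
  delta_v <- as.integer(delta_v)
  if (is.na(delta_v) || delta_v < 2L || delta_v %% 2L != 0L)
    stop("config error: delta_v must be an even integer >= 2")
  # axis must pass through the target (it defines the pencil of planes)
  off <- axis$point - target
  off <- off - sum(off * axis$direction) * axis$direction
  if (sqrt(sum(off^2)) > 1e-9)
    stop("config error: axis does not pass through the target point")
  E <- .axis_basis(axis$direction)
  az <- 2 * pi * (seq_len(delta_v) - 1L) / delta_v
  sectors <- lapply(seq_len(delta_v), function(k) {
    a <- az[k]
    u <- drop(E %*% c(cos(a), sin(a), 0))   # in-plane azimuth direction
    nrm <- drop(E %*% c(-sin(a), cos(a), 0)) # plane normal (horizontal)
    plane <- .canonical_hesse(nrm, sum(nrm * target))
    d_ref <- .cross3(axis$direction, plane_normal(plane))
    list(sector_id = k - 1L,
         azimuth = a,
         plane = plane,
         half_plane_sign = if (sum(u * d_ref) >= 0) 1L else -1L,
         representative_point = target + (r / 2) * u)
  })
  structure(list(target = target, axis = axis, working_radius = r,
                 delta_v = delta_v, delta_h = delta_h,
                 basis = E, sectors = sectors),
            class = "sector_database")
}

#' @export
print.sector_database <- function(x, ...) {
  cat(sprintf(paste0("Sector database: delta_v = %d half-planes (%d full ",
                     "planes), r = %g mm, delta_h = %g mm\n"),
              x$delta_v, x$delta_v %/% 2L, x$working_radius, x$delta_h))
  cat(sprintf("  target P = (%g, %g, %g) mm, axis direction (%g, %g, %g)\n",
              x$target[1], x$target[2], x$target[3],
              x$axis$direction[1], x$axis$direction[2], x$axis$direction[3]))
  invisible(x)
}

#' Nearest sector to an azimuth
#'
#' @param db A `"sector_database"`.
#' @param azimuth Query azimuth in radians.
#' @return A list `(sector_id, angular_distance)`; ties go to the lower
#'   sector id.
#' @export
nearest_sector <- function(db, azimuth) {
  stopifnot(inherits(db, "sector_database"))
  az <- vapply(db$sectors, function(s) s$azimuth, numeric(1))
  d <- .circ_dist(az, azimuth)
  # ties (up to float noise) go to the lower id; sectors are in id order
  k <- which(d <= min(d) + 1e-9)[1L]
  list(sector_id = db$sectors[[k]]$sector_id, angular_distance = d[k])
}

#' Pixel grid of a sector frame
#'
#' Maps the image raster of a linear-array frame into its sector plane:
#' scanlines are parallel to the inward ray from the probe contact point
#' toward the axis, spaced `delta_h` laterally along the axis direction;
#' depth samples are spaced `r / n_depth` from the contact surface inward.
#' Lateral offsets are `(i - ceiling((n_lines + 1)/2)) * delta_h`, so the
#' contact ray coincides with a scanline (the center element for odd
#' `n_lines`, element `n_lines/2` for even counts).
#'
#' @param s A sector entry of the database (`db$sectors[[k]]`).
#' @param db The `"sector_database"`.
#' @param n_lines,n_depth Raster dimensions (>= 1).
#' @param probe_contact Contact point of the probe, mm; must lie on the
#'   sector plane (residual below `tol`).
#' @param tol Contact-point residual tolerance, mm.
#' @return An `(n_lines * n_depth) x 3` matrix of points, ordered depth
#'   fastest, with attributes `n_lines`, `n_depth`.
#' @export
sector_sample_grid <- function(s, db, n_lines, n_depth, probe_contact,
                               tol = 1e-6) {
  stopifnot(inherits(db, "sector_database"))
  n_lines <- as.integer(n_lines); n_depth <- as.integer(n_depth)
  if (n_lines < 1L || n_depth < 1L) stop("n_lines and n_depth must be >= 1")
  probe_contact <- .vec3(probe_contact, "probe_contact")
  if (abs(eval_plane(probe_contact, s$plane)) > tol)
    stop("geometry error: probe contact point is not on the sector plane")
  e3 <- db$axis$direction
  v <- probe_contact - db$target
  u <- v - sum(v * e3) * e3          # horizontal (radial) component
  ru <- sqrt(sum(u^2))
  if (ru < 1e-9) stop("geometry error: contact point lies on the axis")
  u <- u / ru
  dz <- (seq_len(n_lines) - ceiling((n_lines + 1L) / 2)) * db$delta_h
  depth <- seq_len(n_depth) * (db$working_radius / n_depth)
  lat <- rep(dz, each = n_depth)
  dep <- rep(depth, times = n_lines)
  pts <- matrix(probe_contact, nrow = n_lines * n_depth, ncol = 3L,
                byrow = TRUE) +
    outer(lat, e3) - outer(dep, u)
  attr(pts, "n_lines") <- n_lines
  attr(pts, "n_depth") <- n_depth
  pts
}

#' Write a sector database as JSON
#'
#' Floats are serialized with 17 significant digits in a fixed key order so
#' the write/read round trip is bit-exact.
#'
#' @param db A `"sector_database"`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_sector_database <- function(db, path) {
  stopifnot(inherits(db, "sector_database"))
  doc <- list(
    schema = "psm3d/sector-database/1",
    target = db$target,
    axis = list(point = db$axis$point, direction = db$axis$direction),
    working_radius = db$working_radius,
    delta_v = db$delta_v,
    delta_h = db$delta_h,
    sectors = lapply(db$sectors, function(s) list(
      sector_id = s$sector_id,
      azimuth = s$azimuth,
      plane = list(theta = s$plane$theta, phi = s$plane$phi,
                   rho = s$plane$rho),
      half_plane_sign = s$half_plane_sign,
      representative_point = s$representative_point)))
  writeLines(jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                              always_decimal = TRUE, pretty = TRUE), path)
  invisible(path)
}

#' Read a sector database written by [write_sector_database()]
#'
#' @param path JSON path.
#' @return A `"sector_database"`.
#' @export
read_sector_database <- function(path) {
  if (!file.exists(path)) stop("sector database file not found: ", path)
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (!identical(doc$schema, "psm3d/sector-database/1"))
    stop("unrecognized sector database schema: ", format(doc$schema))
  axis <- line_param(unlist(doc$axis$point), unlist(doc$axis$direction))
  sectors <- lapply(doc$sectors, function(s) list(
    sector_id = as.integer(s$sector_id),
    azimuth = s$azimuth,
    plane = plane_hesse(s$plane$theta, s$plane$phi, s$plane$rho),
    half_plane_sign = as.integer(s$half_plane_sign),
    representative_point = unlist(s$representative_point)))
  structure(list(target = unlist(doc$target), axis = axis,
                 working_radius = doc$working_radius,
                 delta_v = as.integer(doc$delta_v), delta_h = doc$delta_h,
                 basis = .axis_basis(axis$direction), sectors = sectors),
            class = "sector_database")
}
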
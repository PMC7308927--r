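# 3D Hough plane detection and the three-point dual-space matching step.
#
# A spatial point (x, y, z) maps to the dual surface
# rho(theta, phi) = x sin t cos p + y sin t sin p + z cos t in the
# (theta, phi, rho) parameter space; points sharing a plane have dual
# surfaces meeting in one parameter-space cell, so the accumulator peak
# identifies the plane supported by the most points. The "improved"
# (three-point, inverse) form skips the accumulator: three non-collinear
# points determine the parameter-space intersection point directly, which
# is what sector matching uses.

#' Binning specification for the 3D Hough accumulator
#'
#' The parameter ranges are fixed: `theta` in `[0, pi]`, `phi` in
#' `[-pi, pi]`, `rho` in `[0, rho_max]`.
#'
#' @param d_theta,d_phi Angular bin widths in radians (default 1 degree).
#' @param d_rho Distance bin width in mm (default 0.5).
#' @param rho_max Upper end of the distance range in mm.
#' @return An object of class `"hough_bin_spec"`.
#' @export
hough_bin_spec <- function(d_theta = pi / 180, d_phi = pi / 180,
                           d_rho = 0.5, rho_max = 50) {
  if (!all(is.finite(c(d_theta, d_phi, d_rho, rho_max))) ||
      any(c(d_theta, d_phi, d_rho, rho_max) <= 0))
    stop("all bin widths and rho_max must be positive")
  structure(list(d_theta = d_theta, d_phi = d_phi, d_rho = d_rho,
                 rho_max = rho_max,
                 n_theta = as.integer(ceiling(pi / d_theta - 1e-9)),
                 n_phi = as.integer(ceiling(2 * pi / d_phi - 1e-9)),
                 n_rho = as.integer(ceiling(rho_max / d_rho - 1e-9))),
            class = "hough_bin_spec")
}

#' Dual value of a point at given normal angles
#'
#' @param p A point (length-3 numeric) or `n x 3` matrix.
#' @param theta,phi Normal angles in radians.
#' @return `x sin(t)cos(p) + y sin(t)sin(p) + z cos(t)` in mm; may be
#'   negative (the caller decides range clipping).
#' @export
dual_value <- function(p, theta, phi) {
  n <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  if (is.matrix(p)) return(drop(p %*% n))
  sum(.vec3(p) * n)
}

.points_matrix <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3L)
    return(points)
  }
  if (is.list(points)) {
    if (length(points) == 0L) return(matrix(numeric(0), 0L, 3L))
    return(do.call(rbind, lapply(points, .vec3)))
  }
  if (is.numeric(points) && length(points) == 3L) return(matrix(points, 1L, 3L))
  stop("points must be an n x 3 matrix or a list of length-3 vectors")
}

# bin centers
.theta_centers <- function(spec) (seq_len(spec$n_theta) - 0.5) * spec$d_theta
.phi_centers <- function(spec) -pi + (seq_len(spec$n_phi) - 0.5) * spec$d_phi

#' Fill the 3D Hough accumulator
#'
#' Every point casts one vote per (theta-bin, phi-bin) pair, at the rho bin
#' containing its dual value evaluated at the bin-center angles; (theta, phi)
#' cells whose dual value falls outside `[0, rho_max]` are skipped.
#'
#' @param points An `n x 3` matrix (or list of length-3 vectors), mm.
#' @param spec A [hough_bin_spec()].
#' @return An object of class `"hough_accumulator"` with integer `counts`
#'   of dimension `(n_theta, n_phi, n_rho)`.
#' @export
hough_accumulate <- function(points, spec = hough_bin_spec()) {
  stopifnot(inherits(spec, "hough_bin_spec"))
  pts <- .points_matrix(points)
  nt <- spec$n_theta; np <- spec$n_phi; nr <- spec$n_rho
  counts <- array(0L, dim = c(nt, np, nr))
  if (nrow(pts) > 0L) {
    th <- .theta_centers(spec); ph <- .phi_centers(spec)
    st <- sin(th); ct <- cos(th)
    # unit normals for all (theta, phi) cells: nt x np matrices
    nx <- outer(st, cos(ph)); ny <- outer(st, sin(ph))
    nz <- matrix(ct, nt, np)
    cell_t <- rep.int(seq_len(nt), np)
    cell_p <- rep(seq_len(np), each = nt)
    per_point <- vector("list", nrow(pts))
    for (i in seq_len(nrow(pts))) {
      rho <- pts[i, 1L] * nx + pts[i, 2L] * ny + pts[i, 3L] * nz
      ir <- floor(as.vector(rho) / spec$d_rho) + 1L
      keep <- ir >= 1L & ir <= nr
      per_point[[i]] <- cell_t[keep] + nt * (cell_p[keep] - 1L) +
        nt * np * (ir[keep] - 1L)
    }
    idx_all <- unlist(per_point, use.names = FALSE)
    if (length(idx_all))
      counts <- array(tabulate(idx_all, nbins = nt * np * nr),
                      dim = c(nt, np, nr))
  }
  structure(list(spec = spec, counts = counts, n_points = nrow(pts)),
            class = "hough_accumulator")
}

#' @export
print.hough_accumulator <- function(x, ...) {
  cat(sprintf("3D Hough accumulator: %d x %d x %d bins, %d points, %d votes\n",
              dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3],
              x$n_points, sum(x$counts)))
  invisible(x)
}

#' Detect the dominant plane in a point cloud
#'
#' Runs the full accumulator and returns the bin-center plane of the
#' maximum-count cell; ties are broken by the smallest
#' (theta-bin, phi-bin, rho-bin) lexicographic index.
#'
#' @param points `n x 3` matrix of points, `n >= 3`.
#' @param spec A [hough_bin_spec()].
#' @return A list with elements `plane` (a `"plane_hesse"` at the bin
#'   centers) and `votes` (the peak count).
#' @export
hough_detect_plane <- function(points, spec = hough_bin_spec()) {
  pts <- .points_matrix(points)
  if (nrow(pts) < 3L) stop("insufficient data: at least 3 points required")
  if (all(abs(sweep(pts, 2L, pts[1L, ])) < 1e-12))
    stop("ambiguous peak: all points coincide")
  acc <- hough_accumulate(pts, spec)
  mx <- max(acc$counts)
  hits <- which(acc$counts == mx, arr.ind = TRUE)
  # lexicographic (theta, phi, rho) tie-break
  ord <- order(hits[, 1L], hits[, 2L], hits[, 3L])
  b <- hits[ord[1L], ]
  theta <- (b[1L] - 0.5) * spec$d_theta
  phi <- -pi + (b[2L] - 0.5) * spec$d_phi
  rho <- (b[3L] - 0.5) * spec$d_rho
  n <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  list(plane = .canonical_hesse(n, rho), votes = as.integer(mx),
       accumulator = acc)
}

#' Solve the three-point dual-space system
#'
#' Solves the three simultaneous equations
#' `p_i . (sin t cos p, sin t sin p, cos t) = r` for the unique
#' `(theta, phi, rho)`. This is the inverse/three-point route: instead of
#' accumulating votes, the parameter-space intersection point of the three
#' dual surfaces is computed directly. It must agree with
#' [plane_from_three_points()] (a property the test suite enforces).
#'
#' @param a,b,c Three non-collinear points (mm).
#' @return A `"plane_hesse"` object (canonicalized).
#' @export
solve_three_points <- function(a, b, c) {
  a <- .vec3(a); b <- .vec3(b); c <- .vec3(c)
  M <- rbind(a, b, c)
  sv <- svd(rbind(b - a, c - a), nv = 3L)
  if (sv$d[2L] <= 1e-9)
    stop("degenerate input: points are collinear or not distinct")
  # If the plane misses the origin, n.x = r with r != 0; dividing by r gives
  # the linear system M m = 1 with m = n / r.
  m <- tryCatch(solve(M, rep(1, 3)), error = function(e) NULL)
  if (!is.null(m) && all(is.finite(m)) && sqrt(sum(m^2)) > 1e-9 &&
      max(abs(M %*% m - 1)) < 1e-6) {
    return(.canonical_hesse(m, 1))
  }
  # Plane through the origin: normal spans the nullspace of the difference
  # system, r = 0.
  n <- sv$v[, 3L]
  .canonical_hesse(n, sum(n * a))
}

# circular distance between two azimuths in radians
.circ_dist <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d)
}

#' Match two frame points against the sector database
#'
#' Candidate sectors are tried in order of angular proximity of their
#' azimuth to `probe_azimuth` (ties to the lower sector id). For each
#' candidate the score is the worst point-plane distance of `b` and `c`
#' from the sector's full plane (equivalently: whether the three-point
#' dual-space solution for the sector's representative point A together
#' with b and c lands on the sector's stored parameters); the first sector
#' scoring `<= tol` wins. Because a full plane covers two opposite
#' half-plane sectors, the azimuthal ordering performs the half-plane
#' disambiguation: the sector within pi/2 of the probe azimuth is tried
#' first.
#'
#' @param b,c Two distinct points taken from the current probe sector (mm).
#' @param db A sector database from [build_sector_database()].
#' @param tol Acceptance threshold on the point-plane distance, mm.
#'   Defaults to `working_radius * 1e-3`.
#' @param probe_azimuth Azimuth of the probe contact point, radians.
#' @return A list of class `"psm_match"` with `sector_id` (or `NA` on
#'   no-match), `score` (mm), `matched_plane`, and `advice` when unmatched.
#' @export
match_sector <- function(b, c, db, tol = NULL, probe_azimuth) {
  stopifnot(inherits(db, "sector_database"))
  b <- .vec3(b); c <- .vec3(c)
  if (max(abs(b - c)) < 1e-12) stop("b and c must be distinct points")
  if (is.null(tol)) tol <- db$working_radius * 1e-3
  az <- vapply(db$sectors, function(s) s$azimuth, numeric(1))
  ids <- vapply(db$sectors, function(s) s$sector_id, integer(1))
  # quantize distances so exact geometric ties (equal up to float noise)
  # deterministically resolve to the lower sector id
  ord <- order(round(.circ_dist(az, probe_azimuth) / 1e-9), ids)
  for (k in ord) {
    pl <- db$sectors[[k]]$plane
    score <- max(abs(eval_plane(b, pl)), abs(eval_plane(c, pl)))
    if (score <= tol) {
      return(structure(list(sector_id = ids[k], score = score,
                            matched_plane = pl, advice = NULL),
                       class = "psm_match"))
    }
  }
  best <- vapply(seq_along(db$sectors), function(k) {
    pl <- db$sectors[[k]]$plane
    max(abs(eval_plane(b, pl)), abs(eval_plane(c, pl)))
  }, numeric(1))
  structure(list(sector_id = NA_integer_, score = min(best),
                 matched_plane = NULL,
                 advice = paste0("no sector within tolerance ",
                                 format(tol), " mm (best score ",
                                 format(min(best)), " mm); rebuild the ",
                                 "sector database with a larger ",
                                 "vertical resolution delta_v")),
            class = "psm_match")
}

#' @export
print.psm_match <- function(x, ...) {
  if (is.na(x$sector_id)) {
    cat("no match:", x$advice, "\n")
  } else {
    cat(sprintf("matched sector %d (score %.3g mm)\n", x$sector_id, x$score))
  }
  invisible(x)
}

#' Dump an accumulator to CSV (debugging aid)
#'
#' Writes nonzero cells as `theta_bin, phi_bin, rho_bin, theta, phi, rho,
#' count`.
#'
#' @param acc A `"hough_accumulator"`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_accumulator_csv <- function(acc, path) {
  stopifnot(inherits(acc, "hough_accumulator"))
  nz <- which(acc$counts > 0L, arr.ind = TRUE)
  spec <- acc$spec
  df <- data.frame(
    theta_bin = nz[, 1L], phi_bin = nz[, 2L], rho_bin = nz[, 3L],
    theta = (nz[, 1L] - 0.5) * spec$d_theta,
    phi = -pi + (nz[, 2L] - 0.5) * spec$d_phi,
    rho = (nz[, 3L] - 0.5) * spec$d_rho,
    count = acc$counts[nz])
  utils::write.csv(df[order(-df$count), ], path, row.names = FALSE)
  invisible(path)
}
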
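# Plane and line geometry in the target-centered frame.
#
# All lengths are millimetres in a right-handed Cartesian frame whose origin
# is the imaging target P; the database axis L is conventionally the Z axis.
# Planes circulate between two forms: the general form A x + B y + C z + D = 0
# and the Hesse normal form
#
#   x sin(theta) cos(phi) + y sin(theta) sin(phi) + z cos(theta) = rho
#
# with unit normal (sin t cos p, sin t sin p, cos t), theta in [0, pi],
# phi in (-pi, pi], rho >= 0. The Hesse triple (theta, phi, rho) is the
# currency of all sector matching.

.vec3 <- function(p, what = "point") {
  p <- as.numeric(p)
  if (length(p) != 3L || any(!is.finite(p)))
    stop(sprintf("%s must be a finite numeric vector of length 3", what))
  p
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Construct a plane in general form
#'
#' @param A,B,C,D Real coefficients of `A*x + B*y + C*z + D = 0`.
#'   `(A, B, C)` must not all be zero.
#' @return An object of class `"plane_general"`.
#' @export
plane_general <- function(A, B, C, D) {
  co <- as.numeric(c(A, B, C, D))
  if (length(co) != 4L || any(!is.finite(co)))
    stop("plane coefficients must be four finite numbers")
  if (sum(co[1:3]^2) == 0)
    stop("invalid plane: normal (A, B, C) is the zero vector")
  structure(list(A = co[1L], B = co[2L], C = co[3L], D = co[4L]),
            class = "plane_general")
}

#' Construct a plane in Hesse normal form
#'
#' @param theta Polar angle of the unit normal, radians in `[0, pi]`.
#' @param phi Azimuthal angle of the unit normal, radians in `(-pi, pi]`.
#' @param rho Distance from the origin to the plane, mm, `>= 0`.
#' @return An object of class `"plane_hesse"`.
#' @export
plane_hesse <- function(theta, phi, rho) {
  if (!is.finite(theta) || theta < -1e-12 || theta > pi + 1e-12)
    stop("theta must lie in [0, pi]")
  if (!is.finite(phi) || phi < -pi - 1e-12 || phi > pi + 1e-12)
    stop("phi must lie in [-pi, pi]")
  if (!is.finite(rho) || rho < 0)
    stop("rho must be a nonnegative distance in mm")
  structure(list(theta = theta, phi = phi, rho = rho), class = "plane_hesse")
}

#' @export
print.plane_hesse <- function(x, ...) {
  cat(sprintf("Hesse plane: theta = %.6f rad, phi = %.6f rad, rho = %.6f mm\n",
              x$theta, x$phi, x$rho))
  invisible(x)
}

#' @export
print.plane_general <- function(x, ...) {
  cat(sprintf("Plane: %.6g x + %.6g y + %.6g z + %.6g = 0\n",
              x$A, x$B, x$C, x$D))
  invisible(x)
}

# Canonical Hesse triple from an (unnormalized) normal and offset n . x = s.
# Sign chosen so rho >= 0; for rho = 0 the normal with theta <= pi/2 wins,
# and on the equator (theta = pi/2) the one with phi in (-pi/2, pi/2].
.canonical_hesse <- function(n, s, eps = 1e-12) {
  len <- sqrt(sum(n^2))
  if (len < eps) stop("invalid plane: zero normal")
  n <- n / len
  s <- s / len
  if (s < -eps) {
    n <- -n; s <- -s
  } else if (abs(s) <= eps) {
    s <- 0
    if (n[3L] < -eps) n <- -n
    else if (abs(n[3L]) <= eps) {
      if (n[1L] < -eps) n <- -n
      else if (abs(n[1L]) <= eps && n[2L] < 0) n <- -n
    }
  }
  nz <- min(1, max(-1, n[3L]))
  theta <- acos(nz)
  phi <- if (abs(sin(theta)) <= eps) 0 else atan2(n[2L], n[1L])
  plane_hesse(theta, phi, max(s, 0))
}

#' Convert a general-form plane to Hesse normal form
#'
#' The sign of the normal is chosen so that `rho >= 0`; planes through the
#' origin are canonicalized with `theta <= pi/2` (and `phi` in
#' `(-pi/2, pi/2]` when `theta = pi/2`), which makes plane equality testable.
#'
#' @param p A `"plane_general"` object (or anything accepted by
#'   [plane_general()] as a coefficient vector of length 4).
#' @return A `"plane_hesse"` object.
#' @export
hesse_from_general <- function(p) {
  if (!inherits(p, "plane_general")) p <- plane_general(p[1], p[2], p[3], p[4])
  .canonical_hesse(c(p$A, p$B, p$C), -p$D)
}

#' Convert a Hesse-form plane back to general form
#'
#' @param p A `"plane_hesse"` object.
#' @return A `"plane_general"` object with unit `(A, B, C)` and `D = -rho`.
#' @export
general_from_hesse <- function(p) {
  stopifnot(inherits(p, "plane_hesse"))
  st <- sin(p$theta)
  plane_general(st * cos(p$phi), st * sin(p$phi), cos(p$theta), -p$rho)
}

#' Unit normal of a Hesse-form plane
#'
#' @param p A `"plane_hesse"` object.
#' @return Numeric length-3 unit vector.
#' @export
plane_normal <- function(p) {
  stopifnot(inherits(p, "plane_hesse"))
  st <- sin(p$theta)
  c(st * cos(p$phi), st * sin(p$phi), cos(p$theta))
}

#' Signed point-plane residual
#'
#' Evaluates `x sin(t)cos(p) + y sin(t)sin(p) + z cos(t) - rho`. The result
#' is zero iff the point lies on the plane and its absolute value is the
#' point-plane distance in mm.
#'
#' @param p A point (numeric length 3) or an `n x 3` matrix of points.
#' @param plane A `"plane_hesse"` object.
#' @return Signed residual(s) in mm.
#' @export
eval_plane <- function(p, plane) {
  stopifnot(inherits(plane, "plane_hesse"))
  n <- plane_normal(plane)
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 3L)
    return(drop(p %*% n) - plane$rho)
  }
  sum(.vec3(p) * n) - plane$rho
}

#' Plane through three points
#'
#' @param a,b,c Three pairwise distinct, non-collinear points (length-3
#'   numeric vectors, mm).
#' @param tol Collinearity tolerance on the norm of the cross product
#'   `(b - a) x (c - a)`, in mm^2.
#' @return A `"plane_hesse"` object containing all three points to
#'   better than 1e-9 mm.
#' @export
plane_from_three_points <- function(a, b, c, tol = 1e-9) {
  a <- .vec3(a); b <- .vec3(b); c <- .vec3(c)
  n <- .cross3(b - a, c - a)
  if (sqrt(sum(n^2)) <= tol)
    stop("degenerate input: points are collinear or not distinct")
  .canonical_hesse(n, sum(n * a))
}

#' Construct a parametric line
#'
#' @param point A point on the line (mm).
#' @param direction Direction vector; normalized internally.
#' @return An object of class `"line_param"` with unit `direction`.
#' @export
line_param <- function(point, direction) {
  point <- .vec3(point)
  direction <- .vec3(direction, "direction")
  len <- sqrt(sum(direction^2))
  if (len < 1e-12) stop("line direction must be nonzero")
  structure(list(point = point, direction = direction / len),
            class = "line_param")
}

#' @export
print.line_param <- function(x, ...) {
  cat(sprintf("Line: (%.4g, %.4g, %.4g) + t (%.4g, %.4g, %.4g)\n",
              x$point[1], x$point[2], x$point[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Intersection line of two planes
#'
#' The database axis L can be specified as the intersection of two general
#' planes; this recovers it in parametric form.
#'
#' @param p1,p2 `"plane_general"` objects with non-parallel normals.
#' @param tol Parallelism tolerance on the cross-product norm of the unit
#'   normals.
#' @return A `"line_param"` whose points satisfy both plane equations.
#' @export
line_from_two_planes <- function(p1, p2, tol = 1e-9) {
  stopifnot(inherits(p1, "plane_general"), inherits(p2, "plane_general"))
  n1 <- c(p1$A, p1$B, p1$C); n2 <- c(p2$A, p2$B, p2$C)
  u1 <- n1 / sqrt(sum(n1^2)); u2 <- n2 / sqrt(sum(n2^2))
  d <- .cross3(u1, u2)
  if (sqrt(sum(d^2)) <= tol)
    stop("planes are parallel or identical: no unique intersection line")
  # point on both planes: least-squares solution of the 2x3 system
  M <- rbind(n1, n2)
  rhs <- c(-p1$D, -p2$D)
  p0 <- drop(qr.solve(M %*% t(M), rhs))
  point <- drop(t(M) %*% p0)
  line_param(point, d)
}
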
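# Independent oracles used across the suite. Each is deliberately coded
# along a different route than the package implementation it checks.

# Exhaustive Hough accumulator, theta-major with a matrix product per
# theta slab (the package loops over points and uses outer products over
# the whole (theta, phi) grid).
oracle_accumulate <- function(pts, spec) {
  nt <- spec$n_theta; np <- spec$n_phi; nr <- spec$n_rho
  counts <- array(0L, c(nt, np, nr))
  phis <- -pi + (seq_len(np) - 0.5) * spec$d_phi
  for (it in seq_len(nt)) {
    th <- (it - 0.5) * spec$d_theta
    normals <- rbind(sin(th) * cos(phis), sin(th) * sin(phis),
                     rep(cos(th), np))
    rho <- pts %*% normals                       # n_points x np
    ir <- floor(rho / spec$d_rho) + 1L
    keep <- ir >= 1L & ir <= nr
    ip <- matrix(rep(seq_len(np), each = nrow(pts)), nrow(pts), np)
    idx <- ir[keep] + nr * (ip[keep] - 1L)       # packed (rho, phi)
    slab <- matrix(tabulate(idx, nbins = nr * np), nr, np)
    counts[it, , ] <- t(slab)
  }
  counts
}

# Plane through three points via the cross product, returning the raw
# normal and offset (no canonicalization), for residual checks.
oracle_plane_normal <- function(a, b, c) {
  u <- b - a; v <- c - a
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  list(n = n, s = sum(n * a))
}

# Brute-force sector match: argmin of the worst point-plane distance over
# all sectors. A full plane serves two opposite half-plane sectors with
# identical scores, so the argmin is restricted to sectors on the probe's
# side (azimuth within pi/2), mirroring the half-plane disambiguation.
oracle_match <- function(b, c, db, probe_azimuth) {
  az <- vapply(db$sectors, function(s) s$azimuth, numeric(1))
  d <- abs((az - probe_azimuth) %% (2 * pi))
  near <- which(pmin(d, 2 * pi - d) <= pi / 2 + 1e-12)
  scores <- vapply(db$sectors[near], function(s)
    max(abs(eval_plane(b, s$plane)), abs(eval_plane(c, s$plane))),
    numeric(1))
  list(sector_id = db$sectors[[near[which.min(scores)]]]$sector_id,
       score = min(scores))
}

# Dense-sampling first-hit distance to the ring, no bisection.
oracle_ray_ring <- function(origin, direction, phantom, t_max, step = 1e-4) {
  tt <- seq(0, t_max, by = step)
  pts <- matrix(origin, length(tt), 3L, byrow = TRUE) + outer(tt, direction)
  v <- sweep(pts, 2L, phantom$center)
  par <- drop(v %*% phantom$plane_normal)
  d <- sqrt((sqrt(pmax(rowSums(v^2) - par^2, 0)) -
               phantom$ring_radius)^2 + par^2)
  k <- which(d <= phantom$tube_radius)
  if (!length(k)) NA_real_ else tt[k[1L]]
}

# Random well-conditioned Hesse plane (away from the poles, rho bounded
# away from 0 and rho_max).
random_plane <- function(rho_range = c(0.7, 8), theta_range = c(0.2, pi - 0.2)) {
  theta <- stats::runif(1, theta_range[1], theta_range[2])
  phi <- stats::runif(1, -pi + 1e-3, pi - 1e-3)
  rho <- stats::runif(1, rho_range[1], rho_range[2])
  plane_hesse(theta, phi, rho)
}

# n points on a Hesse plane with in-plane spread +/- half_extent. The
# default extent is wide relative to the 0.5 mm rho bins so that a one-bin
# angular error shifts the dual values by more than one rho bin (the
# accumulator's angular discrimination is ~ d_rho / extent).
points_on_plane <- function(plane, n, half_extent = 40) {
  nrm <- plane_normal(plane)
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * nrm) * nrm
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  a <- stats::runif(n, -half_extent, half_extent)
  b <- stats::runif(n, -half_extent, half_extent)
  matrix(plane$rho * nrm, n, 3L, byrow = TRUE) + outer(a, e1) + outer(b, e2)
}

# Canonical-parameter discrepancy between two Hesse planes; the phi gap is
# circular and only counted where it is well defined (sin(theta) > 1e-6).
plane_discrepancy <- function(p1, p2) {
  dphi <- abs(p1$phi - p2$phi)
  dphi <- min(dphi, 2 * pi - dphi)
  if (sin(p1$theta) <= 1e-6 || sin(p2$theta) <= 1e-6) dphi <- 0
  max(abs(p1$theta - p2$theta), dphi, abs(p1$rho - p2$rho))
}

# Noise-free simulation config shared by the geometric-correctness tests.
quiet_sim <- function(delta_v, seed = 1, ...) {
  sim_config(delta_v = delta_v, seed = seed, noise_pos_sd = 0,
             noise_angle_sd = 0, noise_pressure_sd = 0, ...)
}

# B and C as the reconstruction derives them from a pose.
frame_bc <- function(frame, working_radius) {
  p <- frame$pose$position
  a <- atan2(p[2], p[1]) %% (2 * pi)
  list(b = p, c = p - working_radius * c(cos(a), sin(a), 0), azimuth = a)
}
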
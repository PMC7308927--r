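test_that("dual value evaluates the spherical plane equation", {
  expect_equal(dual_value(c(0, 0, 3), 0, 0), 3)
  expect_equal(dual_value(c(2, 0, 0), pi / 2, 0), 2)
  expect_equal(dual_value(c(1, 1, 0), pi / 2, pi / 4), sqrt(2),
               tolerance = 1e-12)
})

test_that("accumulator conserves votes and matches the counting contract", {
  spec <- hough_bin_spec(rho_max = 10)
  # empty input: all-zero counts
  acc <- hough_accumulate(matrix(numeric(0), 0, 3), spec)
  expect_identical(sum(acc$counts), 0L)

  # one point: one vote per (theta, phi) cell whose dual value is in range
  acc <- hough_accumulate(c(0, 0, 2), spec)
  th <- (seq_len(spec$n_theta) - 0.5) * spec$d_theta
  ph <- -pi + (seq_len(spec$n_phi) - 0.5) * spec$d_phi
  in_range <- sum(outer(2 * cos(th), rep(1, spec$n_phi)) >= 0 &
                    outer(2 * cos(th), rep(1, spec$n_phi)) <= 10)
  expect_equal(sum(acc$counts), in_range)
  expect_lte(sum(acc$counts), spec$n_theta * spec$n_phi)

  # grid points on z = 2.2 concentrate in the cell containing (theta=0, rho=2.2)
  g <- as.matrix(expand.grid(x = seq(-1, 1, length.out = 4),
                             y = seq(-1, 1, length.out = 4)))
  pts <- cbind(g, 2.2)
  acc <- hough_accumulate(pts, spec)
  expect_equal(acc$counts[1L, , ceiling(2.2 / spec$d_rho)],
               rep(16L, spec$n_phi))

  # debugging dump: nonzero cells, counts conserved
  path <- tempfile(fileext = ".csv")
  write_accumulator_csv(acc, path)
  dump <- utils::read.csv(path)
  expect_equal(sum(dump$count), sum(acc$counts))
  expect_true(all(dump$count > 0))
})

test_that("peak detection agrees with the exhaustive oracle on random clouds", {
  spec <- hough_bin_spec(rho_max = 10)
  set.seed(21)
  for (i in 1:5) {
    truth <- random_plane()
    pts <- points_on_plane(truth, 80)
    acc <- hough_accumulate(pts, spec)
    expect_identical(as.vector(acc$counts),
                     as.vector(oracle_accumulate(pts, spec)))
    det <- hough_detect_plane(pts, spec)
    expect_lte(abs(det$plane$theta - truth$theta), spec$d_theta)
    dphi <- abs(det$plane$phi - truth$phi)
    expect_lte(min(dphi, 2 * pi - dphi), spec$d_phi)
    expect_lte(abs(det$plane$rho - truth$rho), spec$d_rho)
  }
  expect_error(hough_detect_plane(rbind(c(0, 0, 1), c(1, 0, 0)), spec),
               "insufficient")
  expect_error(hough_detect_plane(rbind(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1)),
                                  spec), "coincide")
})

test_that("axis-aligned planar clouds are recovered with full vote counts", {
  spec <- hough_bin_spec(rho_max = 10)
  g <- as.matrix(expand.grid(seq(-1, 1, length.out = 10),
                             seq(-1, 1, length.out = 10)))
  det <- hough_detect_plane(cbind(g, 2.2), spec)
  expect_equal(det$votes, 100L)
  expect_lte(det$plane$theta, spec$d_theta)
  expect_lte(abs(det$plane$rho - 2.2), spec$d_rho)

  # x = 1.2, with a spread wide enough to resolve the angular bins
  gw <- as.matrix(expand.grid(seq(-20, 20, length.out = 10),
                              seq(-20, 20, length.out = 10)))
  det <- hough_detect_plane(cbind(1.2, gw), spec)
  expect_lte(abs(det$plane$theta - pi / 2), spec$d_theta)
  expect_lte(abs(det$plane$phi), spec$d_phi)
  expect_lte(abs(det$plane$rho - 1.2), spec$d_rho)
  expect_gte(det$votes, 50L)
})

test_that("three-point dual solve equals the cross-product construction", {
  p <- solve_three_points(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(p$theta, acos(1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(p$phi, pi / 4, tolerance = 1e-9)
  expect_equal(p$rho, 1 / sqrt(3), tolerance = 1e-9)

  p <- solve_three_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(c(p$theta, p$phi, p$rho), c(0, 0, 0))

  expect_error(solve_three_points(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)),
               "collinear")

  set.seed(22)
  worst <- 0
  for (i in 1:1000) {
    a <- stats::rnorm(3, sd = 5); b <- stats::rnorm(3, sd = 5)
    c_ <- stats::rnorm(3, sd = 5)
    if (sqrt(sum(oracle_plane_normal(a, b, c_)$n^2)) < 1e-2) next
    worst <- max(worst, plane_discrepancy(solve_three_points(a, b, c_),
                                          plane_from_three_points(a, b, c_)))
  }
  expect_lt(worst, 1e-6)
})

test_that("sector matching finds the generating sector and honors ties", {
  db <- build_sector_database(r = 20, delta_v = 8)
  # self-match: points sampled exactly on sector 3's half-plane
  s3 <- db$sectors[[4L]]
  b <- s3$representative_point
  c_ <- b + c(0, 0, 2)
  m <- match_sector(b, c_, db, probe_azimuth = s3$azimuth)
  expect_identical(m$sector_id, 3L)
  expect_equal(m$score, 0, tolerance = 1e-12)

  # bisector tie: nearer azimuth first; exact tie resolved to the lower id
  mid <- pi / 8
  b <- 5 * c(cos(mid), sin(mid), 0)
  m <- match_sector(b, b + c(0, 0, 1), db, tol = 5, probe_azimuth = mid)
  expect_identical(m$sector_id, 0L)

  # agreement with the brute-force argmin whenever a match exists
  set.seed(23)
  for (i in 1:50) {
    a <- stats::runif(1, 0, 2 * pi)
    jitter <- stats::runif(1, -0.01, 0.01)   # well inside half the spacing
    u <- c(cos(a + jitter), sin(a + jitter), 0)
    b <- stats::runif(1, 2, 10) * u + c(0, 0, stats::runif(1, -3, 3))
    c_ <- stats::runif(1, 2, 10) * u + c(0, 0, stats::runif(1, -3, 3))
    if (max(abs(b - c_)) < 1e-6) next
    # max possible score is 10 * sin(pi/8 + jitter) < 4, so a match exists
    m <- match_sector(b, c_, db, tol = 5, probe_azimuth = a)
    orc <- oracle_match(b, c_, db, a)
    expect_identical(m$sector_id, orc$sector_id)
    expect_equal(m$score, orc$score, tolerance = 1e-12)
  }

  # a plane rotated 10 degrees off every sector is rejected at tight tol
  rot <- 10 * pi / 180
  b <- 5 * c(cos(rot), sin(rot), 0)
  m <- match_sector(b, b + c(0, 0, 3), db, tol = 0.1, probe_azimuth = rot)
  expect_true(is.na(m$sector_id))
  expect_equal(m$score, 5 * sin(rot), tolerance = 1e-9)
  expect_match(m$advice, "delta_v")
})
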
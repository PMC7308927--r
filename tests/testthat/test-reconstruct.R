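test_that("first-crossing depth detection follows its contract", {
  img <- matrix(0, 3, 10)
  img[1, 4] <- 1                 # single bright pixel at sample 4
  img[3, 2] <- 0.8; img[3, 7] <- 1   # two echoes: shallower one wins
  d <- detect_target_depth(img, threshold = 0.5, depth_spacing = 0.25)
  expect_equal(d[1], 4 * 0.25)
  expect_true(is.na(d[2]))       # all-dark scanline
  expect_equal(d[3], 2 * 0.25)
  expect_error(detect_target_depth(img, threshold = 1.5,
                                   depth_spacing = 0.25), "threshold")
  expect_error(detect_target_depth(img), "depth_spacing")
})

test_that("compensation is the identity when disabled or undisturbed", {
  ph <- ring_phantom()
  fr <- simulate_acquisition(ph, quiet_sim(8), calibration_map())
  f <- fr[[3]]
  cal <- calibration_map(r_contact_ref = 10.05 + 4)
  off <- compensate_frame(f, cal, enabled = FALSE)
  expect_equal(off$feedback$correction_mm, 0)
  expect_identical(off$depths, detect_target_depth(f))
  on <- compensate_frame(f, cal, enabled = TRUE)
  expect_equal(on$feedback$correction_mm, 0, tolerance = 1e-9)
  expect_equal(on$depths, off$depths, tolerance = 1e-9)
  # a frame without a pressure reading falls back to disabled
  f2 <- f; f2$pressure <- NULL
  expect_warning(res <- compensate_frame(f2, cal), "pressure")
  expect_equal(res$feedback$correction_mm, 0)
})

test_that("closed-loop compensation restores the reference depth", {
  ph <- ring_phantom()
  sc <- curve_from_controls(kind = "surface")
  fr <- simulate_acquisition(ph, quiet_sim(8, surface_curve = sc),
                             calibration_map())
  cal <- calibration_map(r_contact_ref = 10.05 + 4)
  # elevated control D = 7 (pose channel) and squeezed D = 1.75 (pressure)
  for (k in c(5L, 6L)) {
    res <- compensate_frame(fr[[k]], cal, frame_index = k)
    d <- res$depths[!is.na(res$depths)]
    expect_lt(abs(d - 4), fr[[k]]$depth_spacing)
    expect_equal(res$feedback$correction_mm,
                 abs(fr[[k]]$true_distance - 4), tolerance = 1e-9)
  }
})

test_that("noiseless reconstruction recovers the ring on the matched planes", {
  ph <- ring_phantom()
  db <- build_sector_database(r = 20, delta_v = 8)
  fr <- simulate_acquisition(ph, quiet_sim(8), calibration_map())
  rec <- psm_reconstruct(fr, db, calibration_map())
  expect_identical(rec$skipped, 0L)
  expect_equal(nrow(rec$points), 8L)
  expect_identical(sort(unique(rec$sector_id)), 0:7)
  # placement invariant: every point on its matched sector plane
  for (i in seq_len(nrow(rec$points))) {
    pl <- db$sectors[[rec$sector_id[i] + 1L]]$plane
    expect_lt(abs(eval_plane(rec$points[i, ], pl)), 1e-6)
  }
  er <- error_report(rec, ph)
  expect_lt(er$radial_rmse, 0.1)
  expect_lte(er$radial_rmse, er$max_radial_error)

  # empty input: empty reconstruction
  empty <- psm_reconstruct(list(), db, calibration_map())
  expect_equal(nrow(empty$points), 0L)

  # without compensation the surface distortion shows up per azimuth
  sc <- curve_from_controls(kind = "surface")
  fr2 <- simulate_acquisition(ph, quiet_sim(8, surface_curve = sc),
                              calibration_map())
  raw <- psm_reconstruct(fr2, db, calibration_map(), compensate = FALSE)
  err <- error_report(raw, ph)$errors
  expected <- abs(vapply(fr2, function(f) f$true_distance, numeric(1)) - 4)
  expect_equal(sort(err), sort(expected), tolerance = 0.1)
})

test_that("all frames unmatched raises the rebuild advice", {
  ph <- ring_phantom()
  db <- build_sector_database(r = 20, delta_v = 8)
  fr <- simulate_acquisition(ph, quiet_sim(8), calibration_map())
  # rotate every pose 10 degrees off the database sectors
  rot <- 10 * pi / 180
  R <- matrix(c(cos(rot), sin(rot), 0, -sin(rot), cos(rot), 0, 0, 0, 1), 3)
  for (k in seq_along(fr))
    fr[[k]]$pose$position <- drop(R %*% fr[[k]]$pose$position)
  expect_error(psm_reconstruct(fr, db, calibration_map(), tol = 0.1),
               "delta_v")
})

test_that("target curve accumulates coordinates in azimuth order", {
  ph <- ring_phantom()
  db <- build_sector_database(r = 20, delta_v = 32)
  empty <- psm_reconstruct(list(), db, calibration_map())
  tc0 <- target_curve(empty)
  expect_length(tc0$radians, 0L)

  fr <- simulate_acquisition(ph, quiet_sim(32), calibration_map())
  ideal <- psm_reconstruct(fr, db, calibration_map())
  tci <- target_curve(ideal)
  expect_equal(length(tci$radians), nrow(ideal$points))
  expect_false(is.unsorted(tci$radians))
  ordp <- ideal$points[order(ideal$azimuth), ]
  expect_equal(tci$cum_x, cumsum(ordp[, 1]))
  expect_equal(tci$cum_y, cumsum(ordp[, 2]))

  # a compensated distorted run stays within 5% of the ideal curve
  sc <- curve_from_controls(kind = "surface")
  fr2 <- simulate_acquisition(ph, quiet_sim(32, surface_curve = sc),
                              calibration_map())
  comp <- psm_reconstruct(fr2, db, calibration_map())
  tcc <- target_curve(comp)
  for (ch in c("cum_x", "cum_y")) {
    rng <- diff(range(tci[[ch]]))
    expect_lt(max(abs(tcc[[ch]] - tci[[ch]])), 0.05 * rng)
  }
})

test_that("radial error report matches closed-form and Monte-Carlo cases", {
  ph <- ring_phantom(ring_radius = 10, tube_radius = 0.5)
  mk <- function(pts) structure(
    list(points = pts, intensity = rep(1, nrow(pts)),
         sector_id = rep(0L, nrow(pts)),
         azimuth = atan2(pts[, 2], pts[, 1]) %% (2 * pi),
         feedback = data.frame(), skipped = 0L),
    class = "psm_reconstruction")

  a <- seq(0, 2 * pi, length.out = 13)[-13]
  on_ring <- cbind(10 * cos(a), 10 * sin(a), 0)
  rep0 <- error_report(mk(on_ring), ph)
  expect_equal(rep0$radial_rmse, 0)
  expect_equal(rep0$max_radial_error, 0)

  one_out <- mk(matrix(c(11, 0, 0), 1))
  rep1 <- error_report(one_out, ph)
  expect_equal(rep1$radial_rmse, 1)
  expect_equal(rep1$max_radial_error, 1)

  set.seed(51)
  n <- 1000
  aa <- stats::runif(n, 0, 2 * pi)
  rr <- 10 + stats::rnorm(n, 0, 0.5)
  noisy <- mk(cbind(rr * cos(aa), rr * sin(aa), 0))
  repn <- error_report(noisy, ph)
  expect_lt(abs(repn$radial_rmse - 0.5) / 0.5, 0.2)
  expect_identical(repn$n_points, 1000L)

  degen <- error_report(mk(matrix(numeric(0), 0, 3)), ph)
  expect_true(degen$degenerate)
  expect_identical(degen$n_points, 0L)
  expect_true(is.nan(degen$radial_rmse))
})

test_that("PLY round trip preserves points and intensities", {
  pts <- matrix(stats::rnorm(30), 10)
  path <- tempfile(fileext = ".ply")
  write_ply(pts, path, intensity = seq(0.1, 1, length.out = 10))
  back <- read_ply(path)
  expect_equal(back$points, pts, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$intensity, seq(0.1, 1, length.out = 10),
               tolerance = 1e-6)
  expect_match(readLines(path)[2], "ascii")
})
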
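test_that("calibration curves are exact at controls, periodic, and bounded", {
  # constant controls give a constant curve
  cc <- curve_from_controls(rep(4, 5), kind = "surface")
  expect_equal(cc$value(seq(0, 2 * pi, length.out = 20)), rep(4, 20))

  sc <- curve_from_controls(kind = "surface")
  # the reference control (D = 4 mm) is anchored at azimuth 0
  expect_equal(sc$value(0), 4)
  expect_equal(sc$value(sc$control_radians), sc$control_values,
               tolerance = 1e-12)
  g <- seq(0, 2 * pi, length.out = 2000)
  expect_true(all(sc$value(g) >= min(sc$control_values) - 1e-9))
  expect_true(all(sc$value(g) <= max(sc$control_values) + 1e-9))
  expect_equal(sc$value(g), sc$value(g + 2 * pi), tolerance = 1e-12)
  # between adjacent knots the curve stays inside the bracketing values
  mid <- (sc$control_radians[2] + sc$control_radians[3]) / 2
  expect_true(sc$value(mid) >= min(sc$control_values[2:3]) &&
                sc$value(mid) <= max(sc$control_values[2:3]))

  tc <- curve_from_controls(kind = "tmc")
  expect_equal(tc$value(0), 1)
  expect_true(all(tc$value(g) >= 0.75 - 1e-9 & tc$value(g) <= 2.77 + 1e-9))

  expect_error(curve_from_controls(3, kind = "tmc"), "at least 2")
})

test_that("ray marching finds the first ring hit and agrees with dense sampling", {
  ph <- ring_phantom(ring_radius = 10, tube_radius = 0.5)
  # radial in-plane ray: first hit 4 mm from the outer tube surface
  o <- c(10 + 4 + 0.5, 0, 0)
  expect_equal(ray_ring_distance(o, c(-1, 0, 0), ph), 4, tolerance = 1e-5)
  # vertical ray far from the ring: miss
  expect_true(is.na(ray_ring_distance(c(30, 0, 0), c(0, 0, 1), ph,
                                      t_max = 50)))
  # oblique rays vs dense-sampling oracle
  set.seed(41)
  for (i in 1:12) {
    a <- stats::runif(1, 0, 2 * pi)
    o <- c(16 * cos(a), 16 * sin(a), stats::runif(1, -1, 1))
    d <- c(-cos(a), -sin(a), 0) + stats::rnorm(3, sd = 0.05)
    d <- d / sqrt(sum(d^2))
    t_got <- ray_ring_distance(o, d, ph, t_max = 30)
    t_ref <- oracle_ray_ring(o, d, ph, t_max = 30)
    if (is.na(t_ref)) expect_true(is.na(t_got))
    else expect_equal(t_got, t_ref, tolerance = 1e-3)
  }
  expect_error(ring_phantom(ring_radius = 1, tube_radius = 2), "ring_radius")
})

test_that("undistorted acquisition places the echo at the reference distance", {
  ph <- ring_phantom()
  fr <- simulate_acquisition(ph, quiet_sim(8), calibration_map())
  expect_length(fr, 8L)
  for (k in seq_along(fr)) {
    f <- fr[[k]]
    expect_equal(f$true_distance, 4)
    expect_equal(f$true_azimuth, 2 * pi * (k - 1) / 8)
    d <- detect_target_depth(f)
    hit <- which(!is.na(d))
    expect_length(hit, 1L)        # thin-wire ring: one scanline insonified
    expect_equal(d[hit], 4, tolerance = f$depth_spacing)
    # pose sits at the nominal contact radius, zero pressure
    expect_equal(sqrt(sum(f$pose$position[1:2]^2)), 10.05 + 4,
                 tolerance = 1e-9)
    expect_equal(f$pressure$force, 0)
  }
})

test_that("surface and medium perturbations displace the echo by dt * c", {
  ph <- ring_phantom()
  model <- echo_model()
  sc <- curve_from_controls(kind = "surface")
  fr <- simulate_acquisition(ph, quiet_sim(8, surface_curve = sc),
                             calibration_map())
  # reference azimuth: unchanged; D = 7 control (azimuth pi): echo at 7 mm,
  # i.e. displaced by dt = 2 us worth of depth (3 mm)
  d0 <- detect_target_depth(fr[[1]])
  expect_equal(d0[!is.na(d0)], 4, tolerance = fr[[1]]$depth_spacing)
  d5 <- detect_target_depth(fr[[5]])
  expect_equal(fr[[5]]$true_distance, 7)
  expect_equal(d5[!is.na(d5)], 4 + 2 * model$mm_per_us,
               tolerance = fr[[5]]$depth_spacing)
  # squeezed control (D = 1.75, azimuth 5*pi/4): pressure reads the squeeze
  expect_equal(fr[[6]]$true_distance, 1.75)
  expect_equal(fr[[6]]$pressure$force, (4 - 1.75) / 0.5, tolerance = 1e-9)
  d6 <- detect_target_depth(fr[[6]])
  expect_equal(d6[!is.na(d6)], 1.75, tolerance = fr[[6]]$depth_spacing)

  tc <- curve_from_controls(kind = "tmc")
  cal <- calibration_map(tmc_curve = tc)
  fr <- simulate_acquisition(ph, quiet_sim(8, tmc_curve = tc), cal)
  # TMC = 2.77 control (azimuth 5*pi/4): slowest medium, longest delay
  d6 <- detect_target_depth(fr[[6]])
  expect_equal(tc$value(fr[[6]]$true_azimuth), 2.77, tolerance = 1e-12)
  expect_lt(abs(d6[!is.na(d6)] - (4 + 8.5 * model$mm_per_us)),
            fr[[6]]$depth_spacing)
  # every control azimuth shows the tabulated displacement
  for (k in seq_along(fr)) {
    dt <- tmc_echo_time(tc$value(fr[[k]]$true_azimuth), cal) - 2.7
    d <- detect_target_depth(fr[[k]])
    expect_lt(abs(d[!is.na(d)] - (4 + dt * model$mm_per_us)),
              fr[[k]]$depth_spacing)
  }
})

test_that("identical seeds reproduce the acquisition bit-exactly", {
  ph <- ring_phantom()
  cfg <- sim_config(delta_v = 8, seed = 99)   # noise at its defaults
  f1 <- simulate_acquisition(ph, cfg, calibration_map())
  f2 <- simulate_acquisition(ph, cfg, calibration_map())
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))
  f3 <- simulate_acquisition(ph, sim_config(delta_v = 8, seed = 100),
                             calibration_map())
  expect_false(identical(f1[[1]]$pose$position, f3[[1]]$pose$position))
  expect_error(sim_config(delta_v = 8), "seed")
  expect_error(sim_config(delta_v = 5, seed = 1), "even")
})
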
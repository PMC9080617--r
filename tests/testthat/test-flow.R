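geom <- build_geometry()

test_that("unbaffled field has the single-loop structure", {
  geom0 <- build_geometry(list(baffle_count = 0)) # unbaffled reactor
  f <- make_unbaffled_field(geom0, amplitude = 5000)
  # upflow on the aerated side (x > 0), downflow opposite
  expect_gt(f$velocity(70, 450)$vz, 0)
  expect_lt(f$velocity(-70, 450)$vz, 0)
  # |Vx| minimal at mid-height, larger near top and bottom
  expect_lt(abs(f$velocity(0, 450)$vx), abs(f$velocity(0, 100)$vx))
  expect_lt(abs(f$velocity(0, 450)$vx), abs(f$velocity(0, 800)$vx))
  # zero amplitude -> identically zero velocity
  f0 <- make_unbaffled_field(geom0, 0)
  v <- f0$velocity(runif(20, -79, 79), runif(20, 1, 899))
  expect_equal(v$vx, rep(0, 20))
  expect_equal(v$vz, rep(0, 20))
})

test_that("fields are divergence-free and respect the walls", {
  set.seed(42)
  h <- 0.1
  fb <- make_baffled_field(geom, 4000, 500)
  fu <- make_unbaffled_field(geom, 6000, shape = 0.1)
  # random fluid points with stencil clearance from baffles and walls
  x <- runif(3000, -79, 79)
  z <- runif(3000, 1, 899)
  keep <- point_in_fluid(geom, x, z)
  for (i in seq_len(nrow(geom$baffle_centers))) {
    cc <- geom$baffle_centers[i, ]
    keep <- keep & sqrt((x - cc[1])^2 + (z - cc[2])^2) > geom$baffle_radius + 2 * h
  }
  x <- x[keep][1:1000]; z <- z[keep][1:1000]
  for (f in list(fb, fu)) {
    div <- (f$velocity(x + h, z)$vx - f$velocity(x - h, z)$vx) / (2 * h) +
      (f$velocity(x, z + h)$vz - f$velocity(x, z - h)$vz) / (2 * h)
    v <- f$velocity(x, z)
    peak <- max(sqrt(v$vx^2 + v$vz^2))
    expect_lt(max(abs(div)), 1e-6 * peak)
    # no-penetration: normal velocity vanishes on sampled wall points
    zs <- seq(0.5, 899.5, length.out = 40)
    xs <- seq(-79.5, 79.5, length.out = 40)
    vn <- c(
      f$velocity(rep(-80, 40), zs)$vx, f$velocity(rep(80, 40), zs)$vx,
      f$velocity(xs, rep(0, 40))$vz, f$velocity(xs, rep(900, 40))$vz
    )
    expect_lt(max(abs(vn)), 1e-9)
  }
})

test_that("baffled field degenerates, zeroes solids and boosts mid-height transport", {
  # cell amplitude 0 equals the plain base-profile field
  fb0 <- make_baffled_field(geom, 3000, 0, shape = 0.05, channel = 0)
  fu <- make_unbaffled_field(geom, 3000, shape = 0.05)
  x <- runif(50, -79, 79); z <- runif(50, 1, 899)
  expect_equal(fb0$velocity(x, z), fu$velocity(x, z))
  # solid region: zero velocity at a baffle centre
  fb <- make_baffled_field(geom, 3000, 400)
  expect_equal(fb$velocity(0, 90), list(vx = 0, vz = 0))
  # adding cells raises |Vx| on the five standard lines (same base amplitude)
  with_cells <- mean(vapply(horizontal_lines(geom),
                            function(l) line_average(fb, l), numeric(1)))
  without <- mean(vapply(horizontal_lines(geom),
                         function(l) line_average(make_baffled_field(geom, 3000, 0), l),
                         numeric(1)))
  expect_gt(with_cells, without)
})

test_that("aeration_lookup returns exact, interpolated and flat values", {
  cal <- default_aeration_calibration()
  expect_equal(aeration_lookup(cal, 0.02, FALSE),
               c(vz_target = 10.2, vx_target = 0.52))
  expect_equal(aeration_lookup(cal, 0.02, TRUE),
               c(vz_target = 9.6, vx_target = 1.0))
  # linear interpolation at 0.03 vvm = midpoint of the 0.02 / 0.04 rows
  expect_equal(aeration_lookup(cal, 0.03, TRUE),
               c(vz_target = (9.6 + 10.4) / 2, vx_target = (1.0 + 1.3) / 2))
  # with-baffles vertical velocity saturates between 0.06 and 0.1 vvm
  expect_equal(aeration_lookup(cal, 0.08, TRUE)[["vz_target"]], 10.4)
  expect_error(aeration_lookup(cal, 0.15, TRUE), "outside")
  bad <- cal; bad$vz_target[bad$baffled & bad$rate == 0.1] <- 99
  expect_error(aeration_lookup(bad, 0.02, TRUE), "non-increasing")
})

test_that("calibrated fields are linear in their amplitudes and deterministic", {
  f1 <- calibrate_field(geom, 0.02, TRUE)
  f2 <- calibrate_field(geom, 0.02, TRUE)
  expect_identical(f1$amplitudes, f2$amplitudes)
  # doubling both amplitudes doubles both line averages
  d <- make_baffled_field(geom, 2 * f1$amplitudes$base, 2 * f1$amplitudes$cell)
  expect_equal(vertical_velocity(d, geom), 2 * vertical_velocity(f1, geom),
               tolerance = 1e-10)
  expect_equal(horizontal_velocity(d, geom), 2 * horizontal_velocity(f1, geom),
               tolerance = 1e-10)
})

test_that("baffles raise mid-height horizontal velocity at least 1.8-fold", {
  fb <- calibrate_field(geom, 0.02, TRUE)
  fu <- calibrate_field(geom, 0.02, FALSE)
  mid <- sampling_line(c(-80, 375), c(80, 375), "vx")
  expect_gte(line_average(fb, mid), 1.8 * line_average(fu, mid))
})

test_that("turbulence proxy follows k = 1.5 (I |V|)^2", {
  f <- make_unbaffled_field(geom, 5000)
  f0 <- turbulence_field(f, intensity = 0, eddy_time = 0.5)
  x <- runif(30, -79, 79); z <- runif(30, 1, 899)
  expect_equal(f0$k(x, z), rep(0, 30))
  ft <- turbulence_field(f, intensity = 0.2, eddy_time = 0.7)
  v <- ft$velocity(x, z)
  expect_equal(ft$k(x, z), 1.5 * (0.2 * sqrt(v$vx^2 + v$vz^2))^2)
  expect_true(all(ft$k(x, z) >= 0))
  expect_equal(ft$eddy_time, 0.7)
  expect_error(turbulence_field(f, intensity = 1.2), "intensity")
})

test_that("field_to_grid exports the expected schema", {
  f <- calibrate_field(geom, 0.02, FALSE)
  g <- field_to_grid(f, pitch = 40)
  expect_named(g, c("x_mm", "z_mm", "vx_mm_s", "vz_mm_s", "k_mm2_s2"))
  expect_equal(nrow(g), length(seq(-80, 80, 40)) * length(seq(0, 900, 40)))
  tmp <- withr::local_tempfile(fileext = ".csv")
  field_to_grid(f, pitch = 40, file = tmp)
  expect_equal(utils::read.csv(tmp), g)
})
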
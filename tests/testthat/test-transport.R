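geom <- build_geometry()

test_that("particle_spec computes the Stokes relaxation time in SI", {
  sp <- particle_spec()
  expect_equal(sp$tau_s, 1000 * (5e-6)^2 / (18 * 1e-3))
  sp2 <- particle_spec(diameter_um = 10, fluid_viscosity = 2e-3)
  expect_equal(sp2$tau_s, 1000 * (10e-6)^2 / (18 * 2e-3))
  expect_error(particle_spec(diameter_um = 0))
})

test_that("injection splits ports evenly, jitters in-fluid and is reproducible", {
  f <- calibrate_field(geom, 0.02, FALSE)
  st <- inject_particles(geom, f, 1000, seed = 1)
  expect_equal(as.integer(table(st$port)), c(500L, 500L))
  expect_true(all(point_in_fluid(geom, st$x, st$z)))
  expect_true(all(sqrt((st$x - geom$port_positions[st$port, 1])^2 +
                       (st$z - geom$port_positions[st$port, 2])^2) <= 2))
  # odd n: extra particle at the first port
  expect_equal(as.integer(table(inject_particles(geom, f, 7, seed = 1)$port)),
               c(4L, 3L))
  # zero jitter -> exactly the port coordinates, velocity = local fluid velocity
  st0 <- inject_particles(geom, f, 2, seed = 1, jitter_radius = 0)
  expect_equal(st0$x, geom$port_positions[, 1])
  expect_equal(st0$z, geom$port_positions[, 2])
  v <- f$velocity(st0$x, st0$z)
  expect_equal(st0$vx, v$vx)
  expect_equal(st0$vz, v$vz)
  expect_identical(inject_particles(geom, f, 100, seed = 7),
                   inject_particles(geom, f, 100, seed = 7))
  # port inside a baffle is a configuration error
  gbad <- build_geometry(list(ports = rbind(c(0, 90), c(-60, 700))))
  expect_error(inject_particles(gbad, f, 10, seed = 1), "port")
})

test_that("DRW samples have the prescribed moments", {
  set.seed(99)
  expect_equal(drw_sample(0, eddy_time = 0.5, n = 10)$ux, rep(0, 10))
  k <- 6 # sd per component = sqrt(2k/3) = 2
  d <- drw_sample(k, eddy_time = 0.5, n = 1e5)
  se_mean <- 2 / sqrt(1e5)
  expect_lt(abs(mean(d$ux)), 3 * se_mean)
  expect_lt(abs(mean(d$uz)), 3 * se_mean)
  se_var <- 4 * sqrt(2 / (1e5 - 1))
  expect_lt(abs(var(d$ux) - 2 * k / 3), 3 * se_var)
  expect_lt(abs(var(d$uz) - 2 * k / 3), 3 * se_var)
  expect_lt(abs(mean(d$lifetime) - 0.5), 3 * 0.5 / sqrt(1e5))
  # components independent
  expect_lt(abs(cor(d$ux, d$uz)), 3 / sqrt(1e5))
})

test_that("advance is exact for an equilibrated tracer in uniform flow", {
  U <- c(12, -7)
  f <- custom_flow_field(function(x, z) {
    n <- max(length(x), length(z))
    list(vx = rep(U[1], n), vz = rep(U[2], n))
  }, geom)
  sp <- particle_spec()
  x <- 10; z <- 400; vx <- U[1]; vz <- U[2]
  for (i in 1:50) {
    s <- advance_particles(f, sp, x, z, vx, vz, dt = 0.004)
    x <- s$x; z <- s$z; vx <- s$vx; vz <- s$vz
  }
  expect_equal(x, 10 + 50 * 0.004 * U[1], tolerance = 1e-12)
  expect_equal(z, 400 + 50 * 0.004 * U[2], tolerance = 1e-12)
  # zero field, zero fluctuation: statics
  f0 <- custom_flow_field(function(x, z) {
    n <- max(length(x), length(z))
    list(vx = rep(0, n), vz = rep(0, n))
  }, geom)
  s <- advance_particles(f0, sp, 5, 500, 0, 0, dt = 0.004)
  expect_equal(c(s$x, s$z), c(5, 500))
})

test_that("tracer orbits solid-body rotation with the analytic period", {
  omega <- 1 # rad/s about (0, 450)
  f <- custom_flow_field(function(x, z) {
    list(vx = -omega * (z - 450), vz = omega * (x - 0))
  }, geom, psi = function(x, z) omega * ((x - 0)^2 + (z - 450)^2) / 2)
  sp <- particle_spec() # tau ~ 1.4 us -> tracer limit
  dt <- 0.004
  nstep <- round(2 * pi / omega / dt)
  x <- 30; z <- 450; vx <- 0; vz <- omega * 30
  for (i in seq_len(nstep)) {
    s <- advance_particles(f, sp, x, z, vx, vz, dt)
    x <- s$x; z <- s$z; vx <- s$vx; vz <- s$vz
  }
  # after one analytic period the particle is back within 0.1% of the orbit
  err <- atan2(z - 450, x) - (omega * nstep * dt - 2 * pi)
  err <- (err + pi) %% (2 * pi) - pi
  expect_lt(abs(err), 2 * pi * 0.001)
  expect_equal(sqrt(x^2 + (z - 450)^2), 30, tolerance = 1e-3)
})

test_that("reflect_boundary mirrors walls and baffle circles specularly", {
  # wall crossing: mirrored about x = -80, normal velocity flipped
  r <- reflect_boundary(geom, -79, 450, -81, 450, -10, 5)
  expect_equal(c(r$x, r$z), c(-79, 450))
  expect_equal(c(r$vx, r$vz), c(10, 5))
  # vertical entry into the lowest baffle (boundary at z = 125 above centre 90)
  r <- reflect_boundary(geom, 0, 130, 0, 120, 0, -50)
  expect_equal(c(r$x, r$z), c(0, 130))
  expect_equal(c(r$vx, r$vz), c(0, 50))
  # a step fully inside the fluid is untouched
  r <- reflect_boundary(geom, 10, 400, 12, 402, 20, 20)
  expect_equal(c(r$x, r$z, r$vx, r$vz), c(12, 402, 20, 20))
})

test_that("random steps into a baffle end outside, on the incoming side", {
  set.seed(11)
  cc <- geom$baffle_centers[3, ] # (0, 330)
  R <- geom$baffle_radius
  for (i in 1:200) {
    th <- runif(1, 0, 2 * pi)
    old <- cc + (R + runif(1, 0.5, 4)) * c(cos(th), sin(th))
    if (!point_in_fluid(geom, old[1], old[2])) next
    step <- (cc - old) * runif(1, 0.8, 1.3) + rnorm(2, 0, 1)
    new <- old + step
    r <- reflect_boundary(geom, old[1], old[2], new[1], new[2], step[1], step[2])
    expect_true(point_in_fluid(geom, r$x, r$z))
    # incoming side: reflected point stays in the half-plane of the old point
    expect_gte((r$x - cc[1]) * (old[1] - cc[1]) + (r$z - cc[2]) * (old[2] - cc[2]),
               -1e-9)
  }
})

test_that("track records the full grid, stays in fluid and is bit-reproducible", {
  f <- calibrate_field(geom, 0.02, TRUE)
  tr <- track(f, n = 8, t_max = 2, seed = 3)
  expect_equal(ncol(tr$x), 21L) # 2 / 0.1 + 1
  expect_equal(tr$record_times, seq(0, 2, by = 0.1))
  expect_true(all(point_in_fluid(geom, as.vector(tr$x), as.vector(tr$z))))
  tr2 <- track(f, n = 8, t_max = 2, seed = 3)
  expect_identical(tr, tr2)
  expect_error(track(f, n = 4, dt = 0.03, record_dt = 0.1, t_max = 1, seed = 1),
               "integer multiple")
})

test_that("without dispersion tracers conserve the streamfunction and circulate", {
  geom0 <- build_geometry(list(baffle_count = 0)) # unbaffled reactor
  f <- calibrate_field(geom0, 0.02, FALSE)
  tr <- track(f, n = 10, t_max = 60, seed = 5, turbulence = FALSE)
  psi0 <- f$psi(tr$x[, 1], tr$z[, 1])
  psi1 <- f$psi(tr$x[, ncol(tr$x)], tr$z[, ncol(tr$z)])
  g <- field_to_grid(f, pitch = 5)
  psi_max <- max(abs(f$psi(g$x_mm, g$z_mm)))
  expect_lt(max(abs(psi1 - psi0)), 1e-3 * psi_max)
  # single-loop topology: every particle's x changes sign within 60 s
  expect_true(all(apply(tr$x, 1, function(x) min(x) < 0 && max(x) > 0)))
})

test_that("trajectory CSV round-trips with metadata", {
  f <- calibrate_field(geom, 0.02, TRUE)
  tr <- track(f, n = 4, t_max = 1, seed = 9)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(tr, tmp)
  expect_true(any(startsWith(readLines(tmp, 3), "#")))
  back <- read_trajectories(tmp)
  expect_equal(back$x, tr$x, ignore_attr = TRUE)
  expect_equal(back$z, tr$z, ignore_attr = TRUE)
  expect_equal(back$seed, tr$seed)
  expect_equal(back$regime, tr$regime)
  expect_equal(back$aeration_vvm, tr$aeration_vvm)
})
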
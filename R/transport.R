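#' Particle specification for algal-cell tracers
#'
#' Algal cells are modelled as 5 micron spheres with the density of the medium,
#' so the Stokes relaxation time `tau_p = rho_p d^2 / (18 mu)` is about 1.4
#' microseconds and the particles are effectively tracers; the drag and
#' pressure-gradient force terms are nevertheless carried in the integrator for
#' generality.
#'
#' @param diameter_um Particle diameter in micrometres (default 5).
#' @param density Particle density in kg/m^3 (default 1000).
#' @param fluid_viscosity Dynamic viscosity of the medium in Pa s (default 1e-3).
#' @param fluid_density Fluid density in kg/m^3 (default 1000).
#' @return A `particle_spec` object with the relaxation time `tau_s` (seconds).
#' @export
particle_spec <- function(diameter_um = 5, density = 1000,
                          fluid_viscosity = 1e-3, fluid_density = 1000) {
  stopifnot(diameter_um > 0, density > 0, fluid_viscosity > 0, fluid_density > 0)
  d <- diameter_um * 1e-6
  structure(
    list(
      diameter_um = diameter_um, density = density,
      fluid_viscosity = fluid_viscosity, fluid_density = fluid_density,
      tau_s = density * d^2 / (18 * fluid_viscosity)
    ),
    class = "particle_spec"
  )
}

#' Inject particles at the entrance ports
#'
#' Splits `n` particles evenly across the two ports (any odd remainder goes to
#' the first port), jitters each initial position uniformly within
#' `jitter_radius` of its port (rejecting non-fluid points), and initialises
#' the particle velocity to the local fluid velocity.
#'
#' @param geom A [build_geometry()] object whose ports must lie in the fluid.
#' @param field A `flow_field` supplying initial velocities.
#' @param n Number of particles (>= 1).
#' @param seed Optional integer seed; `NULL` continues the current RNG stream.
#' @param jitter_radius Jitter disc radius in mm (default 2; 0 places
#'   particles exactly at the ports).
#' @return Data frame with columns `particle_id`, `port`, `x`, `z`, `vx`, `vz`.
#' @export
inject_particles <- function(geom, field, n, seed = NULL, jitter_radius = 2) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  ports <- geom$port_positions
  if (!all(point_in_fluid(geom, ports[, 1], ports[, 2]))) {
    stop("injection port lies outside the fluid domain")
  }
  n1 <- ceiling(n / 2)
  port_id <- rep(c(1L, 2L), c(n1, n - n1))
  x <- ports[port_id, 1]
  z <- ports[port_id, 2]
  if (jitter_radius > 0) {
    todo <- rep(TRUE, n)
    while (any(todo)) {
      m <- sum(todo)
      r <- jitter_radius * sqrt(stats::runif(m))
      th <- stats::runif(m, 0, 2 * pi)
      xx <- ports[port_id[todo], 1] + r * cos(th)
      zz <- ports[port_id[todo], 2] + r * sin(th)
      ok <- point_in_fluid(geom, xx, zz)
      idx <- which(todo)[ok]
      x[idx] <- xx[ok]
      z[idx] <- zz[ok]
      todo[idx] <- FALSE
    }
  }
  v <- field$velocity(x, z)
  data.frame(particle_id = seq_len(n), port = port_id, x = x, z = z,
             vx = v$vx, vz = v$vz)
}

#' Discrete-random-walk eddy samples
#'
#' Draws per-eddy Gaussian velocity fluctuations with standard deviation
#' `sqrt(2 k / 3)` per component (isotropic turbulence) and exponentially
#' distributed eddy lifetimes with mean `eddy_time`. Within the tracking loop a
#' fluctuation is held constant until its eddy expires and is then redrawn.
#'
#' @param k Turbulent kinetic energy proxy, mm^2/s^2 (scalar or length-`n`).
#' @param eddy_time Mean eddy lifetime, s.
#' @param n Number of draws.
#' @return Data frame with columns `ux`, `uz` (mm/s) and `lifetime` (s).
#' @export
drw_sample <- function(k, eddy_time, n = 1L) {
  stopifnot(all(k >= 0), eddy_time > 0)
  sd <- sqrt(2 * rep_len(k, n) / 3)
  data.frame(
    ux = stats::rnorm(n, 0, sd),
    uz = stats::rnorm(n, 0, sd),
    lifetime = stats::rexp(n, rate = 1 / eddy_time)
  )
}

# Material acceleration (V . grad) V of the steady fluid field, by a
# directional central difference along the local flow direction.
fluid_accel <- function(field, x, z, eps = 0.05) {
  v <- field$velocity(x, z)
  sp <- sqrt(v$vx^2 + v$vz^2)
  dx <- ifelse(sp > 0, v$vx / pmax(sp, 1e-300), 0)
  dz <- ifelse(sp > 0, v$vz / pmax(sp, 1e-300), 0)
  vp <- field$velocity(x + eps * dx, z + eps * dz)
  vm <- field$velocity(x - eps * dx, z - eps * dz)
  list(ax = (vp$vx - vm$vx) * sp / (2 * eps), az = (vp$vz - vm$vz) * sp / (2 * eps))
}

#' Advance particles one time step
#'
#' Integrates `dv_p/dt = (u_f + u' - v_p)/tau_p + (rho_f/rho_p) DV/Dt` with an
#' integrator that is exact for the linear drag relaxation (exponential
#' update), so it stays stable at time steps thousands of times larger than
#' `tau_p`. The effective carrier velocity is evaluated with a Heun
#' (predictor-corrector) stage so that in the tracer limit positions follow
#' streamlines to second order. No boundary handling is done here; see
#' [reflect_boundary()].
#'
#' @param field A `flow_field`.
#' @param spec A [particle_spec()].
#' @param x,z Positions (mm).
#' @param vx,vz Particle velocities (mm/s).
#' @param dt Time step (s, > 0).
#' @param uprime_x,uprime_z Held DRW velocity fluctuations (mm/s, default 0).
#' @param pressure_gradient Include the pressure-gradient (fluid acceleration)
#'   term (default TRUE).
#' @return List with updated `x`, `z`, `vx`, `vz`.
#' @export
advance_particles <- function(field, spec, x, z, vx, vz, dt,
                              uprime_x = 0, uprime_z = 0,
                              pressure_gradient = TRUE) {
  stopifnot(dt > 0)
  tau <- spec$tau_s
  beta <- spec$fluid_density / spec$density
  pg_x <- 0; pg_z <- 0
  if (pressure_gradient) {
    a <- fluid_accel(field, x, z)
    if (any(!is.finite(a$ax)) || any(!is.finite(a$az))) {
      stop("non-finite fluid acceleration encountered")
    }
    pg_x <- tau * beta * a$ax
    pg_z <- tau * beta * a$az
  }
  v1 <- field$velocity(x, z)
  u1x <- v1$vx + uprime_x + pg_x
  u1z <- v1$vz + uprime_z + pg_z
  # predictor position, then corrected carrier velocity
  v2 <- field$velocity(x + dt * u1x, z + dt * u1z)
  ux <- (u1x + v2$vx + uprime_x + pg_x) / 2
  uz <- (u1z + v2$vz + uprime_z + pg_z) / 2
  if (any(!is.finite(ux)) || any(!is.finite(uz))) {
    bad <- which(!is.finite(ux) | !is.finite(uz))[1]
    stop(sprintf("non-finite field value near (%.2f, %.2f) mm", x[bad], z[bad]))
  }
  e <- exp(-dt / tau)
  list(
    x = x + ux * dt + tau * (vx - ux) * (1 - e),
    z = z + uz * dt + tau * (vz - uz) * (1 - e),
    vx = ux + (vx - ux) * e,
    vz = uz + (vz - uz) * e
  )
}

#' Specular reflection at walls and baffles
#'
#' If the step from `(old_x, old_z)` to `(new_x, new_z)` leaves the rectangle
#' or enters a baffle circle, the end position is reflected specularly about
#' the crossed surface and the velocity component normal to that surface is
#' negated, repeatedly up to `max_reflect` times; a particle still outside the
#' fluid after that is returned to its old position.
#'
#' @param geom A [build_geometry()] object.
#' @param old_x,old_z Previous positions (must be in the fluid).
#' @param new_x,new_z Proposed positions.
#' @param vx,vz Velocities (mm/s).
#' @param max_reflect Reflection cap (default 10).
#' @return List with `x`, `z`, `vx`, `vz`, all positions in the fluid.
#' @export
reflect_boundary <- function(geom, old_x, old_z, new_x, new_z, vx, vz,
                             max_reflect = 10L) {
  xmin <- geom$x_extent[1]; xmax <- geom$x_extent[2]
  zmin <- geom$z_extent[1]; zmax <- geom$z_extent[2]
  r <- geom$baffle_radius
  cc <- geom$baffle_centers

  for (iter in seq_len(max_reflect)) {
    bad <- !point_in_fluid(geom, new_x, new_z)
    if (!any(bad)) break

    # rectangle walls: mirror the coordinate, flip the normal velocity
    m <- new_x <= xmin
    new_x[m] <- 2 * xmin - new_x[m]; vx[m] <- -vx[m]
    m <- new_x >= xmax
    new_x[m] <- 2 * xmax - new_x[m]; vx[m] <- -vx[m]
    m <- new_z <= zmin
    new_z[m] <- 2 * zmin - new_z[m]; vz[m] <- -vz[m]
    m <- new_z >= zmax
    new_z[m] <- 2 * zmax - new_z[m]; vz[m] <- -vz[m]

    # baffle circles: reflect about the tangent at the entry point
    for (i in seq_len(nrow(cc))) {
      cx <- cc[i, 1]; cz <- cc[i, 2]
      inside <- (new_x - cx)^2 + (new_z - cz)^2 <= r^2
      if (!any(inside)) next
      idx <- which(inside)
      ox <- old_x[idx]; oz <- old_z[idx]
      px <- new_x[idx]; pz <- new_z[idx]
      dx <- px - ox; dz <- pz - oz
      fx <- ox - cx; fz <- oz - cz
      a <- dx^2 + dz^2
      b <- 2 * (fx * dx + fz * dz)
      cq <- fx^2 + fz^2 - r^2
      disc <- b^2 - 4 * a * cq
      t <- ifelse(disc >= 0 & a > 0, (-b - sqrt(pmax(disc, 0))) / (2 * a), NA_real_)
      hit <- !is.na(t) & t >= 0 & t <= 1
      # entry point found: specular reflection about the tangent plane there
      hx <- ox + t * dx; hz <- oz + t * dz
      nx <- (hx - cx) / r; nz <- (hz - cz) / r
      dot <- (px - hx) * nx + (pz - hz) * nz
      rx <- px - 2 * dot * nx
      rz <- pz - 2 * dot * nz
      vdot <- vx[idx] * nx + vz[idx] * nz
      rvx <- vx[idx] - 2 * vdot * nx
      rvz <- vz[idx] - 2 * vdot * nz
      # no geometric entry point (e.g. old position already too close):
      # push radially out of the circle and flip the radial velocity
      pr <- sqrt((px - cx)^2 + (pz - cz)^2)
      pr <- pmax(pr, 1e-12)
      qx <- cx + (px - cx) * (2 * r - pr) / pr
      qz <- cz + (pz - cz) * (2 * r - pr) / pr
      nrx <- (px - cx) / pr; nrz <- (pz - cz) / pr
      vdr <- vx[idx] * nrx + vz[idx] * nrz
      new_x[idx] <- ifelse(hit, rx, qx)
      new_z[idx] <- ifelse(hit, rz, qz)
      vx[idx] <- ifelse(hit, rvx, vx[idx] - 2 * vdr * nrx)
      vz[idx] <- ifelse(hit, rvz, vz[idx] - 2 * vdr * nrz)
    }
  }
  stuck <- !point_in_fluid(geom, new_x, new_z)
  if (any(stuck)) {
    new_x[stuck] <- old_x[stuck]
    new_z[stuck] <- old_z[stuck]
  }
  list(x = new_x, z = new_z, vx = vx, vz = vz)
}

#' Track particles through a flow field
#'
#' Full Lagrangian simulation: particles are injected at the two ports and
#' advanced with [advance_particles()] under discrete-random-walk dispersion
#' and specular boundary reflection; positions are recorded on a uniform grid
#' of record times. Deterministic given `seed`.
#'
#' @param field A (calibrated) `flow_field`.
#' @param geom Geometry (defaults to the field's).
#' @param spec A [particle_spec()].
#' @param n Number of particles (default 1000).
#' @param dt Integration step, s (default 0.004).
#' @param record_dt Recording interval, s (default 0.1); must be an integer
#'   multiple of `dt`.
#' @param t_max Tracking horizon, s (default 60).
#' @param seed Master seed (default 1).
#' @param jitter_radius Injection jitter radius, mm.
#' @param turbulence Apply DRW dispersion (default TRUE; FALSE forces `k = 0`).
#' @param pressure_gradient Passed to [advance_particles()].
#' @return A `trajectory_set`: list with `record_times` (s), `x` and `z`
#'   (n x n_records matrices, mm), `particle_ids`, `seed`, `regime`,
#'   `aeration_vvm`.
#' @export
track <- function(field, geom = field$geom, spec = particle_spec(), n = 1000L,
                  dt = 0.004, record_dt = 0.1, t_max = 60, seed = 1L,
                  jitter_radius = 2, turbulence = TRUE,
                  pressure_gradient = TRUE) {
  steps_per_rec <- record_dt / dt
  if (abs(steps_per_rec - round(steps_per_rec)) > 1e-9) {
    stop("record_dt must be an integer multiple of dt")
  }
  steps_per_rec <- as.integer(round(steps_per_rec))
  n_rec <- as.integer(floor(t_max / record_dt + 1e-9)) + 1L

  set.seed(seed)
  st <- inject_particles(geom, field, n, seed = NULL, jitter_radius = jitter_radius)
  x <- st$x; z <- st$z; vx <- st$vx; vz <- st$vz

  X <- matrix(NA_real_, n, n_rec)
  Z <- matrix(NA_real_, n, n_rec)
  X[, 1L] <- x; Z[, 1L] <- z

  use_drw <- turbulence && field$turbulence_intensity > 0
  upx <- numeric(n); upz <- numeric(n)
  clock <- numeric(n)  # expired at t = 0 -> drawn on first step

  kfun <- field$k
  eddy <- field$eddy_time
  for (rec in seq_len(n_rec - 1L)) {
    for (s in seq_len(steps_per_rec)) {
      if (use_drw) {
        expired <- clock <= 0
        if (any(expired)) {
          m <- sum(expired)
          d <- drw_sample(kfun(x[expired], z[expired]), eddy, m)
          upx[expired] <- d$ux
          upz[expired] <- d$uz
          clock[expired] <- d$lifetime
        }
        clock <- clock - dt
      }
      adv <- advance_particles(field, spec, x, z, vx, vz, dt,
                               uprime_x = upx, uprime_z = upz,
                               pressure_gradient = pressure_gradient)
      ref <- reflect_boundary(geom, x, z, adv$x, adv$z, adv$vx, adv$vz)
      x <- ref$x; z <- ref$z; vx <- ref$vx; vz <- ref$vz
    }
    X[, rec + 1L] <- x
    Z[, rec + 1L] <- z
  }

  structure(
    list(
      record_times = record_dt * (seq_len(n_rec) - 1L),
      x = X, z = Z, particle_ids = seq_len(n), seed = seed,
      regime = field$regime, aeration_vvm = field$aeration_vvm
    ),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "<trajectory_set> %d particles x %d records (every %.3g s), regime=%s, seed=%s\n",
    nrow(x$x), ncol(x$x), diff(x$record_times[1:2]), x$regime, format(x$seed)
  ))
  invisible(x)
}

#' Write / read trajectory CSV
#'
#' Long-format CSV with columns `t_s`, `particle_id`, `x_mm`, `z_mm`, preceded
#' by `#`-prefixed metadata lines carrying seed, regime and aeration rate.
#'
#' @param traj A `trajectory_set`.
#' @param file Path.
#' @return `read_trajectories()` returns a `trajectory_set`.
#' @export
write_trajectories <- function(traj, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# seed: %s", format(traj$seed)),
    sprintf("# regime: %s", traj$regime),
    sprintf("# aeration_vvm: %s", format(traj$aeration_vvm))
  ), con)
  n <- nrow(traj$x)
  long <- data.frame(
    t_s = rep(traj$record_times, each = n),
    particle_id = rep(traj$particle_ids, times = length(traj$record_times)),
    x_mm = as.vector(traj$x),
    z_mm = as.vector(traj$z)
  )
  utils::write.csv(long, con, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(file) {
  hdr <- readLines(file, n = 10L)
  meta <- hdr[startsWith(hdr, "#")]
  getm <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (length(ln)) trimws(sub(paste0("^# ", key, ":"), "", ln[1])) else NA_character_
  }
  df <- utils::read.csv(file, comment.char = "#")
  times <- sort(unique(df$t_s))
  ids <- sort(unique(df$particle_id))
  df <- df[order(df$t_s, df$particle_id), ]
  n <- length(ids)
  structure(
    list(
      record_times = times,
      x = matrix(df$x_mm, n, length(times)),
      z = matrix(df$z_mm, n, length(times)),
      particle_ids = ids,
      seed = suppressWarnings(as.integer(getm("seed"))),
      regime = getm("regime"),
      aeration_vvm = suppressWarnings(as.numeric(getm("aeration_vvm")))
    ),
    class = "trajectory_set"
  )
}
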
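#' @title Divergence-free synthetic flow fields
#' @description Streamfunction-based emulators of the liquid circulation in a
#'   flat-panel airlift photobioreactor. Two regimes are available: a single
#'   large circulation loop (no baffles) and the same loop with a superposed
#'   stack of counter-rotating baffle-scale vortex cells. Velocities are the
#'   analytic curl of the streamfunction, so the fields are divergence-free by
#'   construction and the normal velocity vanishes on the rectangular walls.
#' @name synthetic-flow
NULL

new_flow_field <- function(psi, velocity, geom, regime, aeration_vvm = NA_real_,
                           amplitudes = list(), turbulence_intensity = 0,
                           eddy_time = 0.5) {
  f <- structure(
    list(
      psi = psi, velocity = velocity, geom = geom, regime = regime,
      aeration_vvm = aeration_vvm, amplitudes = amplitudes,
      turbulence_intensity = turbulence_intensity, eddy_time = eddy_time
    ),
    class = "flow_field"
  )
  f$k <- make_k_fun(f)
  f
}

make_k_fun <- function(field) {
  intensity <- field$turbulence_intensity
  vel <- field$velocity
  function(x, z) {
    v <- vel(x, z)
    1.5 * (intensity * sqrt(v$vx^2 + v$vz^2))^2
  }
}

# Analytic streamfunction pieces. Vertical profile
# P(z) = sin(bz) + shape * sin(3bz): the third harmonic flattens the interior
# (plug-like vertical flow) and thereby lowers the |Vx|/|Vz| line-average
# ratio. Horizontal profile S(x): half-sine for the open panel (`channel = 0`,
# one smooth loop filling the width) or the plateau 1 - ((x-xc)/hw)^(2m) for
# `channel = m > 0`, which concentrates the vertical flow into wall jets in
# the side gaps around a central baffle column and leaves a slow interior.
base_parts <- function(geom, shape, channel = 0) {
  a <- pi / diff(geom$x_extent)
  b <- pi / diff(geom$z_extent)
  xmin <- geom$x_extent[1]
  zmin <- geom$z_extent[1]
  if (channel > 0) {
    hw <- diff(geom$x_extent) / 2
    xc <- mean(geom$x_extent)
    m <- channel
    S <- function(x) 1 - ((x - xc) / hw)^(2 * m)
    Sp <- function(x) -(2 * m / hw) * ((x - xc) / hw)^(2 * m - 1)
  } else {
    S <- function(x) sin(a * (x - xmin))
    Sp <- function(x) a * cos(a * (x - xmin))
  }
  list(
    S = S, Sp = Sp,
    P = function(z) sin(b * (z - zmin)) + shape * sin(3 * b * (z - zmin)),
    Pp = function(z) b * cos(b * (z - zmin)) + 3 * shape * b * cos(3 * b * (z - zmin)),
    W = function(z) sin(b * (z - zmin)),
    Wp = function(z) b * cos(b * (z - zmin))
  )
}

# Zero the velocity inside baffle circles and outside the rectangle (solid /
# out-of-domain regions).
mask_solid <- function(geom, x, z, vx, vz) {
  solid <- !point_in_fluid(geom, x, z)
  vx[solid] <- 0
  vz[solid] <- 0
  list(vx = unname(vx), vz = unname(vz))
}

#' Single-loop circulation field (no baffles)
#'
#' Builds the unbaffled regime: one circulation cell filling the panel, upflow
#' on the aerated side (x > 0), downflow on the other, horizontal flow
#' strongest near the top and bottom. The streamfunction is
#' `psi = -A * sin(pi*(x - xmin)/Lx) * P(z)` with
#' `P(z) = sin(pi*z/Lz) + shape * sin(3*pi*z/Lz)`.
#'
#' @param geom A [build_geometry()] object (its baffles, if any, are ignored
#'   except that velocity is zeroed inside them).
#' @param amplitude Streamfunction amplitude `A` in mm^2/s (>= 0).
#' @param shape Third-harmonic coefficient of the vertical profile, default 0.
#'   Values in roughly \[0, 0.3\] flatten the interior vertical flow; used by
#'   [calibrate_field()] to match the printed horizontal/vertical velocity
#'   ratio.
#' @param channel Horizontal base-profile selector: 0 (default) for the
#'   half-sine open-panel loop, or a positive integer `m` for the plateau
#'   profile with wall jets (see [make_baffled_field()]).
#' @return A `flow_field` object with `$psi(x, z)`, `$velocity(x, z)` and
#'   `$k(x, z)` closures (mm, mm/s, mm^2/s^2).
#' @export
make_unbaffled_field <- function(geom, amplitude, shape = 0, channel = 0) {
  stopifnot(amplitude >= 0)
  p <- base_parts(geom, shape, channel)
  psi <- function(x, z) -amplitude * p$S(x) * p$P(z)
  velocity <- function(x, z) {
    vx <- amplitude * p$S(x) * p$Pp(z)
    vz <- -amplitude * p$Sp(x) * p$P(z)
    mask_solid(geom, x, z, vx, vz)
  }
  new_flow_field(psi, velocity, geom, "unbaffled",
                 amplitudes = list(base = amplitude, cell = 0, shape = shape,
                                   channel = channel))
}

#' Channelled circulation plus baffle-scale vortex cells
#'
#' Builds the baffled regime. The central baffle column blocks the middle of
#' the panel and channels the circulation into the open side gaps, so the base
#' loop uses a plateau horizontal profile (`channel = 2` by default) whose
#' vertical flow is concentrated in wall jets; on top of it sits a stack of
#' counter-rotating vortex cells whose vertical wavelength equals the baffle
#' spacing, phased on the baffle stack so horizontal transport is enhanced
#' between baffles. Velocity inside a baffle circle is defined as zero (solid
#' region); trajectories are kept out of the circles by specular reflection in
#' the transport module.
#'
#' With `cell_amplitude = 0` the field degenerates to
#' `make_unbaffled_field(geom, base_amplitude, shape, channel)` (same base
#' profile, no cells).
#'
#' @inheritParams make_unbaffled_field
#' @param base_amplitude Amplitude of the base circulation (mm^2/s, >= 0).
#' @param cell_amplitude Amplitude of the vortex-cell stack (mm^2/s, >= 0).
#' @param channel Plateau exponent of the base profile (default 2: the jet
#'   fills the side gap left open by the 70 mm baffles in the 160 mm panel).
#' @return A `flow_field` object.
#' @export
make_baffled_field <- function(geom, base_amplitude, cell_amplitude, shape = 0,
                               channel = 2) {
  stopifnot(base_amplitude >= 0, cell_amplitude >= 0)
  p <- base_parts(geom, shape, channel)
  if (nrow(geom$baffle_centers) >= 2L) {
    spacing <- unname(geom$baffle_centers[2, 2] - geom$baffle_centers[1, 2])
    z0 <- unname(geom$baffle_centers[1, 2])
  } else {
    spacing <- 120
    z0 <- 90
  }
  wc <- 2 * pi / spacing
  cfun <- function(z) sin(wc * (z - z0))
  cpfun <- function(z) wc * cos(wc * (z - z0))
  A <- base_amplitude
  B <- cell_amplitude
  psi <- function(x, z) -A * p$S(x) * p$P(z) - B * p$S(x) * p$W(z) * cfun(z)
  velocity <- function(x, z) {
    vx <- A * p$S(x) * p$Pp(z) + B * p$S(x) * (p$Wp(z) * cfun(z) + p$W(z) * cpfun(z))
    vz <- -A * p$Sp(x) * p$P(z) - B * p$Sp(x) * p$W(z) * cfun(z)
    mask_solid(geom, x, z, vx, vz)
  }
  new_flow_field(psi, velocity, geom, "baffled",
                 amplitudes = list(base = A, cell = B, shape = shape,
                                   channel = channel))
}

#' Build a flow field from user-supplied closures
#'
#' Low-level constructor for analytic test fields (uniform flow, solid-body
#' rotation, ...). The `velocity` closure must take vectors `(x, z)` in mm and
#' return `list(vx, vz)` in mm/s; `psi` is optional and only needed for
#' streamline diagnostics.
#'
#' @param velocity Function `(x, z) -> list(vx, vz)`.
#' @param geom A [build_geometry()] object.
#' @param psi Optional streamfunction closure `(x, z) -> mm^2/s`.
#' @param regime Label, default `"custom"`.
#' @return A `flow_field`.
#' @export
custom_flow_field <- function(velocity, geom, psi = NULL, regime = "custom") {
  if (is.null(psi)) psi <- function(x, z) rep(NA_real_, max(length(x), length(z)))
  new_flow_field(psi, velocity, geom, regime)
}

#' Attach a turbulence proxy to a flow field
#'
#' The turbulent kinetic energy proxy is `k(x, z) = 1.5 * (intensity * |V|)^2`
#' (the isotropic-turbulence relation for a given turbulence intensity), and
#' `eddy_time` is the mean eddy lifetime used by the discrete-random-walk
#' dispersion sampler.
#'
#' @param field A `flow_field`.
#' @param intensity Turbulence intensity as a fraction of the local speed
#'   (0 <= intensity < 1); 0 disables dispersion.
#' @param eddy_time Mean eddy lifetime in seconds (> 0).
#' @return The field with updated `$k` and `$eddy_time`.
#' @export
turbulence_field <- function(field, intensity = 0.10, eddy_time = 0.5) {
  stopifnot(intensity >= 0, intensity < 1, eddy_time > 0)
  field$turbulence_intensity <- intensity
  field$eddy_time <- eddy_time
  field$k <- make_k_fun(field)
  field
}

#' Aeration-rate calibration table
#'
#' Line-averaged velocity targets (cm/s) per aeration rate (vvm) and regime.
#' The printed values cover 0.02 and 0.04 vvm in both regimes and 0.06 and
#' 0.1 vvm without baffles; with baffles the vertical velocity saturates above
#' 0.04 vvm, so both targets are held flat there.
#'
#' @return Data frame with columns `rate` (vvm), `baffled` (logical),
#'   `vz_target`, `vx_target` (cm/s).
#' @export
default_aeration_calibration <- function() {
  cal <- data.frame(
    rate = c(0.02, 0.04, 0.06, 0.10, 0.02, 0.04, 0.06, 0.10),
    baffled = rep(c(FALSE, TRUE), each = 4L),
    vz_target = c(10.2, 13.9, 16.5, 20.1, 9.6, 10.4, 10.4, 10.4),
    vx_target = c(0.52, 0.62, 0.70, 0.90, 1.0, 1.3, 1.3, 1.3)
  )
  validate_calibration(cal)
  cal
}

validate_calibration <- function(cal) {
  stopifnot(
    all(c("rate", "baffled", "vz_target", "vx_target") %in% names(cal)),
    all(cal$rate > 0), all(cal$vz_target > 0), all(cal$vx_target > 0)
  )
  bf <- cal[cal$baffled & cal$rate >= 0.06, ]
  bf <- bf[order(bf$rate), ]
  if (nrow(bf) >= 2L && any(diff(bf$vz_target) > 0)) {
    stop("with-baffles vz_target must be non-increasing beyond 0.06 vvm")
  }
  invisible(cal)
}

#' Look up velocity targets for an aeration rate
#'
#' Exact table values at tabulated rates, linear interpolation between
#' adjacent rates within one regime.
#'
#' @param cal Calibration table, see [default_aeration_calibration()].
#' @param rate Aeration rate in vvm.
#' @param baffled Logical regime selector.
#' @return Named numeric vector `c(vz_target = , vx_target = )` in cm/s.
#' @export
aeration_lookup <- function(cal, rate, baffled) {
  validate_calibration(cal)
  sub <- cal[cal$baffled == baffled, ]
  sub <- sub[order(sub$rate), ]
  if (nrow(sub) == 0L) stop("no calibration rows for this regime")
  if (rate < min(sub$rate) || rate > max(sub$rate)) {
    stop(sprintf("aeration rate %g vvm outside calibrated range [%g, %g]",
                 rate, min(sub$rate), max(sub$rate)))
  }
  c(
    vz_target = stats::approx(sub$rate, sub$vz_target, xout = rate)$y,
    vx_target = stats::approx(sub$rate, sub$vx_target, xout = rate)$y
  )
}

#' Calibrate a flow field to line-averaged velocity targets
#'
#' Solves for the streamfunction parameters so that the standard sampling-line
#' averages ([vertical_velocity()], [horizontal_velocity()]) match the
#' aeration-rate targets within `tol` (default 2 percent relative). Both field
#' families are homogeneous of degree one in their amplitudes, so calibration
#' first solves a one-dimensional root find for the parameter controlling the
#' |Vx|/|Vz| ratio (the cell-to-base amplitude ratio when baffled, the vertical
#' profile shape when unbaffled) and then scales the amplitude.
#'
#' @param geom A [build_geometry()] object.
#' @param rate Aeration rate (vvm).
#' @param baffled Logical regime selector.
#' @param cal Calibration table (defaults to the printed targets).
#' @param turbulence_intensity,eddy_time Turbulence proxy parameters attached
#'   to the returned field (see [turbulence_field()]).
#' @param tol Relative tolerance on the two achieved line averages.
#' @return A calibrated `flow_field` with turbulence attached.
#' @export
calibrate_field <- function(geom, rate, baffled,
                            cal = default_aeration_calibration(),
                            turbulence_intensity = 0.10, eddy_time = 0.5,
                            tol = 0.02) {
  tg <- aeration_lookup(cal, rate, baffled)
  target_ratio <- tg[["vx_target"]] / tg[["vz_target"]]

  if (baffled) {
    make <- function(par, amp = 1) make_baffled_field(geom, amp, amp * par)
    lo <- 0; hi <- 2
  } else {
    # ratio(shape) decreases on [0, ~0.175] then rises again; stay on the
    # monotone branch so the root is unique
    make <- function(par, amp = 1) make_unbaffled_field(geom, amp, shape = par)
    lo <- 0; hi <- 0.17
  }
  ratio_of <- function(par) {
    f <- make(par)
    horizontal_velocity(f, geom) / vertical_velocity(f, geom)
  }
  g <- function(par) ratio_of(par) - target_ratio
  glo <- g(lo); ghi <- g(hi)
  if (is.na(glo) || is.na(ghi) || glo * ghi > 0) {
    stop(sprintf(
      "calibration failed (%s, %g vvm): ratio %0.4f not bracketed by [%0.4f, %0.4f]",
      if (baffled) "baffled" else "unbaffled", rate,
      target_ratio, ratio_of(lo), ratio_of(hi)
    ))
  }
  par <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root

  unit <- make(par, amp = 1)
  vz_unit <- vertical_velocity(unit, geom)
  amp <- tg[["vz_target"]] / vz_unit
  field <- make(par, amp = amp)
  field$aeration_vvm <- rate
  field <- turbulence_field(field, turbulence_intensity, eddy_time)

  got_vz <- vertical_velocity(field, geom)
  got_vx <- horizontal_velocity(field, geom)
  rel <- c(abs(got_vz / tg[["vz_target"]] - 1), abs(got_vx / tg[["vx_target"]] - 1))
  if (any(rel > tol)) {
    stop(sprintf(
      "calibration out of tolerance: achieved (Vz, Vx) = (%.3f, %.3f) cm/s vs target (%.3f, %.3f)",
      got_vz, got_vx, tg[["vz_target"]], tg[["vx_target"]]
    ))
  }
  field
}

#' Sample a flow field on a regular grid
#'
#' @param field A `flow_field`.
#' @param pitch Grid pitch in mm (default 5).
#' @param file Optional path; when given, the grid is written as CSV with a
#'   one-line header.
#' @return Data frame with columns `x_mm`, `z_mm`, `vx_mm_s`, `vz_mm_s`,
#'   `k_mm2_s2` (invisibly when `file` is given).
#' @export
field_to_grid <- function(field, pitch = 5, file = NULL) {
  geom <- field$geom
  xs <- seq(geom$x_extent[1], geom$x_extent[2], by = pitch)
  zs <- seq(geom$z_extent[1], geom$z_extent[2], by = pitch)
  g <- expand.grid(x_mm = xs, z_mm = zs)
  v <- field$velocity(g$x_mm, g$z_mm)
  out <- data.frame(
    x_mm = g$x_mm, z_mm = g$z_mm,
    vx_mm_s = v$vx, vz_mm_s = v$vz,
    k_mm2_s2 = field$k(g$x_mm, g$z_mm)
  )
  if (!is.null(file)) {
    utils::write.csv(out, file, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf(
    "<flow_field> regime=%s, aeration=%s vvm, amplitudes: base=%.4g cell=%.4g shape=%.4g, turbulence I=%.2f tau_e=%.2g s\n",
    x$regime, format(x$aeration_vvm), x$amplitudes$base, x$amplitudes$cell,
    x$amplitudes$shape %||% 0, x$turbulence_intensity, x$eddy_time
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
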
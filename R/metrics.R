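#' Sampling line for velocity averages
#'
#' @param start,end Length-2 `(x, z)` endpoints in mm.
#' @param component `"vx"` or `"vz"`.
#' @param n_samples Number of equally spaced quadrature points (default 200).
#' @return A `sampling_line` object.
#' @export
sampling_line <- function(start, end, component = c("vz", "vx"), n_samples = 200L) {
  component <- match.arg(component)
  start <- as.numeric(start); end <- as.numeric(end)
  if (isTRUE(all(start == end))) stop("sampling line must have distinct endpoints")
  structure(
    list(start = start, end = end, component = component,
         n_samples = as.integer(n_samples)),
    class = "sampling_line"
  )
}

#' Standard sampling lines
#'
#' The vertical-velocity lines run from z = 100 mm to z = 700 mm at
#' x = -70 and +70 mm; the horizontal-velocity lines span the full panel
#' width at z = 135, 255, 375, 495 and 615 mm (offset 15 mm plus multiples of
#' the 120 mm baffle spacing).
#'
#' @param geom A [build_geometry()] object.
#' @return List of `sampling_line` objects.
#' @export
vertical_lines <- function(geom) {
  list(
    sampling_line(c(-70, 100), c(-70, 700), "vz"),
    sampling_line(c(70, 100), c(70, 700), "vz")
  )
}

#' @rdname vertical_lines
#' @export
horizontal_lines <- function(geom) {
  lapply(15 + 120 * (1:5), function(z) {
    sampling_line(c(geom$x_extent[1], z), c(geom$x_extent[2], z), "vx")
  })
}

#' Line-averaged velocity magnitude
#'
#' Mean of the absolute value of one velocity component over `n_samples`
#' equally spaced midpoint nodes on a line (midpoint quadrature, second-order
#' accurate and free of endpoint-weighting bias), skipping points that fall
#' inside a baffle circle (solid). Magnitude averaging is used throughout:
#' signed averages over full-width lines in a circulating flow would cancel
#' to about zero and could not reproduce nonzero horizontal-velocity values.
#'
#' @param field A `flow_field`.
#' @param line A [sampling_line()].
#' @return Average in cm/s.
#' @export
line_average <- function(field, line) {
  t <- (seq_len(line$n_samples) - 0.5) / line$n_samples
  x <- line$start[1] + t * (line$end[1] - line$start[1])
  z <- line$start[2] + t * (line$end[2] - line$start[2])
  fluid <- point_in_fluid(field$geom, x, z)
  # wall endpoints of full-width lines are fluid-boundary points, keep them out
  if (!any(fluid)) stop("all points on the sampling line are solid")
  v <- field$velocity(x[fluid], z[fluid])
  comp <- if (line$component == "vx") v$vx else v$vz
  mean(abs(comp)) / 10  # mm/s -> cm/s
}

#' Standard vertical and horizontal velocity metrics
#'
#' `vertical_velocity()` is the mean of the two vertical-line averages;
#' `horizontal_velocity()` is the mean over the five horizontal lines.
#'
#' @param field A `flow_field`.
#' @param geom A [build_geometry()] object (defaults to the field's own).
#' @return Velocity in cm/s.
#' @export
vertical_velocity <- function(field, geom = field$geom) {
  mean(vapply(vertical_lines(geom), function(l) line_average(field, l), numeric(1)))
}

#' @rdname vertical_velocity
#' @export
horizontal_velocity <- function(field, geom = field$geom) {
  mean(vapply(horizontal_lines(geom), function(l) line_average(field, l), numeric(1)))
}

#' Signed percent change
#'
#' `100 * (new - reference) / reference`, the comparison arithmetic used for
#' all before/after statements (cycle periods, velocities, probabilities).
#'
#' @param reference Baseline value (nonzero).
#' @param new New value.
#' @return Percent change (sign preserved).
#' @examples
#' percent_change(17.1, 14.1)  # -17.5 (1 d.p.)
#' percent_change(27.9, 43.6)  # +56.3
#' @export
percent_change <- function(reference, new) {
  if (any(reference == 0)) stop("reference must be nonzero")
  100 * (new - reference) / reference
}

#' Velocity metrics report
#'
#' @param field A calibrated `flow_field`.
#' @param file Optional path for a JSON report.
#' @return List with `vz_cm_s`, `vx_cm_s`, `regime`, `aeration_vvm`.
#' @export
velocity_report <- function(field, file = NULL) {
  rep <- list(
    vz_cm_s = vertical_velocity(field),
    vx_cm_s = horizontal_velocity(field),
    regime = field$regime,
    aeration_vvm = field$aeration_vvm
  )
  if (!is.null(file)) {
    jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}
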
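#' Binarize trajectories into light/dark series
#'
#' Applies the light/dark classification at every recorded position of every
#' particle.
#'
#' @param traj A `trajectory_set` from [track()].
#' @param model A [light_model()].
#' @param geom A [build_geometry()] object.
#' @param C Biomass concentration, g/L.
#' @return An `ld_series_set`: list with `states` (particles x records logical
#'   matrix, `TRUE` = light), `record_times`, `particle_ids`, `concentration`.
#' @export
binarize <- function(traj, model, geom, C) {
  states <- matrix(
    is_light(model, geom, as.vector(traj$x), C),
    nrow = nrow(traj$x)
  )
  structure(
    list(states = states, record_times = traj$record_times,
         particle_ids = traj$particle_ids, concentration = C),
    class = "ld_series_set"
  )
}

#' Complete L/D cycle durations of one series
#'
#' A complete cycle is one maximal light interval followed immediately by one
#' maximal dark interval, both lying strictly inside the recorded series
#' (leading and trailing partial intervals are discarded because their true
#' extent is unknown). Durations are measured on the record grid: each sample
#' contributes one `dt`.
#'
#' @param states Logical vector (`TRUE` = light) at uniform record times.
#' @param dt Record interval in seconds (default 0.1).
#' @return Numeric vector of cycle durations (s); empty when no complete
#'   cycle exists.
#' @examples
#' cycle_periods(rep(rep(c(TRUE, FALSE), c(30, 70)), 3)) # 10 s cycles
#' @export
cycle_periods <- function(states, dt = 0.1) {
  r <- rle(as.logical(states))
  L <- length(r$lengths)
  if (L < 4L) return(numeric(0))     # need interior light + dark runs
  # interior runs are 2..(L-1); a cycle is a light run i with its dark
  # successor i+1, both interior
  i <- which(r$values)
  i <- i[i >= 2L & i + 1L <= L - 1L]
  (r$lengths[i] + r$lengths[i + 1L]) * dt
}

#' Per-particle flashing statistics
#'
#' @param states Logical vector (`TRUE` = light).
#' @param dt Record interval, s.
#' @return List with `t_av_s` (mean cycle period, `NA` when the particle has
#'   no complete cycle), `f_hz` (`1/t_av_s`), `light_fraction`,
#'   `n_complete_cycles`.
#' @export
particle_stats <- function(states, dt = 0.1) {
  p <- cycle_periods(states, dt)
  t_av <- if (length(p)) mean(p) else NA_real_
  list(
    t_av_s = t_av,
    f_hz = if (is.na(t_av)) NA_real_ else 1 / t_av,
    light_fraction = mean(states),
    n_complete_cycles = length(p)
  )
}

#' Population flashing-light summary
#'
#' Aggregates per-particle statistics: the population L/D cycle period
#' `T_av_p` is the arithmetic mean of the defined per-particle average
#' periods, the light-time fraction is the unweighted mean over all particles
#' (defined for every particle), and the histogram is the empirical
#' distribution over 5 s bins. By default the histogram is over per-particle
#' average periods; `histogram_over = "cycles"` bins individual cycle
#' instances instead.
#'
#' @param series An `ld_series_set` from [binarize()] (or a logical matrix,
#'   particles in rows).
#' @param dt Record interval, s (taken from the series when available).
#' @param bin_width Histogram bin width, s (default 5).
#' @param histogram_over `"per_particle"` (default) or `"cycles"`.
#' @return An `ld_summary`: list with `t_av_p_s`, `mean_light_fraction`,
#'   `histogram` (`edges_s`, `probabilities`), `n_used`, `n_total` and a
#'   `per_particle` data frame.
#' @export
population_summary <- function(series, dt = NULL, bin_width = 5,
                               histogram_over = c("per_particle", "cycles")) {
  histogram_over <- match.arg(histogram_over)
  if (inherits(series, "ld_series_set")) {
    states <- series$states
    if (is.null(dt)) dt <- diff(series$record_times[1:2])
  } else {
    states <- as.matrix(series)
    if (is.null(dt)) dt <- 0.1
  }
  n <- nrow(states)
  per <- lapply(seq_len(n), function(i) particle_stats(states[i, ], dt))
  pp <- data.frame(
    particle_id = seq_len(n),
    t_av_s = vapply(per, `[[`, numeric(1), "t_av_s"),
    f_hz = vapply(per, `[[`, numeric(1), "f_hz"),
    light_fraction = vapply(per, `[[`, numeric(1), "light_fraction"),
    n_complete_cycles = vapply(per, `[[`, integer(1), "n_complete_cycles")
  )
  defined <- !is.na(pp$t_av_s)
  if (!any(defined)) stop("no particle completed an L/D cycle; cannot summarise")

  vals <- if (histogram_over == "per_particle") {
    pp$t_av_s[defined]
  } else {
    unlist(lapply(seq_len(n), function(i) cycle_periods(states[i, ], dt)))
  }
  edges <- seq(0, bin_width * ceiling(max(vals) / bin_width + 1e-12), by = bin_width)
  if (length(edges) < 2L) edges <- c(0, bin_width)
  counts <- tabulate(findInterval(vals, edges, rightmost.closed = FALSE),
                     nbins = length(edges) - 1L)

  structure(
    list(
      t_av_p_s = mean(pp$t_av_s[defined]),
      mean_light_fraction = mean(pp$light_fraction),
      histogram = list(edges_s = edges, probabilities = counts / length(vals)),
      n_used = sum(defined),
      n_total = n,
      per_particle = pp
    ),
    class = "ld_summary"
  )
}

#' Probability mass of one histogram bin
#'
#' @param summary An `ld_summary`.
#' @param lo,hi Bin edges in seconds; must coincide with stored edges.
#' @return Probability of `[lo, hi)`.
#' @export
bin_probability <- function(summary, lo, hi) {
  e <- summary$histogram$edges_s
  p <- summary$histogram$probabilities
  i <- which(abs(e[-length(e)] - lo) < 1e-9 & abs(e[-1] - hi) < 1e-9)
  if (!length(i)) return(0)
  p[i]
}

#' Write an ld_summary as JSON (plus optional per-particle CSV)
#'
#' @param summary An `ld_summary`.
#' @param file JSON path.
#' @param per_particle_file Optional CSV path for the per-particle table.
#' @export
write_ld_summary <- function(summary, file, per_particle_file = NULL) {
  jsonlite::write_json(
    list(
      t_av_p_s = summary$t_av_p_s,
      mean_light_fraction = summary$mean_light_fraction,
      histogram = summary$histogram,
      n_used = summary$n_used,
      n_total = summary$n_total
    ),
    file, auto_unbox = TRUE, digits = NA
  )
  if (!is.null(per_particle_file)) {
    utils::write.csv(summary$per_particle, per_particle_file, row.names = FALSE)
  }
  invisible(file)
}

#' @export
print.ld_summary <- function(x, ...) {
  cat(sprintf(
    "<ld_summary> T_av_p = %.2f s, light fraction = %.3f, n_used = %d/%d\n",
    x$t_av_p_s, x$mean_light_fraction, x$n_used, x$n_total
  ))
  invisible(x)
}
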
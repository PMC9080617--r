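#' Beer-Lambert light attenuation model with critical depth
#'
#' Light enters the panel through one face and is attenuated exponentially by
#' the culture: `I(d) = I0 * exp(-sigma_a * C * d)` with `d` the depth from
#' the illuminated face (cm), `C` the biomass concentration (g/L) and
#' `sigma_a` the specific attenuation coefficient (1/cm per g/L). The critical
#' depth is where `I` falls to the critical intensity `I_crit` below which
#' photosynthesis is light-limited:
#' `d_crit(C) = ln(I0 / I_crit) / (sigma_a * C)`.
#'
#' @param sigma_a Specific attenuation coefficient, 1/cm per (g/L), > 0.
#' @param I0 Incident intensity at the face, umol m^-2 s^-1 (default 530).
#' @param I_crit Critical intensity (default 96.84).
#' @param illuminated_face `"x_min"` or `"x_max"` (default `"x_max"`).
#' @return A `light_model` object.
#' @export
light_model <- function(sigma_a, I0 = 530, I_crit = 96.84,
                        illuminated_face = c("x_max", "x_min")) {
  if (!(I0 > I_crit && I_crit > 0)) stop("need I0 > I_crit > 0")
  if (sigma_a <= 0) stop("sigma_a must be positive")
  structure(
    list(sigma_a = sigma_a, I0 = I0, I_crit = I_crit,
         illuminated_face = match.arg(illuminated_face)),
    class = "light_model"
  )
}

#' Fit the attenuation coefficient to (concentration, critical depth) pairs
#'
#' Under Beer-Lambert attenuation each calibration pair gives
#' `K_j = C_j * d_crit_j = ln(I0 / I_crit) / sigma_a`; the fit takes the
#' logarithmic mean of the per-pair `K_j` (least squares in log space with the
#' slope fixed at -1, i.e. symmetric treatment of multiplicative error) and
#' returns the corresponding model.
#'
#' @param calibration Data frame with columns `concentration_g_per_L` and
#'   `critical_depth_cm` (aliases `C` / `d_crit` accepted), all positive.
#' @inheritParams light_model
#' @return A `light_model` whose `$sigma_a` is the fitted coefficient.
#' @examples
#' m <- fit_attenuation(data.frame(concentration_g_per_L = c(0.28, 1.7),
#'                                 critical_depth_cm = c(5, 1)))
#' critical_depth(m, 0.85)  # ~1.8 cm, i.e. 2 cm to the nearest cm
#'
#' # the bundled three-point calibration table
#' cal <- read.csv(system.file("extdata", "critical_depth_calibration.csv",
#'                             package = "pbrflash"))
#' fit_attenuation(cal)
#' @export
fit_attenuation <- function(calibration, I0 = 530, I_crit = 96.84,
                            illuminated_face = c("x_max", "x_min")) {
  C <- calibration$concentration_g_per_L %||% calibration$C
  d <- calibration$critical_depth_cm %||% calibration$d_crit
  if (is.null(C) || is.null(d) || length(C) < 1L) {
    stop("calibration needs columns concentration_g_per_L and critical_depth_cm")
  }
  if (any(C <= 0) || any(d <= 0)) stop("calibration values must be positive")
  K <- exp(mean(log(C * d)))
  light_model(sigma_a = log(I0 / I_crit) / K, I0 = I0, I_crit = I_crit,
              illuminated_face = match.arg(illuminated_face))
}

#' Critical depth for a concentration
#'
#' @param model A [light_model()].
#' @param C Biomass concentration, g/L (> 0; vectorised).
#' @return Critical depth in cm.
#' @export
critical_depth <- function(model, C) {
  if (any(C <= 0)) stop("concentration must be positive")
  log(model$I0 / model$I_crit) / (model$sigma_a * C)
}

#' Critical depth from a measured intensity profile
#'
#' Locates the depth where the intensity crosses `I_crit` by linear
#' interpolation in `(depth, log I)` between the bracketing samples, matching
#' exponential attenuation exactly when the profile is exponential.
#'
#' @param profile Data frame with columns `depth_cm` and `I` (intensity),
#'   strictly decreasing in `I` and spanning `I_crit`.
#' @param I_crit Critical intensity.
#' @return Depth in cm.
#' @export
critical_depth_from_profile <- function(profile, I_crit = 96.84) {
  d <- profile$depth_cm
  I <- profile$I
  if (is.unsorted(rev(I), strictly = TRUE)) {
    stop("profile intensities must be strictly decreasing with depth")
  }
  if (I_crit > max(I) || I_crit < min(I)) {
    stop("I_crit outside the range of the profile")
  }
  hit <- which(I == I_crit)
  if (length(hit)) return(d[hit[1]])
  j <- which(I < I_crit)[1]      # first sample below the critical intensity
  i <- j - 1L
  d[i] + (d[j] - d[i]) * (log(I[i]) - log(I_crit)) / (log(I[i]) - log(I[j]))
}

#' Depth from the illuminated face
#'
#' @param model A [light_model()].
#' @param geom A [build_geometry()] object.
#' @param x x-coordinate(s) in mm.
#' @return Depth in cm (light travels along -x or +x from the chosen face).
#' @export
light_depth_cm <- function(model, geom, x) {
  if (model$illuminated_face == "x_max") {
    (geom$x_extent[2] - x) / 10
  } else {
    (x - geom$x_extent[1]) / 10
  }
}

#' Classify positions into light or dark zone
#'
#' A point is in the light zone iff its depth from the illuminated face does
#' not exceed the critical depth for the given concentration; the vertical
#' coordinate plays no role (the light/dark boundary is a plane parallel to
#' the illuminated face).
#'
#' @param model A [light_model()].
#' @param geom A [build_geometry()] object.
#' @param x,z Position(s) in mm (vectorised; `z` is accepted for interface
#'   symmetry).
#' @param C Concentration, g/L.
#' @return Character vector of `"light"` / `"dark"`.
#' @export
classify_position <- function(model, geom, x, z = NULL, C) {
  ifelse(is_light(model, geom, x, C), "light", "dark")
}

#' @rdname classify_position
#' @return `is_light()` returns a logical vector.
#' @export
is_light <- function(model, geom, x, C) {
  light_depth_cm(model, geom, x) <= critical_depth(model, C)
}

#' @export
print.light_model <- function(x, ...) {
  cat(sprintf(
    "<light_model> sigma_a=%.4g /cm/(g/L), I0=%g, I_crit=%g umol/m2/s, face=%s\n",
    x$sigma_a, x$I0, x$I_crit, x$illuminated_face
  ))
  invisible(x)
}
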
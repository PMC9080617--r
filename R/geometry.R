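#' Reactor geometry for a flat-panel photobioreactor with horizontal baffles
#'
#' Builds the two-dimensional (x-z mid-plane) description of a flat-panel
#' airlift photobioreactor: a rectangular fluid domain with a vertical stack of
#' circular cross-sections of horizontal tube baffles, two particle injection
#' ports and one illuminated face. Coordinates are continuous millimetres with
#' the origin at the bottom centre of the panel; the 20 cm panel length is the
#' out-of-plane direction and plays no role in the plane model.
#'
#' The default geometry is a 160 mm wide, 900 mm tall panel with six 70 mm
#' diameter baffles centred on the panel mid-line (x = 0), the lowest 90 mm
#' above the bottom and successive baffles 120 mm apart, and injection ports at
#' (60, 10) and (-60, 700) mm.
#'
#' @param config Named list overriding defaults. Recognised keys:
#'   `x_extent` (length-2, mm), `z_extent` (length-2, mm), `depth_y` (mm,
#'   informational), `baffle_count`, `baffle_diameter_mm`,
#'   `first_baffle_center_mm` (length-2 `(x, z)`), `baffle_spacing_mm`,
#'   `baffle_centers` (n x 2 matrix, overrides count/first/spacing),
#'   `ports` (2 x 2 matrix of `(x, z)` rows), `illuminated_face`
#'   (`"x_min"` or `"x_max"`).
#' @return An object of class `reactor_geometry`: a list with fields
#'   `x_extent`, `z_extent`, `depth_y`, `baffle_diameter`, `baffle_radius`,
#'   `baffle_centers` (n x 2 matrix), `port_positions` (2 x 2 matrix),
#'   `illuminated_face`.
#' @examples
#' geom <- build_geometry()
#' nrow(geom$baffle_centers)      # 6
#' geom$baffle_centers[1, ]       # c(0, 90)
#' @export
build_geometry <- function(config = list()) {
  stopifnot(is.list(config))
  get <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default

  x_extent <- as.numeric(get("x_extent", c(-80, 80)))
  z_extent <- as.numeric(get("z_extent", c(0, 900)))
  depth_y <- as.numeric(get("depth_y", 160))
  diam <- as.numeric(get("baffle_diameter_mm", 70))
  count <- as.integer(get("baffle_count", 6L))
  first <- as.numeric(get("first_baffle_center_mm", c(0, 90)))
  spacing <- as.numeric(get("baffle_spacing_mm", 120))

  if (length(x_extent) != 2L || diff(x_extent) <= 0) {
    stop("x_extent must be an increasing length-2 vector (mm)")
  }
  if (length(z_extent) != 2L || diff(z_extent) <= 0) {
    stop("z_extent must be an increasing length-2 vector (mm)")
  }
  if (diam <= 0 || spacing <= 0 || depth_y <= 0) {
    stop("baffle_diameter_mm, baffle_spacing_mm and depth_y must be positive")
  }
  if (count < 0L) stop("baffle_count must be >= 0")

  if (!is.null(config$baffle_centers)) {
    centers <- matrix(as.numeric(config$baffle_centers), ncol = 2)
  } else if (count == 0L) {
    centers <- matrix(numeric(0), ncol = 2)
  } else {
    centers <- cbind(rep(first[1], count), first[2] + spacing * (seq_len(count) - 1L))
  }
  colnames(centers) <- c("x", "z")

  ports <- get("ports", rbind(c(60, 10), c(-60, 700)))
  ports <- matrix(as.numeric(ports), ncol = 2)
  colnames(ports) <- c("x", "z")

  face <- match.arg(get("illuminated_face", "x_max"), c("x_min", "x_max"))

  geom <- structure(
    list(
      x_extent = x_extent, z_extent = z_extent, depth_y = depth_y,
      baffle_diameter = diam, baffle_radius = diam / 2,
      baffle_centers = centers, port_positions = ports,
      illuminated_face = face
    ),
    class = "reactor_geometry"
  )
  validate_geometry(geom)
  geom
}

validate_geometry <- function(geom) {
  r <- geom$baffle_radius
  cc <- geom$baffle_centers
  n <- nrow(cc)
  for (i in seq_len(n)) {
    inside <- cc[i, 1] - r > geom$x_extent[1] && cc[i, 1] + r < geom$x_extent[2] &&
      cc[i, 2] - r > geom$z_extent[1] && cc[i, 2] + r < geom$z_extent[2]
    if (!inside) {
      stop(sprintf(
        "baffle %d at (%g, %g) mm is not strictly inside the fluid rectangle",
        i, cc[i, 1], cc[i, 2]
      ))
    }
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- sqrt(sum((cc[i, ] - cc[j, ])^2))
        if (d < 2 * r) {
          stop(sprintf("baffles %d and %d overlap (centre distance %.1f mm < %g mm)",
                       i, j, d, 2 * r))
        }
      }
    }
  }
  invisible(geom)
}

#' Is a point inside the fluid domain?
#'
#' A point is in the fluid iff it lies strictly inside the rectangular panel
#' cross-section and strictly outside every baffle circle; boundaries count as
#' not-in-fluid. Vectorised over `x` and `z`.
#'
#' @param geom A [build_geometry()] object.
#' @param x,z Point coordinates in mm (recycled to common length).
#' @return Logical vector.
#' @examples
#' geom <- build_geometry()
#' point_in_fluid(geom, 0, 90)    # FALSE: baffle centre
#' point_in_fluid(geom, 0, 126)   # TRUE: 36 mm > 35 mm radius
#' @export
point_in_fluid <- function(geom, x, z) {
  n <- max(length(x), length(z))
  x <- rep_len(as.numeric(x), n)
  z <- rep_len(as.numeric(z), n)
  ok <- x > geom$x_extent[1] & x < geom$x_extent[2] &
    z > geom$z_extent[1] & z < geom$z_extent[2]
  r2 <- geom$baffle_radius^2
  cc <- geom$baffle_centers
  for (i in seq_len(nrow(cc))) {
    ok <- ok & ((x - cc[i, 1])^2 + (z - cc[i, 2])^2 > r2)
  }
  ok
}

#' Fluid cross-sectional area
#'
#' Rectangle area minus the area of the baffle circles, in mm^2.
#'
#' @param geom A [build_geometry()] object.
#' @return Numeric scalar (mm^2).
#' @export
fluid_area <- function(geom) {
  diff(geom$x_extent) * diff(geom$z_extent) -
    nrow(geom$baffle_centers) * pi * geom$baffle_radius^2
}

#' @export
print.reactor_geometry <- function(x, ...) {
  cat(sprintf(
    "<reactor_geometry> x: [%g, %g] mm, z: [%g, %g] mm, %d baffle(s) d=%g mm, illuminated %s\n",
    x$x_extent[1], x$x_extent[2], x$z_extent[1], x$z_extent[2],
    nrow(x$baffle_centers), x$baffle_diameter, x$illuminated_face
  ))
  invisible(x)
}
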
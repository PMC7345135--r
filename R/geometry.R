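#' Meshing controls
#'
#' Options controlling the structured suspension mesh. The membrane band
#' is always meshed with `membrane_layers` structured rings across its
#' thickness (the narrow-band analogue of a commercial mesher's "narrow
#' factor"); away from the band, radial element sizes grow geometrically
#' from the band thickness at rate `max_growth_rate`, clamped to
#' `[min_element_size, max_element_size]`. `max_element_size` also sets
#' the tangential spacing along the cell boundary.
#'
#' @param max_element_size Largest element extent in m.
#' @param min_element_size Smallest radial ladder size in m (the membrane
#'   band itself may be thinner; it is governed by `membrane_layers`).
#' @param max_growth_rate Geometric growth factor between adjacent radial
#'   layers, >= 1.
#' @param membrane_layers Number of structured element layers across the
#'   membrane band, >= 2.
#' @return An object of class `meshing_options`.
#' @export
meshing_options <- function(max_element_size = 5e-7,
                            min_element_size = 1e-8,
                            max_growth_rate = 1.2,
                            membrane_layers = 3L) {
  if (!is.finite(max_element_size) || max_element_size <= 0 ||
      !is.finite(min_element_size) || min_element_size <= 0)
    stop("element sizes must be positive lengths in m", call. = FALSE)
  if (min_element_size > max_element_size)
    stop("'min_element_size' must not exceed 'max_element_size'",
         call. = FALSE)
  if (!is.finite(max_growth_rate) || max_growth_rate < 1)
    stop("'max_growth_rate' must be >= 1", call. = FALSE)
  membrane_layers <- as.integer(membrane_layers)
  if (is.na(membrane_layers) || membrane_layers < 2L)
    stop("'membrane_layers' must be an integer >= 2", call. = FALSE)
  structure(list(max_element_size = max_element_size,
                 min_element_size = min_element_size,
                 max_growth_rate = max_growth_rate,
                 membrane_layers = membrane_layers),
            class = "meshing_options")
}

#' Build the 2D suspension geometry for a cell model
#'
#' The suspension domain is a square of side W = L (top and bottom edges
#' are the electrodes, the sides are insulating) with the cell centred in
#' it. The side is chosen so the inclusion occupies the requested area
#' fraction: W = sqrt(pi R^2 / P) for a circle, sqrt(pi a b / P) for an
#' ellipse.
#'
#' @param cell A [cell_model()].
#' @param P Area fraction of the inclusion, 0 < P < 0.5.
#' @return An object of class `geometry2d` with fields `W`, `L`, `shape`,
#'   `R` or `a`/`b`, membrane thickness `t` and `P`.
#' @examples
#' cm <- cell_model(radius = 5e-6, membrane_thickness = 5e-9, dimension = 2,
#'                  membrane = material(1e-7, 5), cytoplasm = material(1, 80),
#'                  medium = material(1, 80))
#' g <- build_geometry(cm, P = 0.035)
#' g$W * 1e6  # ~ 47.4 um
#' @export
build_geometry <- function(cell, P = 0.035) {
  stopifnot(inherits(cell, "cell_model"))
  if (!is.numeric(P) || length(P) != 1L || !is.finite(P) || P <= 0 || P >= 0.5)
    stop("'P' must be an area fraction in (0, 0.5)", call. = FALSE)
  if (cell$shape == "ellipse") {
    area <- pi * cell$a * cell$b
    extent <- 2 * max(cell$a, cell$b)
  } else {
    area <- pi * cell$radius^2
    extent <- 2 * cell$radius
  }
  side <- sqrt(area / P)
  if (extent >= side)
    stop(sprintf(paste0("inclusion does not fit in the domain at P = %g; ",
                        "the side would be %g m but the inclusion spans %g m ",
                        "(require side > %g m, i.e. P < %g)"),
                 P, side, extent, extent, area / extent^2), call. = FALSE)
  structure(list(W = side, L = side, shape = cell$shape,
                 R = if (cell$shape == "circle") cell$radius,
                 a = if (cell$shape == "ellipse") cell$a,
                 b = if (cell$shape == "ellipse") cell$b,
                 t = cell$membrane_thickness, P = P),
            class = "geometry2d")
}

#' @export
print.geometry2d <- function(x, ...) {
  inc <- if (x$shape == "ellipse")
    sprintf("ellipse a = %g um, b = %g um", x$a * 1e6, x$b * 1e6)
  else sprintf("circle R = %g um", x$R * 1e6)
  cat(sprintf("<geometry2d> square %g x %g um, %s, membrane %g nm (P = %g)\n",
              x$W * 1e6, x$L * 1e6, inc, x$t * 1e9, x$P))
  invisible(x)
}

#' Inclusion area fraction of a geometry
#'
#' Exact round trip of the fraction used by [build_geometry()].
#' @param geom A `geometry2d`.
#' @return Numeric scalar, inclusion area / (W L).
#' @export
area_fraction <- function(geom) {
  stopifnot(inherits(geom, "geometry2d"))
  area <- if (geom$shape == "ellipse") pi * geom$a * geom$b else pi * geom$R^2
  area / (geom$W * geom$L)
}
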
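#' Vacuum permittivity (F/m)
#'
#' Fixed physical constant used throughout the package for conversions
#' between complex relative permittivity and complex conductivity.
#' @export
EPS0 <- 8.8541878128e-12

#' Define a dielectric phase
#'
#' A material is one homogeneous dielectric phase, described by a
#' frequency-independent conductivity and relative permittivity. The
#' frequency dependence of its complex permittivity/conductivity comes
#' entirely from the displacement term.
#'
#' @param conductivity Conductivity in S/m; must be finite and >= 0
#'   (0 is a pure dielectric).
#' @param rel_permittivity Relative permittivity (dimensionless); must be
#'   finite and > 0.
#' @return An object of class `material`.
#' @examples
#' saline <- material(conductivity = 1, rel_permittivity = 80)
#' membrane <- material(conductivity = 1e-7, rel_permittivity = 5)
#' @export
material <- function(conductivity, rel_permittivity) {
  stopifnot(is.numeric(conductivity), length(conductivity) == 1L,
            is.numeric(rel_permittivity), length(rel_permittivity) == 1L)
  if (!is.finite(conductivity) || conductivity < 0)
    stop("'conductivity' must be finite and >= 0 (S/m)", call. = FALSE)
  if (!is.finite(rel_permittivity) || rel_permittivity <= 0)
    stop("'rel_permittivity' must be finite and > 0", call. = FALSE)
  structure(list(conductivity = conductivity,
                 rel_permittivity = rel_permittivity),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> sigma = %g S/m, eps_r = %g\n",
              x$conductivity, x$rel_permittivity))
  invisible(x)
}

check_frequency <- function(f) {
  if (!is.numeric(f) || any(!is.finite(f)) || any(f <= 0))
    stop("'f' must be a positive finite frequency in Hz", call. = FALSE)
  invisible(f)
}

#' Complex relative permittivity of a material
#'
#' Evaluates eps* = eps_r + sigma / (j omega eps0) at frequency `f`
#' (time-harmonic convention exp(+j omega t), so a lossy material has a
#' negative imaginary part).
#'
#' @param mat A [material()].
#' @param f Frequency in Hz (> 0); vectorised.
#' @return Complex relative permittivity (same length as `f`).
#' @examples
#' complex_permittivity(material(0, 80), 1e6)   # 80 + 0i
#' complex_permittivity(material(1, 80), 1e6)   # 80 - 1.8e4i
#' @export
complex_permittivity <- function(mat, f) {
  stopifnot(inherits(mat, "material"))
  check_frequency(f)
  w <- 2 * pi * f
  mat$rel_permittivity + mat$conductivity / (1i * w * EPS0)
}

#' Complex conductivity of a material
#'
#' Evaluates sigma* = sigma + j omega eps0 eps_r at frequency `f`. This is
#' j omega eps0 times [complex_permittivity()]; the two representations
#' carry identical information at a given frequency.
#'
#' @inheritParams complex_permittivity
#' @return Complex conductivity in S/m (same length as `f`).
#' @export
complex_conductivity <- function(mat, f) {
  stopifnot(inherits(mat, "material"))
  check_frequency(f)
  mat$conductivity + 1i * 2 * pi * f * EPS0 * mat$rel_permittivity
}

#' Convert between complex permittivity and complex conductivity
#'
#' `eps_to_sigma()` returns sigma* = j omega eps0 eps*;
#' `sigma_to_eps()` returns eps* = sigma* / (j omega eps0).
#' The round trip is exact to machine precision.
#'
#' @param eps_star,sigma_star Complex values (vectorised).
#' @param f Frequency in Hz (> 0), recycled against the first argument.
#' @return Complex vector.
#' @export
eps_to_sigma <- function(eps_star, f) {
  check_frequency(f)
  1i * 2 * pi * f * EPS0 * eps_star
}

#' @rdname eps_to_sigma
#' @export
sigma_to_eps <- function(sigma_star, f) {
  check_frequency(f)
  sigma_star / (1i * 2 * pi * f * EPS0)
}

#' Define a single-shell cell model
#'
#' A biological cell modelled as a conductive cytoplasm core wrapped in a
#' thin, poorly conducting membrane, suspended in a conductive medium.
#' The geometry is a circle of radius `radius` (or an ellipse with
#' semi-axes `a`, `b`); `dimension` selects the 2D (`n = 2`) or 3D
#' (`n = 3`) shell factor v = (1 - dm/R)^n used by the analytical model.
#'
#' For an elliptical cell the analytical shell factor uses the semi-minor
#' axis as the governing radius; the analytical single-shell formula is
#' exact only for the circular/spherical case, so elliptical models are
#' primarily intended for the FEM path.
#'
#' @param radius Cell radius R in m (circle). Ignored if `a`,`b` given.
#' @param membrane_thickness Membrane thickness dm in m; 0 < dm < R.
#' @param dimension Shell-factor dimension n, 2 or 3.
#' @param membrane,cytoplasm,medium [material()] objects for the three
#'   phases.
#' @param a,b Optional semi-major/semi-minor axes in m for an elliptical
#'   cell (both or neither).
#' @param membrane_model Optional function `f -> complex sigma*` (S/m)
#'   overriding the membrane material's complex conductivity; used by the
#'   thin-shell equivalence to install a frequency-dependent equivalent
#'   membrane. Default `NULL` (use `membrane`).
#' @return An object of class `cell_model`.
#' @examples
#' cm <- cell_model(radius = 5e-6, membrane_thickness = 5e-9,
#'                  dimension = 2,
#'                  membrane  = material(1e-7, 5),
#'                  cytoplasm = material(1, 80),
#'                  medium    = material(1, 80))
#' @export
cell_model <- function(radius = NULL, membrane_thickness, dimension = 2,
                       membrane, cytoplasm, medium,
                       a = NULL, b = NULL, membrane_model = NULL) {
  stopifnot(inherits(membrane, "material"),
            inherits(cytoplasm, "material"),
            inherits(medium, "material"))
  if (!dimension %in% c(2, 3))
    stop("'dimension' must be 2 or 3", call. = FALSE)
  dm <- membrane_thickness
  if (!is.numeric(dm) || !is.finite(dm) || dm <= 0)
    stop("'membrane_thickness' must be a positive length in m", call. = FALSE)
  ellipse <- !is.null(a) || !is.null(b)
  if (ellipse) {
    if (is.null(a) || is.null(b))
      stop("both semi-axes 'a' and 'b' are required for an ellipse",
           call. = FALSE)
    if (!all(is.finite(c(a, b))) || a <= 0 || b <= 0)
      stop("semi-axes must be positive finite lengths in m", call. = FALSE)
    if (dm >= min(a, b))
      stop("'membrane_thickness' must be smaller than min(a, b)",
           call. = FALSE)
    radius <- min(a, b)
  } else {
    if (is.null(radius) || !is.finite(radius) || radius <= 0)
      stop("'radius' must be a positive length in m", call. = FALSE)
    if (dm >= radius)
      stop("'membrane_thickness' must be smaller than 'radius'",
           call. = FALSE)
  }
  if (!is.null(membrane_model) && !is.function(membrane_model))
    stop("'membrane_model' must be NULL or a function of frequency",
         call. = FALSE)
  structure(list(radius = radius, a = if (ellipse) a, b = if (ellipse) b,
                 shape = if (ellipse) "ellipse" else "circle",
                 membrane_thickness = dm, dimension = as.integer(dimension),
                 membrane = membrane, cytoplasm = cytoplasm, medium = medium,
                 membrane_model = membrane_model),
            class = "cell_model")
}

#' @export
print.cell_model <- function(x, ...) {
  geom <- if (x$shape == "ellipse")
    sprintf("ellipse a = %g um, b = %g um", x$a * 1e6, x$b * 1e6)
  else sprintf("circle R = %g um", x$radius * 1e6)
  cat(sprintf("<cell_model> %s, membrane %g nm, n = %d%s\n", geom,
              x$membrane_thickness * 1e9, x$dimension,
              if (!is.null(x$membrane_model)) " (equivalent membrane)" else ""))
  cat("  membrane : "); print(x$membrane)
  cat("  cytoplasm: "); print(x$cytoplasm)
  cat("  medium   : "); print(x$medium)
  invisible(x)
}

#' Shell factor of a cell model
#'
#' v = (1 - dm/R)^n with n the model dimension. Lies strictly in (0, 1)
#' for a valid model.
#' @param cell A [cell_model()].
#' @return Numeric scalar.
#' @export
shell_factor <- function(cell) {
  stopifnot(inherits(cell, "cell_model"))
  (1 - cell$membrane_thickness / cell$radius)^cell$dimension
}

# complex conductivity of each region at frequency f, honouring a
# frequency-dependent equivalent membrane if installed
region_sigma_star <- function(cell, f) {
  mem <- if (is.null(cell$membrane_model))
    complex_conductivity(cell$membrane, f)
  else cell$membrane_model(f)
  list(medium    = complex_conductivity(cell$medium, f),
       membrane  = mem,
       cytoplasm = complex_conductivity(cell$cytoplasm, f))
}

# membrane complex relative permittivity, honouring the override
membrane_eps_star <- function(cell, f) {
  if (is.null(cell$membrane_model))
    complex_permittivity(cell$membrane, f)
  else sigma_to_eps(cell$membrane_model(f), f)
}
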
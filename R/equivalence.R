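#' Thin-shell equivalence specification
#'
#' Describes the replacement of the true membrane (thickness `l1`,
#' material `material_1`) plus an added layer of thickness `l2` carved
#' out of the adjacent phase (`material_2`, normally identical to the
#' cytoplasm) by a single thicker membrane of thickness `l1 + l2`.
#'
#' @param l1 True membrane thickness in m (> 0).
#' @param l2 Added layer thickness in m (>= 0). `l2 = 0` is the identity.
#' @param material_1 Membrane [material()].
#' @param material_2 [material()] of the added layer (the intracellular
#'   fluid in the standard construction).
#' @return An object of class `equivalence_spec`.
#' @export
equivalence_spec <- function(l1, l2, material_1, material_2) {
  stopifnot(inherits(material_1, "material"), inherits(material_2, "material"))
  if (!is.finite(l1) || l1 <= 0)
    stop("'l1' must be a positive thickness in m", call. = FALSE)
  if (!is.finite(l2) || l2 < 0)
    stop("'l2' must be a non-negative thickness in m", call. = FALSE)
  structure(list(l1 = l1, l2 = l2,
                 material_1 = material_1, material_2 = material_2),
            class = "equivalence_spec")
}

#' Equivalent complex conductivity of a thickened membrane
#'
#' Treats the true membrane (thickness `l1`, complex conductivity
#' sigma_1*) and the added layer (`l2`, sigma_2*) as two electrolytes in
#' series with equal cross-sections and returns the complex conductivity
#' of the single layer of thickness `l1 + l2` with the same series
#' impedance:
#'
#'   sigma_e* = (l1 + l2) sigma_1* sigma_2* /
#'              (l1 sigma_2* + l2 sigma_1*).
#'
#' For a flat three-layer stack the substitution is exact at every
#' frequency; for a curved shell it is accurate to O((l1+l2)/R). When the
#' added layer is a good conductor the membrane capacitance per unit
#' area, Im(sigma_e*)/(omega eps0) * eps0 / (l1+l2), is preserved.
#'
#' @param spec An [equivalence_spec()].
#' @param f Frequency in Hz (> 0); vectorised.
#' @return Complex equivalent conductivity sigma_e* in S/m.
#' @examples
#' es <- equivalence_spec(5e-9, 15e-9, material(1e-7, 5), material(1, 80))
#' equivalent_conductivity(es, 1e6)  # ~ 1.3e-6 + 1.11e-3i (eps_r ~ 20)
#' @export
equivalent_conductivity <- function(spec, f) {
  stopifnot(inherits(spec, "equivalence_spec"))
  check_frequency(f)
  s1 <- complex_conductivity(spec$material_1, f)
  s2 <- complex_conductivity(spec$material_2, f)
  den <- spec$l1 * s2 + spec$l2 * s1
  scale <- (spec$l1 + spec$l2) * pmax(Mod(s1), Mod(s2))
  if (any(Mod(den) <= .Machine$double.eps * scale))
    stop("degenerate materials: l1 sigma_2* + l2 sigma_1* vanishes",
         call. = FALSE)
  (spec$l1 + spec$l2) * s1 * s2 / den
}

#' Transform a cell model to its reduced-mesh equivalent
#'
#' Returns a cell model whose membrane is `l2` thicker than the input's,
#' thickened inward (the membrane outer surface stays at the cell
#' boundary and the added layer replaces cytoplasm), with the
#' frequency-dependent equivalent complex conductivity from
#' [equivalent_conductivity()] installed as the membrane dielectric. The
#' added layer takes the electrical parameters of the cytoplasm. The
#' analytical shell factor of the returned model is
#' v = (1 - (l1+l2)/R)^n, and FEM geometries built from it use a membrane
#' band of thickness l1 + l2, so meshing it needs fewer elements.
#'
#' `l2 = 0` returns a model whose spectra are identical to the input's.
#'
#' @param cell A [cell_model()] (with a plain membrane material).
#' @param l2 Added layer thickness in m (>= 0); `l1 + l2` must stay below
#'   the governing radius.
#' @return A [cell_model()] with `membrane_thickness = l1 + l2` and a
#'   `membrane_model` function implementing sigma_e*(f).
#' @examples
#' cm <- cell_model(radius = 5e-6, membrane_thickness = 5e-9, dimension = 2,
#'                  membrane = material(1e-7, 5), cytoplasm = material(1, 80),
#'                  medium = material(1, 80))
#' eq <- equivalent_cell(cm, l2 = 15e-9)   # 1:3 thickness ratio
#' eq$membrane_thickness                    # 2e-08
#' @export
equivalent_cell <- function(cell, l2) {
  stopifnot(inherits(cell, "cell_model"))
  if (!is.null(cell$membrane_model))
    stop("'cell' already carries an equivalent membrane; ",
         "apply the transform to the original model", call. = FALSE)
  if (!is.finite(l2) || l2 < 0)
    stop("'l2' must be a non-negative thickness in m", call. = FALSE)
  if (l2 == 0) return(cell)
  l1 <- cell$membrane_thickness
  if (l1 + l2 >= cell$radius)
    stop(sprintf("l1 + l2 = %g m must be smaller than the governing radius %g m",
                 l1 + l2, cell$radius), call. = FALSE)
  spec <- equivalence_spec(l1, l2, cell$membrane, cell$cytoplasm)
  mem_fun <- function(f) equivalent_conductivity(spec, f)
  out <- cell
  out$membrane_thickness <- l1 + l2
  out$membrane_model <- mem_fun
  out$equivalence <- spec
  out
}

#' Series impedance of a flat layered stack
#'
#' Per-unit-area complex impedance of flat dielectric layers in series,
#' Z = sum(l_k / sigma_k*). Exposed as the independent reference for the
#' flat-slab exactness of the thin-shell substitution.
#'
#' @param thicknesses Layer thicknesses in m.
#' @param materials List of [material()]s, one per layer.
#' @param f Frequency in Hz (> 0), scalar.
#' @return Complex impedance times area, in Ohm m^2.
#' @export
stack_impedance <- function(thicknesses, materials, f) {
  stopifnot(length(thicknesses) == length(materials))
  check_frequency(f)
  stopifnot(length(f) == 1L)
  z <- 0 + 0i
  for (k in seq_along(materials))
    z <- z + thicknesses[k] / complex_conductivity(materials[[k]], f)
  z
}
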
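# Pillar geometry and Euler-Bernoulli bending stiffness.

#' Micropillar geometry
#'
#' @param diameter_um pillar diameter D in um.
#' @param height_um pillar height L in um.
#' @param youngs_modulus_pa Young's modulus E of the cured elastomer in Pa.
#' @param pitch_um lattice centre-to-centre distance in um.
#' @param lattice_type \code{"square"} or \code{"hexagonal"}.
#' @param stiffness_override optional bending stiffness in nN/um to use
#'   instead of the beam-theory formula (e.g. an independently calibrated
#'   or published value).
#' @return Object of class \code{pillar_geometry}.
#' @export
pillar_geometry <- function(diameter_um = 0.9, height_um = 1,
                            youngs_modulus_pa = 2e6, pitch_um = 1.8,
                            lattice_type = c("square", "hexagonal"),
                            stiffness_override = NULL) {
  lattice_type <- match.arg(lattice_type)
  vals <- c(diameter_um, height_um, youngs_modulus_pa, pitch_um)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop_cellmech("pillar geometry values must be positive",
                  "cellmech_spec_error")
  structure(list(diameter_um = diameter_um, height_um = height_um,
                 youngs_modulus_pa = youngs_modulus_pa, pitch_um = pitch_um,
                 lattice_type = lattice_type,
                 stiffness_override = stiffness_override),
            class = "pillar_geometry")
}

#' Bending stiffness of a cylindrical micropillar
#'
#' Euler-Bernoulli cantilever with circular cross-section:
#' \deqn{k = 3 E I / L^3, \quad I = \pi D^4 / 64
#'       \quad\Rightarrow\quad k = \frac{3}{64} \pi E \frac{D^4}{L^3}.}
#' Returned in nN/um (1 Pa = 1e-3 nN/um^2, so k[nN/um] =
#' (3/64) pi (E[Pa] 1e-3) D^4 / L^3 with D, L in um).
#'
#' If the geometry carries a \code{stiffness_override}, that value is
#' returned instead, with a provenance note; when the override disagrees
#' with the formula by more than 1\% a discrepancy message reports both
#' values and their ratio, so that inconsistent published stiffness /
#' geometry combinations are surfaced rather than silently adopted.
#'
#' @param geom a \code{\link{pillar_geometry}}.
#' @param quiet suppress the discrepancy message.
#' @return Stiffness in nN/um with attributes \code{source}
#'   (\code{"formula"} or \code{"override"}), \code{formula_value_nN_um}
#'   and, for overrides, \code{note}.
#' @export
pillar_stiffness <- function(geom, quiet = FALSE) {
  stopifnot(inherits(geom, "pillar_geometry"))
  E_nN_um2 <- geom$youngs_modulus_pa * 1e-3
  k_formula <- (3 / 64) * pi * E_nN_um2 *
    geom$diameter_um^4 / geom$height_um^3
  if (is.null(geom$stiffness_override))
    return(structure(k_formula, source = "formula",
                     formula_value_nN_um = k_formula))
  k <- geom$stiffness_override
  note <- NULL
  if (abs(k / k_formula - 1) > 0.01) {
    note <- sprintf(paste0(
      "stiffness override %.4g nN/um differs from the Euler-Bernoulli ",
      "value %.4g nN/um for D = %.3g um, L = %.3g um, E = %.3g Pa ",
      "(ratio %.3g); check geometry or calibration"),
      k, k_formula, geom$diameter_um, geom$height_um,
      geom$youngs_modulus_pa, k_formula / k)
    if (!quiet) message(note)
  }
  structure(k, source = "override", formula_value_nN_um = k_formula,
            note = note)
}

#' Traction force from a pillar deflection
#'
#' F = k d, componentwise for vectors, k |d| for magnitudes.
#'
#' @param displacement_um deflection in um (scalar or vector).
#' @param stiffness_nN_um bending stiffness in nN/um.
#' @return Force in nN, same shape as \code{displacement_um}.
#' @export
traction_force <- function(displacement_um, stiffness_nN_um) {
  as.numeric(stiffness_nN_um) * displacement_um
}
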
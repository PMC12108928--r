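# Neo-Hookean hyperelastic helpers for the leaflet material card.
# These document and convert the constitutive parameters of the leaflet
# tissue; the fatigue pipeline itself consumes only the S-N / fracture
# constants in `material_properties()`.

#' Neo-Hookean parameters from shear modulus and Poisson's ratio
#'
#' One-term neo-Hookean strain energy uses `C10 = mu0 / 2` and
#' `D1 = 3 (1 - 2 nu) / (mu0 (nu + 1))`; the incompressible limit
#' `nu = 0.5` gives `D1 = 0`.
#'
#' @param mu0 Initial shear modulus, MPa, positive.
#' @param nu Poisson's ratio in `[0, 0.5]`.
#' @return A list with `c10` (MPa) and `d1` (1/MPa).
#' @export
#' @examples
#' neo_hookean_params(2, 0.5)  # c10 = 1, d1 = 0
neo_hookean_params <- function(mu0, nu) {
  if (mu0 <= 0) stop("`mu0` must be positive", call. = FALSE)
  if (nu < 0 || nu > 0.5) stop("`nu` must lie in [0, 0.5]", call. = FALSE)
  list(c10 = mu0 / 2, d1 = 3 * (1 - 2 * nu) / (mu0 * (nu + 1)))
}

#' Neo-Hookean strain energy per unit reference volume
#'
#' `U = c10 (I1 - 3) + (1 / d1) (Jel - 1)^2`, with `I1` the first deviatoric
#' strain invariant and `Jel` the elastic volume ratio. For `d1 = 0`
#' (incompressible) the volumetric term is only defined at `j_el = 1`, where
#' it vanishes; any other `j_el` violates incompressibility and errors.
#'
#' @param c10 MPa.
#' @param d1 1/MPa, non-negative.
#' @param i1 First deviatoric invariant, `>= 3` for admissible states.
#' @param j_el Elastic volume ratio, positive.
#' @return Strain energy density `U` in MPa.
#' @export
neo_hookean_energy <- function(c10, d1, i1, j_el) {
  if (j_el <= 0) stop("`j_el` must be positive", call. = FALSE)
  if (i1 < 3) stop("`i1` must be >= 3 for an admissible isochoric state",
                   call. = FALSE)
  vol <- if (d1 == 0) {
    if (j_el != 1) {
      stop("d1 = 0 (incompressible) requires j_el = 1", call. = FALSE)
    }
    0
  } else {
    (1 / d1) * (j_el - 1)^2
  }
  c10 * (i1 - 3) + vol
}
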
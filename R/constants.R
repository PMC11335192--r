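# Physical constants (CODATA 2018)
.FARADAY_C_PER_MOL <- 96485.33212
.GAS_R_J_PER_MOL_K <- 8.314462618

#' Boltzmann slope factor from an effective valence
#'
#' Converts the effective valence `z_eff` of a voltage-dependent charge
#' movement into the slope factor of the corresponding Boltzmann Q-V
#' relationship, `sigma = RT / (z_eff * F)`, expressed in mV.
#'
#' @param z_eff Effective valence of the moving charge (dimensionless, > 0).
#' @param temperature_K Absolute temperature in kelvin. Default 291.15 K
#'   (18 degrees C, the standard oocyte incubation temperature).
#' @return Slope factor in mV.
#' @seealso [z_from_slope_factor()]
#' @export
#' @examples
#' slope_factor_mV(1)        # ~25.1 mV at 18 C
slope_factor_mV <- function(z_eff, temperature_K = 291.15) {
  stopifnot(is.numeric(z_eff), all(z_eff > 0), temperature_K > 0)
  1000 * .GAS_R_J_PER_MOL_K * temperature_K / (z_eff * .FARADAY_C_PER_MOL)
}

#' Effective valence from a Boltzmann slope factor
#'
#' Inverse of [slope_factor_mV()]: `z_eff = RT / (sigma * F)` with `sigma`
#' in mV.
#'
#' @param sigma_mV Boltzmann slope factor in mV (> 0).
#' @inheritParams slope_factor_mV
#' @return Effective valence (dimensionless).
#' @export
z_from_slope_factor <- function(sigma_mV, temperature_K = 291.15) {
  stopifnot(is.numeric(sigma_mV), all(sigma_mV > 0), temperature_K > 0)
  1000 * .GAS_R_J_PER_MOL_K * temperature_K / (sigma_mV * .FARADAY_C_PER_MOL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
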
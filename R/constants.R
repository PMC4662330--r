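#' Physical constants of water at 20 degrees Celsius
#'
#' Density and dynamic viscosity of water used in the Hagen-Poiseuille
#' conductivity calculation. Viscosity is expressed in MPa s so that
#' conductivities come out in kg m s^-1 MPa^-1, the unit convention of
#' needle hydraulic anatomy.
#'
#' @param rho Water density, kg m^-3. Default 998.205 (20 degrees C).
#' @param eta Water dynamic viscosity, MPa s. Default 1.002e-9 (20 degrees C;
#'   equal to the familiar 1.002e-3 Pa s).
#'
#' @return An object of class `water_constants`: a list with elements `rho`
#'   and `eta`.
#' @examples
#' water_constants()
#' @export
water_constants <- function(rho = 998.205, eta = 1.002e-9) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0) {
    abort("`rho` must be a single positive finite number (kg m^-3).")
  }
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) || eta <= 0) {
    abort("`eta` must be a single positive finite number (MPa s).")
  }
  structure(list(rho = rho, eta = eta), class = "water_constants")
}

#' @export
print.water_constants <- function(x, ...) {
  cat("Water constants: rho =", x$rho, "kg m^-3, eta =", x$eta, "MPa s\n")
  invisible(x)
}
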
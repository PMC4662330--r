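#' Orient a pair of lumen diameters
#'
#' Returns the pair ordered as (maximum, minimum). Measurement tables
#' sometimes record the two lumen axes in arbitrary order; the conductivity
#' formula requires `d_max >= d_min`.
#'
#' @param d1,d2 Numeric vectors of lumen diameters, um. Both must be positive
#'   and finite.
#'
#' @return A tibble with columns `d_max` and `d_min` (um). Idempotent:
#'   applying it to its own output changes nothing.
#' @examples
#' orient_tracheid(3.8, 6.2)
#' @export
orient_tracheid <- function(d1, d2) {
  if (!is.numeric(d1) || !is.numeric(d2) || length(d1) != length(d2)) {
    abort("`d1` and `d2` must be numeric vectors of equal length.")
  }
  bad <- !is.finite(d1) | !is.finite(d2) | d1 <= 0 | d2 <= 0
  if (any(bad)) {
    abort(sprintf("Diameters must be positive and finite (first offending pair at position %d).",
                  which(bad)[1]))
  }
  tibble::tibble(d_max = pmax(d1, d2), d_min = pmin(d1, d2))
}

#' Theoretical hydraulic conductivity of an elliptical tracheid lumen
#'
#' Hagen-Poiseuille conductivity of a single conduit,
#' \deqn{k_t = \frac{\pi \rho}{8 \eta} r_{lum}^4,}
#' with the elliptical-lumen modification
#' \deqn{r_{lum}^4 = \frac{d_{max}^3 d_{min}^3}{8 d_{max}^2 + 8 d_{min}^2}.}
#' Diameters are converted from um to m before evaluation, so with the
#' default [water_constants()] the result is in kg m s^-1 MPa^-1 and
#' single-tracheid values land on the 1e-12 to 1e-11 scale typical of
#' conifer needle tracheids. For a circular lumen (`d_max == d_min`) the
#' expression reduces exactly to the classical \eqn{(\pi\rho/8\eta)(d/2)^4}.
#'
#' @param d_max,d_min Maximum and minimum lumen diameter, um. Vectorised;
#'   every pair must satisfy `d_max >= d_min > 0`. Use [orient_tracheid()]
#'   first if the order is not guaranteed.
#' @param constants A [water_constants()] object.
#'
#' @return Numeric vector of conductivities, kg m s^-1 MPa^-1.
#' @examples
#' tracheid_conductivity(6.2, 3.8)
#' @export
tracheid_conductivity <- function(d_max, d_min, constants = water_constants()) {
  if (!inherits(constants, "water_constants")) {
    abort("`constants` must be created by water_constants().")
  }
  if (!is.numeric(d_max) || !is.numeric(d_min) || length(d_max) != length(d_min)) {
    abort("`d_max` and `d_min` must be numeric vectors of equal length.")
  }
  bad <- !is.finite(d_max) | !is.finite(d_min) | d_min <= 0 | d_max <= 0
  if (any(bad)) {
    abort(sprintf("Diameters must be positive and finite (first offending pair at position %d).",
                  which(bad)[1]))
  }
  if (any(d_max < d_min)) {
    abort(sprintf(paste0("`d_max` must be >= `d_min` for every tracheid ",
                         "(first violation at position %d); use orient_tracheid()."),
                  which(d_max < d_min)[1]))
  }
  dmx <- d_max * 1e-6
  dmn <- d_min * 1e-6
  r4 <- dmx^3 * dmn^3 / (8 * dmx^2 + 8 * dmn^2)
  (pi * constants$rho / (8 * constants$eta)) * r4
}
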
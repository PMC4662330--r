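#' Reference group means for spruce sun/shade needles under drought
#'
#' Published group means (with 95% confidence intervals) of the 14 needle
#' traits for the 2 x 2 design of canopy position (sun, shade) by treatment
#' (control, drought) in ~20-year-old Norway spruce. Values are stored as
#' printed, together with the print scale: e.g. `k_th` values are on the
#' 1e-11 scale, so a stored mean of 61 denotes 6.1e-10 kg m s^-1 MPa^-1.
#' These means calibrate the synthetic-data generator
#' ([reference_calibration()]) and are the inputs to the derived
#' percent-reduction and fold-difference statistics
#' ([results_comparisons()]).
#'
#' @return A tibble with columns `trait`, `canopy`, `treatment`, `mean`,
#'   `ci_lo`, `ci_hi`, `scale` (multiplier turning the printed value into
#'   absolute units) and `unit`.
#' @examples
#' reference_means()
#' @export
reference_means <- function() {
  path <- system.file("extdata", "spruce_reference_means.csv",
                      package = "needlehydro", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    trait = "c", canopy = "c", treatment = "c",
                    mean = "d", ci_lo = "d", ci_hi = "d",
                    scale = "d", unit = "c"))
}

#' Generator calibration targets from the reference group means
#'
#' Converts the printed reference means ([reference_means()]) into the
#' absolute-unit target means the synthetic-data generator needs: per group,
#' tracheid count `n_t`, diameters `d_max` and `d_min` (um), flatness `f_t`,
#' and areas `a_n`, `a_v` (mm^2), `a_x`, `a_p` (um^2).
#'
#' @return A tibble with one row per group (complete 2 x 2 design) and the
#'   eight target columns.
#' @examples
#' reference_calibration()
#' @export
reference_calibration <- function() {
  wide <- reference_means() |>
    dplyr::mutate(value = .data$mean * .data$scale) |>
    dplyr::select(dplyr::all_of(c("trait", "canopy", "treatment", "value"))) |>
    tidyr::pivot_wider(names_from = "trait", values_from = "value")
  wide |>
    dplyr::transmute(
      treatment = .data$treatment, canopy = .data$canopy,
      n_t = .data$N_t, d_max = .data$d_max, d_min = .data$d_min,
      f_t = .data$F_t, a_n = .data$A_n, a_v = .data$A_v,
      a_x = .data$A_x, a_p = .data$A_p
    ) |>
    dplyr::arrange(.data$canopy, .data$treatment)
}

#' Reference whole-tree accumulated sap flow
#'
#' Season totals (17 May to 7 August) of sap flow per unit crown projected
#' area for the control and drought plots, mm.
#'
#' @return A tibble with columns `treatment` and `total_mm`.
#' @export
sapflow_reference <- function() {
  tibble::tibble(treatment = c("control", "drought"), total_mm = c(198, 87))
}

validate_calibration <- function(calibration) {
  req <- c("treatment", "canopy", "n_t", "d_max", "d_min", "f_t",
           "a_n", "a_v", "a_x", "a_p")
  check_columns(calibration, req, "Calibration")
  if (nrow(calibration) != 4L ||
      nrow(dplyr::distinct(calibration[, c("treatment", "canopy")])) != 4L) {
    abort("Calibration must contain exactly one row per group of the 2 x 2 design.")
  }
  num <- calibration[, setdiff(req, c("treatment", "canopy"))]
  if (any(!vapply(num, is.numeric, logical(1))) || any(as.matrix(num) <= 0)) {
    abort("All calibration targets must be positive numbers.")
  }
  if (any(calibration$d_max < calibration$d_min)) {
    abort("Calibration requires d_max target >= d_min target in every group.")
  }
  if (any(calibration$f_t < 1)) abort("Calibration flatness targets must be >= 1.")
  if (any(calibration$a_v >= calibration$a_n)) {
    abort("Calibration requires a_v < a_n (mm^2) in every group.")
  }
  if (any(calibration$a_x + calibration$a_p > calibration$a_v * 1e6)) {
    abort("Calibration requires a_x + a_p <= a_v in every group.")
  }
  invisible(calibration)
}
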
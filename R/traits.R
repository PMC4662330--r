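tracheid_schema <- function() {
  c(id_cols(), "tracheid_id", "d_max_um", "d_min_um", "a_lum_um2")
}

needle_schema <- function() {
  c(id_cols(), "family", "a_n_mm2", "a_v_mm2", "a_x_um2", "a_p_um2")
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing column(s): %s.", what,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Validate tracheid- and needle-level measurement tables
#'
#' Checks the structural invariants a needle cross-section must satisfy:
#' positive oriented diameters (`d_max >= d_min > 0`) and positive lumen
#' areas per tracheid; per needle, a vascular cylinder smaller than the
#' needle section (`a_v < a_n`), xylem plus phloem fitting inside the
#' vascular cylinder (`a_x + a_p <= a_v`), total lumen area not exceeding
#' xylem area, positive xylem area, and at least one tracheid.
#'
#' @param tracheids Tracheid table: columns `treatment`, `canopy`, `tree_id`,
#'   `shoot_id`, `needle_id`, `tracheid_id`, `d_max_um`, `d_min_um`,
#'   `a_lum_um2`.
#' @param needles Needle table: columns `treatment`, `canopy`, `tree_id`,
#'   `shoot_id`, `needle_id`, `family`, `a_n_mm2`, `a_v_mm2`, `a_x_um2`,
#'   `a_p_um2`.
#'
#' @return Invisibly `TRUE`; aborts with an informative message on the first
#'   violated invariant.
#' @export
validate_needle_tables <- function(tracheids, needles) {
  check_columns(tracheids, tracheid_schema(), "Tracheid table")
  check_columns(needles, needle_schema(), "Needle table")

  with(tracheids, {
    if (any(!is.finite(d_max_um) | !is.finite(d_min_um) | d_min_um <= 0)) {
      abort("Tracheid diameters must be finite and positive.")
    }
    if (any(d_max_um < d_min_um)) {
      abort("Tracheid table contains d_max_um < d_min_um; orient diameters first.")
    }
    if (any(!is.finite(a_lum_um2) | a_lum_um2 <= 0)) {
      abort("Tracheid lumen areas must be finite and positive.")
    }
  })

  if (any(needles$a_x_um2 <= 0)) abort("Needle table contains non-positive xylem area (a_x_um2).")
  if (any(needles$a_v_mm2 >= needles$a_n_mm2)) {
    abort("Needle table violates a_v < a_n for at least one needle.")
  }
  if (any(needles$a_x_um2 + needles$a_p_um2 > needles$a_v_mm2 * 1e6 * (1 + 1e-9))) {
    abort("Needle table violates a_x + a_p <= a_v for at least one needle.")
  }

  lum <- tracheids |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols()))) |>
    dplyr::summarise(n_lum = sum(.data$a_lum_um2), .groups = "drop")
  joined <- dplyr::inner_join(needles, lum, by = id_cols())
  if (nrow(joined) < nrow(needles)) {
    abort("Every needle must have at least one tracheid; some needles have none.")
  }
  if (any(joined$n_lum > joined$a_x_um2 * (1 + 1e-9))) {
    abort("Total lumen area exceeds xylem area for at least one needle.")
  }
  invisible(TRUE)
}

#' Compute needle-level anatomical and hydraulic traits
#'
#' Aggregates a tracheid-level measurement table to one row per needle and
#' joins the needle-level areas, producing the standard trait set:
#' tracheid-level quantities are averaged (`d_max`, `d_min`, `A_lum`, and
#' flatness `F_t` as the mean of per-tracheid `d_max/d_min` ratios) or
#' summed (`N_lum`, and conductivity `k_th` as the sum of per-tracheid
#' [tracheid_conductivity()]); `N_t` is the tracheid count. Xylem-specific
#' conductivity is reported on two scales: `k_s = k_th / A_x` with `A_x`
#' left in um^2 (the reported-scale convention under which needle-level
#' values fall on the 1e-12 scale conventional in the needle-anatomy
#' literature) and `k_s_si` with `A_x` converted to m^2. Area proportions
#' `A_x_pct` and `A_p_pct` are percentages of the needle cross-section
#' after converting `A_n` to um^2.
#'
#' @inheritParams validate_needle_tables
#' @param constants A [water_constants()] object.
#' @param validate Run [validate_needle_tables()] first? Default `TRUE`.
#'
#' @return A tibble with one row per needle: identifier columns, `family`,
#'   the 14 traits `A_lum` (um^2), `A_n` (mm^2), `A_p` (um^2), `A_p_pct` (%),
#'   `A_v` (mm^2), `A_x` (um^2), `A_x_pct` (%), `d_max` (um), `d_min` (um),
#'   `F_t` (-), `k_th` (kg m s^-1 MPa^-1), `k_s` (reported scale), `N_lum`
#'   (um^2), `N_t` (count), plus `k_s_si` (kg m^-1 s^-1 MPa^-1).
#' @examples
#' sim <- simulate_needles(sim_config(seed = 1))
#' traits <- needle_traits(sim$tracheids, sim$needles)
#' @export
needle_traits <- function(tracheids, needles, constants = water_constants(),
                          validate = TRUE) {
  if (validate) validate_needle_tables(tracheids, needles)

  agg <- tracheids |>
    dplyr::mutate(k_t = tracheid_conductivity(.data$d_max_um, .data$d_min_um,
                                              constants)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols()))) |>
    dplyr::summarise(
      A_lum = mean(.data$a_lum_um2),
      d_max = mean(.data$d_max_um),
      d_min = mean(.data$d_min_um),
      F_t   = mean(.data$d_max_um / .data$d_min_um),
      N_t   = dplyr::n(),
      N_lum = sum(.data$a_lum_um2),
      k_th  = sum(.data$k_t),
      .groups = "drop"
    )

  needles |>
    dplyr::inner_join(agg, by = id_cols()) |>
    dplyr::mutate(
      A_n = .data$a_n_mm2,
      A_v = .data$a_v_mm2,
      A_x = .data$a_x_um2,
      A_p = .data$a_p_um2,
      A_x_pct = 100 * .data$A_x / (.data$A_n * 1e6),
      A_p_pct = 100 * .data$A_p / (.data$A_n * 1e6),
      k_s = .data$k_th / .data$A_x,
      k_s_si = .data$k_th / (.data$A_x * 1e-12)
    ) |>
    dplyr::select(dplyr::all_of(c(id_cols(), "family", trait_names(), "k_s_si")))
}

#' Read and write the standard measurement and trait tables
#'
#' Thin readr wrappers fixing the column types of the three CSV schemas used
#' throughout the package (tracheid table, needle table, trait table).
#'
#' @param path File path.
#' @name table_io
#' @return A tibble (`read_*`), or the input invisibly (`write_*`).
#' @export
read_tracheid_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          treatment = "c", canopy = "c", tree_id = "c",
                          shoot_id = "c", needle_id = "c", tracheid_id = "c",
                          .default = "d"))
  check_columns(df, tracheid_schema(), "Tracheid table")
  df
}

#' @rdname table_io
#' @export
read_needle_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          treatment = "c", canopy = "c", tree_id = "c",
                          shoot_id = "c", needle_id = "c", family = "c",
                          .default = "d"))
  check_columns(df, needle_schema(), "Needle table")
  df
}

#' @rdname table_io
#' @param df Table to write.
#' @export
write_trait_table <- function(df, path) {
  readr::write_csv(df, path)
  invisible(df)
}
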
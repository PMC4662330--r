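cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# lognormal draws with expectation `mean` (mean-one multiplicative noise when
# mean = 1)
rlnorm_mean <- function(n, mean, sdlog) {
  if (sdlog == 0) return(rep(mean, length.out = n))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Configuration for the hierarchical needle simulator
#'
#' Encodes the sampling design (trees per plot, shoots per tree and canopy
#' position, needles per shoot) and the distributional parameters of the
#' generator. The defaults reproduce the field design the package targets:
#' 2 treatments x 3 trees x 2 canopy positions x 5 shoots x 7 needles
#' (420 needles in all).
#'
#' @param trees_per_plot Trees per treatment plot. Default 3.
#' @param shoots_per_tree Shoots sampled per tree and canopy position.
#'   Default 5.
#' @param needles_per_shoot Needles per shoot. Default 7.
#' @param tree_cv,shoot_cv Coefficients of variation of the multiplicative
#'   lognormal tree- and shoot-level random effects (mean 1). The effect
#'   scales linear dimensions by its square root and tracheid count
#'   proportionally, so area-level traits vary roughly twice as much between
#'   trees as diameters do. Defaults 0.08 and 0.05.
#' @param tracheid_cv Within-needle coefficient of variation of the minimum
#'   lumen diameter. Default 0.25.
#' @param count_cv Coefficient of variation of the per-needle tracheid count
#'   around its group target (rounded, minimum 1). Default 0.12.
#' @param flatness_sdlog Log-scale spread of the per-tracheid flatness excess
#'   (`F_t - 1`). Default 0.8; must be large enough for the within-group
#'   diameter/flatness correlation to be solvable (see
#'   [simulate_needles()]).
#' @param packing_mean Mean lumen packing fraction (total lumen area / xylem
#'   area). `NULL` (default) calibrates it per group from the group's
#'   expected lumen area and its xylem-area target so that xylem and the
#'   downstream areas recover their targets; a number overrides all groups.
#' @param packing_cv Coefficient of variation of the per-needle packing draw.
#'   Default 0.08.
#' @param area_cv Residual lognormal noise on the needle-level areas `a_n`,
#'   `a_v`, `a_p` around their calibration ratios to `a_x`. Default 0.06.
#' @param max_packing Feasibility bound on the packing fraction. Default 0.6.
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' sim_config(seed = 42)
#' @export
sim_config <- function(trees_per_plot = 3, shoots_per_tree = 5,
                       needles_per_shoot = 7, tree_cv = 0.08, shoot_cv = 0.05,
                       tracheid_cv = 0.25, count_cv = 0.12,
                       flatness_sdlog = 0.8, packing_mean = NULL,
                       packing_cv = 0.08, area_cv = 0.06, max_packing = 0.6,
                       seed = 1L) {
  counts <- c(trees_per_plot, shoots_per_tree, needles_per_shoot)
  if (any(counts < 1) || any(counts != round(counts))) {
    abort("Design counts must be integers >= 1.")
  }
  cvs <- c(tree_cv, shoot_cv, tracheid_cv, count_cv, packing_cv, area_cv)
  if (any(cvs < 0)) abort("Coefficients of variation must be >= 0.")
  if (flatness_sdlog < 0) abort("`flatness_sdlog` must be >= 0.")
  if (!is.null(packing_mean) &&
      (packing_mean <= 0 || packing_mean >= 1)) {
    abort("`packing_mean` must lie in (0, 1).")
  }
  if (max_packing <= 0 || max_packing > 1) abort("`max_packing` must be in (0, 1].")
  if (length(seed) != 1L || !is.finite(seed)) abort("`seed` must be a single integer.")
  structure(list(
    trees_per_plot = as.integer(trees_per_plot),
    shoots_per_tree = as.integer(shoots_per_tree),
    needles_per_shoot = as.integer(needles_per_shoot),
    tree_cv = tree_cv, shoot_cv = shoot_cv, tracheid_cv = tracheid_cv,
    count_cv = count_cv, flatness_sdlog = flatness_sdlog,
    packing_mean = packing_mean, packing_cv = packing_cv, area_cv = area_cv,
    max_packing = max_packing, seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("Needle simulation config: 2 treatments x %d trees x 2 canopy ",
                     "positions x %d shoots x %d needles (seed %d)\n"),
              x$trees_per_plot, x$shoots_per_tree, x$needles_per_shoot, x$seed))
  invisible(x)
}

# Per-group distribution parameters. Within a group the per-tracheid pair
# (d_min, flatness) is drawn from a Gaussian-copula lognormal model whose
# correlation is solved so that E[d_min], E[d_max] = E[d_min * flatness] and
# E[flatness] all hit their targets simultaneously: with
# d_min = m exp(s z - s^2/2) and flatness = 1 + k exp(t w), w correlated r
# with z, matching the three targets requires
# s t r = log((d_max/d_min - 1) / (f_t - 1)), which is negative whenever the
# mean flatness exceeds the ratio of mean diameters (flat tracheids tend to
# be the narrow ones). If |r| would exceed 1 it is clamped: the diameter
# means are then still exact but the flatness mean drifts toward the
# diameter ratio (the zero-variance limit forces F_t = d_max/d_min).
group_sim_params <- function(row, config) {
  s <- cv_to_sdlog(config$tracheid_cv)
  t <- config$flatness_sdlog
  ratio_excess <- row$d_max / row$d_min - 1
  flat_excess <- row$f_t - 1
  str_needed <- if (ratio_excess > 0 && flat_excess > 0) {
    log(ratio_excess / flat_excess)
  } else 0
  r <- if (s * t > 0) max(-1, min(1, str_needed / (s * t))) else 0
  str_used <- s * t * r
  clamped <- s * t > 0 && abs(str_needed / (s * t)) > 1
  k <- ratio_excess * exp(-t^2 / 2 - str_used)
  e_alum <- pi / 4 * row$d_min^2 * exp(s^2) * (1 + ratio_excess * exp(str_used))
  # expected per-needle total lumen area carries the second moment of the
  # mean-one tree x shoot effect (count ~ e, lumen area ~ e)
  e2 <- (1 + config$tree_cv^2) * (1 + config$shoot_cv^2)
  p0 <- if (is.null(config$packing_mean)) {
    row$n_t * e_alum * e2 / row$a_x
  } else {
    config$packing_mean
  }
  if (!is.finite(p0) || p0 <= 0 || p0 > config$max_packing) {
    abort(sprintf(paste0("Infeasible calibration for group %s/%s: implied lumen ",
                         "packing fraction %.3f outside (0, %.2f] - the a_x target ",
                         "is too small for the expected total lumen area."),
                  row$canopy, row$treatment, p0, config$max_packing))
  }
  list(s = s, t = t, r = r, k = k, e_alum = e_alum, p0 = p0, clamped = clamped)
}

#' Simulate a hierarchical needle-anatomy dataset
#'
#' Generates tracheid- and needle-level measurement tables with the study's
#' nested design (treatment plot, tree, canopy position, shoot, needle,
#' tracheid) and the variance structure a shoot-within-tree mixed model
#' assumes. Sizes are lognormal; tree and shoot effects are multiplicative
#' lognormal with mean one; per tracheid, the minimum diameter and the
#' flatness excess are drawn jointly with a group-specific negative
#' correlation so that the group means of `d_min`, `d_max` and mean-of-ratio
#' flatness all match the calibration targets (see the methods vignette).
#' Lumen areas are exact ellipse areas `pi * d_max * d_min / 4`; xylem area
#' is total lumen area divided by a per-needle packing-fraction draw, and
#' the remaining section areas scale from xylem area by the calibration's
#' area ratios with lognormal noise.
#'
#' @param config A [sim_config()].
#' @param calibration Group target means, one row per cell of the 2 x 2
#'   design; default [reference_calibration()].
#'
#' @return An object of class `needle_sim`: a list with tibbles `tracheids`
#'   and `needles` in the standard schemas, plus the `config` and
#'   `calibration` used. Output is byte-identical for identical inputs.
#' @examples
#' sim <- simulate_needles(sim_config(seed = 7))
#' nrow(sim$needles)  # 420 needles under the default design
#' @export
simulate_needles <- function(config = sim_config(),
                             calibration = reference_calibration()) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config().")
  validate_calibration(calibration)
  params <- lapply(seq_len(nrow(calibration)), function(i) {
    group_sim_params(calibration[i, ], config)
  })
  if (any(vapply(params, `[[`, logical(1), "clamped"))) {
    warn(paste("Diameter/flatness correlation clamped at -1 for at least one",
               "group; mean flatness will sit below its target. Increase",
               "`flatness_sdlog` or `tracheid_cv` to restore it."))
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  families <- c("15", "27", "29")
  trees <- tidyr::expand_grid(
    treatment = c("control", "drought"),
    tree_num = seq_len(config$trees_per_plot)
  ) |>
    dplyr::mutate(
      tree_id = sprintf("%s_T%02d", .data$treatment, .data$tree_num),
      family = families[(.data$tree_num - 1L) %% length(families) + 1L],
      e_tree = rlnorm_mean(dplyr::n(), 1, cv_to_sdlog(config$tree_cv))
    )

  shoots <- tidyr::expand_grid(
    trees, canopy = c("sun", "shade"),
    shoot_num = seq_len(config$shoots_per_tree)
  ) |>
    dplyr::mutate(
      # ids carry the canopy so shoots from the two crown positions of one
      # tree are never pooled by the shoot-within-tree random effect
      shoot_id = sprintf("%s_S%d", .data$canopy, .data$shoot_num),
      e_shoot = rlnorm_mean(dplyr::n(), 1, cv_to_sdlog(config$shoot_cv))
    )

  needles <- tidyr::expand_grid(
    shoots, needle_num = seq_len(config$needles_per_shoot)
  ) |>
    dplyr::mutate(needle_id = sprintf("N%d", .data$needle_num)) |>
    dplyr::left_join(calibration, by = c("treatment", "canopy")) |>
    dplyr::mutate(
      group = match(paste(.data$treatment, .data$canopy),
                    paste(calibration$treatment, calibration$canopy)),
      e = .data$e_tree * .data$e_shoot,
      n_tracheids = pmax(1L, as.integer(round(rlnorm_mean(
        dplyr::n(), .data$n_t * .data$e, cv_to_sdlog(config$count_cv)))))
    )

  # tracheid-level draws, fully vectorised over the expanded table
  tr <- needles[rep(seq_len(nrow(needles)), needles$n_tracheids), ] |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols()))) |>
    dplyr::mutate(tracheid_id = sprintf("L%d", dplyr::row_number())) |>
    dplyr::ungroup()
  par_of <- function(name) {
    vapply(params, `[[`, numeric(1), name)[tr$group]
  }
  s <- par_of("s"); tt <- par_of("t"); r <- par_of("r"); k <- par_of("k")
  z <- rnorm(nrow(tr)); u <- rnorm(nrow(tr))
  w <- r * z + sqrt(pmax(0, 1 - r^2)) * u
  lin <- sqrt(tr$e)
  dmin_draw <- tr$d_min * lin * exp(s * z - s^2 / 2)
  dmax_draw <- dmin_draw * (1 + k * exp(tt * w))
  tracheids <- tr |>
    dplyr::mutate(d_max_um = .env$dmax_draw, d_min_um = .env$dmin_draw,
                  a_lum_um2 = pi * .env$dmax_draw * .env$dmin_draw / 4) |>
    dplyr::select(dplyr::all_of(tracheid_schema()))

  n_lum <- tracheids |>
    dplyr::group_by(dplyr::across(dplyr::all_of(id_cols()))) |>
    dplyr::summarise(n_lum = sum(.data$a_lum_um2), .groups = "drop")
  p0 <- vapply(params, `[[`, numeric(1), "p0")
  needle_tab <- needles |>
    dplyr::inner_join(n_lum, by = id_cols()) |>
    dplyr::mutate(
      inv_packing = rlnorm_mean(dplyr::n(), 1 / p0[.data$group],
                                cv_to_sdlog(config$packing_cv)),
      a_x_um2 = pmax(.data$n_lum * .data$inv_packing,
                     .data$n_lum / config$max_packing),
      a_n_mm2 = .data$a_x_um2 * (.data$a_n * 1e6 / .data$a_x) *
        rlnorm_mean(dplyr::n(), 1, cv_to_sdlog(config$area_cv)) / 1e6,
      a_v_mm2 = .data$a_x_um2 * (.data$a_v * 1e6 / .data$a_x) *
        rlnorm_mean(dplyr::n(), 1, cv_to_sdlog(config$area_cv)) / 1e6,
      a_p_um2 = .data$a_x_um2 * (.data$a_p / .data$a_x) *
        rlnorm_mean(dplyr::n(), 1, cv_to_sdlog(config$area_cv)),
      # constraint projection; inactive under sane calibrations
      a_v_mm2 = pmax(.data$a_v_mm2, (.data$a_x_um2 + .data$a_p_um2) * 1.001 / 1e6),
      a_n_mm2 = pmax(.data$a_n_mm2, .data$a_v_mm2 * 1.001)
    ) |>
    dplyr::select(dplyr::all_of(needle_schema()))

  structure(list(tracheids = tracheids, needles = needle_tab,
                 config = config, calibration = calibration),
            class = "needle_sim")
}

#' @export
print.needle_sim <- function(x, ...) {
  cat(sprintf("Simulated needle dataset: %d needles, %d tracheids (seed %d)\n",
              nrow(x$needles), nrow(x$tracheids), x$config$seed))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes `tracheids.csv` and `needles.csv` in the standard schemas plus a
#' JSON manifest recording the seed and every configuration field.
#'
#' @param sim A `needle_sim` from [simulate_needles()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(sim, dir) {
  if (!inherits(sim, "needle_sim")) abort("`sim` must be a needle_sim.")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tracheids = file.path(dir, "tracheids.csv"),
             needles = file.path(dir, "needles.csv"),
             manifest = file.path(dir, "simulation_manifest.json"))
  readr::write_csv(sim$tracheids, paths[["tracheids"]])
  readr::write_csv(sim$needles, paths[["needles"]])
  cfg <- sim$config
  class(cfg) <- NULL
  cfg$packing_mean <- if (is.null(cfg$packing_mean)) "auto" else cfg$packing_mean
  jsonlite::write_json(list(seed = sim$config$seed, config = cfg),
                       paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
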
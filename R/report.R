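#' Percent reduction of a group mean relative to control
#'
#' `100 * (control - drought) / control`. Negative values indicate an
#' increase under drought. Vectorised.
#'
#' @param control_mean,drought_mean Group means; `control_mean` must be
#'   positive.
#' @return Numeric percent reduction.
#' @examples
#' percent_reduction(61, 36)  # ~41
#' @export
percent_reduction <- function(control_mean, drought_mean) {
  if (!is.numeric(control_mean) || !is.numeric(drought_mean)) {
    abort("Means must be numeric.")
  }
  if (any(!is.finite(control_mean)) || any(control_mean <= 0)) {
    abort("`control_mean` must be positive and finite.")
  }
  100 * (control_mean - drought_mean) / control_mean
}

#' Fold difference between two group means
#'
#' `a / b`; by convention the larger-canopy (sun) mean goes in the
#' numerator when comparing canopy positions. Vectorised.
#'
#' @param a Numerator mean.
#' @param b Denominator mean; must be positive.
#' @return Numeric ratio.
#' @examples
#' fold_difference(61, 18)  # ~3.4
#' @export
fold_difference <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b)) abort("Means must be numeric.")
  if (any(!is.finite(b)) || any(b <= 0)) abort("`b` must be positive and finite.")
  a / b
}

round_by_rule <- function(value, rule) {
  switch(rule,
         "nearest integer" = round(value),
         "1 d.p." = round(value, 1),
         "2 d.p." = round(value, 2),
         abort(sprintf("Unknown rounding rule '%s'.", rule)))
}

#' Derived comparison statistics across the 2 x 2 group means
#'
#' Computes, for every trait in a group-means table, the drought percent
#' reduction within each canopy position, the sun/shade fold difference
#' within each treatment, the pooled sun/shade ratio (means pooled across
#' treatments before the ratio), and the cross-group mean. Computation is
#' exact; the conventional rounding (nearest integer for percentages, 1
#' decimal for folds, 2 for means) is applied only in the `printed` column
#' and the rule used is recorded alongside every value.
#'
#' @param means A group-means table with columns `trait`, `canopy`,
#'   `treatment`, `mean`; defaults to the bundled reference means
#'   ([reference_means()]), so the headline comparison statistics are
#'   reproducible without any data.
#' @return A tibble: `trait`, `kind`, `context` (canopy or treatment the
#'   comparison is conditioned on, or `"pooled"`/`"all groups"`), `value`
#'   (unrounded), `printed` (rounded), `rounding`.
#' @examples
#' comps <- results_comparisons()
#' subset(comps, trait == "k_th" & kind == "drought reduction")
#' @export
results_comparisons <- function(means = reference_means()) {
  check_columns(means, c("trait", "canopy", "treatment", "mean"), "Group means")
  cell <- function(tr, cn, tx) {
    v <- means$mean[means$trait == tr & means$canopy == cn & means$treatment == tx]
    if (length(v) != 1L) abort(sprintf("Expected one mean for %s/%s/%s.", tr, cn, tx))
    v
  }
  purrr::map_dfr(unique(means$trait), function(tr) {
    sc <- cell(tr, "sun", "control"); sd_ <- cell(tr, "sun", "drought")
    hc <- cell(tr, "shade", "control"); hd <- cell(tr, "shade", "drought")
    rows <- dplyr::bind_rows(
      tibble::tibble(kind = "drought reduction", context = c("sun", "shade"),
                     value = c(percent_reduction(sc, sd_),
                               percent_reduction(hc, hd)),
                     rounding = "nearest integer"),
      tibble::tibble(kind = "sun/shade fold", context = c("control", "drought"),
                     value = c(fold_difference(sc, hc),
                               fold_difference(sd_, hd)),
                     rounding = "1 d.p."),
      tibble::tibble(kind = "pooled sun/shade fold", context = "pooled",
                     value = fold_difference(mean(c(sc, sd_)), mean(c(hc, hd))),
                     rounding = "1 d.p."),
      tibble::tibble(kind = "cross-group mean", context = "all groups",
                     value = mean(c(sc, sd_, hc, hd)),
                     rounding = "2 d.p.")
    )
    rows |>
      dplyr::mutate(trait = tr, .before = 1) |>
      dplyr::mutate(printed = purrr::map2_dbl(.data$value, .data$rounding,
                                              round_by_rule),
                    .after = "value")
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> needle traits -> mixed-model report ->
#' derived comparisons, writing every table as CSV plus a JSON manifest to
#' `out_dir`. With identical inputs and seed, every output file is
#' reproduced byte-identically except the manifest's `created` timestamp.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [sim_config()]; its seed drives all randomness. Ignored
#'   when `tracheid_csv`/`needle_csv` are supplied.
#' @param calibration Generator calibration; default
#'   [reference_calibration()].
#' @param tracheid_csv,needle_csv Optional paths to measurement tables to
#'   analyse instead of simulating.
#' @param traits_to_test Traits to model; default all 14.
#' @return Invisibly, a list with the output `paths` and the in-memory
#'   `traits`, `report` and `comparisons` objects.
#' @examples
#' \donttest{
#' out <- run_pipeline(tempfile("ndl"), sim_config(seed = 1),
#'                     traits_to_test = c("A_n", "k_th"))
#' }
#' @export
run_pipeline <- function(out_dir, config = sim_config(),
                         calibration = reference_calibration(),
                         tracheid_csv = NULL, needle_csv = NULL,
                         traits_to_test = trait_names()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(tracheid_csv) != is.null(needle_csv)) {
    abort("Provide both `tracheid_csv` and `needle_csv`, or neither.")
  }
  if (is.null(tracheid_csv)) {
    sim <- simulate_needles(config, calibration)
    tracheids <- sim$tracheids
    needles <- sim$needles
    write_dataset(sim, out_dir)
    source_desc <- list(kind = "simulated", seed = config$seed)
  } else {
    if (!file.exists(tracheid_csv)) abort(sprintf("Input file not found: %s", tracheid_csv))
    if (!file.exists(needle_csv)) abort(sprintf("Input file not found: %s", needle_csv))
    tracheids <- read_tracheid_table(tracheid_csv)
    needles <- read_needle_table(needle_csv)
    source_desc <- list(kind = "loaded", tracheid_csv = tracheid_csv,
                        needle_csv = needle_csv)
  }

  traits <- needle_traits(tracheids, needles)
  report <- lme_report(traits, traits_to_test)
  sim_means <- report$means |>
    dplyr::select(dplyr::all_of(c("trait", "canopy", "treatment", "mean")))
  comparisons <- results_comparisons(sim_means)

  paths <- c(
    traits = file.path(out_dir, "traits.csv"),
    tests = file.path(out_dir, "lme_tests.csv"),
    means = file.path(out_dir, "group_means.csv"),
    comparisons = file.path(out_dir, "comparisons.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_csv(traits, paths[["traits"]])
  readr::write_csv(report$tests, paths[["tests"]])
  readr::write_csv(report$means, paths[["means"]])
  readr::write_csv(comparisons, paths[["comparisons"]])

  data_files <- setdiff(list.files(out_dir, full.names = TRUE),
                        paths[["manifest"]])
  manifest <- list(
    package = "needlehydro",
    version = as.character(utils::packageVersion("needlehydro")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), tz = "UTC"),
    source = source_desc,
    traits_tested = traits_to_test,
    n_needles = nrow(traits),
    md5 = as.list(setNames(unname(tools::md5sum(data_files)),
                           basename(data_files)))
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(paths = paths, traits = traits, report = report,
                 comparisons = comparisons))
}
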
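# Small hand-built measurement tables used across tests.

tiny_ids <- function(needle_id = "N1") {
  list(treatment = "control", canopy = "sun", tree_id = "T1",
       shoot_id = "S1", needle_id = needle_id)
}

tiny_tracheids <- function(d_max = c(6.2, 4.0), d_min = c(3.8, 4.0),
                           needle_id = "N1") {
  ids <- tiny_ids(needle_id)
  tibble::tibble(
    treatment = ids$treatment, canopy = ids$canopy, tree_id = ids$tree_id,
    shoot_id = ids$shoot_id, needle_id = ids$needle_id,
    tracheid_id = sprintf("L%d", seq_along(d_max)),
    d_max_um = d_max, d_min_um = d_min,
    a_lum_um2 = pi * d_max * d_min / 4
  )
}

tiny_needles <- function(a_n_mm2 = 0.35, a_v_mm2 = 0.019, a_x_um2 = 930,
                         a_p_um2 = 1270, needle_id = "N1") {
  ids <- tiny_ids(needle_id)
  tibble::tibble(
    treatment = ids$treatment, canopy = ids$canopy, tree_id = ids$tree_id,
    shoot_id = ids$shoot_id, needle_id = ids$needle_id, family = "15",
    a_n_mm2 = a_n_mm2, a_v_mm2 = a_v_mm2, a_x_um2 = a_x_um2,
    a_p_um2 = a_p_um2
  )
}

# calibration with every drought target set equal to its control target
null_calibration <- function() {
  cal <- reference_calibration()
  for (cn in c("sun", "shade")) {
    ctrl <- cal[cal$canopy == cn & cal$treatment == "control", -(1:2)]
    cal[cal$canopy == cn & cal$treatment == "drought", -(1:2)] <- ctrl
  }
  cal
}

# generator config with all stochastic components switched off
degenerate_config <- function(seed = 1) {
  sim_config(tree_cv = 0, shoot_cv = 0, tracheid_cv = 0, count_cv = 0,
             packing_cv = 0, area_cv = 0, flatness_sdlog = 0, seed = seed)
}

group_trait_means <- function(traits) {
  traits |>
    dplyr::group_by(canopy, treatment) |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), mean),
                     .groups = "drop")
}
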
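test_that("default design reproduces the study arithmetic", {
  sim <- simulate_needles(sim_config(seed = 1))
  expect_equal(nrow(sim$needles), 2 * 3 * 2 * 5 * 7)  # 420 needles
  per_tree_canopy <- sim$needles |>
    dplyr::count(treatment, tree_id, canopy)
  expect_true(all(per_tree_canopy$n == 35))  # 7 needles x 5 shoots
  expect_equal(length(unique(sim$needles$tree_id)), 6L)
  expect_setequal(unique(sim$needles$family), c("15", "27", "29"))
})

test_that("identical seed and config give identical output, new seed differs", {
  a <- simulate_needles(sim_config(seed = 99))
  b <- simulate_needles(sim_config(seed = 99))
  c <- simulate_needles(sim_config(seed = 100))
  expect_identical(a$tracheids, b$tracheids)
  expect_identical(a$needles, b$needles)
  expect_false(identical(a$tracheids, c$tracheids))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_needles(sim_config(seed = 7)))
  expect_identical(rnorm(1), before)
})

test_that("emitted tables satisfy every section invariant", {
  sim <- simulate_needles(sim_config(seed = 21))
  expect_true(validate_needle_tables(sim$tracheids, sim$needles))
  # synthetic lumens are exact ellipses
  expect_equal(sim$tracheids$a_lum_um2,
               pi * sim$tracheids$d_max_um * sim$tracheids$d_min_um / 4,
               tolerance = 1e-9)
})

test_that("zero-noise generator hits the calibration targets exactly", {
  sim <- simulate_needles(degenerate_config())
  traits <- needle_traits(sim$tracheids, sim$needles)
  cal <- reference_calibration()
  gm <- traits |>
    dplyr::group_by(canopy, treatment) |>
    dplyr::summarise(dplyr::across(c(d_max, d_min, N_t, A_n, A_v, A_x, A_p, F_t),
                                   mean), .groups = "drop") |>
    dplyr::inner_join(cal, by = c("canopy", "treatment"),
                      suffix = c("", "_target"))
  expect_equal(gm$d_max, gm$d_max_target)
  expect_equal(gm$d_min, gm$d_min_target)
  expect_equal(gm$N_t, round(gm$n_t))
  # areas match targets up to tracheid-count rounding
  count_ratio <- round(gm$n_t) / gm$n_t
  expect_equal(gm$A_n, gm$a_n * count_ratio, tolerance = 1e-9)
  expect_equal(gm$A_x, gm$a_x * count_ratio, tolerance = 1e-9)
  # with zero spread the flatness ratio collapses to the diameter ratio
  expect_equal(gm$F_t, gm$d_max_target / gm$d_min_target)
  # every needle within a group is identical
  spread <- traits |>
    dplyr::group_by(canopy, treatment) |>
    dplyr::summarise(s = sd(A_n), .groups = "drop")
  expect_true(all(spread$s < 1e-12))
})

test_that("between-tree variance grows with the tree-level CV", {
  v_between <- vapply(c(0, 0.05, 0.15), function(cv) {
    vs <- vapply(1:3, function(s) {
      sim <- simulate_needles(sim_config(trees_per_plot = 6, tree_cv = cv,
                                         seed = 300 + s))
      tree_means <- sim$needles |>
        dplyr::group_by(treatment, tree_id) |>
        dplyr::summarise(m = mean(a_n_mm2), .groups = "drop_last") |>
        dplyr::summarise(v = var(m), .groups = "drop")
      mean(tree_means$v)
    }, numeric(1))
    mean(vs)
  }, numeric(1))
  expect_true(all(diff(v_between) > 0))
})

test_that("infeasible calibrations are refused naming the group", {
  cal <- reference_calibration()
  cal$a_x[cal$canopy == "sun" & cal$treatment == "control"] <- 700
  expect_error(simulate_needles(sim_config(), cal), "sun/control")
  expect_error(simulate_needles(sim_config(), cal), "packing")
  # structural calibration errors
  bad <- reference_calibration()
  bad$d_min[1] <- bad$d_max[1] + 1
  expect_error(simulate_needles(sim_config(), bad), "d_max")
  expect_error(sim_config(trees_per_plot = 0), "counts")
  expect_error(sim_config(tree_cv = -0.1), "variation")
  expect_error(sim_config(packing_mean = 1.2), "packing_mean")
})

test_that("unsolvable flatness correlation warns and preserves diameters", {
  cfg <- sim_config(tracheid_cv = 0.05, flatness_sdlog = 0.1, seed = 2)
  expect_warning(sim <- simulate_needles(cfg), "clamped")
  gm <- sim$tracheids |>
    dplyr::filter(canopy == "sun", treatment == "control")
  expect_equal(mean(gm$d_max_um), 6.2, tolerance = 0.05)
})
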
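sim_traits <- function(seed = 1, ...) {
  sim <- simulate_needles(sim_config(seed = seed, ...))
  needle_traits(sim$tracheids, sim$needles)
}

test_that("zero random-effect data yield null variance components and
           fixed effects equal to group means", {
  traits <- sim_traits(seed = 2, tree_cv = 0, shoot_cv = 0)
  fit <- fit_trait_model(traits, "A_n", fixed = "canopy*drought", method = "REML")
  re_var <- fit$varcomp$variance[fit$varcomp$group != "Residual"]
  expect_true(all(re_var < 1e-3 * var(traits$A_n)))
  expect_true(fit$singular)  # flagged, not dropped
  gm <- group_means_ci(traits, "A_n")
  raw <- traits |>
    dplyr::group_by(canopy, treatment) |>
    dplyr::summarise(m = mean(A_n), .groups = "drop")
  cmp <- dplyr::inner_join(gm, raw, by = c("canopy", "treatment"))
  expect_equal(cmp$mean, cmp$m, tolerance = 1e-3)
})

test_that("likelihood-ratio ladder is well-formed", {
  traits <- sim_traits(seed = 3)
  for (trait in c("A_n", "k_th", "N_t")) {
    lad <- lrt_ladder(traits, trait)
    expect_equal(lad$factor, c("canopy", "drought", "interaction"))
    expect_true(all(lad$chisq >= 0))
    expect_true(all(lad$p_value >= 0 & lad$p_value <= 1))
    expect_true(all(lad$df == 1))
    expect_true(all(is.finite(lad$aic_simpler) & is.finite(lad$aic_complex)))
  }
})

test_that("a nested model never beats its parent on log-likelihood", {
  traits <- sim_traits(seed = 4)
  fits <- lapply(c("canopy", "drought", "canopy+drought", "canopy*drought"),
                 function(fx) fit_trait_model(traits, "A_n", fixed = fx,
                                              method = "ML"))
  names(fits) <- c("canopy", "drought", "add", "int")
  expect_gte(fits$add$logLik, fits$canopy$logLik - 1e-6)
  expect_gte(fits$add$logLik, fits$drought$logLik - 1e-6)
  expect_gte(fits$int$logLik, fits$add$logLik - 1e-6)
})

test_that("k_th is analysed on the log scale and back-transformed", {
  traits <- sim_traits(seed = 5)
  expect_equal(fit_trait_model(traits, "k_th")$transform, "log")
  expect_equal(fit_trait_model(traits, "A_n")$transform, "identity")
  gm <- group_means_ci(traits, "k_th")
  expect_true(all(gm$scale == "geometric"))
  expect_true(all(gm$mean > 0 & gm$ci_lo < gm$mean & gm$mean < gm$ci_hi))
  # forcing identity must change the scale flag
  gm2 <- group_means_ci(traits, "k_th", transform = "identity")
  expect_true(all(gm2$scale == "arithmetic"))
})

test_that("interval ordering holds for every reported group mean", {
  traits <- sim_traits(seed = 6)
  for (trait in c("A_n", "F_t", "k_s")) {
    gm <- group_means_ci(traits, trait)
    expect_equal(nrow(gm), 4L)
    expect_true(all(gm$ci_lo < gm$mean & gm$mean < gm$ci_hi))
  }
})

test_that("tidy and glance methods return the documented shapes", {
  traits <- sim_traits(seed = 7)
  fit <- fit_trait_model(traits, "A_n")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "statistic") %in% names(td)))
  expect_equal(nrow(td), 4L)  # intercept + canopy + treatment + interaction
  gl <- glance(fit)
  expect_equal(gl$nobs, 420L)
  rep_ <- lme_report(traits, traits_to_test = c("A_n", "N_t"))
  expect_equal(nrow(tidy(rep_)), 6L)
  expect_equal(glance(rep_)$n_traits, 2L)
  expect_s3_class(autoplot(rep_), "ggplot")
  expect_s3_class(plot_group_means(rep_$means), "ggplot")
})

test_that("underreplicated designs are refused", {
  traits <- sim_traits(seed = 8)
  one_tree <- traits |>
    dplyr::group_by(treatment) |>
    dplyr::filter(tree_id == dplyr::first(tree_id)) |>
    dplyr::ungroup()
  expect_error(fit_trait_model(one_tree, "A_n"), "2 trees")
  one_shoot <- traits |> dplyr::filter(shoot_id == "sun_S1")
  expect_error(fit_trait_model(one_shoot, "A_n"), "2 shoots")
})

test_that("sap-flow t-test: degenerate, symmetric and reduction cases", {
  same <- tibble::tibble(treatment = rep(c("a", "b"), each = 3),
                         total_mm = rep(c(100, 120, 110), 2))
  r <- sapflow_ttest(same)
  expect_equal(r$t, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$percent_reduction, 0)

  flows <- tibble::tibble(treatment = rep(c("a", "b"), each = 3),
                          total_mm = c(190, 205, 199, 80, 95, 86))
  fwd <- sapflow_ttest(flows)
  swapped <- sapflow_ttest(dplyr::mutate(flows,
    treatment = ifelse(treatment == "a", "b", "a")))
  expect_equal(swapped$t, -fwd$t)
  expect_equal(swapped$p_value, fwd$p_value)

  expect_error(sapflow_ttest(tibble::tibble(treatment = c("a", "b", "b"),
                                            total_mm = c(1, 2, 3))),
               "at least 2")
  expect_error(sapflow_ttest(tibble::tibble(treatment = c("a", "b", "c"),
                                            total_mm = c(1, 2, 3))),
               "two groups")
})
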
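fixed_structures <- function() c("1", "canopy", "drought", "canopy+drought", "canopy*drought")

lme_formula <- function(fixed) {
  rhs <- switch(fixed,
    "1" = "1",
    "canopy" = "canopy",
    "drought" = "treatment",
    "canopy+drought" = "canopy + treatment",
    "canopy*drought" = "canopy * treatment",
    abort(sprintf("Unknown fixed-effect structure '%s'.", fixed))
  )
  as.formula(paste("value ~", rhs, "+ (1 | tree_id / shoot_id)"))
}

resolve_transform <- function(transform, trait) {
  transform <- match.arg(transform, c("auto", "identity", "log"))
  if (transform == "auto") {
    if (trait == "k_th") "log" else "identity"
  } else transform
}

lme_data <- function(traits, trait, transform) {
  check_columns(traits, c(id_cols(), trait), "Trait table")
  value <- traits[[trait]]
  if (transform == "log") {
    if (any(value <= 0)) abort(sprintf("Cannot log-transform '%s': non-positive values.", trait))
    value <- log(value)
  }
  tibble::tibble(
    value = value,
    canopy = factor(traits$canopy, levels = c("shade", "sun")),
    treatment = factor(traits$treatment, levels = c("control", "drought")),
    tree_id = factor(traits$tree_id),
    shoot_id = factor(traits$shoot_id)
  )
}

check_design <- function(d) {
  trees_per_trt <- table(unique(d[, c("treatment", "tree_id")])$treatment)
  if (any(trees_per_trt < 2)) {
    abort("Random effects unidentifiable: need >= 2 trees per treatment plot.")
  }
  shoots <- unique(d[, c("tree_id", "canopy", "shoot_id")])
  if (any(table(shoots$tree_id) < 2)) {
    abort("Random effects unidentifiable: need >= 2 shoots per tree.")
  }
  invisible(d)
}

#' Fit a shoot-within-tree linear mixed-effects model for one needle trait
#'
#' Fits `value ~ <fixed> + (1 | tree_id / shoot_id)` with [lme4::lmer()],
#' where observations enter at needle level and shoots are nested within
#' trees as random intercepts. `k_th` is log-transformed by default
#' (`transform = "auto"`) to linearise its right-skewed distribution; all
#' other traits are analysed on the measurement scale. Maximum likelihood is
#' used whenever the fit feeds a likelihood-ratio comparison; REML for final
#' reported models.
#'
#' @param traits Trait table from [needle_traits()].
#' @param trait Trait column name, e.g. `"A_n"`.
#' @param fixed Fixed-effect structure: one of `"1"`, `"canopy"`,
#'   `"drought"`, `"canopy+drought"`, `"canopy*drought"`.
#' @param transform `"auto"`, `"identity"` or `"log"`.
#' @param method `"ML"` or `"REML"`.
#'
#' @return An object of class `trait_lme` wrapping the `lmerMod` fit with
#'   log-likelihood, AIC, variance components, and `singular`/`converged`
#'   diagnostic flags (degenerate fits are flagged, never dropped).
#' @examples
#' sim <- simulate_needles(sim_config(seed = 1))
#' traits <- needle_traits(sim$tracheids, sim$needles)
#' fit <- fit_trait_model(traits, "A_n", fixed = "canopy*drought")
#' glance(fit)
#' @export
fit_trait_model <- function(traits, trait, fixed = "canopy*drought",
                            transform = "auto", method = c("ML", "REML")) {
  method <- match.arg(method)
  transform <- resolve_transform(transform, trait)
  d <- check_design(lme_data(traits, trait, transform))
  messages <- character()
  fit <- withCallingHandlers(
    lme4::lmer(lme_formula(fixed), data = d, REML = method == "REML",
               control = lme4::lmerControl(check.conv.singular = "ignore")),
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      messages <<- c(messages, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    fit = fit, trait = trait, fixed = fixed, transform = transform,
    method = method, logLik = as.numeric(logLik(fit)), AIC = AIC(fit),
    varcomp = tibble::tibble(group = vc$grp, variance = vc$vcov, sd = vc$sdcor),
    singular = lme4::isSingular(fit),
    converged = !any(grepl("failed to converge", messages)),
    messages = messages
  ), class = "trait_lme")
}

#' @export
print.trait_lme <- function(x, ...) {
  cat(sprintf("trait_lme: %s ~ %s (%s%s), logLik %.2f, AIC %.1f%s\n",
              x$trait, x$fixed, x$method,
              if (x$transform == "log") ", log scale" else "",
              x$logLik, x$AIC,
              if (x$singular) " [singular]" else ""))
  invisible(x)
}

#' @rdname fit_trait_model
#' @param x A `trait_lme` object.
#' @param ... Unused.
#' @export
tidy.trait_lme <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, "Estimate"],
                 std.error = cf[, "Std. Error"], statistic = cf[, "t value"])
}

#' @rdname fit_trait_model
#' @export
glance.trait_lme <- function(x, ...) {
  tibble::tibble(trait = x$trait, fixed = x$fixed, method = x$method,
                 transform = x$transform, logLik = x$logLik, AIC = x$AIC,
                 sigma = stats::sigma(x$fit), nobs = stats::nobs(x$fit),
                 singular = x$singular, converged = x$converged)
}

#' Likelihood-ratio ladder for canopy, drought and their interaction
#'
#' Tests each fixed effect by comparing nested maximum-likelihood fits:
#' the interaction by `canopy*drought` vs `canopy+drought`, the drought main
#' effect by `canopy+drought` vs `canopy`, and the canopy main effect by
#' `canopy+drought` vs `drought`. Each comparison is a chi-square test on
#' the difference in parameter count (1 df here). Both models' AICs are
#' reported for every comparison.
#'
#' @inheritParams fit_trait_model
#' @return A tibble with one row per tested factor: `trait`, `factor`
#'   (`"canopy"`, `"drought"`, `"interaction"`), `aic_simpler`,
#'   `aic_complex`, `df`, `chisq`, `p_value`, and diagnostic flags
#'   `singular_any` and `converged_all`.
#' @examples
#' sim <- simulate_needles(sim_config(seed = 1))
#' traits <- needle_traits(sim$tracheids, sim$needles)
#' lrt_ladder(traits, "A_n")
#' @export
lrt_ladder <- function(traits, trait, transform = "auto") {
  fits <- lapply(
    setNames(nm = c("canopy", "drought", "canopy+drought", "canopy*drought")),
    function(fx) fit_trait_model(traits, trait, fixed = fx,
                                 transform = transform, method = "ML")
  )
  one <- function(factor, simpler, complex) {
    chisq <- max(0, 2 * (fits[[complex]]$logLik - fits[[simpler]]$logLik))
    df <- length(lme4::fixef(fits[[complex]]$fit)) -
      length(lme4::fixef(fits[[simpler]]$fit))
    tibble::tibble(
      trait = trait, factor = factor,
      aic_simpler = fits[[simpler]]$AIC, aic_complex = fits[[complex]]$AIC,
      df = df, chisq = chisq, p_value = pchisq(chisq, df, lower.tail = FALSE),
      singular_any = fits[[simpler]]$singular || fits[[complex]]$singular,
      converged_all = fits[[simpler]]$converged && fits[[complex]]$converged
    )
  }
  dplyr::bind_rows(
    one("canopy", "drought", "canopy+drought"),
    one("drought", "canopy", "canopy+drought"),
    one("interaction", "canopy+drought", "canopy*drought")
  )
}

#' Model-based group means with 95% confidence intervals
#'
#' Estimated population means for the four canopy x treatment cells from the
#' REML fit of the full interaction model, with Wald (normal-approximation)
#' 95% intervals. Traits fitted on the log scale are back-transformed, so
#' their means are geometric and flagged as such in the `scale` column.
#'
#' @inheritParams fit_trait_model
#' @return A tibble with columns `trait`, `canopy`, `treatment`, `mean`,
#'   `ci_lo`, `ci_hi`, `scale` (`"arithmetic"` or `"geometric"`).
#' @examples
#' sim <- simulate_needles(sim_config(seed = 1))
#' traits <- needle_traits(sim$tracheids, sim$needles)
#' group_means_ci(traits, "A_n")
#' @export
group_means_ci <- function(traits, trait, transform = "auto") {
  m <- fit_trait_model(traits, trait, fixed = "canopy*drought",
                       transform = transform, method = "REML")
  em <- emmeans::emmeans(m$fit, ~ canopy * treatment, lmer.df = "asymptotic")
  s <- as.data.frame(summary(em, level = 0.95))
  out <- tibble::tibble(
    trait = trait,
    canopy = as.character(s$canopy),
    treatment = as.character(s$treatment),
    mean = s$emmean, ci_lo = s$asymp.LCL, ci_hi = s$asymp.UCL,
    scale = "arithmetic"
  )
  if (m$transform == "log") {
    out <- out |>
      dplyr::mutate(mean = exp(.data$mean), ci_lo = exp(.data$ci_lo),
                    ci_hi = exp(.data$ci_hi), scale = "geometric")
  }
  out
}

#' Full mixed-model report over all 14 needle traits
#'
#' Runs [lrt_ladder()] and [group_means_ci()] for every trait, mirroring the
#' two summary tables of a drought x canopy needle-anatomy analysis: an
#' AIC/p-value ladder per trait and model-based group means with 95%
#' intervals. No multiple-testing adjustment is applied across traits; each
#' trait is reported on its own, and that choice is deliberate (see the
#' methods vignette).
#'
#' @inheritParams fit_trait_model
#' @param traits_to_test Character vector of trait columns; defaults to the
#'   14 standard traits.
#' @return An object of class `lme_report`: list with tibbles `tests` and
#'   `means`.
#' @export
lme_report <- function(traits, traits_to_test = trait_names()) {
  tests <- purrr::map_dfr(traits_to_test, function(tr) lrt_ladder(traits, tr))
  means <- purrr::map_dfr(traits_to_test, function(tr) group_means_ci(traits, tr))
  structure(list(tests = tests, means = means), class = "lme_report")
}

#' @export
print.lme_report <- function(x, ...) {
  cat(sprintf("lme_report: %d traits, %d likelihood-ratio tests\n",
              length(unique(x$tests$trait)), nrow(x$tests)))
  sig <- x$tests |> dplyr::filter(.data$p_value < 0.05)
  cat(sprintf("  significant at 0.05: %d of %d\n", nrow(sig), nrow(x$tests)))
  invisible(x)
}

#' @rdname lme_report
#' @param x An `lme_report`.
#' @param ... Unused.
#' @export
tidy.lme_report <- function(x, ...) x$tests

#' @rdname lme_report
#' @export
glance.lme_report <- function(x, ...) {
  tibble::tibble(
    n_traits = length(unique(x$tests$trait)),
    n_tests = nrow(x$tests),
    n_significant = sum(x$tests$p_value < 0.05),
    any_singular = any(x$tests$singular_any),
    all_converged = all(x$tests$converged_all)
  )
}

#' Two-sample t-test on per-tree accumulated sap flow
#'
#' Classical pooled-variance two-sample two-tailed t-test comparing per-tree
#' season sap-flow totals (mm per unit crown projected area) between the
#' control and drought groups, with the percent difference of the group
#' means.
#'
#' @param totals A data frame with columns `treatment` (two groups; the
#'   first level is the reference for the percent reduction) and `total_mm`
#'   (one value per tree).
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_control`,
#'   `mean_drought` (named after the two group levels in order), and
#'   `percent_reduction` of the second group relative to the first.
#' @examples
#' flows <- tibble::tibble(
#'   treatment = rep(c("control", "drought"), each = 3),
#'   total_mm = c(190, 205, 199, 80, 95, 86)
#' )
#' sapflow_ttest(flows)
#' @export
sapflow_ttest <- function(totals) {
  check_columns(totals, c("treatment", "total_mm"), "Sap-flow table")
  g <- factor(totals$treatment)
  if (nlevels(g) != 2L) abort("`totals` must contain exactly two groups.")
  if (any(table(g) < 2L)) abort("Each group needs at least 2 trees.")
  tt <- t.test(total_mm ~ g, data = totals, var.equal = TRUE,
               alternative = "two.sided")
  m <- tapply(totals$total_mm, g, mean)
  tibble::tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_control = unname(m[1]), mean_drought = unname(m[2]),
    percent_reduction = unname(percent_reduction(m[1], m[2]))
  )
}
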
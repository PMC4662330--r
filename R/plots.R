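#' Plot model-based group means with 95% intervals
#'
#' Point-and-errorbar display of the 2 x 2 group means per trait, the
#' standard visual summary of a drought x canopy analysis.
#'
#' @param means A group-means tibble from [group_means_ci()] or
#'   `lme_report()$means`.
#' @return A ggplot object.
#' @export
plot_group_means <- function(means) {
  check_columns(means, c("trait", "canopy", "treatment", "mean", "ci_lo", "ci_hi"),
                "Group means")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$canopy, y = .data$mean,
                                      colour = .data$treatment)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "Canopy position", y = "Estimated mean (95% CI)",
                  colour = "Treatment") +
    ggplot2::theme_minimal()
}

#' @rdname lme_report
#' @param object An `lme_report`.
#' @export
autoplot.lme_report <- function(object, ...) {
  plot_group_means(object$means)
}

#' Draw a section layout
#'
#' Outlines the region ellipses and the placed tracheid lumens; a quick
#' visual check of the geometric surrogate.
#'
#' @param layout A [layout_section()] result.
#' @param n_arc Points per ellipse outline. Default 90.
#' @return A ggplot object.
#' @export
plot_section <- function(layout, n_arc = 90) {
  if (!inherits(layout, "section_layout")) abort("`layout` must be a section_layout.")
  arc <- seq(0, 2 * pi, length.out = n_arc)
  ell <- function(cx, cy, a, b, theta, id) {
    tibble::tibble(
      x = cx + a * cos(arc) * cos(theta) - b * sin(arc) * sin(theta),
      y = cy + a * cos(arc) * sin(theta) + b * sin(arc) * cos(theta),
      id = id)
  }
  regions <- purrr::map_dfr(seq_len(nrow(layout$regions)), function(i) {
    r <- layout$regions[i, ]
    ell(0, 0, r$a, r$b, 0, r$region)
  })
  lumens <- purrr::map_dfr(seq_len(nrow(layout$tracheids)), function(i) {
    tr <- layout$tracheids[i, ]
    ell(tr$x, tr$y, tr$a, tr$b, tr$theta, tr$tracheid_id)
  })
  ggplot2::ggplot() +
    ggplot2::geom_path(data = regions,
                       ggplot2::aes(.data$x, .data$y, group = .data$id),
                       colour = "grey40") +
    ggplot2::geom_polygon(data = lumens,
                          ggplot2::aes(.data$x, .data$y, group = .data$id),
                          fill = "steelblue", alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}
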
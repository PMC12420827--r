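# ggplot2 visualisations for the main result types.

#' @rdname run_stand
#' @param object A `stand_run`.
#' @param ... Unused.
#' @export
autoplot.stand_run <- function(object, ...) {
  ggplot2::ggplot(object$annual, ggplot2::aes(x = .data$year, y = .data$agb_t_ha)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Simulation year", y = "Above-ground biomass (t/ha)") +
    ggplot2::theme_minimal()
}

#' @rdname fit_hetero_bayes
#' @param object A `hetero_bayes` fit.
#' @export
autoplot.hetero_bayes <- function(object, ...) {
  band <- posterior_predictive_band(object)
  ggplot2::ggplot(band, ggplot2::aes(x = .data$raoq)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mu_lo, ymax = .data$mu_hi),
                         alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mu)) +
    ggplot2::geom_point(data = object$data,
                        ggplot2::aes(x = .data$raoq, y = .data$bm_loss),
                        alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "Functional diversity (RaoQ)",
                  y = "Biomass loss (%)",
                  title = "Posterior mean response with 95% credible band") +
    ggplot2::theme_minimal()
}

#' @rdname pca_trait_space
#' @param object A `trait_pca`.
#' @param ... Unused.
#' @export
autoplot.trait_pca <- function(object, ...) {
  sc <- object$scores
  ld <- object$loadings
  mult <- max(abs(c(sc$PC1, sc$PC2))) * 0.8
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_segment(data = ld,
                          ggplot2::aes(x = 0, y = 0, xend = .data$PC1 * mult,
                                       yend = .data$PC2 * mult),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "firebrick") +
    ggplot2::geom_text(data = ld,
                       ggplot2::aes(x = .data$PC1 * mult * 1.12,
                                    y = .data$PC2 * mult * 1.12,
                                    label = .data$trait),
                       size = 3, colour = "firebrick") +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * object$variance_fraction[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$variance_fraction[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot predicted diversity effects across drought severities
#'
#' @param effects The result of [predict_diversity_effect()].
#' @return A ggplot: predicted percentage biomass change against diversity,
#'   one curve (with 95 percent CI ribbon) per precipitation reduction.
#' @export
plot_diversity_effect <- function(effects) {
  cv <- effects$curves
  cv$reduction <- factor(cv$precip_change)
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$raoq, y = .data$pred,
                                   colour = .data$reduction,
                                   fill = .data$reduction)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Functional diversity (RaoQ)",
                  y = "Predicted AGB change (%)",
                  colour = "Reduction (mm)", fill = "Reduction (mm)") +
    ggplot2::theme_minimal()
}
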
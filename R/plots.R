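#' Forest plot of a meta-analysis
#'
#' Per-study estimates with normal-approximation CIs and the pooled
#' random-effects estimate below; the dashed line marks the null (odds
#' ratio 1 on the log scale, standardised mean difference 0).
#'
#' @param object A `star_meta`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot star_meta
#' @export
autoplot.star_meta <- function(object, ...) {
  per <- tidy(object)
  per$study <- factor(per$study, levels = rev(per$study))
  pooled <- tibble(study = "RE pooled", estimate = object$pooled,
                   conf.low = object$ci_low, conf.high = object$ci_high)
  lab <- if (object$measure == "OR") "log odds ratio" else "standardised mean difference"
  ggplot2::ggplot(per, ggplot2::aes(x = .data$estimate, y = .data$study)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high), height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), shape = 15) +
    ggplot2::geom_pointrange(data = pooled,
                             ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
                             shape = 18, colour = "firebrick", fatten = 5) +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(x = lab, y = NULL) +
    ggplot2::theme_minimal()
}

#' Positive-versus-negative pooled effects for evaluated options
#'
#' The diagnostic view used to compare candidate options: each option's
#' pooled effect (with CI) in trials where an effect is expected, next to
#' its pooled effect in negative trials where none is. Good options sit far
#' from the null on the left panel and on it in the right panel.
#'
#' @param evaluations An [evaluate_options()] tibble.
#' @return A ggplot.
#' @export
plot_option_evaluation <- function(evaluations) {
  long <- dplyr::bind_rows(
    tibble(option_id = evaluations$option_id, type = evaluations$type,
           side = "expected positive", est = evaluations$pos_est,
           lo = evaluations$pos_lo, hi = evaluations$pos_hi),
    tibble(option_id = evaluations$option_id, type = evaluations$type,
           side = "expected null", est = evaluations$neg_est,
           lo = evaluations$neg_lo, hi = evaluations$neg_hi))
  long <- long[!is.na(long$est), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$est, y = .data$option_id,
                                     colour = .data$type)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::facet_wrap(~side) +
    ggplot2::labs(x = "pooled effect (log OR / SMD)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Dot-and-CI chart of standardised effect sizes
#'
#' @param effect_sizes Tibble with columns `outcome`, `d`, `ci_low`,
#'   `ci_high` (e.g. row-bound [cohens_d()] results).
#' @return A ggplot with the small/moderate/large reference bands.
#' @export
plot_effect_sizes <- function(effect_sizes) {
  ggplot2::ggplot(effect_sizes,
                  ggplot2::aes(x = .data$d, y = .data$outcome)) +
    ggplot2::geom_vline(xintercept = c(-0.8, -0.5, 0, 0.5, 0.8),
                        linetype = c("dotted", "dotted", "dashed", "dotted", "dotted"),
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high)) +
    ggplot2::labs(x = "Cohen's d (pooled SD)", y = NULL) +
    ggplot2::theme_minimal()
}
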
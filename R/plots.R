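#' Boxplot of mortality risk by group
#'
#' Draws the classic risk-distribution boxplot (median, quartile box,
#' whiskers at 1.5 interquartile ranges, outliers hidden) for posterior-mean
#' per-birth risk stratified by a grouping such as wealth quintile.
#'
#' @param risk A `u5_risk` or numeric vector of per-birth risks.
#' @param groups Group labels, one per birth.
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_risk_box <- function(risk, groups, xlab = "group",
                          ylab = "mortality risk") {
  bs <- boxplot_summary(risk, groups)
  ggplot2::ggplot(bs, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$whisker_low, ymax = .data$whisker_high),
      width = 0.25
    ) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median, ymin = .data$q1, ymax = .data$q3),
      fill = "grey90", width = 0.6, linewidth = 0.4
    ) +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.u5_risk <- function(object, ...) {
  df <- tibble(risk = object$posterior_mean)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$risk)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey40") +
    ggplot2::labs(x = "posterior mean mortality risk", y = "births") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.u5_anova <- function(object, ...) {
  df <- tibble(r2 = object$r2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r2)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$estimate, linetype = 2) +
    ggplot2::labs(x = expression(R^2), y = "posterior draws") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.u5_targeting <- function(object, ...) {
  df <- tibble(gain = object$gain_draws)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gain)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "efficiency gain (%)", y = "posterior draws") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.u5_compare <- function(object, ...) {
  df <- object$summary |>
    mutate(null = ifelse(.data$type == "categorical", 1, 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    ) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$null), linetype = 2) +
    ggplot2::facet_wrap(~type, scales = "free") +
    ggplot2::labs(x = "high-risk vs rest (OR or mean difference)", y = NULL) +
    ggplot2::theme_minimal()
}
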
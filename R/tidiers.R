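#' Tidy method for fitted risk models
#'
#' One row per design column with the posterior mean, standard deviation
#' and equal-tailed credible interval of its coefficient.
#'
#' @param x A `u5_fit`.
#' @param conf.level Credible level, default 0.95.
#' @param ... Unused.
#' @return A tibble with columns `term`, `block`, `order`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.u5_fit <- function(x, conf.level = 0.95, ...) {
  a <- (1 - conf.level) / 2
  qs <- apply(x$beta, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  tibble(
    term = colnames(x$beta),
    block = x$design$col_info$block,
    order = x$design$col_info$order,
    estimate = colMeans(x$beta),
    std.error = apply(x$beta, 2, sd),
    conf.low = qs[1, ],
    conf.high = qs[2, ]
  )
}

#' @export
glance.u5_fit <- function(x, ...) {
  tibble(
    n = x$n,
    deaths = x$deaths,
    death_rate = x$deaths / x$n,
    n_columns = ncol(x$beta),
    n_clusters = length(x$design$cluster_levels %||% integer(0)),
    draws = nrow(x$beta),
    chains = x$spec$chains,
    max_rhat = max(x$rhat, na.rm = TRUE),
    sigma_loc = mean(x$sigma_loc)
  )
}

#' @export
tidy.u5_risk <- function(x, conf.level = 0.95, ...) {
  a <- (1 - conf.level) / 2
  qs <- apply(x$draws, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  tibble(
    birth_id = x$birth_id,
    estimate = x$posterior_mean,
    conf.low = qs[1, ],
    conf.high = qs[2, ]
  )
}

#' @export
tidy.u5_anova <- function(x, ...) {
  x$group_means
}

#' @export
glance.u5_anova <- function(x, ...) {
  tibble(
    r.squared = x$estimate,
    conf.low = x$conf[1],
    conf.high = x$conf[2],
    scale = x$scale,
    n_groups = nrow(x$group_means)
  )
}

#' @export
tidy.u5_targeting <- function(x, ...) {
  tibble(
    statistic = c("mortality_poor", "mortality_high_risk",
                  "efficiency_gain_pct"),
    estimate = c(x$poor_rate, x$hr_mean, x$gain_mean),
    conf.low = c(NA, x$hr_conf[1], x$gain_conf[1]),
    conf.high = c(NA, x$hr_conf[2], x$gain_conf[2])
  )
}

#' @export
glance.u5_targeting <- function(x, ...) {
  tibble(
    q = x$q, set_size = x$m, mortality_poor = x$poor_rate,
    mortality_high_risk = x$hr_mean, efficiency_gain = x$gain_mean,
    efficiency_gain_point = x$gain_point
  )
}

#' @export
tidy.u5_compare <- function(x, ...) {
  x$summary
}

#' @export
tidy.u5_equity_report <- function(x, ...) {
  bind_rows(
    tibble(statistic = "npd", term = NA_character_, estimate = x$npd,
           conf.low = NA_real_, conf.high = NA_real_),
    tibble(statistic = "anova_r2_wealth", term = NA_character_,
           estimate = x$anova_wealth$estimate,
           conf.low = x$anova_wealth$conf[1],
           conf.high = x$anova_wealth$conf[2]),
    tidy(x$targeting) |>
      mutate(term = NA_character_) |>
      select("statistic", "term", "estimate", "conf.low", "conf.high"),
    x$comparison$summary |>
      mutate(statistic = paste0("compare_", .data$statistic)) |>
      select("statistic", "term", "estimate", "conf.low", "conf.high")
  )
}
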
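#' Full equity report for one survey
#'
#' Bundles the equity analyses for a fitted risk posterior: observed NPD,
#' the Bayesian ANOVA R-squared of risk on wealth quintile, per-quintile
#' boxplot summaries of posterior-mean risk, targeting efficiency gains,
#' and high- versus low-risk group comparisons.
#'
#' @param risk A `u5_risk` aligned with `table` rows.
#' @param table The analysis table the model was fit to.
#' @param q Targeted / high-risk fraction, default 0.20.
#' @return A `u5_equity_report`; [tidy()] returns one row per statistic and
#'   [write_equity_report()] exports JSON and CSV.
#' @examples
#' \donttest{
#' births <- generate_survey(gradient_scenario(n_births = 3000, seed = 3))
#' tab <- prepare_births(births)
#' fit <- fit_risk_model(tab, model_spec(max_interaction_order = 1,
#'                                       chains = 2, warmup = 150,
#'                                       draws_total = 200))
#' rep <- equity_report(posterior_risk(fit), tab)
#' rep
#' }
#' @export
equity_report <- function(risk, table, q = 0.20) {
  stopifnot(inherits(risk, "u5_risk"),
            "wealth_quintile" %in% names(table))
  report <- list(
    n = nrow(table),
    deaths = sum(table$died_u5 == 1),
    u5mr = mean(table$died_u5 == 1),
    q = q,
    npd = npd_fraction(table),
    anova_wealth = anova_r2(risk, table$wealth_quintile),
    boxplot = boxplot_summary(risk, table$wealth_quintile),
    targeting = targeting(risk, table, q = q),
    comparison = compare_groups(risk, table, q = q)
  )
  structure(report, class = "u5_equity_report")
}

#' @export
print.u5_equity_report <- function(x, ...) {
  cat("Equity report\n")
  cat(sprintf("  births %d, deaths %d (U5MR %.3f)\n", x$n, x$deaths, x$u5mr))
  cat(sprintf("  NPD: %.1f%% of deaths outside the poorest quintile\n",
              100 * x$npd))
  cat(sprintf("  wealth-quintile R2: %.3f (95%% CI %.3f - %.3f)\n",
              x$anova_wealth$estimate, x$anova_wealth$conf[1],
              x$anova_wealth$conf[2]))
  print(x$targeting)
  invisible(x)
}

#' @rdname equity_report
#' @param report A `u5_equity_report`.
#' @param dir Output directory; `equity_report.json` and
#'   `equity_report.csv` are written there.
#' @export
write_equity_report <- function(report, dir) {
  stopifnot(inherits(report, "u5_equity_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- tidy(report)
  p_csv <- file.path(dir, "equity_report.csv")
  write.csv(tab, p_csv, row.names = FALSE)
  payload <- list(
    schema = "u5equity/equity_report/v1",
    n = report$n, deaths = report$deaths, u5mr = report$u5mr, q = report$q,
    npd = report$npd,
    anova_wealth = list(
      estimate = report$anova_wealth$estimate,
      conf_low = report$anova_wealth$conf[1],
      conf_high = report$anova_wealth$conf[2],
      group_means = report$anova_wealth$group_means
    ),
    targeting = list(
      mortality_poor = report$targeting$poor_rate,
      mortality_high_risk = report$targeting$hr_mean,
      mortality_high_risk_conf = report$targeting$hr_conf,
      efficiency_gain = report$targeting$gain_mean,
      efficiency_gain_conf = report$targeting$gain_conf,
      gain_point = report$targeting$gain_point
    ),
    comparison = report$comparison$summary,
    boxplot = report$boxplot
  )
  p_json <- file.path(dir, "equity_report.json")
  jsonlite::write_json(payload, p_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(csv = p_csv, json = p_json))
}
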
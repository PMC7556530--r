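#' Non-poor-deaths (NPD) fraction
#'
#' The share of observed under-5 deaths occurring to births outside the
#' poorest wealth quintile (quintiles 2-5, the top 80% of wealth). Under
#' perfect equity of mortality across wealth the NPD is 80%; a pro-poor
#' mortality gradient pushes it below 80%.
#'
#' @param table An analysis table with `died_u5` and `wealth_quintile`.
#' @return A single proportion in `[0, 1]`, or `NA` (with a warning) when
#'   the table has no deaths.
#' @examples
#' tab <- tibble::tibble(died_u5 = c(1, 1, 1, 1, 1, rep(0, 5)),
#'                       wealth_quintile = c(1, 1, 2, 3, 5, 1:5))
#' npd_fraction(tab) # 3 of 5 deaths outside quintile 1
#' @export
npd_fraction <- function(table) {
  stopifnot(all(c("died_u5", "wealth_quintile") %in% names(table)))
  deaths <- sum(table$died_u5 == 1)
  if (deaths == 0) {
    warn("no deaths; NPD undefined")
    return(NA_real_)
  }
  sum(table$died_u5 == 1 & table$wealth_quintile >= 2) / deaths
}

#' Per-draw Bayesian ANOVA R-squared of mortality risk
#'
#' For each posterior draw `s`, decomposes the variance of the per-birth
#' risks \eqn{p_i^{(s)}} across the given grouping:
#' \deqn{R^2(s) = \frac{\sum_i (\bar p_{g(i)}^{(s)} - \bar p^{(s)})^2}
#'                     {\sum_i (p_i^{(s)} - \bar p^{(s)})^2}}
#' and summarises the draws by the posterior mean and the equal-tailed 95%
#' interval. This is the share of risk variability explained by group
#' membership; computed on the probability scale by default (set
#' `scale = "logit"` to decompose log-odds instead).
#'
#' @param risk A `u5_risk`, an S x N draws matrix, or a single numeric risk
#'   vector.
#' @param groups Group labels, one per birth.
#' @param scale `"probability"` (default) or `"logit"`.
#' @return A `u5_anova` object; see [tidy()] and [glance()].
#' @examples
#' anova_r2(c(0.1, 0.2, 0.3, 0.4), groups = c("A", "A", "B", "B"))
#' @export
anova_r2 <- function(risk, groups, scale = c("probability", "logit")) {
  scale <- match.arg(scale)
  M <- .risk_matrix(risk)
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(M))
  if (scale == "logit") M <- qlogis(M)
  g <- nlevels(groups)
  if (g < 2) {
    warn("fewer than 2 groups; R-squared is identically 0")
    r2 <- rep(0, nrow(M))
  } else {
    n_g <- as.numeric(table(groups))
    # S x g matrix of per-draw group means
    gm <- M %*% (stats::model.matrix(~ groups - 1) %*% diag(1 / n_g))
    mbar <- as.numeric(M %*% rep(1 / ncol(M), ncol(M)))
    ss_tot <- rowSums((M - mbar)^2)
    ss_btw <- as.numeric(((gm - mbar)^2) %*% n_g)
    r2 <- ifelse(ss_tot > 0, ss_btw / ss_tot, 0)
  }
  group_means <- if (g >= 2) colMeans(gm) else mean(M)
  structure(
    list(
      r2 = r2,
      estimate = mean(r2),
      conf = .ci95(r2),
      group_means = tibble(
        group = levels(groups),
        n = as.integer(table(groups)),
        mean_risk = as.numeric(group_means)
      ),
      scale = scale,
      grouping = deparse(substitute(groups))[1]
    ),
    class = "u5_anova"
  )
}

#' @export
print.u5_anova <- function(x, ...) {
  cat(sprintf(
    "Bayesian ANOVA R-squared (%s scale): %.4f (95%% CI %.4f - %.4f)\n",
    x$scale, x$estimate, x$conf[1], x$conf[2]
  ))
  invisible(x)
}

#' Five-number boxplot summaries of risk by group
#'
#' Per-group median, quartiles, and whisker ends at the most extreme data
#' points within 1.5 interquartile ranges of the quartiles; points beyond
#' the whiskers are counted as outliers and excluded from the whisker
#' bounds. Quartiles use the standard continuous (type 7) quantile rule.
#'
#' @param x Per-birth risks: a numeric vector or a `u5_risk` (whose
#'   posterior means are summarised).
#' @param groups Group labels, one per birth.
#' @return A tibble with one row per group: `group`, `n`, `whisker_low`,
#'   `q1`, `median`, `q3`, `whisker_high`, `n_outliers`.
#' @export
boxplot_summary <- function(x, groups) {
  if (inherits(x, "u5_risk")) x <- x$posterior_mean
  stopifnot(is.numeric(x), length(x) == length(groups))
  tibble(group = as.factor(groups), value = x) |>
    group_by(.data$group) |>
    summarise(
      n = dplyr::n(),
      q1 = quantile(.data$value, 0.25, names = FALSE),
      median = median(.data$value),
      q3 = quantile(.data$value, 0.75, names = FALSE),
      whisker_low = min(.data$value[.data$value >= q1 - 1.5 * (q3 - q1)]),
      whisker_high = max(.data$value[.data$value <= q3 + 1.5 * (q3 - q1)]),
      n_outliers = sum(.data$value < q1 - 1.5 * (q3 - q1) |
                         .data$value > q3 + 1.5 * (q3 - q1)),
      .groups = "drop"
    ) |>
    select("group", "n", "whisker_low", "q1", "median", "q3",
           "whisker_high", "n_outliers")
}

# indices of the m largest values, ties broken by position (stable)
.top_idx <- function(p, m) {
  order(-p, seq_along(p))[seq_len(m)]
}

#' Risk-based versus poverty-based targeting
#'
#' Compares the observed death rate among the fraction `q` of births ranked
#' highest-risk by the model against the death rate among the `q` poorest
#' births (lowest wealth rank), and reports the efficiency gain
#' \deqn{\mathrm{gain} = \frac{\mathrm{HRDeaths} - \mathrm{PoorDeaths}}
#'                            {\mathrm{PoorDeaths}} \times 100.}
#' Both comparison sets have exactly `floor(q N)` births, with ties at the
#' cutoff broken stably by table position. The high-risk set is formed per
#' posterior draw (giving a posterior distribution of the gain) and once
#' from the posterior-mean risks (the point version). Because only risk
#' ranks matter, the gain is invariant to monotone transformations of the
#' risk draws.
#'
#' @param risk A `u5_risk` or draws matrix aligned with `table` rows.
#' @param table An analysis table with `died_u5` and `wealth_cdf`.
#' @param q Targeted fraction, default 0.20.
#' @return A `u5_targeting` object; see [tidy()] and [glance()].
#' @export
targeting <- function(risk, table, q = 0.20) {
  stopifnot(q > 0, q < 1,
            all(c("died_u5", "wealth_cdf") %in% names(table)))
  M <- .risk_matrix(risk)
  n <- nrow(table)
  stopifnot(ncol(M) == n)
  m <- floor(q * n)
  if (m < 1) abort("q too small: empty target set")
  y <- as.numeric(table$died_u5)

  poor_idx <- order(table$wealth_cdf, seq_len(n))[seq_len(m)]
  poor_rate <- mean(y[poor_idx])

  hr_rate <- apply(M, 1, function(p) mean(y[.top_idx(p, m)]))
  boundary_ties <- apply(M, 1, function(p) {
    ps <- sort(p, decreasing = TRUE)
    ps[m] == ps[m + 1]
  })
  if (any(boundary_ties)) {
    inform(paste0(sum(boundary_ties),
                  " draw(s) had risk ties at the targeting cutoff; ",
                  "broken stably by birth order in the table"))
  }
  hr_point <- mean(y[.top_idx(colMeans(M), m)])

  if (poor_rate == 0) {
    warn("no deaths among the poorest set; efficiency gain undefined")
    gain <- rep(NA_real_, length(hr_rate))
    gain_point <- NA_real_
  } else {
    gain <- (hr_rate - poor_rate) / poor_rate * 100
    gain_point <- (hr_point - poor_rate) / poor_rate * 100
  }
  structure(
    list(
      q = q, m = m, poor_rate = poor_rate,
      hr_draws = hr_rate, gain_draws = gain,
      hr_point = hr_point, gain_point = gain_point,
      hr_mean = mean(hr_rate), hr_conf = .ci95(hr_rate),
      gain_mean = mean(gain), gain_conf = .ci95(gain)
    ),
    class = "u5_targeting"
  )
}

#' @export
print.u5_targeting <- function(x, ...) {
  cat(sprintf("Targeting the %.0f%% highest-risk vs the %.0f%% poorest\n",
              100 * x$q, 100 * x$q))
  cat(sprintf("  mortality poor:      %.3f\n", x$poor_rate))
  cat(sprintf("  mortality high risk: %.3f (95%% CI %.3f - %.3f)\n",
              x$hr_mean, x$hr_conf[1], x$hr_conf[2]))
  cat(sprintf("  efficiency gain:     %.1f%% (95%% CI %.1f%% - %.1f%%)\n",
              x$gain_mean, x$gain_conf[1], x$gain_conf[2]))
  invisible(x)
}

#' Compare the high-risk group to the rest of the births
#'
#' Per posterior draw, splits births into the top-`q` highest-risk set and
#' the remaining births, then contrasts the two groups on each covariate:
#' odds ratios of prevalence for categorical covariates (with the
#' Haldane-Anscombe 0.5 continuity correction when a cell is empty, with a
#' note counting corrected draws) and high-minus-low mean differences for
#' continuous ones. Draws are summarised by the posterior mean and 95%
#' interval; a covariate is flagged significant when its interval excludes
#' the null (1 for ratios, 0 for differences).
#'
#' @param risk A `u5_risk` or draws matrix aligned with `table` rows.
#' @param table An analysis table.
#' @param q Fraction defining the high-risk group, default 0.20.
#' @param categorical,continuous Covariate columns to contrast.
#' @return A `u5_compare` object whose `summary` tibble has one row per
#'   covariate; [tidy()] returns it.
#' @export
compare_groups <- function(risk, table, q = 0.20,
                           categorical = c("urban", "sex", "prior_death"),
                           continuous = c("wealth_cdf", "maternal_education",
                                          "maternal_age_at_birth",
                                          "birth_order")) {
  M <- .risk_matrix(risk)
  n <- nrow(table)
  stopifnot(ncol(M) == n, q > 0, q < 1)
  m <- floor(q * n)
  if (m < 1 || m >= n) abort("q leaves an empty group")
  top_sets <- apply(M, 1, function(p) .top_idx(p, m)) # m x S

  rows <- list()
  draws_out <- list()
  for (v in intersect(categorical, names(table))) {
    one <- switch(v, sex = "male", urban = "urban", "1")
    x <- .binary01(table[[v]], one)
    if (length(unique(x)) < 2) {
      inform(paste0("covariate '", v, "' is constant; comparison skipped"))
      next
    }
    tot <- sum(x)
    n_corr <- 0L
    or_draws <- apply(top_sets, 2, function(idx) {
      a <- sum(x[idx]) # covariate present, high risk
      b <- m - a
      cc <- tot - a
      d <- (n - m) - cc
      if (any(c(a, b, cc, d) == 0)) {
        n_corr <<- n_corr + 1L
        a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
      }
      (a * d) / (b * cc)
    })
    if (n_corr > 0) {
      inform(paste0("odds ratio for '", v, "': continuity correction in ",
                    n_corr, " draw(s)"))
    }
    ci <- .ci95(or_draws)
    rows[[v]] <- tibble(
      term = v, type = "categorical", statistic = "odds_ratio",
      estimate = mean(or_draws), conf.low = ci[1], conf.high = ci[2],
      significant = ci[1] > 1 | ci[2] < 1
    )
    draws_out[[v]] <- or_draws
  }
  for (v in intersect(continuous, names(table))) {
    x <- as.numeric(table[[v]])
    if (length(unique(x)) < 2) {
      inform(paste0("covariate '", v, "' is constant; comparison skipped"))
      next
    }
    tot <- sum(x)
    diff_draws <- apply(top_sets, 2, function(idx) {
      hi <- sum(x[idx]) / m
      lo <- (tot - sum(x[idx])) / (n - m)
      hi - lo
    })
    ci <- .ci95(diff_draws)
    rows[[v]] <- tibble(
      term = v, type = "continuous", statistic = "mean_difference",
      estimate = mean(diff_draws), conf.low = ci[1], conf.high = ci[2],
      significant = ci[1] > 0 | ci[2] < 0
    )
    draws_out[[v]] <- diff_draws
  }
  structure(
    list(summary = bind_rows(rows), draws = draws_out, q = q, m = m),
    class = "u5_compare"
  )
}

#' @export
print.u5_compare <- function(x, ...) {
  cat(sprintf("High-risk (top %.0f%%) vs remaining births\n", 100 * x$q))
  print(x$summary)
  invisible(x)
}
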
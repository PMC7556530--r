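test_that("NPD counts deaths outside the poorest quintile", {
  # 10 births: 2 deaths in quintile 1, 3 deaths spread over quintiles 2-5
  tab <- toy_analysis_table(
    n = 10,
    died = c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0),
    wealth_cdf = c(0.05, 0.15, 0.3, 0.5, 0.9, 0.1, 0.35, 0.55, 0.75, 0.95)
  )
  expect_equal(npd_fraction(tab), 3 / 5)

  # all deaths among the poorest -> 0
  tab$wealth_quintile <- ifelse(tab$died_u5 == 1, 1L, 3L)
  expect_equal(npd_fraction(tab), 0)

  # no deaths -> flagged missing
  tab$died_u5 <- 0
  expect_warning(out <- npd_fraction(tab), "no deaths")
  expect_true(is.na(out))
})

test_that("NPD approaches 80% when deaths are uniform over quintiles", {
  set.seed(12)
  n <- 100000
  tab <- toy_analysis_table(n, died = rbinom(n, 1, 0.1),
                            wealth_cdf = (seq_len(n) - 0.5) / n)
  expect_lt(abs(npd_fraction(tab) - 0.8), 0.01)
})

test_that("per-draw ANOVA R2 matches hand computation and closed cases", {
  # groups fully separated -> 1; identical group means -> 0
  expect_equal(anova_r2(c(0.1, 0.1, 0.3, 0.3), c("A", "A", "B", "B"))$estimate, 1)
  expect_equal(anova_r2(c(0.1, 0.3, 0.1, 0.3), c("A", "A", "B", "B"))$estimate, 0)
  # hand-computed: SS_between 0.04 / SS_total 0.05
  out <- anova_r2(c(0.1, 0.2, 0.3, 0.4), c("A", "A", "B", "B"))
  expect_equal(out$estimate, 0.8, tolerance = 1e-12)
  # single group -> 0 with a warning
  expect_warning(one <- anova_r2(c(0.1, 0.2), c("A", "A")), "fewer than 2")
  expect_equal(one$estimate, 0)
  # zero total variance in a draw -> 0 for that draw
  M <- rbind(c(0.2, 0.2, 0.2, 0.2), c(0.1, 0.2, 0.3, 0.4))
  out2 <- anova_r2(M, c("A", "A", "B", "B"))
  expect_equal(out2$r2, c(0, 0.8), tolerance = 1e-12)
})

test_that("ANOVA R2 equals a brute-force one-way decomposition per draw", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(6:20, 1)
    S <- 7
    M <- matrix(runif(S * n, 0.01, 0.5), S, n)
    g <- sample(letters[1:3], n, replace = TRUE)
    while (length(unique(g)) < 2) g <- sample(letters[1:3], n, replace = TRUE)
    out <- anova_r2(M, g)
    # independent route: linear-model R2 of risk on group, draw by draw
    brute <- vapply(seq_len(S), function(s) {
      summary(lm(M[s, ] ~ factor(g)))$r.squared
    }, numeric(1))
    expect_equal(out$r2, brute, tolerance = 1e-12)
    expect_true(all(out$r2 >= 0 & out$r2 <= 1))
    expect_true(out$conf[1] <= out$estimate && out$estimate <= out$conf[2])
  }
})

test_that("ANOVA group means and interval come from the draws", {
  M <- rbind(c(0.1, 0.2, 0.3, 0.5), c(0.2, 0.3, 0.4, 0.6))
  out <- anova_r2(M, c("A", "A", "B", "B"))
  expect_equal(out$group_means$mean_risk, c(mean(c(0.1, 0.2, 0.2, 0.3)),
                                            mean(c(0.3, 0.5, 0.4, 0.6))))
  expect_equal(length(out$r2), 2)
})

test_that("boxplot summaries follow the 1.5-IQR whisker rule", {
  # single value per group: all five numbers coincide
  bs <- boxplot_summary(c(0.2, 0.4), groups = c("A", "B"))
  expect_equal(bs$whisker_low, c(0.2, 0.4))
  expect_equal(bs$median, c(0.2, 0.4))
  expect_equal(bs$whisker_high, c(0.2, 0.4))

  # values 1..100 against a brute-force type-7 quantile computation
  x <- as.numeric(1:100)
  bs2 <- boxplot_summary(x, groups = rep("g", 100))
  expect_equal(bs2$median, 50.5)
  expect_equal(bs2$q1, quantile(x, 0.25, names = FALSE))
  expect_equal(bs2$q3, quantile(x, 0.75, names = FALSE))
  expect_equal(bs2$whisker_low, 1)
  expect_equal(bs2$whisker_high, 100)
  expect_equal(bs2$n_outliers, 0L)

  # an extreme outlier moves no whisker
  bs3 <- boxplot_summary(c(x, 1e6), groups = rep("g", 101))
  expect_equal(bs3$whisker_high, max(x[x <= bs3$q3 + 1.5 * (bs3$q3 - bs3$q1)]))
  expect_equal(bs3$n_outliers, 1L)
})

test_that("targeting reproduces the toy efficiency-gain arithmetic", {
  # 10 births; top-2 risk set holds 2 deaths, poorest-2 holds 1 death
  tab <- toy_analysis_table(
    n = 10,
    died = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
    wealth_cdf = c(0.05, 0.5, 0.6, 0.15, 0.3, 0.4, 0.7, 0.8, 0.9, 0.95)
  )
  p <- c(0.9, 0.8, 0.1, 0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  out <- targeting(p, tab, q = 0.2)
  expect_equal(out$poor_rate, 0.5) # poorest two: births 1 and 4 -> 1 death
  expect_equal(out$hr_mean, 1.0)
  expect_equal(out$gain_mean, 100)
  expect_equal(out$gain_point, 100)

  # risk ranking identical to poverty ranking -> gain exactly 0
  p2 <- 1 - tab$wealth_cdf
  out2 <- targeting(p2, tab, q = 0.2)
  expect_equal(out2$gain_mean, 0)

  # no deaths among the poorest set -> undefined gain, flagged
  tab3 <- tab
  tab3$died_u5 <- c(0, 0, 1, 0, 0, 0, 0, 0, 0, 1)
  expect_warning(out3 <- targeting(p, tab3, q = 0.2), "undefined")
  expect_true(is.na(out3$gain_mean))
})

test_that("targeting gains are invariant to monotone risk transforms", {
  fix <- small_fit_cache()
  out1 <- targeting(fix$risk, fix$tab)
  transformed <- list(
    qlogis(fix$risk$draws),
    fix$risk$draws^3,
    exp(5 * fix$risk$draws)
  )
  for (M in transformed) {
    out2 <- targeting(M, fix$tab)
    expect_equal(out2$hr_draws, out1$hr_draws, tolerance = 1e-12)
    expect_equal(out2$gain_draws, out1$gain_draws, tolerance = 1e-12)
  }
})

test_that("true-risk targeting is optimal among equally sized subsets", {
  # exhaustive check on a 12-birth toy: the top-risk subset maximises the
  # expected death count over all C(12,2) candidate subsets
  set.seed(8)
  p <- round(runif(12, 0.02, 0.6), 3)
  sets <- utils::combn(12, 2)
  expected_deaths <- colSums(matrix(p[sets], nrow = 2))
  top <- order(-p, seq_along(p))[1:2]
  top_expected <- sum(p[top])
  expect_gte(top_expected, max(expected_deaths))
  # hence the expected gain over ANY other 2-birth targeting rule is >= 0
  expect_true(all((top_expected - expected_deaths) / expected_deaths >= 0))
})

test_that("group comparison reproduces 2x2 odds-ratio arithmetic", {
  # 8 births, high-risk half has prevalence 3/4, the rest 1/4
  tab <- tibble::tibble(
    birth_id = 1:8,
    died_u5 = c(1, 1, 0, 0, 0, 0, 0, 0),
    wealth_cdf = (1:8 - 0.5) / 8,
    urban = c("urban", "urban", "urban", "rural", "urban", "rural",
              "rural", "rural"),
    prior_death = c(1, 1, 1, 0, 1, 0, 0, 0)
  )
  p <- c(0.9, 0.8, 0.7, 0.6, 0.1, 0.1, 0.1, 0.1)
  out <- compare_groups(p, tab, q = 0.5,
                        categorical = c("urban", "prior_death"),
                        continuous = "wealth_cdf")
  or <- out$summary[out$summary$term == "urban", ]
  expect_equal(or$estimate, 9)
  # mean difference for the continuous covariate
  md <- out$summary[out$summary$term == "wealth_cdf", ]
  expect_equal(md$estimate, mean(tab$wealth_cdf[1:4]) - mean(tab$wealth_cdf[5:8]))
})

test_that("comparisons flag signal and stay null under independence", {
  set.seed(21)
  n <- 400
  S <- 200
  x <- rbinom(n, 1, 0.5)
  # risk draws independent of the covariate: interval straddles 1
  M <- matrix(runif(S * n), S, n)
  tab <- tibble::tibble(birth_id = 1:n, died_u5 = rbinom(n, 1, 0.2),
                        wealth_cdf = runif(n), prior_death = x)
  out <- compare_groups(M, tab, q = 0.2, categorical = "prior_death",
                        continuous = character(0))
  row <- out$summary[out$summary$term == "prior_death", ]
  expect_true(row$conf.low < 1 && row$conf.high > 1)
  expect_false(row$significant)
  # a constant covariate is skipped with a note
  tab$urban <- "rural"
  expect_message(
    out2 <- compare_groups(M, tab, q = 0.2,
                           categorical = c("urban", "prior_death"),
                           continuous = character(0)),
    "constant"
  )
  expect_false("urban" %in% out2$summary$term)
})

test_that("high-risk births are poorer under a wealth gradient", {
  fix <- small_fit_cache()
  out <- compare_groups(fix$risk, fix$tab)
  wc <- out$summary[out$summary$term == "wealth_cdf", ]
  expect_lt(wc$estimate, 0)
  expect_true(wc$significant)
  # prior loss is over-represented in the high-risk group
  pd <- out$summary[out$summary$term == "prior_death", ]
  expect_gt(pd$estimate, 1)
})

test_that("the equity report bundles and tidies every statistic", {
  fix <- small_fit_cache()
  rep <- suppressMessages(equity_report(fix$risk, fix$tab))
  expect_s3_class(rep, "u5_equity_report")
  td <- tidy(rep)
  expect_true(all(c("npd", "anova_r2_wealth", "efficiency_gain_pct") %in%
                    td$statistic))
  expect_true(any(grepl("compare_", td$statistic)))
  dir <- withr::local_tempdir()
  paths <- write_equity_report(rep, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[["json"]])
  expect_equal(js$npd, rep$npd, tolerance = 1e-9)
  expect_equal(js$n, nrow(fix$tab))
})

test_that("plot builders return ggplot objects", {
  fix <- small_fit_cache()
  expect_s3_class(plot_risk_box(fix$risk, fix$tab$wealth_quintile), "ggplot")
  expect_s3_class(autoplot(fix$risk), "ggplot")
  expect_s3_class(autoplot(anova_r2(fix$risk, fix$tab$wealth_quintile)),
                  "ggplot")
  expect_s3_class(autoplot(targeting(fix$risk, fix$tab)), "ggplot")
  expect_s3_class(autoplot(compare_groups(fix$risk, fix$tab)), "ggplot")
})
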
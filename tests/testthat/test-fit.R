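# helper: a one-draw fitted object with hand-chosen coefficients, for
# checking the risk map without any sampling
fake_fit <- function(tab, beta_named, spec) {
  design <- suppressMessages(build_design(tab, spec))
  beta <- matrix(0, nrow = 1, ncol = ncol(design$X),
                 dimnames = list(NULL, colnames(design$X)))
  beta[1, names(beta_named)] <- beta_named
  structure(
    list(beta = beta, u = NULL, sigma = matrix(1, 1, 1), sigma_loc = 1,
         design = design, spec = spec, seed = 0L,
         rhat = c(alpha = 1), n = nrow(tab), deaths = sum(tab$died_u5)),
    class = "u5_fit"
  )
}

test_that("posterior risk reproduces a hand-computed inverse-logit exactly", {
  tab <- tibble::tibble(
    birth_id = 1:4,
    wealth_cdf = c(0.1, 0.3, 0.6, 0.9),
    prior_death = c(0, 1, 0, 1),
    died_u5 = c(0, 1, 0, 0),
    cluster_id = 1
  )
  spec <- model_spec(continuous = "wealth_cdf", binary = "prior_death",
                     spline_knots = list(), max_interaction_order = 1,
                     cluster_effect = FALSE, chains = 1, draws_total = 1)
  fit <- fake_fit(tab, c("(Intercept)" = -2, wealth_cdf = 0.7,
                         prior_death = -0.4), spec)
  risk <- posterior_risk(fit)
  # independent arithmetic: standardise by hand, then inverse-logit
  w <- tab$wealth_cdf
  z <- (w - mean(w)) / sd(w)
  pd <- tab$prior_death - mean(tab$prior_death)
  expected <- 1 / (1 + exp(-(-2 + 0.7 * z - 0.4 * pd)))
  expect_equal(as.numeric(risk$draws), expected, tolerance = 1e-12)
  expect_equal(risk$posterior_mean, expected, tolerance = 1e-12)

  # all-zero coefficients give risk 1/2 everywhere
  fit0 <- fake_fit(tab, c("(Intercept)" = 0), spec)
  expect_equal(as.numeric(posterior_risk(fit0)$draws), rep(0.5, 4))

  # raising a positively-weighted covariate raises that draw's risk
  tab2 <- tab
  tab2$wealth_cdf <- tab$wealth_cdf + 0.05
  r2 <- posterior_risk(fit, newdata = tab2)
  expect_true(all(r2$draws > risk$draws))
})

test_that("an intercept-only model recovers the death rate", {
  set.seed(31)
  n <- 10000
  tab <- tibble::tibble(
    birth_id = seq_len(n),
    died_u5 = rbinom(n, 1, 0.1),
    cluster_id = 1
  )
  spec <- model_spec(continuous = character(0), binary = character(0),
                     max_interaction_order = 1, cluster_effect = FALSE,
                     chains = 2, warmup = 200, draws_total = 500)
  fit <- fit_risk_model(tab, spec, seed = 2)
  risk <- posterior_risk(fit)
  d <- sum(tab$died_u5)
  # flat-prior conjugate benchmark: Beta(1 + d, 1 + n - d)
  beta_mean <- (1 + d) / (2 + n)
  beta_sd <- sqrt(beta_mean * (1 - beta_mean) / n)
  expect_lt(abs(mean(risk$posterior_mean) - beta_mean), 3 * beta_sd)
  # every birth shares the same risk in every draw
  expect_lt(max(apply(risk$draws, 1, sd)), 1e-12)
})

test_that("degenerate outcomes are rejected", {
  tab <- tibble::tibble(birth_id = 1:50, died_u5 = 0,
                        wealth_cdf = runif(50), cluster_id = 1)
  spec <- model_spec(continuous = "wealth_cdf", binary = character(0),
                     max_interaction_order = 1, cluster_effect = FALSE,
                     chains = 1, warmup = 10, draws_total = 10)
  expect_error(fit_risk_model(tab, spec), "no deaths")
  tab$died_u5 <- 1
  expect_error(fit_risk_model(tab, spec), "no survivors")
})

test_that("posterior agrees with an independent JAGS fit of the same model", {
  set.seed(77)
  n <- 1500
  x1 <- rnorm(n)
  x2 <- rbinom(n, 1, 0.5)
  eta <- -1.6 + 0.9 * x1 - 0.7 * x2
  y <- rbinom(n, 1, plogis(eta))
  tab <- tibble::tibble(birth_id = seq_len(n), died_u5 = y,
                        wealth_cdf = x1, prior_death = x2, cluster_id = 1)
  spec <- model_spec(continuous = "wealth_cdf", binary = "prior_death",
                     spline_knots = list(), max_interaction_order = 1,
                     prior_scales = 5, # wide: match the fixed JAGS prior
                     cluster_effect = FALSE,
                     chains = 2, warmup = 500, draws_total = 3000)
  fit <- fit_risk_model(tab, spec, seed = 3)
  est <- colMeans(fit$beta)

  # same model, same priors, independent engine
  X <- fit$design$X[, 2:3]
  model_str <- "
  model {
    for (i in 1:n) {
      logit(p[i]) <- a + b1 * x1[i] + b2 * x2[i]
      y[i] ~ dbern(p[i])
    }
    a ~ dnorm(0, 0.04)
    b1 ~ dnorm(0, 0.04)
    b2 ~ dnorm(0, 0.04)
  }"
  jm <- rjags::jags.model(
    textConnection(model_str),
    data = list(y = y, x1 = X[, 1], x2 = X[, 2], n = n),
    n.chains = 1, n.adapt = 300, quiet = TRUE
  )
  stats::update(jm, 300, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("a", "b1", "b2"), n.iter = 3000,
                            progress.bar = "none")
  jags_est <- colMeans(as.matrix(sm))
  expect_equal(unname(est[1:3]), unname(jags_est[c("a", "b1", "b2")]),
               tolerance = 0.035)
})

test_that("vanishing interaction priors collapse to the main-effects fit", {
  fix <- small_fit_cache()
  tab <- fix$tab
  spec_main <- model_spec(max_interaction_order = 1, chains = 2,
                          warmup = 400, draws_total = 400)
  spec_tiny <- model_spec(max_interaction_order = 2,
                          prior_scales = c(1, 1e-6), chains = 2,
                          warmup = 400, draws_total = 400)
  fit_main <- suppressWarnings(fit_risk_model(tab, spec_main, seed = 4))
  fit_tiny <- suppressWarnings(fit_risk_model(tab, spec_tiny, seed = 4))
  # interaction coefficients are crushed to zero
  inter_cols <- fit_tiny$design$col_info$order == 2
  expect_lt(max(abs(colMeans(fit_tiny$beta[, inter_cols]))), 1e-4)
  # and per-birth risks match the main-effects model closely
  r_main <- posterior_risk(fit_main)$posterior_mean
  r_tiny <- posterior_risk(fit_tiny)$posterior_mean
  expect_lt(mean(abs(r_main - r_tiny)), 0.01)
  expect_lt(max(abs(r_main - r_tiny)), 0.05)
})

test_that("risk draws are calibrated to the observed death rate", {
  fix <- small_fit_cache()
  per_draw_mean <- rowMeans(fix$risk$draws)
  obs <- mean(fix$tab$died_u5)
  expect_lt(abs(mean(per_draw_mean) - obs), 2 * sd(per_draw_mean) + 0.005)
})

test_that("order-wise scales shrink harder with interaction order", {
  fix <- small_fit_cache()
  tab <- fix$tab
  spec <- model_spec(max_interaction_order = 3, chains = 2,
                     warmup = 400, draws_total = 400)
  fit <- suppressWarnings(fit_risk_model(tab, spec, seed = 6))
  sig <- colMeans(fit$sigma)
  # the data carry main effects only, so higher orders shrink hardest
  expect_true(all(diff(sig) < 0))
})

test_that("the wealth gradient is recovered without material bias", {
  res <- sapply(1:3, function(seed) {
    births <- generate_survey(gradient_scenario(n_births = 20000, seed = seed))
    tab <- suppressMessages(prepare_births(births))
    spec <- model_spec(spline_knots = list(), max_interaction_order = 1,
                       chains = 2, warmup = 300, draws_total = 600)
    fit <- suppressWarnings(fit_risk_model(tab, spec, seed = seed))
    draws <- fit$beta[, "wealth_cdf"]
    c(est = mean(draws),
      truth = -1.5 * fit$design$scales[["wealth_cdf"]],
      sd = sd(draws))
  })
  expect_true(all(res["est", ] < 0)) # right sign in every replicate
  # no systematic bias: the seed-averaged error is small against the
  # posterior spread (per-seed error is ordinary sampling noise)
  expect_lt(abs(mean(res["est", ] - res["truth", ])),
            0.5 * mean(res["sd", ]))
})

test_that("fit returns exactly the requested number of pooled draws", {
  fix <- small_fit_cache()
  expect_equal(nrow(fix$fit$beta), 400)
  expect_equal(nrow(fix$risk$draws), 400)
  expect_equal(ncol(fix$risk$draws), nrow(fix$tab))
  # draws_total not divisible by chains still returns draws_total
  tab <- fix$tab[1:500, ]
  spec <- model_spec(max_interaction_order = 1, chains = 3, warmup = 100,
                     draws_total = 100, cluster_effect = FALSE)
  fit <- suppressWarnings(suppressMessages(fit_risk_model(tab, spec, seed = 8)))
  expect_equal(nrow(fit$beta), 100)
})

test_that("tidy and glance expose coefficient and model summaries", {
  fix <- small_fit_cache()
  td <- tidy(fix$fit)
  expect_true(all(c("term", "block", "order", "estimate", "conf.low",
                    "conf.high") %in% names(td)))
  expect_equal(nrow(td), ncol(fix$fit$beta))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fix$fit)
  expect_equal(gl$n, nrow(fix$tab))
  expect_equal(gl$draws, 400)
  tr <- tidy(fix$risk)
  expect_equal(nrow(tr), nrow(fix$tab))
  expect_true(all(tr$estimate > 0 & tr$estimate < 1))
})
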
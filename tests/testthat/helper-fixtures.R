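# Small programmatic fixtures shared across test files.

# A minimal valid birth table built by hand; one survey, three mothers.
toy_births <- function() {
  tibble::tibble(
    birth_id = 1:6,
    survey_id = "S1",
    cluster_id = c(1, 1, 2, 2, 3, 3),
    mother_id = c(1, 1, 1, 2, 2, 3),
    birth_order = c(1, 2, 3, 1, 2, 1),
    birth_date = c(2006, 2008, 2011, 2007, 2009.5, 2008.5),
    survey_date = 2015,
    sex = c("male", "female", "male", "female", "male", "female"),
    maternal_age_at_birth = c(19, 21, 24, 25, 27.5, 30),
    maternal_education = c(0, 0, 0, 6, 6, 11),
    wealth_score = c(-1.2, -1.2, -1.2, 0.3, 0.3, 2.1),
    urban = c("rural", "rural", "rural", "rural", "rural", "urban"),
    died_u5 = c(0, 1, 0, 0, 0, 0),
    death_date = c(NA, 2009, NA, NA, NA, NA)
  )
}

# An analysis-like table with fully controllable risk and wealth, used by
# the equity-metric tests; risks are supplied by the caller.
toy_analysis_table <- function(n, died, wealth_cdf,
                               quintile = assign_quintiles(wealth_cdf)) {
  tibble::tibble(
    birth_id = seq_len(n),
    died_u5 = died,
    wealth_cdf = wealth_cdf,
    wealth_quintile = quintile
  )
}

# A quick small fitted model on gradient-scenario data, cached per session
# because several tests probe the same fit.
small_fit_cache <- local({
  env <- new.env()
  function() {
    if (is.null(env$fit)) {
      births <- generate_survey(gradient_scenario(n_births = 4000, seed = 11))
      tab <- suppressMessages(prepare_births(births))
      spec <- model_spec(max_interaction_order = 2, chains = 2,
                         warmup = 500, draws_total = 400)
      env$tab <- tab
      env$fit <- suppressWarnings(
        suppressMessages(fit_risk_model(tab, spec, seed = 11))
      )
      env$risk <- posterior_risk(env$fit)
    }
    list(fit = env$fit, tab = env$tab, risk = env$risk)
  }
})
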
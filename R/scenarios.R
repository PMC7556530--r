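#' Define a synthetic-survey scenario
#'
#' A scenario fixes the ground-truth risk surface and population structure
#' from which [generate_survey()] simulates a DHS-like birth-history table.
#' The linear predictor for each birth is, on the log-odds scale,
#'
#' \deqn{\eta = \alpha + \sum_v \beta_v t_v + \gamma (F(w) - 0.5) +
#'   \sum_{I} \beta_I \prod_{v \in I} t_v + u_{c}}
#'
#' where \eqn{F(w)} is the true (distribution-function) wealth rank of the
#' mother's household, \eqn{u_c} is a cluster effect with standard deviation
#' `cluster_sd`, and the covariate terms \eqn{t_v} are on fixed, documented
#' scales: maternal age in decades centred at 25, education in years centred
#' at 6, birth order centred at 2, birth year in years centred at the middle
#' of the usual analysis window (`survey_year - 7.5`), wealth as
#' \eqn{F(w) - 0.5}, and `sex` (male = 1), `urban` (urban = 1) and
#' `prior_death` as 0/1 indicators.
#'
#' `prob_fun`, when supplied, replaces the covariate part of the surface: it
#' receives the per-birth covariate table (including `wealth_cdf_true`,
#' `wealth_quintile_true`, `maternal_education`, `urban`, `sex`,
#' `maternal_age_at_birth`, `birth_order`, `prior_death`) and must return a
#' death probability in (0,1) per birth; the cluster effect is then added on
#' the log-odds scale. This supports benchmark surfaces defined directly on
#' the probability scale.
#'
#' @param n_mothers Number of mothers (one household each).
#' @param max_parity Maximum number of births per mother; parity is uniform
#'   on `1:max_parity`.
#' @param n_clusters Number of sampling clusters.
#' @param cluster_sd Standard deviation of the cluster effect (log-odds).
#' @param baseline_logit Intercept of the risk surface (log-odds).
#' @param effect_sizes Named numeric vector of main effects (log-odds per
#'   unit of the scales above); valid names are `"age"`, `"education"`,
#'   `"sex"`, `"urban"`, `"prior_death"`, `"birth_order"`, `"birth_year"`.
#' @param interaction_effects Named numeric vector of interaction effects;
#'   names are `:`-joined covariate keys, e.g. `"urban:prior_death:wealth"`.
#' @param wealth_gradient Log-odds change per unit of true wealth rank.
#' @param wealth_dist Household wealth-score distribution: a list with
#'   element `dist` in `c("lognormal", "normal", "uniform")` plus its
#'   parameters (`meanlog`/`sdlog`, `mean`/`sd`, or `min`/`max`).
#' @param prob_fun Optional function giving the death probability directly
#'   (see Details).
#' @param survey_year Calendar year of the (single) survey.
#' @param p_urban Probability a mother lives in an urban cluster.
#' @param seed Integer seed; [generate_survey()] is byte-reproducible in it.
#' @return A `u5_scenario` list.
#' @seealso [equity_scenario()], [gradient_scenario()],
#'   [interaction_scenario()], [quintile_step_scenario()],
#'   [quintile_variance_scenario()]
#' @export
scenario_config <- function(n_mothers = 4000,
                            max_parity = 4,
                            n_clusters = 150,
                            cluster_sd = 0.3,
                            baseline_logit = qlogis(0.08),
                            effect_sizes = numeric(0),
                            interaction_effects = numeric(0),
                            wealth_gradient = 0,
                            wealth_dist = list(dist = "lognormal",
                                               meanlog = 0, sdlog = 1),
                            prob_fun = NULL,
                            survey_year = 2015,
                            p_urban = 0.4,
                            seed = 1L) {
  stopifnot(
    n_mothers >= 1, max_parity >= 1, n_clusters >= 1, cluster_sd >= 0,
    is.finite(baseline_logit), is.numeric(wealth_gradient),
    is.null(prob_fun) || is.function(prob_fun)
  )
  valid <- c("age", "education", "sex", "urban", "prior_death",
             "birth_order", "birth_year")
  if (length(effect_sizes) > 0) {
    bad <- setdiff(names(effect_sizes), valid)
    if (length(bad) > 0) {
      abort(paste0("unknown effect name(s): ", paste(bad, collapse = ", ")))
    }
  }
  if (length(interaction_effects) > 0) {
    keys <- unlist(strsplit(names(interaction_effects), ":", fixed = TRUE))
    bad <- setdiff(keys, c(valid, "wealth"))
    if (length(bad) > 0) {
      abort(paste0("unknown interaction key(s): ", paste(bad, collapse = ", ")))
    }
  }
  structure(
    list(
      n_mothers = as.integer(n_mothers),
      max_parity = as.integer(max_parity),
      n_clusters = as.integer(n_clusters),
      cluster_sd = cluster_sd,
      baseline_logit = baseline_logit,
      effect_sizes = effect_sizes,
      interaction_effects = interaction_effects,
      wealth_gradient = wealth_gradient,
      wealth_dist = wealth_dist,
      prob_fun = prob_fun,
      survey_year = survey_year,
      p_urban = p_urban,
      seed = as.integer(seed)
    ),
    class = "u5_scenario"
  )
}

#' Canned benchmark scenarios
#'
#' Ready-made scenarios used throughout the tests and examples.
#'
#' * `equity_scenario()`: perfect equity — every birth has the same death
#'   probability `p`, independent of wealth and everything else. Under this
#'   surface the non-poor-deaths fraction is 80% in expectation.
#' * `quintile_step_scenario()`: a pro-poor mortality gradient in its
#'   starkest form — births in the poorest fifth of the true wealth
#'   distribution die with probability `p_poorest`, all others with
#'   `p_other`.
#' * `gradient_scenario()`: a smooth negative wealth gradient plus modest
#'   effects of residence, maternal age, education and a prior sibling
#'   death, with clustered baseline risk — a caricature of a typical
#'   high-mortality survey.
#' * `interaction_scenario()`: the gradient scenario plus rural-by-prior-
#'   death-by-wealth interactions, so that no single risk factor identifies
#'   the highest-risk births.
#' * `quintile_variance_scenario()`: a surface built directly on the
#'   probability scale in which the share of risk variance attributable to
#'   wealth-quintile membership equals `f` exactly (see Details).
#'
#' @details
#' `quintile_variance_scenario()` draws household wealth uniformly (so the
#' true wealth rank is the score itself) and sets
#' \deqn{p_i = p_0 + a (w_i - 0.5) + g (e_i - 6)}
#' with \eqn{w} the wealth rank and \eqn{e} maternal education, uniform on
#' `0:12` and independent of wealth. Risk then varies between quintiles
#' (through the quintile means of \eqn{w}) and within them (through
#' education and within-quintile wealth), and \eqn{a, g} are solved so that
#' the between-quintile share of the total risk variance equals `f` and the
#' total risk standard deviation equals `total_sd`. Cluster effects are off,
#' so the surface is fully attributable to modelled covariates.
#'
#' @param n_births Number of births (mothers each have a single birth in the
#'   scenarios that fix the birth count).
#' @param p,p_poorest,p_other,p0 Death probabilities.
#' @param f Target between-quintile share of risk variance, in (0,1).
#' @param total_sd Total standard deviation of true risk.
#' @param seed Integer seed.
#' @return A `u5_scenario`.
#' @name scenarios
NULL

#' @rdname scenarios
#' @export
equity_scenario <- function(n_births = 200000, p = 0.10, seed = 1L) {
  scenario_config(
    n_mothers = n_births, max_parity = 1, n_clusters = 400, cluster_sd = 0,
    baseline_logit = qlogis(p), wealth_gradient = 0, seed = seed
  )
}

#' @rdname scenarios
#' @export
quintile_step_scenario <- function(n_births = 200000, p_poorest = 0.20,
                                   p_other = 0.10, seed = 1L) {
  scenario_config(
    n_mothers = n_births, max_parity = 1, n_clusters = 400, cluster_sd = 0,
    baseline_logit = qlogis(p_other),
    wealth_dist = list(dist = "uniform", min = 0, max = 1),
    prob_fun = function(d) {
      ifelse(d$wealth_quintile_true == 1L, p_poorest, p_other)
    },
    seed = seed
  )
}

#' @rdname scenarios
#' @export
gradient_scenario <- function(n_births = 20000, seed = 1L) {
  scenario_config(
    n_mothers = max(1L, as.integer(round(n_births / 2.5))),
    max_parity = 4, n_clusters = 250, cluster_sd = 0.25,
    baseline_logit = qlogis(0.12),
    wealth_gradient = -1.5,
    effect_sizes = c(
      age = -0.20, education = -0.03, sex = 0.10, urban = -0.30,
      prior_death = 0.50, birth_order = 0.05, birth_year = -0.02
    ),
    seed = seed
  )
}

#' @rdname scenarios
#' @export
interaction_scenario <- function(n_births = 20000, seed = 1L) {
  cfg <- gradient_scenario(n_births = n_births, seed = seed)
  # poor rural births to mothers with a prior loss carry extra risk that no
  # single factor reveals: a negative prior-death-by-wealth slope, partly
  # cancelled in urban areas by the three-way term
  cfg$interaction_effects <- c(
    "prior_death:wealth" = -1.50,
    "urban:prior_death:wealth" = 1.00
  )
  cfg
}

#' @rdname scenarios
#' @export
quintile_variance_scenario <- function(f, n_births = 20000, p0 = 0.10,
                                       total_sd = 0.04, seed = 1L) {
  stopifnot(f > 0, f < 1)
  # wealth rank uniform: Var(w) = 1/12; quintile means of w have variance
  # 0.08 about 0.5, leaving 1/12 - 0.08 = 1/300 within quintiles.
  # education uniform on 0:12: Var = (13^2 - 1)/12 = 14.
  v_tot <- total_sd^2
  a2 <- f * v_tot / 0.08
  g2 <- (v_tot - a2 / 12) / 14
  if (g2 <= 0) {
    abort("f too large for this total_sd: no within-quintile variance left")
  }
  a <- sqrt(a2)
  g <- sqrt(g2)
  scenario_config(
    n_mothers = n_births, max_parity = 1, n_clusters = 200, cluster_sd = 0,
    baseline_logit = qlogis(p0),
    wealth_dist = list(dist = "uniform", min = 0, max = 1),
    prob_fun = function(d) {
      p0 + a * (d$wealth_cdf_true - 0.5) + g * (d$maternal_education - 6)
    },
    seed = seed
  )
}
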
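#' Simulate a DHS-like birth-history survey from a known risk surface
#'
#' Draws mothers (one household each) with cluster assignment, wealth score,
#' education, residence and an age-at-first-birth, then simulates their
#' births sequentially in birth order: each birth's prior-death indicator is
#' determined by the earlier simulated outcomes of the same mother, its
#' death is a Bernoulli draw from the true probability implied by the
#' scenario's risk surface, and deaths receive a death date uniform within
#' five years of birth. First birth dates are spread over the thirteen years
#' before the survey, with subsequent births roughly two years apart, so
#' that the generated table deliberately contains births outside the
#' five-to-ten-years-before-survey analysis window.
#'
#' The returned table carries, alongside the observable record columns, the
#' ground truth per birth: `true_lp` (linear predictor, log-odds) and
#' `true_p = plogis(true_lp)`. [survey_truth()] extracts them;
#' [write_survey()] writes observable records and truth to separate CSVs.
#'
#' @param config A `u5_scenario` from [scenario_config()] or one of the
#'   canned scenarios.
#' @return A tibble with one row per birth: `birth_id`, `survey_id`,
#'   `cluster_id`, `mother_id`, `birth_order`, `birth_date`, `survey_date`,
#'   `sex`, `maternal_age_at_birth`, `maternal_education`, `wealth_score`,
#'   `urban`, `died_u5`, `death_date`, `true_lp`, `true_p`. The scenario is
#'   attached as attribute `"config"`.
#' @examples
#' births <- generate_survey(equity_scenario(n_births = 500, seed = 42))
#' mean(births$died_u5)
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "u5_scenario"))
  set.seed(config$seed)

  n_m <- config$n_mothers
  sy <- config$survey_year

  wd <- config$wealth_dist
  wealth_score <- switch(wd$dist,
    lognormal = stats::rlnorm(n_m, wd$meanlog, wd$sdlog),
    normal = rnorm(n_m, wd$mean, wd$sd),
    uniform = runif(n_m, wd$min, wd$max),
    abort(paste0("unknown wealth distribution: ", wd$dist))
  )
  wealth_cdf_true <- switch(wd$dist,
    lognormal = stats::plnorm(wealth_score, wd$meanlog, wd$sdlog),
    normal = stats::pnorm(wealth_score, wd$mean, wd$sd),
    uniform = stats::punif(wealth_score, wd$min, wd$max)
  )

  mothers <- tibble(
    mother_id = seq_len(n_m),
    cluster_id = sample.int(config$n_clusters, n_m, replace = TRUE),
    wealth_score = wealth_score,
    wealth_cdf_true = wealth_cdf_true,
    wealth_quintile_true = pmin(pmax(ceiling(5 * wealth_cdf_true), 1L), 5L),
    maternal_education = sample(0:12, n_m, replace = TRUE),
    urban01 = rbinom(n_m, 1, config$p_urban),
    age_first_birth = pmin(pmax(rnorm(n_m, 19.5, 3), 13), 45),
    parity = sample.int(config$max_parity, n_m, replace = TRUE),
    first_birth_date = runif(n_m, sy - 13, sy - 0.5)
  )
  u_cluster <- rnorm(config$n_clusters, 0, config$cluster_sd)

  # simulate birth-by-birth so prior_death only sees earlier outcomes
  out <- vector("list", config$max_parity)
  earliest_death <- rep(Inf, n_m) # earliest death date among prior births
  birth_date <- mothers$first_birth_date
  for (j in seq_len(config$max_parity)) {
    alive_idx <- which(mothers$parity >= j)
    if (j > 1) {
      birth_date <- birth_date + 2 + runif(n_m, -0.5, 1)
    }
    idx <- alive_idx[birth_date[alive_idx] <= sy]
    if (length(idx) == 0) next
    m <- mothers[idx, ]
    bd <- birth_date[idx]
    d <- tibble(
      mother_id = m$mother_id,
      cluster_id = m$cluster_id,
      birth_order = j,
      birth_date = bd,
      sex = ifelse(rbinom(length(idx), 1, 0.512) == 1, "male", "female"),
      maternal_age_at_birth = m$age_first_birth + (bd - mothers$first_birth_date[idx]),
      maternal_education = m$maternal_education,
      wealth_score = m$wealth_score,
      wealth_cdf_true = m$wealth_cdf_true,
      wealth_quintile_true = m$wealth_quintile_true,
      urban01 = m$urban01,
      prior_death = as.numeric(is.finite(earliest_death[idx]) &
                                 earliest_death[idx] < bd)
    )
    lp <- .true_linear_predictor(d, config) + u_cluster[d$cluster_id]
    if (any(!is.finite(lp))) {
      abort("scenario yields a non-finite linear predictor; reject config")
    }
    p <- plogis(lp)
    died <- rbinom(nrow(d), 1, p)
    death_date <- ifelse(died == 1, bd + runif(nrow(d), 0, 5), NA_real_)
    d$died_u5 <- died
    d$death_date <- death_date
    d$true_lp <- lp
    d$true_p <- p
    out[[j]] <- d
    dd <- which(died == 1)
    if (length(dd) > 0) {
      earliest_death[idx[dd]] <- pmin(earliest_death[idx[dd]], death_date[dd])
    }
  }

  births <- bind_rows(out) |>
    arrange(.data$mother_id, .data$birth_order) |>
    mutate(
      birth_id = dplyr::row_number(),
      survey_id = "S1",
      survey_date = sy + 0.5,
      urban = ifelse(.data$urban01 == 1, "urban", "rural")
    ) |>
    select(
      "birth_id", "survey_id", "cluster_id", "mother_id", "birth_order",
      "birth_date", "survey_date", "sex", "maternal_age_at_birth",
      "maternal_education", "wealth_score", "urban", "died_u5", "death_date",
      "true_lp", "true_p"
    )
  attr(births, "config") <- config
  births
}

# covariate terms of the scenario risk surface, on the generator's
# documented scales; `d` must carry the per-birth covariate columns.
.scenario_terms <- function(d, config) {
  list(
    wealth = d$wealth_cdf_true - 0.5,
    age = (d$maternal_age_at_birth - 25) / 10,
    education = d$maternal_education - 6,
    sex = as.numeric(d$sex == "male"),
    urban = as.numeric(d$urban01 == 1),
    prior_death = d$prior_death,
    birth_order = d$birth_order - 2,
    birth_year = d$birth_date - (config$survey_year - 7.5)
  )
}

.true_linear_predictor <- function(d, config) {
  if (!is.null(config$prob_fun)) {
    p <- config$prob_fun(d)
    if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
      abort("prob_fun returned probabilities outside (0, 1)")
    }
    return(qlogis(p))
  }
  terms <- .scenario_terms(d, config)
  lp <- rep(config$baseline_logit, nrow(d))
  lp <- lp + config$wealth_gradient * terms$wealth
  es <- config$effect_sizes
  for (nm in names(es)) lp <- lp + es[[nm]] * terms[[nm]]
  ie <- config$interaction_effects
  for (nm in names(ie)) {
    keys <- strsplit(nm, ":", fixed = TRUE)[[1]]
    prod_term <- Reduce(`*`, terms[keys])
    lp <- lp + ie[[nm]] * prod_term
  }
  lp
}

#' Evaluate a scenario's true risk surface on a covariate grid
#'
#' Computes the death probability a scenario assigns to given covariate
#' combinations, without simulating outcomes or cluster effects. Useful for
#' checking analytic properties of a scenario (monotonicity, interaction
#' structure) against the generated data.
#'
#' @param config A `u5_scenario`.
#' @param grid A data frame with columns `wealth_cdf_true`,
#'   `maternal_age_at_birth`, `maternal_education`, `sex`, `urban01`,
#'   `prior_death`, `birth_order`, `birth_date` (missing columns are filled
#'   with reference values), and optionally `wealth_quintile_true`.
#' @return `grid` with columns `true_lp` and `true_p` appended.
#' @export
scenario_risk <- function(config, grid) {
  stopifnot(inherits(config, "u5_scenario"))
  defaults <- list(
    wealth_cdf_true = 0.5, maternal_age_at_birth = 25,
    maternal_education = 6, sex = "female", urban01 = 0, prior_death = 0,
    birth_order = 2, birth_date = config$survey_year - 7.5
  )
  grid <- as_tibble(grid)
  for (nm in names(defaults)) {
    if (!nm %in% names(grid)) grid[[nm]] <- defaults[[nm]]
  }
  if (!"wealth_quintile_true" %in% names(grid)) {
    grid$wealth_quintile_true <-
      pmin(pmax(ceiling(5 * grid$wealth_cdf_true), 1L), 5L)
  }
  lp <- .true_linear_predictor(grid, config)
  grid$true_lp <- lp
  grid$true_p <- plogis(lp)
  grid
}

#' Extract or export the simulated ground truth
#'
#' @param births A table from [generate_survey()].
#' @return `survey_truth()` returns a tibble keyed by `birth_id` with the
#'   true linear predictor and death probability.
#' @export
survey_truth <- function(births) {
  stopifnot(all(c("birth_id", "true_lp", "true_p") %in% names(births)))
  births |> select("birth_id", "true_lp", "true_p")
}

#' @rdname survey_truth
#' @param dir Output directory (created if needed); `births.csv`,
#'   `truth.csv` and `scenario.txt` (key=value lines) are written there.
#' @return `write_survey()` returns the paths, invisibly.
#' @export
write_survey <- function(births, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obs <- births |> select(-dplyr::any_of(c("true_lp", "true_p")))
  p1 <- file.path(dir, "births.csv")
  p2 <- file.path(dir, "truth.csv")
  write.csv(obs, p1, row.names = FALSE)
  write.csv(survey_truth(births), p2, row.names = FALSE)
  cfg <- attr(births, "config")
  p3 <- file.path(dir, "scenario.txt")
  if (!is.null(cfg)) {
    scalars <- cfg[vapply(cfg, function(x) {
      is.atomic(x) && length(x) == 1
    }, logical(1))]
    writeLines(paste0(names(scalars), "=", unlist(scalars)), p3)
  }
  invisible(c(births = p1, truth = p2, scenario = p3))
}

#' Read a birth-record CSV
#'
#' Reads a CSV written by [write_survey()] (or any external extract using
#' the documented column schema) and validates the required columns.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of birth records.
#' @export
read_births <- function(path) {
  births <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_births(births)
  births
}
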
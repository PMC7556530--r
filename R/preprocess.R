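#' Restrict births to the analysis window
#'
#' Keeps exactly the births that occurred at least five but less than ten
#' years before their survey date, i.e. with
#' `survey_date - birth_date` in `[5, 10)`. Births younger than five years
#' are excluded because their under-5 outcome is censored; births ten or
#' more years old are excluded to limit recall error. Records with a
#' missing survey date cannot be windowed and are rejected with a warning.
#'
#' The exclusion tally is attached as attribute `"exclusions"` (a tibble
#' with columns `reason` and `n`) and can be read with
#' [filter_exclusions()]. The filter is idempotent.
#'
#' @param births A data frame of birth records with `birth_date` and
#'   `survey_date` in decimal years.
#' @return The filtered tibble.
#' @examples
#' b <- tibble::tibble(birth_date = c(2008, 2012, 2004),
#'                     survey_date = 2014)
#' filter_births(b)
#' @export
filter_births <- function(births) {
  stopifnot(all(c("birth_date", "survey_date") %in% names(births)))
  births <- as_tibble(births)
  age <- births$survey_date - births$birth_date
  missing_sd <- is.na(births$survey_date) | is.na(births$birth_date)
  too_recent <- !missing_sd & age < 5
  too_old <- !missing_sd & age >= 10
  if (any(missing_sd)) {
    warn(paste0(sum(missing_sd), " record(s) with missing dates rejected"))
  }
  excl <- tibble(
    reason = c("under_5y_before_survey", "10y_or_more_before_survey",
               "missing_date"),
    n = c(sum(too_recent), sum(too_old), sum(missing_sd))
  )
  kept <- births[!missing_sd & !too_recent & !too_old, , drop = FALSE]
  attr(kept, "exclusions") <- excl
  kept
}

#' @rdname filter_births
#' @export
filter_exclusions <- function(births) {
  attr(births, "exclusions")
}

#' Empirical distribution-function transform of wealth scores
#'
#' Maps raw wealth-index scores, whose scale is arbitrary and
#' survey-specific, onto the unit interval by their within-survey empirical
#' distribution value, so that wealth is comparable across surveys as a
#' relative rank. The midpoint-rank convention `(rank - 0.5) / n` is used,
#' with tied scores receiving their average rank, so output always lies
#' strictly inside (0, 1) and is invariant to any strictly increasing
#' rescaling of the raw scores.
#'
#' This is the vector-level primitive; [add_wealth_cdf()] applies it at the
#' household level of a birth table.
#'
#' @param scores Numeric wealth scores.
#' @param survey_id Optional grouping vector: the transform is computed
#'   independently within each survey.
#' @return Numeric vector in (0, 1), same length as `scores`.
#' @examples
#' wealth_cdf_transform(c(10, 20, 30, 40))
#' @export
wealth_cdf_transform <- function(scores, survey_id = NULL) {
  if (is.null(survey_id)) survey_id <- rep(1L, length(scores))
  stopifnot(length(scores) == length(survey_id))
  out <- rep(NA_real_, length(scores))
  for (s in unique(survey_id)) {
    i <- which(survey_id == s)
    x <- scores[i]
    if (length(unique(x)) == 1 && length(x) > 1) {
      warn(paste0("all wealth scores identical in survey ", s,
                  "; wealth rank set to 0.5"))
    }
    r <- rank(x, ties.method = "average")
    out[i] <- (r - 0.5) / length(x)
  }
  out
}

#' Attach household-level wealth ranks to a birth table
#'
#' Computes the within-survey wealth distribution over unique households
#' (mothers), so a household with many births counts once, and joins the
#' resulting `wealth_cdf` back to every birth of the household.
#'
#' @param births A birth table with `survey_id`, `mother_id` and
#'   `wealth_score`.
#' @return `births` with a `wealth_cdf` column appended.
#' @export
add_wealth_cdf <- function(births) {
  stopifnot(all(c("survey_id", "mother_id", "wealth_score") %in% names(births)))
  hh <- births |>
    distinct(.data$survey_id, .data$mother_id, .data$wealth_score)
  dup <- hh |> count(.data$survey_id, .data$mother_id) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("a household (mother) has more than one wealth score")
  }
  n_hh <- hh |> count(.data$survey_id)
  if (any(n_hh$n < 2)) {
    warn("fewer than 2 households in a survey; wealth ranks are degenerate")
  }
  hh$wealth_cdf <- wealth_cdf_transform(hh$wealth_score, hh$survey_id)
  births |>
    as_tibble() |>
    left_join(hh |> select(-"wealth_score"),
              by = c("survey_id", "mother_id"))
}

#' Assign wealth quintiles from wealth ranks
#'
#' Quintile `k` collects ranks in `((k-1)/5, k/5]`; quintile 1 is the
#' poorest fifth, quintile 5 the richest.
#'
#' @param wealth_cdf Numeric vector in (0, 1).
#' @return Integer vector in `1:5`.
#' @examples
#' assign_quintiles(c(0.19, 0.21, 0.5))
#' @export
assign_quintiles <- function(wealth_cdf) {
  stopifnot(all(wealth_cdf > 0 & wealth_cdf < 1, na.rm = TRUE))
  as.integer(pmin(pmax(ceiling(5 * wealth_cdf), 1L), 5L))
}

#' Prior-death indicator
#'
#' Flags births whose mother had already lost an earlier child before the
#' index birth: the indicator is 1 exactly when some sibling of lower birth
#' order died under five *and* that death occurred strictly before the index
#' birth date. It is 0 for every first birth, and never uses information
#' from later births. When a died sibling has no recorded death date, the
#' death is counted as preceding the index birth only if the sibling's birth
#' date plus five years precedes it (a conservative bound on the death
#' date); the number of such fallbacks is reported in a message.
#'
#' @param births A birth table with `survey_id`, `mother_id`, `birth_order`,
#'   `birth_date`, `died_u5` and (optionally) `death_date`.
#' @return `births` with a `prior_death` column (0/1) appended.
#' @export
add_prior_death <- function(births) {
  stopifnot(all(c("survey_id", "mother_id", "birth_order", "birth_date",
                  "died_u5") %in% names(births)))
  births <- as_tibble(births)
  if (!"death_date" %in% names(births)) births$death_date <- NA_real_
  n_fallback <- sum(births$died_u5 == 1 & is.na(births$death_date))
  if (n_fallback > 0) {
    inform(paste0(n_fallback, " death(s) without a death date; treated as ",
                  "pre-index only when birth_date + 5 precedes the index birth"))
  }
  ord <- order(births$survey_id, births$mother_id, births$birth_order)
  b <- births[ord, ]
  # effective date a prior death is known to have happened by
  eff <- ifelse(b$died_u5 == 1,
                ifelse(is.na(b$death_date), b$birth_date + 5, b$death_date),
                Inf)
  prior <- b |>
    mutate(.eff = eff) |>
    group_by(.data$survey_id, .data$mother_id) |>
    mutate(.prior = as.numeric(
      cummin(dplyr::lag(.data$.eff, default = Inf)) < .data$birth_date
    )) |>
    ungroup() |>
    pull(".prior")
  res <- births
  res$prior_death <- prior[order(ord)]
  res
}

#' Build the model-ready analysis table
#'
#' Chains the preprocessing steps in their required order: the prior-death
#' indicator is computed on the full birth history (siblings outside the
#' analysis window still inform it), then births are restricted to the
#' five-to-ten-year window, records missing any model covariate are dropped
#' (and counted), wealth ranks are computed over the households remaining in
#' the window, and quintiles are assigned. An input that already carries a
#' `wealth_quintile` column (e.g. survey-assigned quintiles) keeps it;
#' otherwise quintiles are cut from `wealth_cdf` at 0.2, 0.4, 0.6, 0.8.
#'
#' @param births A raw birth-record table (see [validate_births()] for the
#'   required columns).
#' @return An analysis tibble with `wealth_cdf`, `wealth_quintile` and
#'   `prior_death` appended; window-exclusion counts are attached as
#'   attribute `"exclusions"` and dropped-for-missingness counts as
#'   attribute `"n_dropped_missing"`.
#' @examples
#' births <- generate_survey(equity_scenario(n_births = 300, seed = 7))
#' tab <- prepare_births(births)
#' table(tab$wealth_quintile)
#' @export
prepare_births <- function(births) {
  validate_births(births)
  tab <- births |>
    add_prior_death() |>
    filter_births()
  excl <- attr(tab, "exclusions")
  covariate_cols <- c("birth_order", "birth_date", "sex",
                      "maternal_age_at_birth", "maternal_education",
                      "wealth_score", "urban", "died_u5")
  cc <- complete.cases(tab[, covariate_cols])
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " record(s) dropped for missing covariates"))
    tab <- tab[cc, , drop = FALSE]
  }
  tab <- tab |> add_wealth_cdf()
  if (!"wealth_quintile" %in% names(tab)) {
    tab$wealth_quintile <- assign_quintiles(tab$wealth_cdf)
  }
  attr(tab, "exclusions") <- excl
  attr(tab, "n_dropped_missing") <- n_dropped
  tab
}
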
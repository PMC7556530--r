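#' Convert DHS-style century-month codes to decimal years
#'
#' DHS recode files store dates as century-month codes (CMC): the number of
#' months elapsed since January 1900. These helpers convert between CMC and
#' the decimal-year scale used throughout this package. The mapping places a
#' date at the midpoint of its month. This is a convenience for preparing
#' external birth-history extracts; it has not been validated against any
#' specific recode file.
#'
#' @param cmc Integer vector of century-month codes.
#' @param year Numeric vector of decimal years.
#' @return `cmc_to_year()` returns decimal years; `year_to_cmc()` returns
#'   integer century-month codes.
#' @examples
#' cmc_to_year(1200) # December 1999
#' year_to_cmc(2000.0)
#' @export
cmc_to_year <- function(cmc) {
  1900 + (cmc - 0.5) / 12
}

#' @rdname cmc_to_year
#' @export
year_to_cmc <- function(year) {
  as.integer(floor((year - 1900) * 12) + 1)
}

# columns every birth-record table must carry
.required_birth_cols <- c(
  "birth_id", "survey_id", "cluster_id", "mother_id", "birth_order",
  "birth_date", "survey_date", "sex", "maternal_age_at_birth",
  "maternal_education", "wealth_score", "urban", "died_u5"
)

#' Validate a birth-record table
#'
#' Checks that a data frame carries the columns required by the preprocessing
#' and modelling functions, with an informative error naming any missing
#' column. Called internally by [prepare_births()] and [run_pipeline()].
#'
#' @param births A data frame of birth records.
#' @return `births`, invisibly, if valid.
#' @export
validate_births <- function(births) {
  stopifnot(is.data.frame(births))
  missing_cols <- setdiff(.required_birth_cols, names(births))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "birth table is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(births)
}

# 0/1 coding for the two categorical covariates, tolerant of labels
.binary01 <- function(x, one_label) {
  if (is.numeric(x)) return(as.numeric(x != 0))
  as.numeric(x == one_label)
}

# equal-tailed 95% interval
.ci95 <- function(x) {
  unname(quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
}

# split-half potential scale reduction factor for a vector of pooled draws
# laid out chain-by-chain; each chain is split in two for the diagnostic.
.split_rhat <- function(x, chains) {
  n <- length(x)
  per <- n %/% chains
  if (per < 4) return(NA_real_)
  half <- per %/% 2
  segs <- list()
  for (ch in seq_len(chains)) {
    off <- (ch - 1) * per
    segs[[2 * ch - 1]] <- x[off + seq_len(half)]
    segs[[2 * ch]] <- x[off + half + seq_len(half)]
  }
  m <- length(segs)
  means <- vapply(segs, mean, numeric(1))
  vars <- vapply(segs, var, numeric(1))
  W <- mean(vars)
  B <- half * var(means)
  if (!is.finite(W) || W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}
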
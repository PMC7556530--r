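#' Piecewise-linear (hinge) spline basis
#'
#' Returns the covariate itself plus one hinge column `pmax(0, x - k)` per
#' knot. Together with an intercept, linear combinations of these columns
#' reproduce exactly every continuous piecewise-linear function with breaks
#' at the knots. Knots outside the observed range of `x` produce a constant
#' column and are dropped with a warning.
#'
#' @param x Numeric vector.
#' @param knots Numeric vector of strictly increasing knot locations (may be
#'   empty, giving the single linear column).
#' @return A numeric matrix with named columns; retained knots are attached
#'   as attribute `"knots"`.
#' @examples
#' piecewise_linear_basis(c(1, 2, 3), knots = 2)
#' @export
piecewise_linear_basis <- function(x, knots = numeric(0)) {
  stopifnot(is.numeric(x))
  knots <- as.numeric(knots)
  if (length(knots) > 1 && any(diff(knots) <= 0)) {
    abort("knots must be strictly increasing")
  }
  inside <- knots > min(x, na.rm = TRUE) & knots < max(x, na.rm = TRUE)
  if (any(!inside)) {
    warn(paste0(sum(!inside), " knot(s) outside the observed range dropped"))
    knots <- knots[inside]
  }
  out <- matrix(x, ncol = 1, dimnames = list(NULL, "x"))
  for (k in knots) {
    out <- cbind(out, pmax(0, x - k))
    colnames(out)[ncol(out)] <- paste0("hinge_", format(k, digits = 6))
  }
  attr(out, "knots") <- knots
  out
}

#' Specify the mortality-risk model
#'
#' Collects the covariate list, spline knots, interaction order, shrinkage
#' schedule and sampler settings for [fit_risk_model()].
#'
#' The default model uses the eight base covariates of the analysis table —
#' five continuous (maternal age at birth, wealth rank, maternal education,
#' birth year, birth order) and three binary (child sex, urban residence,
#' prior sibling death). Continuous covariates enter the main effects
#' through piecewise-linear splines; all size-2 to size-`max_interaction_order`
#' products of the (standardised, linear) base covariates form the
#' interaction blocks. All coefficients of a given interaction order `k`
#' share a scale \eqn{\sigma_k} with a Half-Normal(`prior_scales[k]`) prior;
#' the schedule must be strictly decreasing so higher-order interactions are
#' shrunk harder.
#'
#' @param continuous,binary Character vectors of covariate column names.
#' @param spline_knots `NULL` for default knots at the 25/50/75% covariate
#'   quantiles, an empty `list()` for no knots (linear main effects), or a
#'   named list mapping covariate name to raw-scale knot locations.
#' @param max_interaction_order Highest interaction order (1 = main effects
#'   only; default 4).
#' @param prior_scales Half-Normal scales for the coefficient-scale priors
#'   of orders 1..`max_interaction_order`; strictly decreasing.
#' @param cluster_effect Include a sampling-cluster random intercept with
#'   scale \eqn{\sigma_{loc} \sim} Half-Normal(1)?
#' @param chains,warmup,draws_total Sampler settings: number of chains,
#'   warmup iterations per chain, and total post-warmup draws pooled across
#'   chains (default 4 chains, 500 warmup, 1000 draws).
#' @return A `u5_model_spec`.
#' @export
model_spec <- function(continuous = c("maternal_age_at_birth", "wealth_cdf",
                                      "maternal_education", "birth_date",
                                      "birth_order"),
                       binary = c("sex", "urban", "prior_death"),
                       spline_knots = NULL,
                       max_interaction_order = 4,
                       prior_scales = c(1, 0.5, 0.25, 0.125),
                       cluster_effect = TRUE,
                       chains = 4,
                       warmup = 500,
                       draws_total = 1000) {
  stopifnot(
    max_interaction_order >= 1,
    max_interaction_order <= max(1, length(continuous) + length(binary)),
    draws_total >= 1, chains >= 1, warmup >= 0
  )
  prior_scales <- prior_scales[seq_len(max_interaction_order)]
  if (any(!is.finite(prior_scales)) || any(prior_scales <= 0)) {
    abort("prior_scales must be positive for every used order")
  }
  if (length(prior_scales) > 1 && any(diff(prior_scales) >= 0)) {
    abort("prior_scales must be strictly decreasing in interaction order")
  }
  if (!is.null(spline_knots) && length(spline_knots) > 0) {
    ok <- vapply(spline_knots, function(k) all(diff(k) > 0), logical(1))
    if (!all(ok)) abort("spline knots must be strictly increasing")
  }
  structure(
    list(
      continuous = continuous, binary = binary, spline_knots = spline_knots,
      max_interaction_order = as.integer(max_interaction_order),
      prior_scales = prior_scales,
      cluster_effect = isTRUE(cluster_effect),
      chains = as.integer(chains), warmup = as.integer(warmup),
      draws_total = as.integer(draws_total)
    ),
    class = "u5_model_spec"
  )
}

# 0/1 base covariate values on the analysis table
.base_covariates <- function(table, spec) {
  vals <- list()
  for (v in spec$continuous) {
    if (!v %in% names(table)) abort(paste0("missing covariate column: ", v))
    vals[[v]] <- as.numeric(table[[v]])
  }
  for (v in spec$binary) {
    if (!v %in% names(table)) abort(paste0("missing covariate column: ", v))
    one <- switch(v, sex = "male", urban = "urban", "1")
    vals[[v]] <- .binary01(table[[v]], one)
  }
  vals
}

#' Build the design matrix for the risk model
#'
#' Standardises the continuous covariates (mean 0, sd 1), centres the binary
#' ones, expands the continuous main effects into piecewise-linear spline
#' bases, and forms every size-2 to size-`max_interaction_order` product of
#' the standardised base covariates as interaction columns (interactions use
#' the linear, not the splined, version of continuous covariates). Constant
#' covariates are excluded from the design, with a message. Standardisation
#' constants and knots are stored so the same transform can be applied to
#' new data via the `reuse` argument.
#'
#' @param table An analysis table from [prepare_births()].
#' @param spec A [model_spec()].
#' @param reuse Optionally, a previous `u5_design` whose standardisation
#'   constants, knots and cluster levels are applied unchanged.
#' @return A `u5_design` list with the matrix `X` (leading intercept
#'   column), per-column metadata `col_info` (`column`, `block`, `order`),
#'   transform constants, and the cluster index.
#' @export
build_design <- function(table, spec = model_spec(), reuse = NULL) {
  stopifnot(inherits(spec, "u5_model_spec"))
  if (any(!complete.cases(table[, intersect(names(table),
                                            c(spec$continuous, spec$binary))]))) {
    abort("missing covariate values in analysis table; drop or impute first")
  }
  vals <- .base_covariates(table, spec)
  n <- nrow(table)

  if (is.null(reuse)) {
    centers <- vapply(vals, mean, numeric(1))
    scales <- vapply(vals, sd, numeric(1))
    scales[spec$binary] <- 1 # binary covariates are centred only
    knots <- .resolve_knots(vals, spec)
  } else {
    centers <- reuse$centers
    scales <- reuse$scales
    knots <- reuse$knots
  }

  if (is.null(reuse)) {
    constant <- names(scales)[!is.finite(scales) | scales == 0 |
                                vapply(vals, function(x) {
                                  length(unique(x)) == 1
                                }, logical(1))]
    if (length(constant) > 0) {
      inform(paste0("constant covariate(s) excluded: ",
                    paste(constant, collapse = ", ")))
    }
    active <- setdiff(names(vals), constant)
  } else {
    constant <- reuse$constant
    active <- reuse$active
  }

  std <- lapply(setNames(active, active), function(v) {
    (vals[[v]] - centers[[v]]) / scales[[v]]
  })

  cols <- list(`(Intercept)` = rep(1, n))
  info <- list(tibble(column = "(Intercept)", block = "(Intercept)",
                      order = 0L))
  for (v in intersect(spec$continuous, active)) {
    if (is.null(reuse)) {
      basis <- piecewise_linear_basis(std[[v]], knots[[v]])
      knots[[v]] <- attr(basis, "knots")
    } else {
      # apply stored knots verbatim so new data gets identical columns
      basis <- matrix(std[[v]], ncol = 1)
      for (k in knots[[v]]) basis <- cbind(basis, pmax(0, std[[v]] - k))
    }
    cn <- c(v, paste0(v, "_h", seq_along(knots[[v]])))
    cn <- cn[seq_len(ncol(basis))]
    for (j in seq_len(ncol(basis))) cols[[cn[j]]] <- basis[, j]
    info[[length(info) + 1]] <- tibble(column = cn, block = v, order = 1L)
  }
  for (v in intersect(spec$binary, active)) {
    cols[[v]] <- std[[v]]
    info[[length(info) + 1]] <- tibble(column = v, block = v, order = 1L)
  }
  if (spec$max_interaction_order >= 2) {
    for (k in 2:spec$max_interaction_order) {
      if (length(active) < k) break
      combos <- utils::combn(active, k, simplify = FALSE)
      for (cmb in combos) {
        nm <- paste(cmb, collapse = ":")
        cols[[nm]] <- Reduce(`*`, std[cmb])
        info[[length(info) + 1]] <- tibble(column = nm, block = nm,
                                           order = as.integer(k))
      }
    }
  }
  X <- do.call(cbind, cols)
  col_info <- bind_rows(info)
  if (is.null(reuse)) {
    zero <- apply(X, 2, function(x) all(x == 0))
    if (any(zero)) {
      X <- X[, !zero, drop = FALSE]
      col_info <- col_info[!zero, ]
    }
  } else {
    X <- X[, reuse$col_info$column, drop = FALSE]
    col_info <- reuse$col_info
  }

  if (spec$cluster_effect && "cluster_id" %in% names(table)) {
    lev <- if (is.null(reuse)) {
      sort(unique(table$cluster_id))
    } else {
      reuse$cluster_levels
    }
    cluster_index <- match(table$cluster_id, lev) - 1L
    cluster_index[is.na(cluster_index)] <- -1L # unseen cluster -> no offset
  } else {
    lev <- NULL
    cluster_index <- integer(0)
  }

  structure(
    list(
      X = X, col_info = col_info, centers = centers, scales = scales,
      knots = knots, active = active, constant = constant,
      cluster_levels = lev, cluster_index = cluster_index,
      birth_id = table$birth_id %||% seq_len(n), spec = spec
    ),
    class = "u5_design"
  )
}

.resolve_knots <- function(vals, spec) {
  knots <- list()
  for (v in spec$continuous) {
    if (is.null(spec$spline_knots)) {
      k_raw <- unname(quantile(vals[[v]], c(0.25, 0.5, 0.75), names = FALSE))
      k_raw <- unique(k_raw)
      k_raw <- k_raw[k_raw > min(vals[[v]]) & k_raw < max(vals[[v]])]
    } else {
      k_raw <- spec$spline_knots[[v]] %||% numeric(0)
    }
    mu <- mean(vals[[v]])
    s <- sd(vals[[v]])
    knots[[v]] <- if (is.finite(s) && s > 0) (k_raw - mu) / s else numeric(0)
  }
  knots
}
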
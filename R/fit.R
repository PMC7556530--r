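#' Fit the hierarchical Bayesian logistic mortality-risk model
#'
#' Fits, by exact-conditional Gibbs sampling with Polya-Gamma data
#' augmentation, the model
#' \deqn{\mathrm{logit}\, p_i = \alpha + x_i'\beta + u_{c(i)}}
#' where the design `x` holds the splined main effects and the interaction
#' products of [build_design()], every coefficient of interaction order `k`
#' has prior \eqn{N(0, \sigma_k^2)} with
#' \eqn{\sigma_k \sim} Half-Normal(`prior_scales[k]`), the cluster effects
#' are \eqn{u_c \sim N(0, \sigma_{loc}^2)} with
#' \eqn{\sigma_{loc} \sim} Half-Normal(1), and
#' \eqn{\alpha \sim N(0, 5^2)} on the log-odds scale. One model is fit per
#' survey; pass a single-survey table.
#'
#' Exactly `spec$draws_total` post-warmup draws are returned, pooled across
#' chains. The split potential-scale-reduction diagnostic is computed for
#' the intercept, each order scale and the cluster scale; values above 1.05
#' raise a warning (not a failure). Perfect separation does not break the
#' fit (the priors regularise it) but an all-deaths or all-survivors
#' outcome is an error.
#'
#' @param table An analysis table from [prepare_births()].
#' @param spec A [model_spec()].
#' @param seed Integer seed for the sampler.
#' @return A `u5_fit` object: posterior draws of the coefficients
#'   (`beta`, draws x columns), cluster effects (`u`), order scales
#'   (`sigma`), cluster scale (`sigma_loc`), plus the design and
#'   diagnostics. Methods: [tidy()], [glance()], `print()`.
#' @export
fit_risk_model <- function(table, spec = model_spec(), seed = 1L) {
  stopifnot(inherits(spec, "u5_model_spec"))
  y <- as.numeric(table$died_u5)
  if (any(is.na(y))) abort("missing outcome values")
  if (sum(y) == 0) abort("no deaths in the data; the model cannot be fit")
  if (sum(y) == nrow(table)) abort("no survivors in the data")

  design <- build_design(table, spec)
  .check_separation(table, spec, y)

  n_cluster <- length(design$cluster_levels %||% integer(0))
  cl <- if (n_cluster > 0) design$cluster_index else integer(0)

  chains <- spec$chains
  keep_per <- ceiling(spec$draws_total / chains)
  runs <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + 977L * (ch - 1L))
    runs[[ch]] <- gibbs_logit_cpp(
      design$X, y, design$col_info$order, spec$prior_scales,
      fixed_sd = 5, cluster = cl, n_cluster = n_cluster, loc_scale = 1,
      n_warmup = spec$warmup, n_keep = keep_per
    )
  }
  beta <- do.call(rbind, lapply(runs, `[[`, "beta"))
  u <- do.call(rbind, lapply(runs, `[[`, "u"))
  sigma <- do.call(rbind, lapply(runs, `[[`, "sigma"))
  sigma_loc <- unlist(lapply(runs, `[[`, "sigma_loc"))
  colnames(beta) <- design$col_info$column
  colnames(sigma) <- paste0("sigma_order", seq_len(ncol(sigma)))

  rhat <- c(
    alpha = .split_rhat(beta[, 1], chains),
    setNames(
      vapply(seq_len(ncol(sigma)), function(g) {
        .split_rhat(sigma[, g], chains)
      }, numeric(1)),
      colnames(sigma)
    ),
    sigma_loc = if (n_cluster > 0) .split_rhat(sigma_loc, chains) else NA_real_
  )
  bad <- rhat[!is.na(rhat) & rhat > 1.05]
  if (length(bad) > 0) {
    warn(paste0("convergence diagnostics above 1.05 for: ",
                paste(names(bad), collapse = ", "),
                "; consider more warmup or draws"))
  }

  # trim any pooling surplus evenly: drop the last draw of the last chains
  S <- spec$draws_total
  total <- chains * keep_per
  keep <- rep(TRUE, total)
  extra <- total - S
  if (extra > 0) {
    drop_chains <- chains - seq_len(extra) + 1L
    keep[drop_chains * keep_per] <- FALSE
  }
  idx <- which(keep)
  structure(
    list(
      beta = beta[idx, , drop = FALSE],
      u = if (n_cluster > 0) u[idx, , drop = FALSE] else NULL,
      sigma = sigma[idx, , drop = FALSE],
      sigma_loc = sigma_loc[idx],
      design = design, spec = spec, seed = as.integer(seed),
      rhat = rhat, n = nrow(table), deaths = sum(y)
    ),
    class = "u5_fit"
  )
}

.check_separation <- function(table, spec, y) {
  for (v in spec$binary) {
    if (!v %in% names(table)) next
    one <- switch(v, sex = "male", urban = "urban", "1")
    x <- .binary01(table[[v]], one)
    tab <- table(factor(x, levels = 0:1), factor(y, levels = 0:1))
    if (any(tab == 0)) {
      inform(paste0("possible separation: covariate '", v,
                    "' has an empty outcome cell; priors regularise the fit"))
    }
  }
}

#' @export
print.u5_fit <- function(x, ...) {
  cat("Hierarchical Bayesian logistic mortality-risk model\n")
  cat(sprintf("  births: %d  deaths: %d (%.3f)\n", x$n, x$deaths,
              x$deaths / x$n))
  cat(sprintf("  design columns: %d  interaction order: %d  clusters: %d\n",
              ncol(x$beta), x$spec$max_interaction_order,
              length(x$design$cluster_levels %||% integer(0))))
  cat(sprintf("  draws: %d (%d chains)  max split-Rhat: %.3f\n",
              nrow(x$beta), x$spec$chains, max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Per-birth posterior mortality-risk draws
#'
#' Applies every posterior parameter draw to the design matrix (including
#' the cluster effect) and inverse-logit transforms, giving an S x N matrix
#' of death probabilities: row `s` is the risk surface under draw `s`,
#' column `i` the risk distribution of birth `i`. The per-birth posterior
#' mean is attached.
#'
#' @param fit A `u5_fit`.
#' @param newdata Optionally a new analysis table; the training
#'   standardisation constants, knots and cluster levels are reused
#'   (unseen clusters get a zero offset).
#' @return A `u5_risk` object: `draws` (S x N), `posterior_mean` (length
#'   N), `birth_id`.
#' @export
posterior_risk <- function(fit, newdata = NULL) {
  stopifnot(inherits(fit, "u5_fit"))
  design <- if (is.null(newdata)) {
    fit$design
  } else {
    build_design(newdata, fit$spec, reuse = fit$design)
  }
  if (ncol(fit$beta) != ncol(design$X)) {
    abort("draw / design column mismatch")
  }
  eta <- fit$beta %*% t(design$X)
  n_cluster <- length(fit$design$cluster_levels %||% integer(0))
  if (n_cluster > 0 && length(design$cluster_index) > 0) {
    seen <- design$cluster_index >= 0
    if (any(seen)) {
      eta[, seen] <- eta[, seen] + fit$u[, design$cluster_index[seen] + 1L,
                                         drop = FALSE]
    }
  }
  draws <- plogis(eta)
  structure(
    list(
      draws = draws,
      posterior_mean = colMeans(draws),
      birth_id = design$birth_id
    ),
    class = "u5_risk"
  )
}

#' @export
print.u5_risk <- function(x, ...) {
  cat(sprintf("Posterior mortality risk: %d draws x %d births\n",
              nrow(x$draws), ncol(x$draws)))
  cat(sprintf("  mean risk %.4f  (range of per-birth means %.4f - %.4f)\n",
              mean(x$posterior_mean), min(x$posterior_mean),
              max(x$posterior_mean)))
  invisible(x)
}

# normalise the various accepted risk inputs to an S x N matrix
.risk_matrix <- function(risk) {
  if (inherits(risk, "u5_risk")) return(risk$draws)
  if (is.matrix(risk)) return(risk)
  if (is.numeric(risk)) return(matrix(risk, nrow = 1))
  abort("risk must be a u5_risk object, a draws matrix, or a numeric vector")
}

#' Export a risk posterior
#'
#' Writes the per-birth posterior mean as CSV and (optionally) the full
#' draw matrix as a compressed RDS archive.
#'
#' @param risk A `u5_risk`.
#' @param dir Output directory.
#' @param draws Also write the full draw matrix?
#' @return The written paths, invisibly.
#' @export
write_risk <- function(risk, dir, draws = FALSE) {
  stopifnot(inherits(risk, "u5_risk"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "posterior_mean.csv")
  write.csv(
    tibble(birth_id = risk$birth_id, posterior_mean = risk$posterior_mean),
    p1, row.names = FALSE
  )
  paths <- p1
  if (draws) {
    p2 <- file.path(dir, "risk_draws.rds")
    saveRDS(risk$draws, p2, compress = "xz")
    paths <- c(paths, p2)
  }
  invisible(paths)
}
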
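#' Run the full simulate - preprocess - fit - analyse pipeline
#'
#' Orchestrates one end-to-end analysis: obtain birth records (either a
#' canned scenario simulated on the fly or a CSV on disk), build the
#' analysis table, fit the hierarchical risk model, compute the posterior
#' risk draws and the equity report, and write every artifact plus a run
#' manifest to `out_dir`. All randomness (simulation and sampler) funnels
#' through `seed`. Any stage failure propagates as an error tagged with the
#' stage name.
#'
#' @param input Either the name of a canned scenario (`"equity"`,
#'   `"gradient"`, `"interaction"`) or a path to a birth-record CSV.
#' @param out_dir Output directory, created if needed.
#' @param spec A [model_spec()]; the default full model is heavy, so scale
#'   `chains`/`warmup`/`draws_total` and `max_interaction_order` to the
#'   problem at hand.
#' @param q Targeted fraction for the equity analyses.
#' @param seed Integer seed.
#' @param n_births Birth count when simulating a named scenario.
#' @param save_draws Write the full risk draw matrix (RDS)?
#' @return Invisibly, a list with the `u5_equity_report`, the fitted model
#'   and the written paths.
#' @export
run_pipeline <- function(input, out_dir, spec = model_spec(), q = 0.20,
                         seed = 1L, n_births = 10000, save_draws = FALSE) {
  stopifnot(q > 0, q < 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("[", stage, "] ", conditionMessage(e)))
    })
    timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    res
  }

  births <- tick("simulate", {
    if (input %in% c("equity", "gradient", "interaction")) {
      cfg <- switch(input,
        equity = equity_scenario(n_births = n_births, seed = seed),
        gradient = gradient_scenario(n_births = n_births, seed = seed),
        interaction = interaction_scenario(n_births = n_births, seed = seed)
      )
      b <- generate_survey(cfg)
      write_survey(b, out_dir)
      b
    } else {
      read_births(input)
    }
  })

  tab <- tick("preprocess", prepare_births(births))
  write.csv(tab |> select(-dplyr::any_of(c("true_lp", "true_p"))),
            file.path(out_dir, "analysis_table.csv"), row.names = FALSE)

  fit <- tick("fit", fit_risk_model(tab, spec, seed = seed))
  risk <- tick("posterior_risk", posterior_risk(fit))
  write_risk(risk, out_dir, draws = save_draws)

  report <- tick("analyze", equity_report(risk, tab, q = q))
  paths <- write_equity_report(report, out_dir)

  manifest <- list(
    package = "u5equity",
    version = as.character(packageVersion("u5equity")),
    r_version = R.version.string,
    input = input,
    seed = as.integer(seed),
    q = q,
    n_births_analysed = nrow(tab),
    spec = list(
      max_interaction_order = spec$max_interaction_order,
      chains = spec$chains, warmup = spec$warmup,
      draws_total = spec$draws_total,
      cluster_effect = spec$cluster_effect
    ),
    timings_sec = timings,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(report = report, fit = fit, risk = risk,
                 table = tab, paths = paths, out_dir = out_dir))
}
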
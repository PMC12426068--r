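# End-to-end pipeline: read or simulate data, fit, check, contrast, and
# write all artifacts with a run log.

#' Run the full analysis pipeline
#'
#' Executes read/simulate -> latent-trait fit -> posterior-predictive
#' checks -> contrast battery, writing every artifact to `out_dir`:
#' `summary.json` (posterior summary + config), `posterior_draws.tsv`
#' (group-level draws), `frequencies.tsv` (the analyzed tables),
#' `ppc.json` / `ppc_scatter.tsv`, `contrasts.json` / `contrasts.tsv`, and
#' `run.log` (seed, priors, versions, convergence diagnostics).  Any stage
#' error aborts with a stage-labeled message.
#'
#' The configuration is a nested list (or a YAML file path) with optional
#' blocks:
#' * `input`: `trials` or `frequencies` (file path) and an optional column
#'   `dialect` mapping for trial files; mutually exclusive with
#' * `simulation`: `n_participants`, `items_per_source`, `n_distractors`,
#'   `heterogeneity_sd`, `remember_rate`, and an optional `mean_prob`
#'   override of the default generating regime;
#' * `coding_rule`: `"remember_only"` (default) or `"remember_plus_know"`;
#' * `design`: item/participant counts when reading external data;
#' * `inference`: arguments of [inference_config()];
#' * `checks`: `n_rep`; `contrasts`: `credibility`;
#' * `seed`: integer master seed (stage seeds are derived from it).
#'
#' @param config Nested list or path to a YAML file.
#' @param out_dir Output directory (created if absent).
#' @param seed Optional master-seed override.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with `tables`, `fit`, `summary`, `ppc`,
#'   `contrasts`, and the artifact paths.
#' @export
run_pipeline <- function(config = list(), out_dir = "mptsource-run", seed = NULL,
                         verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(seed)) seed <- if (!is.null(config$seed)) config$seed else 1
  seed <- as.integer(seed) %% 10^8
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("mptsource %s | %s", packageVersion("mptsource"),
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("R %s | master seed %d", getRversion(), seed))
  say <- function(...) if (verbose) message(...)
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", label, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  constraints <- standard_constraints()
  rule <- if (!is.null(config$coding_rule)) config$coding_rule else "remember_only"

  # --- data stage -----------------------------------------------------
  sim <- config$simulation
  tables <- stage("data", {
    if (!is.null(config$input$frequencies)) {
      say("reading frequency tables")
      read_frequencies(config$input$frequencies)
    } else if (!is.null(config$input$trials)) {
      say("reading trial records (coding rule: ", rule, ")")
      design <- design_spec(
        n_participants = config$design$n_participants %||% 1,
        items_per_source = config$design$items_per_source %||% 9,
        n_distractors = config$design$n_distractors %||% 18)
      recs <- read_trials(config$input$trials,
                          dialect = unlist(config$input$dialect))
      build_frequency_tables(recs, rule = rule, design = design)
    } else {
      say("simulating cohort")
      design <- design_spec(
        n_participants = sim$n_participants %||% 82,
        items_per_source = sim$items_per_source %||% 9,
        n_distractors = sim$n_distractors %||% 18)
      group <- default_group_distribution(
        constraints, heterogeneity_sd = sim$heterogeneity_sd %||% 0.4)
      if (!is.null(sim$mean_prob)) {
        mp <- pnorm(group$mu)
        mp[names(sim$mean_prob)] <- unlist(sim$mean_prob)
        group <- group_distribution(mean_prob = mp, sigma = group$sigma,
                                    constraints = constraints)
      }
      params <- draw_participants(group, design$n_participants, seed = seed)
      recs <- simulate_trials(params, design,
                              remember_rate = sim$remember_rate %||% 0.5,
                              seed = seed + 1L)
      write_trials(recs, file.path(out_dir, "trials.tsv"))
      build_frequency_tables(recs, rule = rule, design = design)
    }
  })
  if (!length(tables)) stop("pipeline stage 'data' failed: no complete participants")
  design <- design_spec(n_participants = length(tables),
                        items_per_source = tables[[1]]$items_per_type[["TI"]],
                        n_distractors = tables[[1]]$items_per_type[["new"]])
  write_frequencies(tables, file.path(out_dir, "frequencies.tsv"))
  log_lines <- c(log_lines,
                 sprintf("participants: %d | items per source: %d | distractors: %d | coding rule: %s",
                         design$n_participants, design$items_per_source,
                         design$n_distractors, rule))

  # --- fit stage ------------------------------------------------------
  inf <- config$inference
  cfg <- inference_config(
    n_chains = inf$n_chains %||% 2,
    n_iterations = inf$n_iterations %||% 50000,
    n_burnin = inf$n_burnin,
    thinning = inf$thinning %||% 10,
    n_adapt = inf$n_adapt %||% 2000,
    seed = seed + 2L,
    prior_mu_sd = inf$prior_mu_sd %||% 1)
  say("fitting latent-trait model (", cfg$n_chains, " chains x ",
      cfg$n_iterations, " iterations)")
  fit <- stage("fit", fit_mpt(tables, constraints, design, cfg))
  export_posterior(fit, file.path(out_dir, "posterior_draws.tsv"),
                   file.path(out_dir, "summary.json"))
  log_lines <- c(log_lines,
                 sprintf("priors: mu %s; sigma %s", fit$priors$mu, fit$priors$sigma),
                 sprintf("sampler: %d chains x %d iterations (burn-in %d, thinning %d), %d retained draws",
                         cfg$n_chains, cfg$n_iterations, cfg$n_burnin,
                         cfg$thinning, nrow(fit$group_prob)),
                 sprintf("max potential scale reduction: %s",
                         format(suppressWarnings(max(fit$diagnostics$rhat, na.rm = TRUE)),
                                digits = 4)))

  # --- checks stage ---------------------------------------------------
  n_rep <- config$checks$n_rep %||% 500
  say("posterior-predictive checks (", n_rep, " replications)")
  ppc <- stage("checks", list(T1 = ppc_T1(fit, n_rep = n_rep, seed = seed + 3L),
                              T2 = ppc_T2(fit, n_rep = n_rep, seed = seed + 4L)))
  export_ppc(ppc, file.path(out_dir, "ppc.json"),
             file.path(out_dir, "ppc_scatter.tsv"))
  log_lines <- c(log_lines, sprintf("PPC: T1 p = %.3f, T2 p = %.3f",
                                    ppc$T1$p_value, ppc$T2$p_value))

  # --- contrasts stage ------------------------------------------------
  say("contrast battery")
  contrasts <- stage("contrasts",
                     contrast_battery(fit, credibility = config$contrasts$credibility %||% 0.95))
  export_contrasts(contrasts, file.path(out_dir, "contrasts.json"),
                   file.path(out_dir, "contrasts.tsv"))

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(tables = tables, fit = fit, summary = summarize_posterior(fit),
                 ppc = ppc, contrasts = contrasts,
                 paths = file.path(out_dir, c("summary.json", "posterior_draws.tsv",
                                              "ppc.json", "contrasts.json", "run.log"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
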
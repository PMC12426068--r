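# Posterior-predictive model checks: T1 (observed mean category
# frequencies) and T2 (across-participant covariance structure of the
# frequencies), each with a posterior-predictive p value.

# vectorized category probabilities: rows = parameter vectors (free scale),
# output P x 25 matrix in freq_matrix column order
category_prob_matrix <- function(theta_free, constraints) {
  map <- free_parameter_map(constraints)
  out <- matrix(0, nrow(theta_free), 25)
  colnames(out) <- as.vector(t(outer(item_types(), response_categories(),
                                     paste, sep = "_")))
  for (t in seq_along(item_types())) {
    paths <- enumerate_tree_paths(item_types()[t])
    for (p in paths) {
      free_nm <- unname(map[p$factors$param])
      prod <- rep(1, nrow(theta_free))
      for (i in seq_along(free_nm)) {
        x <- theta_free[, free_nm[i]]
        prod <- prod * if (p$factors$complement[i]) 1 - x else x
      }
      col <- paste0(item_types()[t], "_", p$category)
      out[, col] <- out[, col] + prod
    }
  }
  out
}

# per-cell item totals matching the 25 freq_matrix columns
cell_totals <- function(design) rep(design$items_per_type, each = 5)

# simulate a replicated P x 25 count matrix from probability rows
simulate_count_matrix <- function(prob, design) {
  P <- nrow(prob)
  out <- matrix(0L, P, 25, dimnames = list(NULL, colnames(prob)))
  for (t in seq_along(item_types())) {
    idx <- (t - 1) * 5 + 1:5
    n <- design$items_per_type[[t]]
    for (p in seq_len(P)) out[p, idx] <- rmultinom(1, n, prob[p, idx])
  }
  out
}

ppc_engine <- function(fit, tables, design, n_rep, seed, statistic) {
  stopifnot(inherits(fit, "mpt_fit"))
  if (is.null(fit$participant_prob))
    stop("fit was run without participant-level monitoring; refit with monitor_participants = TRUE")
  P <- length(tables)
  if (statistic == "T2" && P < 3) stop("T2 needs at least 3 participants")
  obs <- freq_matrix(tables)
  n_draws <- dim(fit$participant_prob)[1]
  n_use <- min(n_rep, n_draws)
  with_seed(seed, {
    idx <- if (n_use < n_draws) sort(sample.int(n_draws, n_use)) else seq_len(n_draws)
    t_obs <- t_rep <- numeric(length(idx))
    skipped <- FALSE
    for (i in seq_along(idx)) {
      theta <- fit$participant_prob[idx[i], , , drop = TRUE]
      theta <- matrix(theta, P, length(fit$free), dimnames = list(NULL, fit$free))
      prob <- category_prob_matrix(theta, fit$constraints)
      expd <- sweep(prob, 2, cell_totals(design), "*")
      rep_counts <- simulate_count_matrix(prob, design)
      if (statistic == "T1") {
        m_exp <- colMeans(expd)
        keep <- m_exp > 0
        if (!all(keep)) skipped <- TRUE
        t_obs[i] <- sum((colMeans(obs)[keep] - m_exp[keep])^2 / m_exp[keep])
        t_rep[i] <- sum((colMeans(rep_counts)[keep] - m_exp[keep])^2 / m_exp[keep])
      } else {
        s_exp <- expected_covariance(expd, prob, design)
        sd_exp <- sqrt(pmax(diag(s_exp), 0))
        scale <- outer(sd_exp, sd_exp)
        keep <- upper.tri(scale, diag = TRUE) & scale > 0
        if (any(upper.tri(scale, diag = TRUE) & scale == 0)) skipped <- TRUE
        t_obs[i] <- sum(((cov(obs) - s_exp)[keep])^2 / scale[keep])
        t_rep[i] <- sum(((cov(rep_counts) - s_exp)[keep])^2 / scale[keep])
      }
    }
    if (skipped) warning("cells with zero expected variability were skipped",
                         call. = FALSE)
    structure(list(statistic = statistic,
                   statistic_observed = t_obs, statistic_predicted = t_rep,
                   p_value = mean(t_rep >= t_obs),
                   n_rep = length(idx), seed = seed,
                   formula = if (statistic == "T1")
                     "sum over cells of (observed mean freq - expected mean freq)^2 / expected mean freq"
                   else
                     "sum over cell pairs (i <= j) of (observed cov - expected cov)^2 / (expected sd_i * expected sd_j)"),
              class = "mpt_ppc")
  })
}

# expected across-participant covariance of the 25 frequency cells under one
# posterior draw: between-participant covariance of expected counts plus the
# average within-participant multinomial covariance (block-diagonal by tree)
expected_covariance <- function(expd, prob, design) {
  P <- nrow(expd)
  between <- if (P > 1) cov(expd) else matrix(0, 25, 25)
  within <- matrix(0, 25, 25)
  for (t in seq_along(item_types())) {
    idx <- (t - 1) * 5 + 1:5
    n <- design$items_per_type[[t]]
    pi_t <- prob[, idx, drop = FALSE]
    within[idx, idx] <- n * (diag(colMeans(pi_t)) - crossprod(pi_t) / P)
  }
  between + within
}

#' Posterior-predictive checks of model fit
#'
#' For each retained posterior draw, the participant-level parameters imply
#' expected response frequencies; a replicated cohort is simulated from the
#' same parameters.  `ppc_T1` measures the chi-square-type distance between
#' mean observed category frequencies (across participants) and their
#' expectation; `ppc_T2` measures a scaled quadratic distance between the
#' observed across-participant covariance matrix of the 25 frequency cells
#' and its expectation under the draw (between-participant covariance of
#' expected counts plus average multinomial covariance).  The
#' posterior-predictive p value is the fraction of draws whose replicated
#' discrepancy meets or exceeds the observed one; extreme values (near 0)
#' signal misfit.
#'
#' @param fit An `mpt_fit` with participant-level draws.
#' @param tables The frequency tables the model was fitted to (default:
#'   taken from the fit).
#' @param design The [design_spec()] (default: from the fit).
#' @param n_rep Number of posterior draws used (capped at the draws
#'   available); Monte-Carlo error of the p value shrinks as
#'   `1/sqrt(n_rep)`.
#' @param seed Integer seed for draw subsampling and replication.
#' @return An object of class `mpt_ppc`: per-draw observed and predicted
#'   statistics, `p_value`, `n_rep`, `seed`, and the statistic's formula.
#' @export
ppc_T1 <- function(fit, tables = fit$tables, design = fit$design,
                   n_rep = 500, seed = NULL) {
  ppc_engine(fit, tables, design, n_rep, seed, "T1")
}

#' @rdname ppc_T1
#' @export
ppc_T2 <- function(fit, tables = fit$tables, design = fit$design,
                   n_rep = 500, seed = NULL) {
  ppc_engine(fit, tables, design, n_rep, seed, "T2")
}

#' @export
print.mpt_ppc <- function(x, ...) {
  cat("Posterior-predictive check ", x$statistic, ": p = ",
      format(x$p_value, digits = 3), " (", x$n_rep, " replications)\n", sep = "")
  invisible(x)
}

#' Write a posterior-predictive check report
#'
#' JSON report with the statistic definition, p value, replication count
#' and summary quantiles of the observed and predicted statistics;
#' optionally the per-draw (observed, predicted) pairs as a delimited table
#' for scatter plotting.
#'
#' @param ppcs A single `mpt_ppc` or list of them.
#' @param path JSON output path.
#' @param scatter_path Optional path for per-draw pairs (tab-separated).
#' @return Invisibly, the report list.
#' @export
export_ppc <- function(ppcs, path, scatter_path = NULL) {
  if (inherits(ppcs, "mpt_ppc")) ppcs <- list(ppcs)
  report <- lapply(ppcs, function(x) {
    list(statistic = x$statistic, formula = x$formula, p_value = x$p_value,
         n_rep = x$n_rep, seed = x$seed,
         observed = unname(quantile(x$statistic_observed, c(0.025, 0.5, 0.975))),
         predicted = unname(quantile(x$statistic_predicted, c(0.025, 0.5, 0.975))))
  })
  names(report) <- vapply(ppcs, `[[`, "", "statistic")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(scatter_path)) {
    pairs <- do.call(rbind, lapply(ppcs, function(x)
      data.frame(statistic = x$statistic, observed = x$statistic_observed,
                 predicted = x$statistic_predicted)))
    write.table(pairs, scatter_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
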
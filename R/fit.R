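# Hierarchical Bayesian estimation of the constrained model via the
# latent-trait approach, sampled with JAGS (rjags).  The JAGS model source
# is generated from the same tree enumeration used for the EQN export, so
# the sampler's likelihood is structurally tied to the package's tree.

#' MCMC configuration for the latent-trait fit
#'
#' @param n_chains Number of chains (>= 2 enables the potential
#'   scale-reduction diagnostic).
#' @param n_iterations Post-adaptation iterations per chain, burn-in
#'   included.  The default matches a typical production run; simulation
#'   studies in the package use much shorter chains.
#' @param n_burnin Burn-in iterations per chain; default 20% of
#'   `n_iterations`.
#' @param thinning Keep every `thinning`-th draw.
#' @param n_adapt JAGS adaptation steps before sampling.
#' @param seed Integer seed; chain RNGs are derived from it.
#' @param prior_mu_sd Standard deviation of the Normal(0, sd^2) prior on
#'   each probit-scale group mean.
#' @param prior_df Degrees of freedom of the Wishart prior on the unscaled
#'   precision matrix; default K + 1 (K = number of free parameters).
#' @param xi_upper Upper bound of the uniform prior on the per-parameter
#'   scaling factors of the scaled inverse-Wishart covariance prior.
#' @return An object of class `mpt_config`.
#' @export
inference_config <- function(n_chains = 2, n_iterations = 50000, n_burnin = NULL,
                             thinning = 10, n_adapt = 2000, seed = 1,
                             prior_mu_sd = 1, prior_df = NULL, xi_upper = 10) {
  if (is.null(n_burnin)) n_burnin <- floor(n_iterations * 0.2)
  stopifnot(n_chains >= 1, n_iterations >= 1, n_burnin >= 0,
            n_burnin < n_iterations, thinning >= 1, prior_mu_sd > 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin),
                 thinning = as.integer(thinning),
                 n_adapt = as.integer(n_adapt),
                 seed = as.integer(seed),
                 prior_mu_sd = prior_mu_sd,
                 prior_df = prior_df,
                 xi_upper = xi_upper),
            class = "mpt_config")
}

# full JAGS model source for the constrained model.  Category probabilities
# use the same closed-form factorization as category_probabilities(), with
# shared attribution terms hoisted into per-participant helper nodes
# (deduplicated textually, so equality constraints collapse them); the
# path-enumeration route stays available as the independent cross-check.
jags_model_source <- function(constraints, pooling = c("latent_trait", "complete")) {
  pooling <- match.arg(pooling)
  map <- free_parameter_map(constraints)
  free <- free_parameters(constraints)
  free_index <- setNames(match(map, free), names(map))
  th <- function(param) sprintf("theta[p,%d]", free_index[[param]])
  thc <- function(param) sprintf("(1-theta[p,%d])", free_index[[param]])

  helpers <- new.env(parent = emptyenv())
  helpers$defs <- character(0); helpers$names <- character(0)
  helper <- function(expr) { # one node per distinct expression
    hit <- match(expr, helpers$names)
    if (!is.na(hit)) return(sprintf("h%d[p]", hit))
    helpers$names <- c(helpers$names, expr)
    id <- length(helpers$names)
    helpers$defs <- c(helpers$defs, sprintf("    h%d[p] <- %s", id, expr))
    sprintf("h%d[p]", id)
  }
  ver_term <- function(v, match_v, e, a) { # e*1{v = source} + (1-e)*guess
    guess <- if (v == "T") th(a) else thc(a)
    if (match_v) sprintf("(%s + %s*%s)", th(e), thc(e), guess)
    else sprintf("%s*%s", thc(e), guess)
  }
  imp_term <- function(m, v, match_m, e, a_true, a_false) {
    a <- if (v == "T") a_true else a_false
    guess <- if (m == "I") th(a) else thc(a)
    if (match_m) sprintf("(%s + %s*%s)", th(e), thc(e), guess)
    else sprintf("%s*%s", thc(e), guess)
  }

  lik <- character(0)
  for (t in seq_along(item_types())) {
    it <- item_types()[t]
    for (c in seq_along(response_categories())) {
      cat <- response_categories()[c]
      if (it == "new") {
        expr <- if (cat == "NEW") {
          sprintf("%s + %s*%s", th("D_new"), thc("D_new"), thc("b"))
        } else {
          v <- substr(cat, 5, 5); m <- substr(cat, 6, 6)
          gh <- helper(sprintf("%s*%s",
                               if (v == "T") th("g_ver") else thc("g_ver"),
                               if (m == "I") th(if (v == "T") "g_imp_true" else "g_imp_false")
                               else thc(if (v == "T") "g_imp_true" else "g_imp_false")))
          sprintf("%s*%s*%s", thc("D_new"), th("b"), gh)
        }
      } else {
        ij <- split_combo(it)
        D <- paste0("D_", it); d <- paste0("d_", it)
        ev <- paste0("e_ver_", it); em <- paste0("e_imp_", it)
        if (cat == "NEW") {
          expr <- sprintf("%s*%s", thc(D), thc("b"))
        } else {
          v <- substr(cat, 5, 5); m <- substr(cat, 6, 6)
          A <- helper(ver_term(v, v == ij$ver, ev, "a_ver"))
          B <- helper(imp_term(m, v, m == ij$imp, em, "a_imp_true", "a_imp_false"))
          gh <- helper(sprintf("%s*%s",
                               if (v == "T") th("g_ver") else thc("g_ver"),
                               if (m == "I") th(if (v == "T") "g_imp_true" else "g_imp_false")
                               else thc(if (v == "T") "g_imp_true" else "g_imp_false")))
          retrieval <- if (v == ij$ver && m == ij$imp)
            sprintf("(%s + %s*%s*%s)", th(d), thc(d), A, B)
          else sprintf("%s*%s*%s", thc(d), A, B)
          expr <- sprintf("%s*%s + %s*%s*%s", th(D), retrieval, thc(D), th("b"), gh)
        }
      }
      lik <- c(lik, sprintf("    pr[p,%d,%d] <- %s", t, c, expr))
    }
    lik <- c(lik, sprintf("    y[p,%d,1:5] ~ dmulti(pr[p,%d,1:5], nitems[%d])", t, t, t))
  }
  lik <- c(helpers$defs, lik)
  person <- if (pooling == "latent_trait") c(
    "    draw[p,1:K] ~ dmnorm(zeros[1:K], W.prec[1:K,1:K])",
    "    for (k in 1:K) { theta[p,k] <- phi(mu[k] + xi[k]*draw[p,k]) }"
  ) else
    "    for (k in 1:K) { theta[p,k] <- phi(mu[k]) }"
  hyper <- if (pooling == "latent_trait") c(
    "  for (k in 1:K) { mu[k] ~ dnorm(0, mu.prec); xi[k] ~ dunif(0, xi.upper) }",
    "  W.prec[1:K,1:K] ~ dwish(V[1:K,1:K], wish.df)"
  ) else
    "  for (k in 1:K) { mu[k] ~ dnorm(0, mu.prec) }"
  paste(c("model {",
          "  for (p in 1:P) {",
          person, lik,
          "  }",
          hyper,
          "}"), collapse = "\n")
}

#' Fit the constrained model hierarchically
#'
#' Latent-trait estimation: each participant's free parameters are
#' \eqn{\theta_{pk} = \Phi(\mu_k + \delta_{pk})} with
#' \eqn{\delta_p \sim N(0, \Sigma)}; group means get Normal(0,
#' `prior_mu_sd`^2) priors and \eqn{\Sigma} a scaled inverse-Wishart prior
#' (Wishart with identity scale and K + 1 degrees of freedom on the
#' unscaled precision, uniform per-parameter scaling factors).  The
#' likelihood is the product of per-participant multinomial likelihoods
#' over the five processing trees.  Sampling is Markov chain Monte Carlo
#' via JAGS.
#'
#' With `pooling = "complete"` all participants share one parameter vector
#' (\eqn{\Sigma} fixed at zero); this degenerate variant exists for
#' calibration and misfit studies, not for substantive analysis.
#'
#' @param tables List of [freq_table()] objects (>= 2 participants for the
#'   latent-trait model).
#' @param constraints An `mpt_constraints` object; default
#'   [standard_constraints()].
#' @param design A [design_spec()] consistent with the tables' item counts.
#' @param config An [inference_config()].
#' @param pooling `"latent_trait"` (default) or `"complete"`.
#' @param monitor_participants Keep participant-level draws (needed by the
#'   posterior-predictive checks)?
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `mpt_fit` with elements
#'   `group_prob` (draws x K matrix of group-level parameters on the
#'   probability scale, \eqn{\Phi(\mu_k)} per draw), `mu` (probit scale),
#'   `participant_prob` (draws x P x K array or `NULL`), `diagnostics`
#'   (per-parameter potential scale reduction), `free`, `constraints`,
#'   `design`, `config`, `priors`, and the fitted `tables`.
#' @export
fit_mpt <- function(tables, constraints = standard_constraints(),
                    design = design_spec(n_participants = length(tables)),
                    config = inference_config(), pooling = c("latent_trait", "complete"),
                    monitor_participants = TRUE, quiet = TRUE) {
  pooling <- match.arg(pooling)
  if (!length(tables)) stop("no frequency tables supplied")
  stopifnot(inherits(config, "mpt_config"), inherits(design, "mpt_design"))
  if (pooling == "latent_trait" && length(tables) < 2)
    stop("the latent-trait model needs at least 2 participants")
  P <- length(tables)
  for (tb in tables) {
    if (!identical(unname(tb$items_per_type), unname(design$items_per_type)))
      stop("frequency tables inconsistent with the design's item counts")
  }
  free <- free_parameters(constraints)
  K <- length(free)
  y <- aperm(vapply(tables, freq_counts, matrix(0L, 5, 5)), c(3, 1, 2))

  df <- if (is.null(config$prior_df)) K + 1 else config$prior_df
  data <- list(y = y, P = P, K = K,
               nitems = unname(design$items_per_type),
               mu.prec = 1 / config$prior_mu_sd^2)
  if (pooling == "latent_trait") {
    data <- c(data, list(zeros = rep(0, K), V = diag(K),
                         wish.df = df, xi.upper = config$xi_upper))
  }
  inits <- lapply(seq_len(config$n_chains), function(ch) {
    ini <- list(mu = rep(0, K),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = (abs(config$seed) %% 10^6) * 1000 + ch)
    if (pooling == "latent_trait") ini$draw <- matrix(0, P, K)
    ini
  })

  src <- jags_model_source(constraints, pooling)
  monitors <- c("mu", if (monitor_participants) "theta")
  run <- function() {
    jm <- rjags::jags.model(textConnection(src), data = data, inits = inits,
                            n.chains = config$n_chains, n.adapt = config$n_adapt,
                            quiet = quiet)
    if (config$n_burnin > 0) update(jm, config$n_burnin,
                                    progress.bar = if (quiet) "none" else "text")
    rjags::coda.samples(jm, monitors, n.iter = config$n_iterations - config$n_burnin,
                        thin = config$thinning,
                        progress.bar = if (quiet) "none" else "text")
  }
  samples <- if (quiet) suppressWarnings(run()) else run()

  mu_cols <- paste0("mu[", seq_len(K), "]")
  rhat <- rep(NA_real_, K)
  if (config$n_chains >= 2) {
    gd <- try(coda::gelman.diag(samples[, mu_cols, drop = FALSE],
                                multivariate = FALSE, autoburnin = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) rhat <- gd$psrf[, 1]
  }
  mat <- as.matrix(samples)
  mu_draws <- mat[, mu_cols, drop = FALSE]
  colnames(mu_draws) <- free
  group_prob <- pnorm(mu_draws)

  participant_prob <- NULL
  if (monitor_participants) {
    participant_prob <- array(NA_real_, c(nrow(mat), P, K),
                              dimnames = list(NULL, NULL, free))
    for (k in seq_len(K)) {
      cols <- paste0("theta[", seq_len(P), ",", k, "]")
      participant_prob[, , k] <- mat[, cols]
    }
  }

  diagnostics <- data.frame(parameter = free, rhat = unname(rhat))
  if (any(is.finite(rhat) & rhat > 1.05)) {
    warning("potential scale reduction above 1.05 for: ",
            paste(free[is.finite(rhat) & rhat > 1.05], collapse = ", "),
            "; consider longer chains", call. = FALSE)
  }
  structure(list(group_prob = group_prob, mu = mu_draws,
                 participant_prob = participant_prob,
                 diagnostics = diagnostics, free = free,
                 constraints = constraints, design = design, config = config,
                 pooling = pooling,
                 priors = list(mu = sprintf("Normal(0, %g^2) on the probit scale",
                                            config$prior_mu_sd),
                               sigma = if (pooling == "latent_trait")
                                 sprintf("scaled inverse-Wishart: Wishart(I, %d) precision, xi ~ Uniform(0, %g)",
                                         df, config$xi_upper) else "fixed at 0"),
                 tables = tables),
            class = "mpt_fit")
}

#' @export
print.mpt_fit <- function(x, ...) {
  cat("Hierarchical MPT fit (", x$pooling, "), ",
      length(x$tables), " participants, ", nrow(x$group_prob),
      " retained draws\n", sep = "")
  print(summarize_posterior(x), digits = 3)
  invisible(x)
}

#' Posterior summaries on the probability scale
#'
#' Median, mean and equal-tailed Bayesian credibility interval of each
#' group-level parameter (\eqn{\Phi(\mu_k)} draws), plus the potential
#' scale-reduction diagnostic.
#'
#' @param fit An `mpt_fit`.
#' @param credibility Interval mass (default 0.95: the 2.5% and 97.5%
#'   quantiles).
#' @return Data frame with columns `parameter`, `median`, `mean`, `lower`,
#'   `upper`, `rhat`.
#' @export
summarize_posterior <- function(fit, credibility = 0.95) {
  stopifnot(inherits(fit, "mpt_fit"), credibility > 0, credibility < 1)
  alpha <- (1 - credibility) / 2
  qs <- apply(fit$group_prob, 2, quantile, probs = c(alpha, 0.5, 1 - alpha),
              names = FALSE)
  data.frame(parameter = fit$free,
             median = qs[2, ],
             mean = colMeans(fit$group_prob),
             lower = qs[1, ],
             upper = qs[3, ],
             rhat = fit$diagnostics$rhat,
             row.names = NULL)
}

#' Export posterior draws and a JSON summary
#'
#' Writes the group-level draws as a delimited table (one column per free
#' parameter, probability scale) and a JSON summary holding per-parameter
#' median/mean/interval/diagnostic plus the priors, seed and sampler
#' configuration.
#'
#' @param fit An `mpt_fit`.
#' @param draws_path Path for the draws table (tab-separated).
#' @param summary_path Path for the JSON summary.
#' @param credibility Interval mass for the summary.
#' @return Invisibly, the summary list.
#' @export
export_posterior <- function(fit, draws_path, summary_path, credibility = 0.95) {
  write.table(as.data.frame(fit$group_prob), draws_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  s <- summarize_posterior(fit, credibility)
  out <- list(parameters = s, credibility = credibility, priors = fit$priors,
              pooling = fit$pooling,
              config = unclass(fit$config),
              n_participants = length(fit$tables),
              n_draws = nrow(fit$group_prob))
  jsonlite::write_json(out, summary_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(out)
}
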
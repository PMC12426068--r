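# Synthetic cohorts: latent-trait participant heterogeneity on the probit
# scale, multinomial frequency sampling, and trial-level records with a
# Remember/Know overlay.

# run expr under a temporary RNG state seeded with `seed` (NULL = use the
# current stream); restores the caller's state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Experimental design of a source-memory study
#'
#' Item and participant counts driving both simulation and likelihood
#' bookkeeping.  Defaults mirror a truth-and-importance feedback
#' experiment: 82 participants study 36 statements (9 per source
#' combination, the 2 x 2 crossing of veracity and importance feedback) and
#' are tested on 54 statements of which 18 are new.
#'
#' @param n_participants Number of participants.
#' @param items_per_source Studied statements per source combination.
#' @param n_distractors New statements on the test list.
#' @return An object of class `mpt_design` with an `items_per_type` vector
#'   (per [item_types()]) and the test-list length `n_test`.
#' @examples
#' design_spec()$n_test # 54
#' @export
design_spec <- function(n_participants = 82, items_per_source = 9, n_distractors = 18) {
  stopifnot(n_participants >= 1, items_per_source >= 1, n_distractors >= 1)
  items <- setNames(c(rep(items_per_source, 4), n_distractors), item_types())
  structure(list(n_participants = as.integer(n_participants),
                 items_per_source = as.integer(items_per_source),
                 n_distractors = as.integer(n_distractors),
                 items_per_type = as.integer(items) |> setNames(item_types()),
                 n_test = as.integer(sum(items))),
            class = "mpt_design")
}

#' Group-level distribution of individual parameters
#'
#' The latent-trait population model: each participant's free parameters
#' are \eqn{\theta_p = \Phi(\mu + \delta_p)} with
#' \eqn{\delta_p \sim N(0, \Sigma)} on the probit scale.
#' `group_distribution()` specifies \eqn{(\mu, \Sigma)} directly (or via
#' probability-scale means); `default_group_distribution()` returns the
#' generating regime used throughout the package's simulations: joint
#' retrieval concentrated on the true-and-important source
#' (`d_TI = .42`, `d_TU = .06`, `d_FI = .05`, `d_FU = .04`), moderate
#' detection (`D = .70`) and neutral guessing and independent retrieval
#' (0.5), with independent probit-scale heterogeneity of standard
#' deviation `heterogeneity_sd`.
#'
#' @param mean_prob Named probability-scale group means, one per free
#'   parameter of `constraints` (converted with `qnorm`).  Give either
#'   this or `mu`.
#' @param mu Named probit-scale group means.
#' @param sigma Covariance matrix on the probit scale (symmetric positive
#'   semi-definite), or a single number taken as a common variance on the
#'   diagonal.
#' @param constraints Constraint set defining the free parameters.
#' @return An object of class `mpt_group` with elements `mu`, `sigma`,
#'   `free` (parameter names) and `constraints`.
#' @export
group_distribution <- function(mean_prob = NULL, mu = NULL, sigma = 0,
                               constraints = standard_constraints()) {
  free <- free_parameters(constraints)
  if (is.null(mu)) {
    if (is.null(mean_prob)) stop("give mean_prob or mu")
    missing <- setdiff(free, names(mean_prob))
    if (length(missing)) stop("mean_prob missing free parameter(s): ",
                              paste(missing, collapse = ", "))
    check_probability(mean_prob[free], "mean_prob")
    mu <- qnorm(mean_prob[free])
  } else {
    missing <- setdiff(free, names(mu))
    if (length(missing)) stop("mu missing free parameter(s): ",
                              paste(missing, collapse = ", "))
    mu <- mu[free]
  }
  k <- length(free)
  if (length(sigma) == 1) sigma <- diag(as.numeric(sigma), k)
  sigma <- as.matrix(sigma)
  if (!all(dim(sigma) == k)) stop("sigma must be ", k, " x ", k)
  if (max(abs(sigma - t(sigma))) > 1e-8) stop("sigma must be symmetric")
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) stop("sigma must be positive semi-definite")
  dimnames(sigma) <- list(free, free)
  structure(list(mu = setNames(as.numeric(mu), free), sigma = sigma,
                 free = free, constraints = constraints),
            class = "mpt_group")
}

#' @rdname group_distribution
#' @param heterogeneity_sd Probit-scale standard deviation shared by all
#'   free parameters in the default regime.
#' @export
default_group_distribution <- function(constraints = standard_constraints(),
                                       heterogeneity_sd = 0.4) {
  free <- free_parameters(constraints)
  mean_prob <- setNames(rep(0.5, length(free)), free)
  mean_prob[intersect(c("D_TI", "D_TU", "D_FI", "D_FU", "D_new"), free)] <- 0.70
  for (nm in c("d_TI", "d_TU", "d_FI", "d_FU")) {
    val <- c(d_TI = 0.42, d_TU = 0.06, d_FI = 0.05, d_FU = 0.04)[[nm]]
    if (nm %in% free) mean_prob[nm] <- val
  }
  group_distribution(mean_prob = mean_prob,
                     sigma = heterogeneity_sd^2,
                     constraints = constraints)
}

#' Draw heterogeneous participant parameters
#'
#' Samples `n` participants from the latent-trait population model:
#' probit-scale free parameters \eqn{\Phi(\mu + \delta_p)},
#' \eqn{\delta_p \sim N(0, \Sigma)}, expanded to full 24-parameter vectors
#' through the constraint set.
#'
#' @param group An [group_distribution()] object.
#' @param n Number of participants.
#' @param seed Integer seed; same seed, same draw.
#' @return List of `n` full [mpt_parameters()] vectors; the free-parameter
#'   matrix (n x K, probability scale) is attached as attribute `"free"`.
#' @export
draw_participants <- function(group, n, seed = NULL) {
  stopifnot(inherits(group, "mpt_group"), n >= 1)
  k <- length(group$free)
  theta <- with_seed(seed, {
    delta <- if (all(group$sigma == 0)) matrix(0, n, k)
             else MASS::mvrnorm(n, mu = rep(0, k), Sigma = group$sigma)
    delta <- matrix(delta, n, k)
    pnorm(sweep(delta, 2, group$mu, "+"))
  })
  colnames(theta) <- group$free
  out <- lapply(seq_len(n), function(p)
    apply_constraints(theta[p, ], group$constraints))
  attr(out, "free") <- theta
  out
}

# per-item categorical responses for all participants, in a fixed RNG
# order (participant-major, item type within participant); tabulating them
# per type gives exact multinomial counts, and simulate_trials reuses the
# identical draw order so both generators agree for the same seed
draw_responses <- function(params_list, design) {
  cats <- response_categories()
  lapply(params_list, function(params) {
    unlist(lapply(item_types(), function(it) {
      pr <- category_probabilities(params, it)
      cats[sample.int(5, design$items_per_type[[it]], replace = TRUE, prob = pr)]
    }), use.names = FALSE)
  })
}

response_tables <- function(responses, design) {
  it_col <- rep(item_types(), times = design$items_per_type)
  lapply(seq_along(responses), function(p) {
    counts <- table(factor(it_col, levels = item_types()),
                    factor(responses[[p]], levels = response_categories()))
    counts <- matrix(as.numeric(counts), 5, 5,
                     dimnames = list(item_types(), response_categories()))
    freq_table(counts, participant = paste0("P", p),
               items_per_type = design$items_per_type)
  })
}

#' Simulate per-participant frequency tables
#'
#' Forward-samples the response counts of every participant and item type
#' from [category_probabilities()]; per item type the counts are
#' multinomial with the design's item total.
#'
#' @param params_list List of full parameter vectors (one per participant),
#'   e.g. from [draw_participants()].
#' @param design A [design_spec()].
#' @param seed Integer seed.
#' @return List of [freq_table()] objects.
#' @export
simulate_frequencies <- function(params_list, design = design_spec(), seed = NULL) {
  stopifnot(inherits(design, "mpt_design"))
  with_seed(seed, response_tables(draw_responses(params_list, design), design))
}

#' Simulate trial-level test records
#'
#' Emits one record per participant and test item: the old/new answer with
#' source attribution implied by the model tree, plus a Remember/Know tag
#' attached to every "old" answer.  The tag is an independent Bernoulli
#' overlay (`remember_rate`), not a modelled cognitive state; it exists to
#' exercise the response-coding paths.  The tags are drawn after all item
#' responses, which use the same draw order as [simulate_frequencies()]:
#' for the same seed, collapsing the records under the
#' `remember_plus_know` coding rule reproduces that function's tables
#' exactly.
#'
#' @inheritParams simulate_frequencies
#' @param remember_rate Probability that an "old" response is tagged
#'   Remember rather than Know.
#' @return Data frame with columns `participant`, `item_id`, `item_type`,
#'   `old_new`, `remember_know` (`NA` for "new" answers), `veracity_response`,
#'   `importance_response` (`NA` for "new" answers).
#' @export
simulate_trials <- function(params_list, design = design_spec(),
                            remember_rate = 0.5, seed = NULL) {
  stopifnot(inherits(design, "mpt_design"), remember_rate >= 0, remember_rate <= 1)
  with_seed(seed, {
    responses <- draw_responses(params_list, design)
    it_col <- rep(item_types(), times = design$items_per_type)
    recs <- lapply(seq_along(responses), function(p) {
      resp <- responses[[p]]
      old <- resp != "NEW"
      rk <- ifelse(old, ifelse(rbinom(length(resp), 1, remember_rate) == 1,
                               "REMEMBER", "KNOW"), NA_character_)
      data.frame(participant = paste0("P", p),
                 item_id = paste0("P", p, "_item", seq_along(resp)),
                 item_type = it_col,
                 old_new = ifelse(old, "OLD", "NEW"),
                 remember_know = rk,
                 veracity_response = ifelse(old, substr(resp, 5, 5), NA_character_),
                 importance_response = ifelse(old, substr(resp, 6, 6), NA_character_))
    })
    do.call(rbind, recs)
  })
}
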
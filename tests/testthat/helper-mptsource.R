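# Shared fixtures: parameter generators, short sampler settings, a cached
# study-size fit reused across test files, and a fake-fit builder for
# summary/contrast/check tests that need known draws.

neutral_params <- function() {
  mpt_parameters(setNames(rep(0.5, 24), mpt_parameter_names()))
}

# frozen by the path-enumeration oracle before the closed form was written:
# all branch probabilities 0.5, target studied as true-and-important
ALL_HALF_TI <- c(NEW = 0.25, OLD_TI = 0.453125, OLD_TU = 0.109375,
                 OLD_FI = 0.109375, OLD_FU = 0.078125)

random_param_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * 24), n, 24)
  colnames(m) <- mpt_parameter_names()
  m
}

# short single-chain sampler used by replication studies
short_config <- function(seed, n_chains = 1, n_iterations = 600,
                         n_burnin = 150, n_adapt = 150) {
  inference_config(n_chains = n_chains, n_iterations = n_iterations,
                   n_burnin = n_burnin, thinning = 1, n_adapt = n_adapt,
                   seed = seed)
}

# one default-regime cohort at study size, fitted once per test session
.fit_cache <- new.env(parent = emptyenv())
cached_study_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    group <- default_group_distribution()
    params <- draw_participants(group, 82, seed = 42)
    tables <- simulate_frequencies(params, design_spec(), seed = 43)
    .fit_cache$generator <- group
    .fit_cache$tables <- tables
    # chains kept deliberately short for test speed; the convergence
    # warning they can raise is not the property under test here
    .fit_cache$fit <- suppressWarnings(fit_mpt(
      tables, config = inference_config(n_chains = 2, n_iterations = 700,
                                        n_burnin = 200, thinning = 1,
                                        n_adapt = 200, seed = 44)))
  }
  .fit_cache$fit
}

# fit object with prescribed draws, for tests of summaries and contrasts
fake_fit <- function(group_prob, participant_prob = NULL,
                     constraints = standard_constraints(),
                     design = design_spec(n_participants = 3), tables = NULL) {
  free <- free_parameters(constraints)
  stopifnot(identical(colnames(group_prob), free))
  structure(list(group_prob = group_prob, mu = qnorm(group_prob),
                 participant_prob = participant_prob,
                 diagnostics = data.frame(parameter = free,
                                          rhat = rep(NA_real_, length(free))),
                 free = free, constraints = constraints, design = design,
                 config = inference_config(n_iterations = 10, n_burnin = 0),
                 pooling = "latent_trait",
                 priors = list(mu = "test", sigma = "test"),
                 tables = tables),
            class = "mpt_fit")
}
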
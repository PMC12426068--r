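# Posterior-predictive checks: exact bounds on degenerate inputs plus
# behavior on a model-consistent study-size fit.

# fit object whose participant draws are all fixed at one free-parameter
# vector (n_draws identical draws, P participants)
constant_draw_fit <- function(free_values, P, n_draws = 20,
                              design = design_spec(n_participants = P),
                              tables = NULL) {
  cs <- standard_constraints()
  free <- free_parameters(cs)
  gp <- matrix(rep(free_values[free], each = n_draws), n_draws,
               dimnames = list(NULL, free))
  pp <- array(NA_real_, c(n_draws, P, length(free)),
              dimnames = list(NULL, NULL, free))
  for (k in seq_along(free)) pp[, , k] <- gp[, k]
  fake_fit(gp, participant_prob = pp, design = design, tables = tables)
}

test_that("data equal to their expectation give zero discrepancy and p = 1", {
  cs <- standard_constraints()
  free <- setNames(rep(0.5, 14), free_parameters(cs))
  free[c("D_TI", "D_TU", "D_FI", "D_FU")] <- 1
  free[c("d_TI", "d_TU", "d_FI", "d_FU")] <- 1
  free["b"] <- 0
  # every target lands on its own category, every distractor on NEW
  counts <- matrix(0, 5, 5, dimnames = list(item_types(), response_categories()))
  counts["TI", "OLD_TI"] <- 9; counts["TU", "OLD_TU"] <- 9
  counts["FI", "OLD_FI"] <- 9; counts["FU", "OLD_FU"] <- 9
  counts["new", "NEW"] <- 18
  tables <- lapply(1:4, function(i) freq_table(counts, paste0("P", i)))
  fit <- constant_draw_fit(free, P = 4, tables = tables)
  expect_warning(res <- ppc_T1(fit, tables, fit$design, n_rep = 20, seed = 1),
                 "skipped")
  expect_equal(res$statistic_observed, rep(0, 20))
  expect_equal(res$p_value, 1)
})

test_that("identical participants reduce T2 to the norm of the expected covariance", {
  free <- setNames(rep(0.5, 14), free_parameters(standard_constraints()))
  counts <- matrix(c(2, 3, 2, 1, 1,
                     2, 3, 2, 1, 1,
                     2, 3, 2, 1, 1,
                     2, 3, 2, 1, 1,
                     8, 4, 3, 2, 1), 5, 5, byrow = TRUE,
                   dimnames = list(item_types(), response_categories()))
  tables <- lapply(1:3, function(i) freq_table(counts, paste0("P", i)))
  fit <- constant_draw_fit(free, P = 3, n_draws = 5, tables = tables)
  res <- ppc_T2(fit, tables, fit$design, n_rep = 5, seed = 2)

  # oracle: observed covariance is 0, expected covariance is the pure
  # multinomial block (between-participant spread of expectations is 0)
  params <- apply_constraints(free, standard_constraints())
  s_exp <- matrix(0, 25, 25)
  for (t in seq_along(item_types())) {
    idx <- (t - 1) * 5 + 1:5
    n <- fit$design$items_per_type[[t]]
    pr <- category_probabilities(params, item_types()[t])
    s_exp[idx, idx] <- n * (diag(pr) - outer(pr, pr))
  }
  sd_exp <- sqrt(diag(s_exp))
  scale <- outer(sd_exp, sd_exp)
  keep <- upper.tri(scale, diag = TRUE) & scale > 0
  oracle <- sum((0 - s_exp)[keep]^2 / scale[keep])
  expect_equal(res$statistic_observed, rep(oracle, 5), tolerance = 1e-10)
})

test_that("a model-consistent study-size fit passes both checks without extreme p values", {
  fit <- cached_study_fit()
  t1 <- ppc_T1(fit, n_rep = 200, seed = 11)
  t2 <- ppc_T2(fit, n_rep = 200, seed = 12)
  for (res in list(t1, t2)) {
    expect_gte(res$p_value, 0.01)
    expect_lte(res$p_value, 0.99)
    expect_equal(res$n_rep, 200)
  }
})

test_that("a pooled fit of a heterogeneous cohort is flagged by the covariance check", {
  g <- default_group_distribution(heterogeneity_sd = 0.4)
  tables <- simulate_frequencies(draw_participants(g, 82, seed = 61),
                                 design_spec(), seed = 62)
  pooled <- fit_mpt(tables, config = short_config(63), pooling = "complete")
  t2 <- ppc_T2(pooled, n_rep = 150, seed = 64)
  expect_lt(t2$p_value, 0.05)
})

test_that("check preconditions are enforced", {
  fit <- cached_study_fit()
  nofree <- fit
  nofree$participant_prob <- NULL
  expect_error(ppc_T1(nofree), "monitor_participants")
  expect_error(ppc_T2(fit, tables = fit$tables[1:2],
                      design = design_spec(n_participants = 2)),
               "at least 3 participants")
})
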
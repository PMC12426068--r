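test_that("certain detection and joint retrieval concentrate all mass on the correct category", {
  p <- unclass(neutral_params())
  p[c("D_TI", "d_TI")] <- 1
  pr <- category_probabilities(mpt_parameters(p), "TI")
  expect_equal(unname(pr["OLD_TI"]), 1)
  expect_equal(sum(pr[c("NEW", "OLD_TU", "OLD_FI", "OLD_FU")]), 0)

  q <- unclass(neutral_params())
  q[c("D_TU", "b")] <- 0
  pr2 <- category_probabilities(mpt_parameters(q), "TU")
  expect_equal(unname(pr2["NEW"]), 1)
})

test_that("all-0.5 parameters reproduce the frozen path-enumeration value", {
  expect_equal(category_probabilities(neutral_params(), "TI"), ALL_HALF_TI,
               tolerance = 1e-12)
  expect_equal(evaluate_paths(enumerate_tree_paths("TI"), neutral_params()),
               ALL_HALF_TI, tolerance = 1e-12)
})

test_that("closed form and path enumeration agree and normalize over random parameters", {
  m <- random_param_matrix(1000, seed = 101)
  paths <- lapply(setNames(nm = item_types()), enumerate_tree_paths)
  for (i in seq_len(nrow(m))) {
    params <- mpt_parameters(m[i, ])
    for (it in item_types()) {
      pr <- category_probabilities(params, it)
      expect_lt(abs(sum(pr) - 1), 1e-12)
      expect_lt(max(abs(pr - evaluate_paths(paths[[it]], params))), 1e-12)
    }
  }
})

test_that("tree structure matches the processing assumptions", {
  # distractors: exactly one direct detect-new path
  new_paths <- enumerate_tree_paths("new")
  direct <- Filter(function(p) nrow(p$factors) == 1, new_paths)
  expect_length(direct, 1)
  expect_identical(direct[[1]]$category, "NEW")
  expect_identical(direct[[1]]$factors$param, "D_new")
  expect_false(direct[[1]]$factors$complement)

  # targets: the joint-retrieval path D_ij * d_ij ends in the correct category
  ti_paths <- enumerate_tree_paths("TI")
  joint <- Filter(function(p) nrow(p$factors) == 2 &&
                    all(!p$factors$complement), ti_paths)
  expect_length(joint, 1)
  expect_identical(joint[[1]]$category, "OLD_TI")
  expect_identical(joint[[1]]$factors$param, c("D_TI", "d_TI"))
})

test_that("correct-attribution probability is monotone in detection and joint retrieval", {
  base <- unclass(neutral_params())
  grid <- seq(0, 1, by = 0.1)
  for (par in c("d_TI", "D_TI")) {
    vals <- vapply(grid, function(v) {
      p <- base; p[par] <- v
      category_probabilities(mpt_parameters(p), "TI")[["OLD_TI"]]
    }, 0)
    expect_true(all(diff(vals) >= -1e-12))
  }
})

test_that("invalid parameter values are rejected", {
  p <- unclass(neutral_params())
  p["b"] <- 1.2
  expect_error(category_probabilities(p, "TI"), "outside")
  p["b"] <- -0.1
  expect_error(mpt_parameters(p), "outside")
  expect_error(mpt_parameters(unclass(neutral_params())[-1]), "missing")
})

test_that("log-likelihood matches the path oracle and handles degenerate cells", {
  # probability-1 outcomes give log-likelihood 0
  p <- unclass(neutral_params())
  p[c("D_TI", "D_TU", "D_FI", "D_FU", "b")] <- 0
  p["D_new"] <- 1
  counts <- matrix(0, 5, 5, dimnames = list(item_types(), response_categories()))
  counts[, "NEW"] <- c(9, 9, 9, 9, 18)
  tab <- freq_table(counts)
  expect_equal(log_likelihood(mpt_parameters(p), tab), 0)

  # a single true-and-important item attributed correctly, all parameters 0.5
  one <- matrix(0, 5, 5, dimnames = list(item_types(), response_categories()))
  one["TI", "OLD_TI"] <- 1
  expect_equal(log_likelihood(neutral_params(), freq_table(one)),
               log(ALL_HALF_TI[["OLD_TI"]]))

  # positive count on an impossible category
  imp <- one
  imp["TI", "OLD_TI"] <- 0; imp["TI", "NEW"] <- 1
  p2 <- unclass(neutral_params()); p2[c("D_TI")] <- 1
  expect_identical(log_likelihood(mpt_parameters(p2), freq_table(imp)), -Inf)

  # oracle equivalence on random parameters and tables
  m <- random_param_matrix(20, seed = 7)
  set.seed(8)
  paths <- lapply(setNames(nm = item_types()), enumerate_tree_paths)
  for (i in seq_len(nrow(m))) {
    params <- mpt_parameters(m[i, ])
    counts <- t(vapply(item_types(), function(it) {
      pr <- category_probabilities(params, it)
      as.numeric(rmultinom(1, 9, pr))
    }, numeric(5)))
    dimnames(counts) <- list(item_types(), response_categories())
    tab <- freq_table(counts)
    oracle <- sum(vapply(item_types(), function(it) {
      pr <- evaluate_paths(paths[[it]], params)
      keep <- counts[it, ] > 0
      sum(counts[it, keep] * log(pr[keep]))
    }, 0))
    expect_equal(log_likelihood(params, tab), oracle, tolerance = 1e-10)
  }
})

test_that("EQN export writes one line per path with complement notation", {
  full <- tempfile(fileext = ".eqn")
  write_eqn(full)
  lines <- readLines(full)
  expect_equal(as.integer(lines[1]), 4 * 15 + 6)
  expect_equal(length(lines) - 1L, 4 * 15 + 6)
  expect_true("target_TI OLD_TI D_TI*d_TI" %in% lines)
  expect_true(any(grepl("^new NEW D_new$", lines)))
  expect_true(any(grepl("(1-D_new)", lines, fixed = TRUE)))

  constrained <- tempfile(fileext = ".eqn")
  write_eqn(constrained, standard_constraints())
  clines <- readLines(constrained)
  expect_false(any(grepl("e_ver_TI|g_ver|D_new", clines)))
  expect_true(any(grepl("e_ver", clines, fixed = TRUE)))
  # every free-parameter set expression evaluates identically in both files
  expect_equal(length(clines), length(lines))
})
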
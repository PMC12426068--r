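# Core model: fixed orderings, parameter vector, tree probabilities,
# equality constraints, multinomial likelihood, EQN export.

#' Fixed orderings used throughout the package
#'
#' All indexing in mptsource uses fixed global orders: source combinations
#' `TI, TU, FI, FU` (T = true, F = false; I = important, U = unimportant),
#' item types `TI, TU, FI, FU, new`, and response categories
#' `NEW, OLD_TI, OLD_TU, OLD_FI, OLD_FU` (an `OLD_vm` response is an "old"
#' judgment plus attribution of veracity `v` and importance `m`).
#'
#' @return A character vector of labels in canonical order.
#' @examples
#' source_combinations()
#' response_categories()
#' @export
source_combinations <- function() c("TI", "TU", "FI", "FU")

#' @rdname source_combinations
#' @export
item_types <- function() c("TI", "TU", "FI", "FU", "new")

#' @rdname source_combinations
#' @export
response_categories <- function() c("NEW", "OLD_TI", "OLD_TU", "OLD_FI", "OLD_FU")

#' Names of the full (unconstrained) parameter vector
#'
#' The unconstrained multidimensional source-memory model has 24
#' probability parameters:
#' * `D_ij` — detection of a target studied with source combination `ij`;
#' * `D_new` — detection of distractors as new;
#' * `d_ij` — joint retrieval of both source features of a detected target;
#' * `e_ver_ij`, `e_imp_ij` — independent retrieval of the veracity
#'   (resp. importance) feature when joint retrieval fails;
#' * `a_ver` — guessing "true" for a detected target; `a_imp_true`,
#'   `a_imp_false` — guessing "important" given the item was assigned to
#'   true (resp. false);
#' * `g_ver`, `g_imp_true`, `g_imp_false` — the analogous guessing
#'   parameters for undetected or new items;
#' * `b` — guessing "old" for an undetected item.
#'
#' Guessing "false" (or "unimportant") is the complement of the
#' corresponding "true" ("important") guessing probability, not a separate
#' parameter.
#'
#' @return Character vector of the 24 parameter names in canonical order.
#' @export
mpt_parameter_names <- function() {
  sc <- source_combinations()
  c(paste0("D_", sc), "D_new",
    paste0("d_", sc),
    paste0("e_ver_", sc),
    paste0("e_imp_", sc),
    "a_ver", "a_imp_true", "a_imp_false",
    "g_ver", "g_imp_true", "g_imp_false",
    "b")
}

#' Construct and validate a full parameter vector
#'
#' @param values Named numeric vector covering all names in
#'   [mpt_parameter_names()]; order is free, the result is reordered
#'   canonically.
#' @return Named numeric vector of length 24, class `mpt_parameters`.
#' @examples
#' p <- mpt_parameters(setNames(rep(0.5, 24), mpt_parameter_names()))
#' @export
mpt_parameters <- function(values) {
  nm <- mpt_parameter_names()
  if (is.null(names(values)) || !all(nm %in% names(values))) {
    missing <- setdiff(nm, names(values))
    stop("parameter vector is missing: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(values), nm)
  if (length(extra)) stop("unknown parameter name(s): ", paste(extra, collapse = ", "))
  values <- values[nm]
  check_probability(values, "parameter")
  structure(values, class = "mpt_parameters")
}

check_probability <- function(x, what) {
  bad <- !is.finite(x) | x < 0 | x > 1
  if (any(bad)) {
    stop(what, " value(s) outside [0, 1]: ",
         paste(names(x)[bad], collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

# veracity/importance letters of a source combination label
split_combo <- function(ij) list(ver = substr(ij, 1, 1), imp = substr(ij, 2, 2))

#' Response-category probabilities of the source-memory tree
#'
#' Computes the probability of each of the five response categories for one
#' item type under the full parameter vector.  For a target studied with
#' source combination `ij`, an "old" response with attribution `(v, m)`
#' arises by detection (`D_ij`) followed by either joint retrieval of both
#' features (`d_ij`, forcing the correct attribution), or independent
#' feature retrieval/guessing; undetected items may still attract an "old"
#' guess (`b`) with `g`-based attribution.  Distractors are recognized as
#' new with `D_new` or guessed.
#'
#' @param params Full parameter vector ([mpt_parameters()] or a named
#'   numeric covering all 24 parameters).
#' @param item_type One of [item_types()].
#' @return Named probability vector over [response_categories()]; sums to 1.
#' @examples
#' p <- mpt_parameters(setNames(rep(0.5, 24), mpt_parameter_names()))
#' category_probabilities(p, "TI")
#' @export
category_probabilities <- function(params, item_type) {
  params <- as_full_params(params)
  item_type <- match.arg(item_type, item_types())
  cats <- response_categories()
  out <- setNames(numeric(5), cats)

  # guessing attribution G(v) * H(m | v), shared by all trees
  guess_old <- function(v, m) {
    gv <- if (v == "T") params[["g_ver"]] else 1 - params[["g_ver"]]
    gi <- if (v == "T") params[["g_imp_true"]] else params[["g_imp_false"]]
    gm <- if (m == "I") gi else 1 - gi
    gv * gm
  }

  if (item_type == "new") {
    Dn <- params[["D_new"]]; b <- params[["b"]]
    out["NEW"] <- Dn + (1 - Dn) * (1 - b)
    for (v in c("T", "F")) for (m in c("I", "U")) {
      out[paste0("OLD_", v, m)] <- (1 - Dn) * b * guess_old(v, m)
    }
    return(out)
  }

  ij <- split_combo(item_type)
  D <- params[[paste0("D_", item_type)]]
  d <- params[[paste0("d_", item_type)]]
  e_v <- params[[paste0("e_ver_", item_type)]]
  e_m <- params[[paste0("e_imp_", item_type)]]
  b <- params[["b"]]

  A <- function(v) { # veracity attribution when joint retrieval fails
    g <- if (v == "T") params[["a_ver"]] else 1 - params[["a_ver"]]
    e_v * (v == ij$ver) + (1 - e_v) * g
  }
  B <- function(m, v) { # importance attribution, guessing conditioned on v
    ai <- if (v == "T") params[["a_imp_true"]] else params[["a_imp_false"]]
    g <- if (m == "I") ai else 1 - ai
    e_m * (m == ij$imp) + (1 - e_m) * g
  }

  out["NEW"] <- (1 - D) * (1 - b)
  for (v in c("T", "F")) for (m in c("I", "U")) {
    joint <- d * (v == ij$ver && m == ij$imp)
    out[paste0("OLD_", v, m)] <-
      D * (joint + (1 - d) * A(v) * B(m, v)) + (1 - D) * b * guess_old(v, m)
  }
  out
}

as_full_params <- function(params) {
  if (inherits(params, "mpt_parameters")) {
    check_probability(unclass(params), "parameter")
    return(params)
  }
  mpt_parameters(params)
}

#' Enumerate every root-to-leaf path of a processing tree
#'
#' Returns the symbolic tree structure: one entry per root-to-leaf path,
#' giving the response category it ends in and the branch factors along the
#' way (each a parameter name plus a flag marking the complement
#' `1 - parameter`).  Summing evaluated path products per category is an
#' independent route to the same probabilities as
#' [category_probabilities()], used for cross-checking, EQN export, and
#' sampler code generation.
#'
#' @param item_type One of [item_types()].
#' @return List of paths; each path is a list with `category` (label) and
#'   `factors` (data frame with columns `param`, `complement`).
#' @seealso [evaluate_paths()]
#' @export
enumerate_tree_paths <- function(item_type) {
  item_type <- match.arg(item_type, item_types())
  paths <- list()
  add <- function(category, factors) {
    paths[[length(paths) + 1L]] <<- list(
      category = category,
      factors = data.frame(param = vapply(factors, `[[`, "", 1),
                           complement = vapply(factors, function(f) isTRUE(f[[2]]), TRUE)))
  }
  f <- function(param, complement = FALSE) list(param, complement)

  # guessing subtree shared by the undetected branch of every tree
  guess_paths <- function(prefix) {
    for (v in c("T", "F")) {
      fv <- if (v == "T") f("g_ver") else f("g_ver", TRUE)
      gi <- if (v == "T") "g_imp_true" else "g_imp_false"
      for (m in c("I", "U")) {
        fm <- if (m == "I") f(gi) else f(gi, TRUE)
        add(paste0("OLD_", v, m), c(prefix, list(fv, fm)))
      }
    }
  }

  if (item_type == "new") {
    add("NEW", list(f("D_new")))
    guess_paths(list(f("D_new", TRUE), f("b")))
    add("NEW", list(f("D_new", TRUE), f("b", TRUE)))
    return(paths)
  }

  ij <- split_combo(item_type)
  Dn <- paste0("D_", item_type); dn <- paste0("d_", item_type)
  ev <- paste0("e_ver_", item_type); em <- paste0("e_imp_", item_type)

  # detected, joint retrieval: correct compound attribution
  add(paste0("OLD_", item_type), list(f(Dn), f(dn)))

  # detected, joint retrieval failed: veracity then importance, each either
  # retrieved independently or guessed (importance guess conditioned on the
  # veracity response)
  ver_branches <- list(
    list(v = ij$ver, fs = list(f(ev))),
    list(v = "T", fs = list(f(ev, TRUE), f("a_ver"))),
    list(v = "F", fs = list(f(ev, TRUE), f("a_ver", TRUE))))
  for (vb in ver_branches) {
    ai <- if (vb$v == "T") "a_imp_true" else "a_imp_false"
    imp_branches <- list(
      list(m = ij$imp, fs = list(f(em))),
      list(m = "I", fs = list(f(em, TRUE), f(ai))),
      list(m = "U", fs = list(f(em, TRUE), f(ai, TRUE))))
    for (ib in imp_branches) {
      add(paste0("OLD_", vb$v, ib$m),
          c(list(f(Dn), f(dn, TRUE)), vb$fs, ib$fs))
    }
  }

  # undetected: old-guessing subtree or "new"
  guess_paths(list(f(Dn, TRUE), f("b")))
  add("NEW", list(f(Dn, TRUE), f("b", TRUE)))
  paths
}

#' Evaluate enumerated paths at a parameter vector
#'
#' @param paths Output of [enumerate_tree_paths()].
#' @param params Full parameter vector.
#' @return Named probability vector over [response_categories()].
#' @export
evaluate_paths <- function(paths, params) {
  params <- as_full_params(params)
  out <- setNames(numeric(5), response_categories())
  for (p in paths) {
    x <- params[p$factors$param]
    x[p$factors$complement] <- 1 - x[p$factors$complement]
    out[p$category] <- out[p$category] + prod(x)
  }
  out
}

#' Equality-constraint sets over the full parameter vector
#'
#' A constraint set maps free parameter names onto groups of full
#' parameters forced to share one value.  Full parameters outside any group
#' remain free under their own name.  `constraint_set()` builds and
#' validates an arbitrary set; `standard_constraints()` returns the
#' restriction set routinely used with this model: `D_new = D_TI`, a single
#' independent-retrieval parameter per dimension
#' (`e_ver = e_ver_TI = ... = e_ver_FU`, likewise `e_imp`), and guessing
#' equated across detection states (`g_ver = a_ver`,
#' `g_imp_true = a_imp_true`, `g_imp_false = a_imp_false`), leaving 14 free
#' parameters.  `no_constraints()` is the identity (24 free parameters).
#'
#' @param groups Named list: free-parameter name -> character vector of
#'   full parameter names sharing its value.  A group's name may itself be
#'   a member (e.g. `D_TI = c("D_TI", "D_new")`) or a new label
#'   (e.g. `e_ver`).
#' @return An object of class `mpt_constraints`.
#' @examples
#' cs <- standard_constraints()
#' free_parameters(cs)
#' @export
constraint_set <- function(groups = list()) {
  nm <- mpt_parameter_names()
  members <- unlist(groups, use.names = FALSE)
  bad <- setdiff(members, nm)
  if (length(bad)) stop("unknown full parameter(s) in constraints: ", paste(bad, collapse = ", "))
  if (anyDuplicated(members)) {
    stop("full parameter(s) in more than one constraint group: ",
         paste(unique(members[duplicated(members)]), collapse = ", "))
  }
  if (is.null(names(groups)) && length(groups)) stop("constraint groups must be named")
  clash <- intersect(names(groups), setdiff(nm, members))
  if (length(clash)) stop("group name collides with an unconstrained parameter: ",
                          paste(clash, collapse = ", "))
  structure(list(groups = groups), class = "mpt_constraints")
}

#' @rdname constraint_set
#' @export
standard_constraints <- function() {
  sc <- source_combinations()
  constraint_set(list(
    D_TI = c("D_TI", "D_new"),
    e_ver = paste0("e_ver_", sc),
    e_imp = paste0("e_imp_", sc),
    a_ver = c("a_ver", "g_ver"),
    a_imp_true = c("a_imp_true", "g_imp_true"),
    a_imp_false = c("a_imp_false", "g_imp_false")))
}

#' @rdname constraint_set
#' @export
no_constraints <- function() constraint_set(list())

#' Map each full parameter to its free parameter
#'
#' @param constraints An `mpt_constraints` object.
#' @return Named character vector: full parameter name -> free name.
#' @export
free_parameter_map <- function(constraints) {
  stopifnot(inherits(constraints, "mpt_constraints"))
  nm <- mpt_parameter_names()
  map <- setNames(nm, nm)
  for (free in names(constraints$groups)) map[constraints$groups[[free]]] <- free
  map
}

#' @rdname free_parameter_map
#' @return `free_parameters()`: character vector of free parameter names,
#'   ordered by first appearance in the canonical full order.
#' @export
free_parameters <- function(constraints) {
  map <- free_parameter_map(constraints)
  unique(unname(map))
}

#' Expand free parameter values to the full vector
#'
#' @param free_values Named numeric vector covering every free parameter of
#'   `constraints`.
#' @param constraints An `mpt_constraints` object.
#' @return Full [mpt_parameters()] vector with every constrained entry
#'   equal to its group's free value.
#' @examples
#' cs <- standard_constraints()
#' free <- setNames(rep(0.5, 14), free_parameters(cs))
#' free["D_TI"] <- 0.8
#' apply_constraints(free, cs)[["D_new"]] # 0.8
#' @export
apply_constraints <- function(free_values, constraints) {
  map <- free_parameter_map(constraints)
  need <- unique(unname(map))
  missing <- setdiff(need, names(free_values))
  if (length(missing)) stop("missing free parameter value(s): ", paste(missing, collapse = ", "))
  check_probability(free_values[need], "free parameter")
  mpt_parameters(setNames(as.numeric(free_values[map]), names(map)))
}

#' Multinomial log-likelihood of a participant frequency table
#'
#' Sum over item types of the multinomial log-likelihood of the observed
#' category counts under [category_probabilities()].  Cells with zero
#' probability and zero count contribute 0 (the usual `0 log 0 = 0`
#' convention); a positive count on a zero-probability category gives
#' `-Inf`.
#'
#' @param params Full parameter vector.
#' @param table A [freq_table()].
#' @return Log-likelihood (scalar; the multinomial coefficient, a data
#'   constant, is omitted).
#' @export
log_likelihood <- function(params, table) {
  counts <- freq_counts(table)
  ll <- 0
  for (it in item_types()) {
    pr <- category_probabilities(params, it)
    n <- counts[it, ]
    pos <- n > 0
    if (any(pos & pr == 0)) return(-Inf)
    ll <- ll + sum(n[pos] * log(pr[pos]))
  }
  ll
}

#' Export the model as an EQN file
#'
#' Writes the processing tree in the standard MPT `.eqn` interchange
#' format: a header line with the number of branch lines, then one line per
#' root-to-leaf path with tree name, response category, and the product of
#' branch terms (`X` or `(1-X)`).  With a constraint set, constrained
#' parameters are renamed to their free parameter so the file encodes the
#' restricted model.
#'
#' @param path Output file path.
#' @param constraints Optional `mpt_constraints`; `NULL` writes the full
#'   24-parameter model.
#' @return Invisibly, the path.
#' @export
write_eqn <- function(path, constraints = NULL) {
  map <- if (is.null(constraints)) setNames(mpt_parameter_names(), mpt_parameter_names())
         else free_parameter_map(constraints)
  lines <- character(0)
  for (it in item_types()) {
    tree <- if (it == "new") "new" else paste0("target_", it)
    for (p in enumerate_tree_paths(it)) {
      nm <- unname(map[p$factors$param])
      term <- ifelse(p$factors$complement, paste0("(1-", nm, ")"), nm)
      lines <- c(lines, paste(tree, p$category, paste(term, collapse = "*")))
    }
  }
  writeLines(c(as.character(length(lines)), lines), path)
  invisible(path)
}
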
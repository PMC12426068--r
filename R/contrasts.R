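# Posterior contrasts: sampled differences between group-level parameters
# on the probability scale, with equal-tailed credibility intervals and the
# zero-exclusion decision rule.

#' Posterior difference between two group-level parameters
#'
#' Computes, draw by draw, the difference between two group-level
#' parameters on the probability scale and summarizes it with the median
#' and an equal-tailed credibility interval.  A difference is credited
#' when the interval excludes zero.
#'
#' @param fit An `mpt_fit`.
#' @param param_a,param_b Free parameter names (see `fit$free`).
#' @param credibility Interval mass (default 0.95).
#' @param name Label for the contrast; default `"param_a - param_b"`.
#' @return A one-row data frame of class `mpt_contrast` with columns
#'   `name`, `median`, `lower`, `upper`, `excludes_zero`; the per-draw
#'   differences are attached as attribute `"draws"`.
#' @export
posterior_difference <- function(fit, param_a, param_b, credibility = 0.95,
                                 name = NULL) {
  stopifnot(inherits(fit, "mpt_fit"))
  for (p in c(param_a, param_b)) {
    if (!p %in% fit$free)
      stop("'", p, "' is not a free parameter of this fit; available: ",
           paste(fit$free, collapse = ", "))
  }
  delta <- fit$group_prob[, param_a] - fit$group_prob[, param_b]
  alpha <- (1 - credibility) / 2
  q <- quantile(delta, c(alpha, 0.5, 1 - alpha), names = FALSE)
  out <- data.frame(name = if (is.null(name)) paste(param_a, "-", param_b) else name,
                    median = q[2], lower = q[1], upper = q[3],
                    excludes_zero = q[1] > 0 | q[3] < 0,
                    row.names = NULL)
  attr(out, "draws") <- delta
  class(out) <- c("mpt_contrast", class(out))
  out
}

#' The standard contrast battery
#'
#' The seven contrasts routinely reported for this model under the
#' standard constraint set, all on the probability scale:
#' joint retrieval of the true-and-important source versus every other
#' combination (`delta_d = d_TI - d_TU`, `delta_d1 = d_TI - d_FI`,
#' `delta_d2 = d_TI - d_FU`), independent retrieval of the veracity versus
#' the importance dimension (`delta_e = e_ver - e_imp`), and item memory
#' (`delta_D = D_TI - D_TU`, `delta_D1 = D_TI - D_FI`,
#' `delta_D2 = D_TI - D_FU`).  No multiplicity correction is applied
#' across the battery.
#'
#' @param fit An `mpt_fit` under [standard_constraints()].
#' @param credibility Interval mass.
#' @return Data frame with one row per contrast (columns as in
#'   [posterior_difference()]).
#' @export
contrast_battery <- function(fit, credibility = 0.95) {
  spec <- list(delta_d = c("d_TI", "d_TU"),
               delta_d1 = c("d_TI", "d_FI"),
               delta_d2 = c("d_TI", "d_FU"),
               delta_e = c("e_ver", "e_imp"),
               delta_D = c("D_TI", "D_TU"),
               delta_D1 = c("D_TI", "D_FI"),
               delta_D2 = c("D_TI", "D_FU"))
  missing <- setdiff(unique(unlist(spec)), fit$free)
  if (length(missing))
    stop("contrast battery needs the standard constraint set; missing free parameter(s): ",
         paste(missing, collapse = ", "))
  out <- do.call(rbind, lapply(names(spec), function(nm) {
    r <- posterior_difference(fit, spec[[nm]][1], spec[[nm]][2],
                              credibility = credibility, name = nm)
    attr(r, "draws") <- NULL
    as.data.frame(r)
  }))
  class(out) <- c("mpt_contrast", class(out))
  out
}

#' Write a contrast report
#'
#' JSON plus a delimited table (name, median, lower, upper,
#' excludes_zero).  The report notes that no multiplicity correction is
#' applied.
#'
#' @param contrasts Data frame from [contrast_battery()] or rows from
#'   [posterior_difference()].
#' @param json_path JSON output path.
#' @param table_path Optional tab-separated output path.
#' @return Invisibly, the report list.
#' @export
export_contrasts <- function(contrasts, json_path, table_path = NULL) {
  df <- as.data.frame(contrasts)
  attr(df, "draws") <- NULL
  report <- list(contrasts = df,
                 note = "equal-tailed credibility intervals; no multiplicity correction across the battery")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  if (!is.null(table_path))
    write.table(df, table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
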
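# Trial-level records: Remember/Know response coding, frequency-table
# construction, and dialect-configurable delimited-text I/O.

trial_columns <- function() {
  c("participant", "item_id", "item_type", "old_new", "remember_know",
    "veracity_response", "importance_response")
}

validate_trials <- function(records) {
  missing <- setdiff(trial_columns(), names(records))
  if (length(missing)) stop("trial records missing column(s): ",
                            paste(missing, collapse = ", "))
  bad <- !records$item_type %in% item_types()
  if (any(bad)) stop("unknown item_type value(s): ",
                     paste(unique(records$item_type[bad]), collapse = ", "))
  if (!all(records$old_new %in% c("OLD", "NEW"))) stop("old_new must be OLD or NEW")
  if (anyDuplicated(records[, c("participant", "item_id")]))
    stop("duplicate (participant, item_id) record(s)")
  old <- records$old_new == "OLD"
  if (any(is.na(records$remember_know[old])) || any(!is.na(records$remember_know[!old])))
    stop("remember_know must be set exactly for OLD responses")
  if (any(is.na(records$veracity_response[old])) ||
      any(is.na(records$importance_response[old])))
    stop("source attribution must be set for OLD responses")
  invisible(records)
}

#' Build frequency tables from trial records under a coding rule
#'
#' Aggregates trial-level records into per-participant frequency tables.
#' Under the `"remember_only"` rule — the focal analysis for stochastic
#' dependence, which is carried by recollection — an "old" response tagged
#' Know is recoded as "new", keeping each item type's multinomial total
#' fixed; under `"remember_plus_know"` every "old" response counts.
#' Participants with a record count different from the design's test-list
#' length are excluded with a warning.
#'
#' @param records Data frame of trial records (columns as produced by
#'   [simulate_trials()] / [read_trials()]).
#' @param rule Coding rule: `"remember_only"` (default) or
#'   `"remember_plus_know"`.
#' @param design A [design_spec()].
#' @return List of [freq_table()] objects, one per complete participant.
#' @export
build_frequency_tables <- function(records, rule = c("remember_only", "remember_plus_know"),
                                   design = design_spec()) {
  rule <- match.arg(rule)
  validate_trials(records)
  keep_old <- records$old_new == "OLD" &
    (rule == "remember_plus_know" | records$remember_know == "REMEMBER")
  category <- ifelse(keep_old,
                     paste0("OLD_", records$veracity_response,
                            records$importance_response),
                     "NEW")
  bad <- !category %in% response_categories()
  if (any(bad)) stop("invalid source attribution(s): ",
                     paste(unique(category[bad]), collapse = ", "))
  out <- list()
  for (pid in unique(records$participant)) {
    rows <- records$participant == pid
    if (sum(rows) != design$n_test) {
      warning("participant ", pid, " has ", sum(rows), " records, expected ",
              design$n_test, "; excluded", call. = FALSE)
      next
    }
    counts <- table(factor(records$item_type[rows], levels = item_types()),
                    factor(category[rows], levels = response_categories()))
    counts <- matrix(as.numeric(counts), 5, 5,
                     dimnames = list(item_types(), response_categories()))
    if (!identical(unname(rowSums(counts)), unname(as.numeric(design$items_per_type))))
      stop("participant ", pid, " item counts do not match the design")
    out[[length(out) + 1L]] <- freq_table(counts, participant = as.character(pid),
                                          items_per_type = design$items_per_type)
  }
  out
}

#' Read and write trial-level records as delimited text
#'
#' Tab-separated, one row per trial.  `read_trials()` accepts a column
#' `dialect`: a named character vector mapping the canonical column names
#' (`participant`, `item_id`, `item_type`, `old_new`, `remember_know`,
#' `veracity_response`, `importance_response`) to the file's column names,
#' for ingesting externally produced exports.
#'
#' @param records Trial-record data frame.
#' @param path File path.
#' @param dialect Named character vector (canonical -> file column name);
#'   default identity.
#' @return `write_trials()`: the path, invisibly; `read_trials()`: a
#'   validated trial-record data frame with canonical columns.
#' @export
write_trials <- function(records, path) {
  validate_trials(records)
  write.table(records[, trial_columns()], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path, dialect = NULL) {
  # colClasses forced: bare "T"/"F" veracity responses must stay character
  df <- read.delim(path, check.names = FALSE, na.strings = c("NA", ""),
                   colClasses = "character")
  if (!is.null(dialect)) {
    missing <- setdiff(unname(dialect), names(df))
    if (length(missing)) stop("file is missing mapped column(s): ",
                              paste(missing, collapse = ", "))
    for (canonical in names(dialect)) df[[canonical]] <- df[[dialect[[canonical]]]]
  }
  validate_trials(df[, trial_columns()])
}
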
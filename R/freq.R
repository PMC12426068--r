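# Per-participant frequency tables and their delimited-text I/O.

#' Per-participant response frequency table
#'
#' A 5 x 5 integer matrix of response counts, rows indexed by
#' [item_types()] and columns by [response_categories()], with the number
#' of test items per type attached.  Row sums must equal the item counts
#' (the multinomial totals are fixed by the design).
#'
#' @param counts 5 x 5 numeric matrix of non-negative integer counts.  Row
#'   and column names, if present, must match the canonical orders.
#' @param participant Participant identifier.
#' @param items_per_type Named integer vector of test items per item type;
#'   defaults to the row sums of `counts`.
#' @return An object of class `mpt_freqtab`.
#' @export
freq_table <- function(counts, participant = NA_character_, items_per_type = NULL) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(5L, 5L))) stop("counts must be a 5 x 5 matrix")
  if (!is.null(rownames(counts)) && !identical(rownames(counts), item_types()))
    stop("count rows must be ordered ", paste(item_types(), collapse = ", "))
  if (!is.null(colnames(counts)) && !identical(colnames(counts), response_categories()))
    stop("count columns must be ordered ", paste(response_categories(), collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  dimnames(counts) <- list(item_types(), response_categories())
  if (is.null(items_per_type)) {
    items_per_type <- rowSums(counts)
  } else {
    items_per_type <- items_per_type[item_types()]
    if (!isTRUE(all.equal(unname(rowSums(counts)), unname(as.numeric(items_per_type)))))
      stop("row sums of counts must equal items_per_type")
  }
  structure(list(participant = participant,
                 counts = matrix(as.integer(counts), 5L, 5L,
                                 dimnames = dimnames(counts)),
                 items_per_type = setNames(as.integer(items_per_type), item_types())),
            class = "mpt_freqtab")
}

#' @rdname freq_table
#' @param table An `mpt_freqtab`.
#' @return `freq_counts()`: the 5 x 5 count matrix.
#' @export
freq_counts <- function(table) {
  stopifnot(inherits(table, "mpt_freqtab"))
  table$counts
}

#' @export
print.mpt_freqtab <- function(x, ...) {
  cat("Frequency table, participant", x$participant, "\n")
  print(x$counts)
  invisible(x)
}

# cohort list -> P x 25 matrix, columns <itemtype>_<category>
freq_matrix <- function(tables) {
  cols <- as.vector(t(outer(item_types(), response_categories(), paste, sep = "_")))
  m <- t(vapply(tables, function(tb) as.vector(t(freq_counts(tb))), numeric(25)))
  colnames(m) <- cols
  rownames(m) <- vapply(tables, function(tb) as.character(tb$participant), "")
  m
}

#' Read and write cohort frequency tables as delimited text
#'
#' Wide tab-separated layout: one row per participant, a `participant`
#' column, then 25 count columns named `<itemtype>_<category>` in the fixed
#' canonical orders (e.g. `TI_NEW`, `TI_OLD_TI`, ..., `new_OLD_FU`).
#'
#' @param tables List of [freq_table()] objects.
#' @param path File path.
#' @return `write_frequencies()`: the path, invisibly;
#'   `read_frequencies()`: a list of `mpt_freqtab`.
#' @export
write_frequencies <- function(tables, path) {
  m <- freq_matrix(tables)
  df <- data.frame(participant = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frequencies
#' @export
read_frequencies <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  cols <- as.vector(t(outer(item_types(), response_categories(), paste, sep = "_")))
  missing <- setdiff(cols, names(df))
  if (length(missing)) stop("frequency file is missing column(s): ",
                            paste(missing, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    counts <- matrix(as.numeric(df[i, cols]), nrow = 5, byrow = TRUE,
                     dimnames = list(item_types(), response_categories()))
    freq_table(counts, participant = as.character(df$participant[i]))
  })
}
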
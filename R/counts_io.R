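# Reading, validating and writing count matrices and sample sheets, plus
# aggregation of technical repeats. Counts are represented as plain integer
# matrices with unique feature rownames and sample colnames; sample sheets as
# data.frames with a fixed column contract.

#' Construct a validated count matrix
#'
#' @param counts numeric matrix of non-negative integer read counts,
#'   features in rows, samples in columns.
#' @param feature_ids,sample_ids optional identifier vectors; default to the
#'   dimnames of `counts`.
#' @return An integer matrix with rownames (features) and colnames (samples).
#' @export
count_matrix <- function(counts, feature_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop("count matrix requires feature and sample identifiers", call. = FALSE)
  }
  if (length(feature_ids) != nrow(counts) || length(sample_ids) != ncol(counts)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  dimnames(counts) <- list(as.character(feature_ids), as.character(sample_ids))
  validate_counts(counts)
}

#' @noRd
validate_counts <- function(counts, allow_noninteger = FALSE) {
  if (!is.numeric(counts)) stop("counts must be numeric", call. = FALSE)
  dup_f <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_f)) {
    stop("duplicated feature id(s): ", paste(dup_f, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s)) {
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0)
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(counts))
    stop(sprintf("negative or non-numeric count at feature '%s', sample '%s'",
                 rownames(counts)[ij[1L]], colnames(counts)[ij[2L]]), call. = FALSE)
  }
  nonint <- which(abs(counts - round(counts)) > 1e-8)
  if (length(nonint)) {
    if (allow_noninteger) {
      warning(sprintf("%d non-integer count(s) rounded to nearest integer",
                      length(nonint)), call. = FALSE)
      counts <- round(counts)
    } else {
      ij <- arrayInd(nonint[1L], dim(counts))
      stop(sprintf(
        "non-integer count at feature '%s', sample '%s' (use allow_noninteger = TRUE to round)",
        rownames(counts)[ij[1L]], colnames(counts)[ij[2L]]), call. = FALSE)
    }
  }
  storage.mode(counts) <- "integer"
  counts
}

infer_sep <- function(path) {
  if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a count matrix from delimited text
#'
#' The first column must hold feature identifiers and the header row sample
#' identifiers. TSV is the default dialect; comma is inferred from a `.csv`
#' extension; gzip is handled transparently.
#'
#' @param path file path.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @param allow_noninteger round non-integer cells to the nearest integer with
#'   a warning (for upstream batch-corrected matrices) instead of erroring.
#' @return A validated count matrix (see [count_matrix()]).
#' @export
read_counts <- function(path, sep = NULL, allow_noninteger = FALSE) {
  sep <- sep %||% infer_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  if (ncol(df) < 2L) stop("count table needs a feature id column plus >= 1 sample", call. = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(df[, -1L, drop = FALSE], 2L, is.numeric))[1L]
    stop(sprintf("non-numeric values in sample column '%s'",
                 colnames(df)[-1L][bad]), call. = FALSE)
  }
  rownames(m) <- ids
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stop("duplicated feature id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  validate_counts(m, allow_noninteger = allow_noninteger)
}

#' Write a count matrix as delimited text
#' @param cm count matrix.
#' @param path output path (`.csv` switches to comma separation; `.gz` gzips).
#' @export
write_counts <- function(cm, path) {
  sep <- infer_sep(path)
  df <- data.frame(feature_id = rownames(cm), cm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated sample sheet
#'
#' @param sample_id character sample identifiers (unique).
#' @param group one of `"control"`, `"DLBCL"`, `"HL"` per sample.
#' @param time,event optional right-censored survival outcome (years > 0 and
#'   0/1 indicator); must be supplied together.
#' @param batch optional batch label.
#' @return A `data.frame` with class `sample_table`.
#' @export
sample_table <- function(sample_id, group, time = NULL, event = NULL, batch = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicated sample id(s): ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "), call. = FALSE)
  }
  group <- as.character(group)
  bad <- setdiff(unique(group), GROUP_LEVELS)
  if (length(bad)) {
    stop(sprintf("unknown group label(s) %s; allowed: %s",
                 paste(sQuote(bad), collapse = ", "),
                 paste(GROUP_LEVELS, collapse = ", ")), call. = FALSE)
  }
  if (is.null(time) != is.null(event)) {
    stop("'time' and 'event' must be supplied together", call. = FALSE)
  }
  df <- data.frame(sample_id = sample_id,
                   group = factor(group, levels = GROUP_LEVELS),
                   stringsAsFactors = FALSE)
  if (!is.null(time)) {
    time <- as.numeric(time)
    event <- as.numeric(event)
    ok <- is.na(time) | time > 0
    if (!all(ok)) stop("survival times must be > 0", call. = FALSE)
    if (!all(is.na(event) | event %in% c(0, 1))) {
      stop("event indicator must be 0/1", call. = FALSE)
    }
    df$time <- time
    df$event <- event
  }
  if (!is.null(batch)) df$batch <- as.character(batch)
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read a sample sheet from delimited text
#' @inheritParams read_counts
#' @return A `sample_table` data.frame.
#' @export
read_samples <- function(path, sep = NULL) {
  sep <- sep %||% infer_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("sample sheet missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if ("time" %in% colnames(df) && !"event" %in% colnames(df)) {
    stop("sample sheet has 'time' without 'event'", call. = FALSE)
  }
  if ("event" %in% colnames(df) && !"time" %in% colnames(df)) {
    stop("sample sheet has 'event' without 'time'", call. = FALSE)
  }
  sample_table(df$sample_id, df$group,
               time = if ("time" %in% colnames(df)) df$time else NULL,
               event = if ("event" %in% colnames(df)) df$event else NULL,
               batch = if ("batch" %in% colnames(df)) df$batch else NULL)
}

#' Write a sample sheet (or any data.frame) as delimited text
#' @param obj data.frame to write.
#' @param path output path.
#' @export
write_table <- function(obj, path) {
  sep <- infer_sep(path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(as.data.frame(obj), con, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
write_samples <- function(obj, path) write_table(obj, path)

#' Aggregate technical repeats by summation
#'
#' Columns mapped to the same subject are summed element-wise, so total reads
#' are conserved. Output column order follows the first occurrence of each
#' subject in the input.
#'
#' @param cm count matrix whose columns are technical repeats.
#' @param mapping named character vector: `names(mapping)` are repeat (column)
#'   ids, values are subject ids.
#' @return A count matrix with one column per subject.
#' @export
aggregate_technical_repeats <- function(cm, mapping) {
  unmapped <- setdiff(colnames(cm), names(mapping))
  if (length(unmapped)) {
    stop("column(s) missing from repeat mapping: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  subj <- as.character(mapping[colnames(cm)])
  agg <- t(rowsum(t(cm), group = subj, reorder = FALSE))
  count_matrix(agg, feature_ids = rownames(cm), sample_ids = colnames(agg))
}
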
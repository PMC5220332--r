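#' Read an expression matrix from delimited text
#'
#' Reads a TSV or CSV expression matrix: first column molecule ids, header
#' row time labels, remaining cells numeric expression values. The delimiter
#' is chosen from the file extension (".csv" = comma, anything else = tab)
#' unless given explicitly. Duplicate ids and non-numeric cells are errors
#' (reported with the offending ids / coordinates); nothing is silently
#' imputed.
#'
#' @param path path to the file.
#' @param delimiter field delimiter; \code{NULL} (default) autodetects from
#'   the extension.
#' @return numeric matrix, rows = molecules (rownames = ids), columns = time
#'   points (colnames = time labels).
#' @export
read_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(raw) < 2L) stop("expected an id column plus time columns: ", path)
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ids in ", path, ": ", paste(dup, collapse = ", "))
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, colnames(raw)[-1L]))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell(s) in ", path, ": ",
         paste(sprintf("row '%s', column '%s'",
                       ids[bad[, 1L]], colnames(vals)[bad[, 2L]]),
               collapse = "; "))
  vals
}

#' Write an association table to TSV
#'
#' Writes the records of a [screen_associations()] result as
#' tab-separated text with 6 significant digits for the numeric columns, in
#' a form that round-trips through [read_results()].
#'
#' @param records a \code{"dynomics_screen"} data.frame.
#' @param path output path.
#' @export
write_results <- function(records, path) {
  df <- as.data.frame(records)
  for (col in c("correlation", "p_value", "fdr"))
    df[[col]] <- signif(df[[col]], 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an association table written by [write_results()]
#'
#' @param path path to the TSV file.
#' @return data.frame with the association-record columns.
#' @export
read_results <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read a reference/query pair list
#'
#' Two-column delimited file (reference_id, query_id) restricting a screen
#' to chosen pairs, e.g. orthologous transcripts across organisms.
#'
#' @inheritParams read_matrix
#' @return data.frame with columns reference_id and query_id.
#' @export
read_pairs <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("pair list needs two columns: ", path)
  stats::setNames(df[, 1:2], c("reference_id", "query_id"))
}

#' Read a raw long-format time course table
#'
#' Long TSV/CSV with columns id, time, value; replicates appear as repeated
#' times. Input format for [resample_trajectory()].
#'
#' @inheritParams read_matrix
#' @return data.frame with columns id, time, value.
#' @export
read_long_timecourse <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("id", "time", "value")
  if (!all(need %in% names(df)))
    stop("long time-course file must have columns id, time, value")
  df[need]
}
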
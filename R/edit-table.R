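#' Edit tables: observed integration states per sampled cell
#'
#' An edit table records, for each sampled cell, the integer-coded state of
#' each of its m genomic targets: 0 = unedited, 1 = silenced, 2..S+1 = scar
#' outcomes 1..S. \code{NA} marks a missing observation (e.g. sequencing
#' dropout of that integration). Edit tables are plain tibbles whose first
#' column \code{cell} holds unique cell ids and whose remaining columns are
#' integer target states.
#'
#' @param states Integer matrix (cells x targets) or data frame of states.
#' @param cells Character cell ids; defaults to rownames of \code{states} or
#'   \code{cell_1..cell_n}.
#' @return A tibble of class \code{edit_table}.
#' @export
edit_table <- function(states, cells = NULL) {
  states <- as.matrix(states)
  if (is.null(cells)) cells <- rownames(states)
  if (is.null(cells)) cells <- paste0("cell_", seq_len(nrow(states)))
  if (anyDuplicated(cells)) stop("cell ids must be unique", call. = FALSE)
  if (length(cells) != nrow(states))
    stop("one cell id per row required", call. = FALSE)
  if (is.null(colnames(states)))
    colnames(states) <- paste0("target_", seq_len(ncol(states)))
  ok <- is.na(states) | (states == floor(states) & states >= 0)
  if (!all(ok))
    stop("states must be non-negative integers (0 unedited, 1 silenced, 2.. scars) or NA",
         call. = FALSE)
  out <- tibble::as_tibble(as.data.frame(states))
  out[] <- lapply(out, as.integer)
  out <- dplyr::bind_cols(tibble::tibble(cell = as.character(cells)), out)
  class(out) <- c("edit_table", class(out))
  out
}

#' Extract the integer state matrix of an edit table
#'
#' @param table An \code{edit_table} (or any data frame with a \code{cell}
#'   column followed by integer state columns).
#' @param silenced_is_missing Remap observed silenced states (1) to missing.
#'   RNA readouts cannot distinguish a silenced integration from a dropout,
#'   so silenced calls may be treated as unobserved.
#' @return Integer matrix with cell ids as rownames.
#' @export
edit_table_states <- function(table, silenced_is_missing = FALSE) {
  stopifnot(is.data.frame(table), "cell" %in% names(table))
  cells <- as.character(table$cell)
  mat <- as.matrix(table[setdiff(names(table), "cell")])
  storage.mode(mat) <- "integer"
  rownames(mat) <- cells
  if (silenced_is_missing) mat[mat == 1L] <- NA_integer_
  mat
}

#' Read / write edit tables as delimited text
#'
#' Files are CSV or TSV (chosen from the extension, or forced via
#' \code{delim}) with a header row of target names; the first column holds
#' cell ids; empty fields or "NA" are missing observations.
#'
#' @param path File path.
#' @param delim Field delimiter; default inferred from the extension
#'   (\code{.csv} vs anything else = tab).
#' @return \code{read_edit_table}: an \code{edit_table} tibble.
#' @rdname edit-table-io
#' @export
read_edit_table <- function(path, delim = NULL) {
  if (is.null(delim))
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          na = c("", "NA"))
  names(df)[1] <- "cell"
  edit_table(as.matrix(df[-1]), cells = df$cell)
}

#' @param table An \code{edit_table}.
#' @rdname edit-table-io
#' @export
write_edit_table <- function(table, path, delim = NULL) {
  if (is.null(delim))
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(tibble::as_tibble(table), path, delim = delim, na = "NA")
  invisible(path)
}

# Check that table cells and tree tips are bijective; returns the state
# matrix with rows ordered to match the given tip labels.
align_table_to_tips <- function(table, tip_labels, silenced_is_missing = FALSE) {
  mat <- edit_table_states(table, silenced_is_missing = silenced_is_missing)
  if (!setequal(rownames(mat), tip_labels) ||
      length(tip_labels) != nrow(mat))
    stop("edit-table cells and tree tip labels must match one-to-one",
         call. = FALSE)
  mat[match(tip_labels, rownames(mat)), , drop = FALSE]
}
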
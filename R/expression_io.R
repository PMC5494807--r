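#' Expression matrix with a young/old sample grouping
#'
#' Container for a normalized (log2-scale) probe- or gene-level expression
#' matrix with a two-level age grouping attached to its columns. Values must
#' be finite; both groups must have at least two samples.
#'
#' @param values numeric matrix, rows = probes/genes (rownames required),
#'   columns = samples (colnames required), log2 intensities.
#' @param groups character/factor of `"young"`/`"old"`, one per column (or a
#'   named vector matched to column names).
#' @param symbols optional per-row gene symbols (for probe-level matrices);
#'   `NULL` means the rownames already are symbols.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `groups` (factor, levels young/old) and `symbols`.
#' @examples
#' m <- expression_matrix(
#'   matrix(rnorm(12, 7), 3, 4,
#'          dimnames = list(c("A", "B", "C"), paste0("s", 1:4))),
#'   groups = c("young", "young", "old", "old"))
#' @export
expression_matrix <- function(values, groups, symbols = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop2("expression matrix needs row and column names")
  }
  if (anyDuplicated(colnames(values))) stop2("duplicate sample ids")
  if (anyDuplicated(rownames(values))) stop2("duplicate row ids")
  if (!all(is.finite(values))) stop2("expression values must all be finite")
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing)) stop2("no group label for sample(s): ",
                               paste(missing, collapse = ", "))
    groups <- groups[colnames(values)]
  }
  if (length(groups) != ncol(values)) {
    stop2("got ", length(groups), " group labels for ", ncol(values), " samples")
  }
  groups <- check_groups(as.character(groups))
  names(groups) <- colnames(values)
  if (!is.null(symbols)) {
    stopifnot(length(symbols) == nrow(values))
    symbols <- as.character(symbols)
  }
  structure(list(values = values, groups = groups, symbols = symbols),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("<expr_matrix> ", nrow(x$values), " rows x ", ncol(x$values),
      " samples (", sum(x$groups == "young"), " young, ",
      sum(x$groups == "old"), " old)",
      if (is.null(x$symbols)) "; rows are gene symbols" else "; probe-level",
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Reads the data table out of either a plain TSV or a GEO series-matrix-style
# file ("!"-prefixed metadata lines, table delimited by
# !series_matrix_table_begin/end markers). Returns the kept lines.
extract_table_lines <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) && length(end)) {
    lines <- lines[(begin[1] + 1):(end[1] - 1)]
  } else {
    lines <- lines[!startsWith(lines, "!")]
  }
  lines[nzchar(lines)]
}

#' Read an expression matrix with sample grouping
#'
#' Accepts a plain TSV (header row of sample ids, first column row ids) or GEO
#' series-matrix-style text, in which `!`-prefixed metadata lines are skipped
#' and the table is taken from between the begin/end markers when present.
#' Samples absent from `group_map` are dropped with a warning.
#'
#' @param path TSV or series-matrix file.
#' @param group_map sample grouping: a named character vector
#'   (`c(sampleid = "young", ...)`), a 2-column data.frame (sample id, group),
#'   or a path to a 2-column TSV.
#' @param symbols optional per-row symbol annotation passed through to
#'   [expression_matrix()].
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, group_map, symbols = NULL) {
  if (!file.exists(path)) stop2("expression matrix file not found: ", path)
  lines <- extract_table_lines(path)
  if (length(lines) < 2) stop2("no data table found in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop2("ragged row in ", path, " at table line ", bad, ": ",
          widths[bad], " fields, expected ", widths[1])
  }
  header <- fields[[1]]
  sample_ids <- gsub('^"|"$', "", header[-1])
  if (anyDuplicated(sample_ids)) {
    stop2("duplicate sample ids in header of ", path, ": ",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  body <- fields[-1]
  row_ids <- gsub('^"|"$', "", vapply(body, `[[`, character(1), 1))
  values <- matrix(NA_real_, length(body), length(sample_ids),
                   dimnames = list(row_ids, sample_ids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (anyNA(v)) stop2("non-numeric value in ", path, " at table line ", i + 1)
    values[i, ] <- v
  }

  gm <- as_group_map(group_map)
  keep <- intersect(sample_ids, names(gm))
  if (length(keep) == 0) {
    stop2("no overlap between samples in ", path, " and the group map")
  }
  dropped <- setdiff(sample_ids, keep)
  if (length(dropped)) {
    warning("dropping ", length(dropped), " sample(s) absent from group map: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  expression_matrix(values[, keep, drop = FALSE], gm[keep], symbols = symbols)
}

# Normalises the accepted group_map representations to a named vector.
as_group_map <- function(group_map) {
  if (is.character(group_map) && length(group_map) == 1 && is.null(names(group_map))) {
    if (!file.exists(group_map)) stop2("group map file not found: ", group_map)
    df <- utils::read.delim(group_map, stringsAsFactors = FALSE)
    group_map <- df
  }
  if (is.data.frame(group_map)) {
    if (ncol(group_map) < 2) stop2("group map needs 2 columns (sample, group)")
    group_map <- stats::setNames(as.character(group_map[[2]]),
                                 as.character(group_map[[1]]))
  }
  if (is.null(names(group_map))) stop2("group map must be named by sample id")
  group_map
}

#' Collapse probe-level rows to gene symbols
#'
#' When several probes map to the same gene symbol their values are collapsed
#' to the unweighted arithmetic mean of their log2 intensities, per sample
#' (i.e. averaging is on the log2 scale the matrix is stored on). Probes
#' without a symbol are dropped. Output rows are one per symbol, in
#' lexicographic order; the operation is idempotent on an already collapsed
#' matrix.
#'
#' @param m an [expression_matrix()].
#' @param mapping probe-to-symbol map: named character vector
#'   (`c(probe = "SYMBOL", ...)`) or 2-column data.frame. If `NULL`, the
#'   matrix's own `symbols` slot is used (or rownames if already symbols).
#' @return A symbol-level [expression_matrix()].
#' @examples
#' m <- expression_matrix(
#'   matrix(c(6, 8, 5, 7, 4, 6, 3, 5), 2, 4, byrow = FALSE,
#'          dimnames = list(c("p1", "p2"), paste0("s", 1:4))),
#'   groups = c("young", "young", "old", "old"))
#' collapse_probes(m, c(p1 = "A", p2 = "A"))$values  # per-sample probe means
#' @export
collapse_probes <- function(m, mapping = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(mapping)) {
    symbols <- m$symbols %||% rownames(m$values)
  } else {
    if (is.data.frame(mapping)) {
      mapping <- stats::setNames(as.character(mapping[[2]]),
                                 as.character(mapping[[1]]))
    }
    symbols <- unname(mapping[rownames(m$values)])
  }
  symbols <- toupper(trimws(symbols))
  keep <- !is.na(symbols) & nzchar(symbols)
  if (!any(keep)) stop2("no probes left after symbol mapping")
  vals <- m$values[keep, , drop = FALSE]
  symbols <- symbols[keep]
  summed <- rowsum(vals, group = symbols)      # sorts group keys
  counts <- as.vector(table(symbols)[rownames(summed)])
  collapsed <- summed / counts
  expression_matrix(collapsed[order(rownames(collapsed)), , drop = FALSE],
                    m$groups)
}
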
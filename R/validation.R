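#' Direction-stratified DE gene list of one dataset
#'
#' Holds a dataset's differentially expressed genes split by direction
#' (up-regulated in old vs in young) together with the universe of symbols
#' measured in that dataset. The two direction lists must be disjoint subsets
#' of the universe.
#'
#' @param dataset_id free-text label (e.g. an accession).
#' @param up_in_old,up_in_young character vectors of symbols.
#' @param universe symbols measured in the dataset; defaults to the union of
#'   the two lists (a minimal universe — supply the full measured set when
#'   available, the overlap test depends on it).
#' @return An object of class `de_gene_list`.
#' @export
de_gene_list <- function(dataset_id, up_in_old, up_in_young, universe = NULL) {
  up_in_old <- unique(toupper(up_in_old))
  up_in_young <- unique(toupper(up_in_young))
  universe <- unique(toupper(universe %||% c(up_in_old, up_in_young)))
  if (length(intersect(up_in_old, up_in_young))) {
    stop2("directions overlap in '", dataset_id, "': ",
          paste(intersect(up_in_old, up_in_young), collapse = ", "))
  }
  if (!all(c(up_in_old, up_in_young) %in% universe)) {
    stop2("DE genes outside the universe in '", dataset_id, "'")
  }
  structure(list(dataset_id = dataset_id, up_in_old = up_in_old,
                 up_in_young = up_in_young, universe = universe),
            class = "de_gene_list")
}

#' @export
print.de_gene_list <- function(x, ...) {
  cat("<de_gene_list> ", x$dataset_id, ": ", length(x$up_in_old),
      " up in old, ", length(x$up_in_young), " up in young, universe ",
      length(x$universe), "\n", sep = "")
  invisible(x)
}

#' Build the study DE gene list from a DE table
#'
#' @param de a `de_table` from [run_diffexp()] or the Table-2-style fixture
#'   from [load_table2_fixture()] (where every row is a DE call).
#' @param dataset_id label for the study list.
#' @return A [de_gene_list()]; universe = all genes in the table.
#' @export
de_list_from_table <- function(de, dataset_id = "study") {
  stopifnot(is.data.frame(de), all(c("gene_symbol", "signed_fc") %in% names(de)))
  is_de <- if ("is_de" %in% names(de)) de$is_de else rep(TRUE, nrow(de))
  de_gene_list(dataset_id,
               up_in_old = de$gene_symbol[is_de & de$signed_fc < 0],
               up_in_young = de$gene_symbol[is_de & de$signed_fc > 0],
               universe = de$gene_symbol)
}

#' Read external DE gene lists from TSV
#'
#' Expects columns `gene_symbol`, `direction`, `dataset_id` with direction in
#' `up_in_old` / `up_in_young` / `ns` (`ns` rows are measured-but-not-DE genes
#' that only extend the dataset's universe).
#'
#' @param path TSV file.
#' @return Named list of [de_gene_list()], one per dataset.
#' @export
read_external_lists <- function(path) {
  if (!file.exists(path)) stop2("external DE list file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_symbol", "direction", "dataset_id")
  if (!all(need %in% names(df))) {
    stop2("external DE list needs columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$direction), c("up_in_old", "up_in_young", "ns"))
  if (length(bad)) stop2("unknown direction value(s): ", paste(bad, collapse = ", "))
  lists <- lapply(split(df, df$dataset_id), function(d) {
    de_gene_list(d$dataset_id[1],
                 up_in_old = d$gene_symbol[d$direction == "up_in_old"],
                 up_in_young = d$gene_symbol[d$direction == "up_in_young"],
                 universe = d$gene_symbol)
  })
  lists[order(names(lists))]
}

#' Hypergeometric overlap significance
#'
#' Upper-tail probability `P(X >= k)` of observing at least `k` shared genes
#' between two lists of sizes `n_study` and `n_external` drawn from a common
#' universe, with `X` hypergeometric. Exact summation (via [stats::phyper()]);
#' symmetric in the two list sizes.
#'
#' @param k observed overlap.
#' @param n_study,n_external list sizes.
#' @param universe_size common universe size.
#' @return p-value in (0, 1].
#' @examples
#' overlap_significance(3, 4, 5, 10)  # 66/252
#' @export
overlap_significance <- function(k, n_study, n_external, universe_size) {
  stopifnot(length(k) == 1, length(universe_size) == 1)
  if (k < 0 || k > min(n_study, n_external) ||
      max(n_study, n_external) > universe_size) {
    stop2("inconsistent counts: k=", k, ", sizes ", n_study, "/", n_external,
          ", universe ", universe_size)
  }
  stats::phyper(k - 1, n_study, universe_size - n_study, n_external,
                lower.tail = FALSE)
}

#' Direction-stratified overlap between study and external DE lists
#'
#' Intersects the study's DE gene lists with external datasets' lists, per
#' direction, on a common universe, and attaches a one-sided hypergeometric
#' p-value to each overlap. In `union_of_external` mode (default) the external
#' datasets are pooled first (universe = union of their universes, direction
#' lists = unions); in `per_dataset` mode each external dataset is intersected
#' with the study separately. The test universe is the intersection of the
#' study universe with the (pooled or per-dataset) external universe unless
#' given explicitly.
#'
#' @param study a [de_gene_list()] for the study data.
#' @param external a [de_gene_list()] or list of them.
#' @param mode `"union_of_external"` or `"per_dataset"`.
#' @param universe optional explicit common universe (character vector).
#' @return A data.frame with one row per direction (and per dataset in
#'   `per_dataset` mode): `dataset_id`, `direction`, `k`, `n_study`,
#'   `n_external`, `universe_size`, `hypergeom_p`, and `genes` (list column of
#'   lexicographically sorted shared symbols).
#' @export
intersect_lists <- function(study, external,
                            mode = c("union_of_external", "per_dataset"),
                            universe = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(study, "de_gene_list"))
  if (inherits(external, "de_gene_list")) external <- list(external)
  stopifnot(length(external) >= 1,
            all(vapply(external, inherits, logical(1), "de_gene_list")))

  if (mode == "union_of_external") {
    external <- list(de_gene_list(
      paste(vapply(external, `[[`, character(1), "dataset_id"), collapse = "+"),
      up_in_old = unique(unlist(lapply(external, `[[`, "up_in_old"))),
      up_in_young = unique(unlist(lapply(external, `[[`, "up_in_young"))),
      universe = unique(unlist(lapply(external, `[[`, "universe")))))
  }

  rows <- lapply(external, function(ext) {
    uni <- toupper(universe %||% intersect(study$universe, ext$universe))
    if (length(uni) == 0) {
      stop2("empty common universe between study and '", ext$dataset_id, "'")
    }
    do.call(rbind, lapply(c("up_in_old", "up_in_young"), function(dir) {
      a <- intersect(study[[dir]], uni)
      b <- intersect(ext[[dir]], uni)
      shared <- sort(intersect(a, b))
      data.frame(dataset_id = ext$dataset_id, direction = dir,
                 k = length(shared), n_study = length(a),
                 n_external = length(b), universe_size = length(uni),
                 hypergeom_p = overlap_significance(length(shared), length(a),
                                                    length(b), length(uni)),
                 genes = I(list(shared)), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(out, class = c("overlap_results", "data.frame"))
}
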
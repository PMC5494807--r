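#' Signed fold change between age groups
#'
#' Computes the fold change of group mean expression as a *signed* ratio:
#' with `r` the ratio of the young-group mean to the old-group mean on the
#' linear scale, the result is `r` when `r >= 1` and `-1/r` otherwise, so
#' `|FC| >= 1` always and the sign encodes direction — *negative* values mean
#' higher expression in the *old* group.
#'
#' Two modes control how the ratio is formed from log2 intensities:
#' `"ratio_of_means"` (default) linearises first and takes the ratio of the
#' arithmetic group means `mean(2^young) / mean(2^old)`;
#' `"diff_of_log_means"` exponentiates the difference of the log2 group means
#' (equivalently a ratio of geometric means).
#'
#' @param values_young,values_old numeric log2 intensities, at least one
#'   finite value each.
#' @param fc_mode `"ratio_of_means"` or `"diff_of_log_means"`.
#' @return Signed fold change (scalar).
#' @examples
#' signed_fold_change(c(3, 3), c(2, 2))  # +2: up in young
#' signed_fold_change(c(2, 2), c(3, 3))  # -2: up in old
#' @export
signed_fold_change <- function(values_young, values_old,
                               fc_mode = c("ratio_of_means", "diff_of_log_means")) {
  fc_mode <- match.arg(fc_mode)
  if (length(values_young) < 1 || length(values_old) < 1 ||
      !all(is.finite(values_young)) || !all(is.finite(values_old))) {
    stop2("each group needs >= 1 finite log2 value")
  }
  r <- switch(fc_mode,
    ratio_of_means = mean(2^values_young) / mean(2^values_old),
    diff_of_log_means = 2^(mean(values_young) - mean(values_old)))
  if (r >= 1) r else -1 / r
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Mann-Whitney/Wilcoxon rank-sum test between two groups of expression
#' values, as used per gene in the differential expression step. The exact
#' enumeration null is used for small samples without ties and the normal
#' approximation with tie/continuity correction otherwise (the behaviour of
#' [stats::wilcox.test()]). When every value in both groups is identical the
#' ranking is degenerate and `p = 1` is returned by convention.
#'
#' @param values_a,values_b numeric vectors, >= 2 values each.
#' @return Two-sided p-value.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # 0.1, the most extreme split
#' @export
wilcoxon_rank_sum <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop2("each group needs >= 2 values")
  }
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1) {
    message("degenerate ranking (all values identical); p = 1 by convention")
    return(1)
  }
  suppressWarnings(
    stats::wilcox.test(values_a, values_b, alternative = "two.sided")$p.value)
}

#' Differential expression between young and old stroma
#'
#' For every gene of a symbol-level expression matrix, computes group mean
#' log2 intensities, the signed fold change (see [signed_fold_change()];
#' negative = up in old), a two-sided Wilcoxon rank-sum p-value, and the
#' differential expression call `|FC| >= threshold`. Following the study
#' design the fixtures come from, the DE call uses the fold-change rule only;
#' the Wilcoxon p is reported alongside and an optional `p_threshold` can
#' additionally be applied.
#'
#' @param m a symbol-level [expression_matrix()] (collapse probe-level input
#'   with [collapse_probes()] first).
#' @param threshold positive fold-change cut-off, must be > 1 (default 1.5).
#' @param fc_mode passed to [signed_fold_change()].
#' @param p_threshold optional Wilcoxon p cut-off additionally required for a
#'   DE call; `NULL` (default) disables it.
#' @return A `de_table`: data.frame with columns `gene_symbol`, `mean_young`,
#'   `mean_old`, `signed_fc`, `wilcoxon_p`, `is_de`, sorted by `signed_fc`
#'   ascending (most up-in-old first; ties broken by symbol), with attributes
#'   `threshold`, `n_up_old`, `n_up_young`.
#' @export
run_diffexp <- function(m, threshold = 1.5,
                        fc_mode = c("ratio_of_means", "diff_of_log_means"),
                        p_threshold = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  fc_mode <- match.arg(fc_mode)
  if (!is.numeric(threshold) || threshold <= 1) {
    stop2("fold-change threshold must be > 1, got ", threshold)
  }
  if (!is.null(m$symbols)) {
    stop2("matrix is probe-level; run collapse_probes() first")
  }
  young <- m$values[, m$groups == "young", drop = FALSE]
  old <- m$values[, m$groups == "old", drop = FALSE]

  mean_young <- rowMeans(young)
  mean_old <- rowMeans(old)
  r <- switch(fc_mode,
    ratio_of_means = rowMeans(2^young) / rowMeans(2^old),
    diff_of_log_means = 2^(mean_young - mean_old))
  signed_fc <- ifelse(r >= 1, r, -1 / r)
  wilcoxon_p <- vapply(seq_len(nrow(m$values)), function(i) {
    wilcoxon_rank_sum(young[i, ], old[i, ])
  }, numeric(1))

  is_de <- abs(signed_fc) >= threshold
  if (!is.null(p_threshold)) is_de <- is_de & wilcoxon_p < p_threshold

  de <- data.frame(gene_symbol = rownames(m$values),
                   mean_young = mean_young, mean_old = mean_old,
                   signed_fc = signed_fc, wilcoxon_p = wilcoxon_p,
                   is_de = is_de, row.names = NULL,
                   stringsAsFactors = FALSE)
  de <- de[order(de$signed_fc, de$gene_symbol), , drop = FALSE]
  rownames(de) <- NULL
  structure(de, class = c("de_table", "data.frame"),
            threshold = threshold,
            n_up_old = sum(de$is_de & de$signed_fc < 0),
            n_up_young = sum(de$is_de & de$signed_fc > 0))
}

#' @export
print.de_table <- function(x, ...) {
  cat("<de_table> ", nrow(x), " genes; |FC| >= ", attr(x, "threshold"),
      ": ", attr(x, "n_up_old"), " up in old, ", attr(x, "n_up_young"),
      " up in young\n", sep = "")
  NextMethod()
}

#' Summarise a DE table
#'
#' @param de a `de_table` from [run_diffexp()].
#' @return List with `n_genes`, `threshold`, `n_up_old`, `n_up_young`.
#' @export
de_summary <- function(de) {
  stopifnot(inherits(de, "de_table"))
  list(n_genes = nrow(de), threshold = attr(de, "threshold"),
       n_up_old = attr(de, "n_up_old"), n_up_young = attr(de, "n_up_young"))
}
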
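#' Rank genes by signed fold change
#'
#' Builds the ranked list that the enrichment score walks: genes in descending
#' order of signed fold change, so the most up-in-young genes sit at the top
#' and the most up-in-old genes at the bottom. Ties are broken
#' lexicographically by symbol for deterministic output.
#'
#' @param de a `de_table` from [run_diffexp()], or any data.frame with
#'   `gene_symbol` and `signed_fc` columns (e.g. [load_table2_fixture()]).
#' @return A `ranked_list`: list with `symbols`, `scores` (non-increasing)
#'   and `N` (universe size).
#' @export
rank_genes <- function(de) {
  stopifnot(is.data.frame(de), all(c("gene_symbol", "signed_fc") %in% names(de)))
  if (nrow(de) == 0) stop2("empty DE table")
  if (anyDuplicated(de$gene_symbol)) {
    stop2("duplicate gene symbols in DE table: ",
          paste(unique(de$gene_symbol[duplicated(de$gene_symbol)]), collapse = ", "))
  }
  ord <- order(-de$signed_fc, de$gene_symbol)
  structure(list(symbols = de$gene_symbol[ord],
                 scores = de$signed_fc[ord],
                 N = nrow(de)),
            class = "ranked_list")
}

#' @export
print.ranked_list <- function(x, ...) {
  cat("<ranked_list> ", x$N, " genes; top ", x$symbols[1], " (",
      format(x$scores[1]), "), bottom ", x$symbols[x$N], " (",
      format(x$scores[x$N]), ")\n", sep = "")
  invisible(x)
}

#' Running-sum enrichment score
#'
#' Walks the ranked list top to bottom keeping a running sum: on a gene that
#' belongs to the set ("hit") the sum increases by `w_i / sum(w)` (unweighted
#' mode: `w_i = 1`, i.e. `1/N_hit`; weighted mode: `w_i = |score_i|`), on a
#' miss it decreases by `1/(N - N_hit)`. The enrichment score is the running
#' sum's maximum-magnitude deviation from zero, kept signed, so `ES` lies in
#' `[-1, 1]`: positive when the set concentrates at the top of the ranking
#' (up in young), *negative* when it concentrates at the bottom (up in old).
#'
#' @param ranked a [rank_genes()] result.
#' @param set a [gene_set()] or character vector of symbols; intersected with
#'   the ranked universe.
#' @param weight_mode `"unweighted"` (classic Kolmogorov-Smirnov statistic,
#'   the default) or `"weighted"` (`w = |score|`, exponent 1).
#' @return List with `es`, `running_sum` (length-N trace for plotting),
#'   `n_hits` and `positions` (hit ranks). If the set has no overlap with the
#'   universe, returns `n_hits = 0` and `es = NA` with a warning.
#' @examples
#' rl <- rank_genes(data.frame(gene_symbol = LETTERS[1:10], signed_fc = 10:1))
#' enrichment_score(rl, c("A", "C", "E"))$es  # 5/7
#' @export
enrichment_score <- function(ranked, set,
                             weight_mode = c("unweighted", "weighted")) {
  stopifnot(inherits(ranked, "ranked_list"))
  weight_mode <- match.arg(weight_mode)
  symbols <- set_symbols(set)
  hit <- toupper(ranked$symbols) %in% symbols   # set symbols are upper-cased
  n_hits <- sum(hit)
  if (n_hits == 0) {
    warning("set has no overlap with the ranked universe; skipped",
            call. = FALSE)
    return(list(es = NA_real_, running_sum = NULL, n_hits = 0L,
                positions = integer(0)))
  }
  if (n_hits == ranked$N) {
    stop2("set covers the whole universe; miss decrement undefined")
  }
  w <- if (weight_mode == "weighted") abs(ranked$scores[hit]) else rep(1, n_hits)
  if (sum(w) == 0) w <- rep(1, n_hits)   # all-zero scores: fall back to equal weights
  steps <- numeric(ranked$N)
  steps[hit] <- w / sum(w)
  steps[!hit] <- -1 / (ranked$N - n_hits)
  running <- cumsum(steps)
  es <- running[which.max(abs(running))]  # first index at max |deviation|
  list(es = es, running_sum = running, n_hits = as.integer(n_hits),
       positions = which(hit))
}

# Fast ES for permutation draws: positions-only computation, O(n_hits).
# For sorted hit positions p, the running sum's local extrema are the values
# just before and just after each hit; both share the miss term (p_i - i)/(N-k).
# `weights` are the (absolute) per-hit weights in position order, or NULL for
# the unweighted statistic. Matches enrichment_score()'s full trace exactly,
# including the first-extremum tie-break.
es_from_positions <- function(positions, N, weights = NULL) {
  k <- length(positions)
  p <- sort.int(positions)
  miss <- (p - seq_len(k)) / (N - k)
  inc <- if (is.null(weights)) seq_len(k) / k else {
    w <- weights[order(positions)]
    if (sum(w) == 0) w <- rep(1, k)
    cumsum(w) / sum(w)
  }
  top <- inc - miss                    # value right after each hit
  bot <- c(0, inc[-k]) - miss          # value just before each hit
  cand <- as.vector(rbind(bot, top))   # trace order: bot_1, top_1, bot_2, ...
  cand[which.max(abs(cand))]
}

#' Permutation p-value for an enrichment score
#'
#' Empirical two-sided p-value for the observed ES of a set. The default
#' `gene_label` scheme keeps the ranking fixed and draws random sets of the
#' same size from the universe; the `phenotype` scheme shuffles the sample
#' group labels, recomputes fold changes and the ranking, and rescores the
#' set (requires the expression matrix; permutations are sampled, never
#' exhaustively enumerated over label splits). The sampled p-value uses the
#' add-one correction `p = (1 + #{|ES_perm| >= |ES_obs|}) / (1 + n_perm)` so
#' it is never zero. With `exact = TRUE` (gene_label only) all
#' `choose(N, n_hits)` placements are enumerated instead and the p-value is
#' the exact exceedance fraction.
#'
#' @param ranked a [rank_genes()] result.
#' @param set gene set or symbol vector.
#' @param n_perm number of permutations (>= 100 unless `exact`).
#' @param seed integer seed (mandatory for reproducibility; the caller's RNG
#'   state is left untouched).
#' @param scheme `"gene_label"` or `"phenotype"`.
#' @param weight_mode passed to the ES computation.
#' @param exact enumerate all placements (gene_label scheme, small universes).
#' @param m expression matrix, required for the phenotype scheme.
#' @param fc_mode fold-change mode for phenotype re-ranking.
#' @return List with `p_perm`, `es_obs`, `n_hits`, `n_perm_used`.
#' @export
permutation_test <- function(ranked, set, n_perm = 1000, seed = 1,
                             scheme = c("gene_label", "phenotype"),
                             weight_mode = c("unweighted", "weighted"),
                             exact = FALSE, m = NULL,
                             fc_mode = "ratio_of_means") {
  scheme <- match.arg(scheme)
  weight_mode <- match.arg(weight_mode)
  obs <- enrichment_score(ranked, set, weight_mode)
  if (obs$n_hits == 0) {
    return(list(p_perm = NA_real_, es_obs = NA_real_, n_hits = 0L,
                n_perm_used = 0L))
  }
  k <- obs$n_hits
  N <- ranked$N
  absw <- if (weight_mode == "weighted") abs(ranked$scores) else NULL

  if (exact) {
    if (scheme != "gene_label") stop2("exact enumeration only for gene_label scheme")
    if (choose(N, k) > 2e5) stop2("choose(N, n_hits) too large for exact enumeration")
    combos <- utils::combn(N, k)
    es_all <- apply(combos, 2, function(pos)
      es_from_positions(pos, N, if (is.null(absw)) NULL else absw[pos]))
    p <- mean(abs(es_all) >= abs(obs$es))
    return(list(p_perm = p, es_obs = obs$es, n_hits = k,
                n_perm_used = ncol(combos)))
  }

  if (n_perm < 100) stop2("n_perm must be >= 100")
  es_perm <- local_seed(seed, {
    if (scheme == "gene_label") {
      vapply(seq_len(n_perm), function(b) {
        pos <- sample.int(N, k)
        es_from_positions(pos, N, if (is.null(absw)) NULL else absw[pos])
      }, numeric(1))
    } else {
      if (is.null(m)) stop2("phenotype scheme needs the expression matrix")
      stopifnot(inherits(m, "expr_matrix"))
      symbols <- set_symbols(set)
      vapply(seq_len(n_perm), function(b) {
        g <- sample(as.character(m$groups))
        mp <- expression_matrix(m$values, g)
        rl <- rank_genes(run_diffexp(mp, fc_mode = fc_mode))
        pos <- which(toupper(rl$symbols) %in% symbols)
        wts <- if (is.null(absw)) NULL else abs(rl$scores[pos])
        es_from_positions(pos, rl$N, wts)
      }, numeric(1))
    }
  })
  p <- (1 + sum(abs(es_perm) >= abs(obs$es))) / (1 + n_perm)
  list(p_perm = p, es_obs = obs$es, n_hits = k, n_perm_used = as.integer(n_perm))
}

#' Benjamini-Hochberg adjustment of permutation p-values
#'
#' Applies the BH step-up procedure over the batch of tested sets and stores
#' the result in a `q_fdr` column.
#'
#' @param results data.frame with a `p_perm` column (as from [run_gsea()]).
#' @return `results` with a `q_fdr` column added/overwritten.
#' @export
fdr_adjust <- function(results) {
  stopifnot(is.data.frame(results), "p_perm" %in% names(results),
            nrow(results) >= 1)
  results$q_fdr <- stats::p.adjust(results$p_perm, method = "BH")
  results
}

#' Gene set enrichment analysis over a DE table
#'
#' Ranks the DE table by signed fold change, scores every admissible gene set
#' with the running-sum enrichment statistic, attaches permutation p-values
#' and BH-adjusted q-values. Sets with fewer than `min_hits` genes present in
#' the universe are skipped and reported in the `skipped` attribute. Results
#' are deterministic given `seed`: each set gets the sub-seed
#' `seed + position` in the collection, so adding or removing sets does not
#' change the others' p-values.
#'
#' @param de a `de_table` (or Table-2-style data.frame, see [rank_genes()]).
#' @param sets a [gene_set_collection()], or named list of symbol vectors.
#' @param weight_mode,scheme,n_perm,seed,m,fc_mode see [permutation_test()].
#' @param min_hits minimum genes of a set present in the universe (default 3).
#' @return An `enrichment_results` data.frame with columns `set_name`,
#'   `n_hits`, `es`, `p_perm`, `q_fdr`; attributes `running_sums` (named list
#'   of traces) and `skipped` (set names below `min_hits`).
#' @export
run_gsea <- function(de, sets, weight_mode = c("unweighted", "weighted"),
                     scheme = c("gene_label", "phenotype"), n_perm = 1000,
                     seed = 1, min_hits = 3, m = NULL,
                     fc_mode = "ratio_of_means") {
  weight_mode <- match.arg(weight_mode)
  scheme <- match.arg(scheme)
  ranked <- rank_genes(de)
  if (is.list(sets) && !inherits(sets, "gene_set_collection")) {
    sets <- gene_set_collection(lapply(names(sets), function(nm)
      if (inherits(sets[[nm]], "gene_set")) sets[[nm]]
      else gene_set(nm, sets[[nm]])))
  }
  stopifnot(inherits(sets, "gene_set_collection"))

  rows <- list(); traces <- list(); skipped <- character(0)
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    n_hits <- sum(toupper(ranked$symbols) %in% set_symbols(s))
    if (n_hits < min_hits) {
      skipped <- c(skipped, s$name)
      next
    }
    sc <- enrichment_score(ranked, s, weight_mode)
    pt <- permutation_test(ranked, s, n_perm = n_perm, seed = seed + i,
                           scheme = scheme, weight_mode = weight_mode,
                           m = m, fc_mode = fc_mode)
    rows[[s$name]] <- data.frame(set_name = s$name, n_hits = sc$n_hits,
                                 es = sc$es, p_perm = pt$p_perm,
                                 stringsAsFactors = FALSE)
    traces[[s$name]] <- sc$running_sum
  }
  if (length(skipped)) {
    message("skipped ", length(skipped), " set(s) with fewer than ", min_hits,
            " genes in the universe: ", paste(skipped, collapse = ", "))
  }
  if (length(rows) == 0) stop2("no gene set overlaps the universe")
  res <- fdr_adjust(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  structure(res, class = c("enrichment_results", "data.frame"),
            running_sums = traces, skipped = skipped,
            weight_mode = weight_mode, scheme = scheme,
            n_perm = n_perm, seed = seed)
}

#' @export
print.enrichment_results <- function(x, ...) {
  cat("<enrichment_results> ", nrow(x), " sets (",
      attr(x, "weight_mode"), " ES, ", attr(x, "scheme"),
      " permutations, n_perm=", attr(x, "n_perm"), ")\n", sep = "")
  NextMethod()
}
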
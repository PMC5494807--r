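#' Configuration for the synthetic expression generator
#'
#' Describes a two-group (young/old) log2-scale expression study with known
#' ground truth, mirroring the design the analysis targets: small unbalanced
#' groups (default 9 young vs 8 old), gene-wise Gaussian log intensities, a
#' sparse fraction of strongly differentially expressed genes, optional
#' coordinated *sub-threshold* shifts across designated gene modules (so set
#' enrichment — not single-gene DE — is what detects them), and optional
#' many-probes-per-gene redundancy.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_young,n_old samples per group (defaults 9 and 8).
#' @param baseline_mean,baseline_sd distribution of gene baseline log2
#'   intensities across genes (defaults 7.0 and 1.0).
#' @param noise_sd within-gene residual sd, log2 units (default 0.3).
#' @param de_fraction fraction of genes given a strong group effect
#'   (default 0.01).
#' @param de_log2fc log2 effect size of DE genes (default 1.5, i.e. linear
#'   fold change ~2.8); applied to the old group, half the genes up and half
#'   down.
#' @param module_specs list of coordinated-module descriptions, each a list
#'   with `name`, `size`, `shift` (log2 units) and `direction` (`"old"` or
#'   `"young"`: which group the shift is added to).
#' @param probes_per_gene probes measuring each gene (default 1); extra
#'   probes jitter around the gene profile with sd `noise_sd / 2`.
#' @param seed integer seed, required.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_genes = 2000, n_young = 9, n_old = 8,
                              baseline_mean = 7, baseline_sd = 1,
                              noise_sd = 0.3, de_fraction = 0.01,
                              de_log2fc = 1.5, module_specs = list(),
                              probes_per_gene = 1, seed) {
  if (missing(seed)) stop2("simulation seed is required")
  stopifnot(n_genes >= 1, n_young >= 2, n_old >= 2, baseline_sd > 0,
            noise_sd > 0, de_fraction >= 0, de_fraction <= 1,
            probes_per_gene >= 1)
  if (de_fraction > 0 && de_log2fc == 0) {
    stop2("de_log2fc must be non-zero when de_fraction > 0")
  }
  for (ms in module_specs) {
    stopifnot(all(c("name", "size", "shift", "direction") %in% names(ms)),
              ms$size >= 1, ms$direction %in% c("old", "young"))
  }
  n_module <- sum(vapply(module_specs, `[[`, numeric(1), "size"))
  if (round(de_fraction * n_genes) + n_module > n_genes) {
    stop2("DE genes plus module genes exceed n_genes")
  }
  structure(list(n_genes = n_genes, n_young = n_young, n_old = n_old,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, de_fraction = de_fraction,
                 de_log2fc = de_log2fc, module_specs = module_specs,
                 probes_per_gene = probes_per_gene, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-group expression study with ground truth
#'
#' Gene `g` gets a baseline `mu_g ~ N(baseline_mean, baseline_sd)`; sample
#' values are `mu_g + group effect + N(0, noise_sd)`. DE genes receive
#' `+/- de_log2fc` in the old group (so in the signed fold-change convention
#' a gene shifted *up in old* comes out with a *negative* signed FC); module
#' genes receive their module's coordinated shift in the stated group. With
#' `probes_per_gene > 1` each probe adds independent `N(0, noise_sd/2)`
#' jitter around its gene's profile and the returned matrix is probe-level
#' (collapse with [collapse_probes()]). Fully reproducible from the seed.
#'
#' @param config a [simulation_config()].
#' @return List with `matrix` (an [expression_matrix()]), `truth` (list:
#'   `de_genes` data.frame with `gene_symbol`, `true_log2fc_old` — positive
#'   means up in old; `module_members` named list; `config` echo) and `sets`
#'   (a [gene_set_collection()] of the injected modules, empty if none).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, {
    genes <- sprintf("GENE%04d", seq_len(config$n_genes))
    samples <- c(sprintf("Y%02d", seq_len(config$n_young)),
                 sprintf("O%02d", seq_len(config$n_old)))
    groups <- rep(c("young", "old"), c(config$n_young, config$n_old))

    mu <- stats::rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
    effect_old <- numeric(config$n_genes)          # log2 shift added to old group

    n_de <- round(config$de_fraction * config$n_genes)
    pool <- sample(genes)                           # random assignment order
    de_genes <- character(0)
    if (n_de > 0) {
      de_genes <- pool[seq_len(n_de)]
      pool <- pool[-seq_len(n_de)]
      sign_up <- rep_len(c(1, -1), n_de)            # half up, half down in old
      effect_old[match(de_genes, genes)] <- sign_up * config$de_log2fc
    }
    module_members <- list()
    for (ms in config$module_specs) {
      members <- sort(pool[seq_len(ms$size)])
      pool <- pool[-seq_len(ms$size)]
      module_members[[ms$name]] <- members
      shift <- if (ms$direction == "old") ms$shift else -ms$shift
      effect_old[match(members, genes)] <- effect_old[match(members, genes)] + shift
    }

    n_samp <- length(samples)
    vals <- matrix(mu, config$n_genes, n_samp) +
      outer(effect_old, as.numeric(groups == "old")) +
      matrix(stats::rnorm(config$n_genes * n_samp, 0, config$noise_sd),
             config$n_genes, n_samp)
    dimnames(vals) <- list(genes, samples)

    symbols <- NULL
    if (config$probes_per_gene > 1) {
      ppg <- config$probes_per_gene
      idx <- rep(seq_len(config$n_genes), each = ppg)
      vals <- vals[idx, , drop = FALSE] +
        matrix(stats::rnorm(length(idx) * n_samp, 0, config$noise_sd / 2),
               length(idx), n_samp)
      rownames(vals) <- sprintf("%s_at%d", genes[idx],
                                rep(seq_len(ppg), times = config$n_genes))
      symbols <- genes[idx]
    }

    truth <- list(
      de_genes = data.frame(
        gene_symbol = de_genes,
        true_log2fc_old = effect_old[match(de_genes, genes)],
        stringsAsFactors = FALSE),
      module_members = module_members,
      config = config)
    sets <- gene_set_collection(lapply(names(module_members), function(nm)
      gene_set(nm, module_members[[nm]], description = "injected module")))
    list(matrix = expression_matrix(vals, groups, symbols = symbols),
         truth = truth, sets = sets)
  })
}

#' Type-I error calibration battery on null data
#'
#' Repeatedly simulates data with *no* injected effects and reports observed
#' false-positive rates for the three inferential steps: the fold-change DE
#' call (fraction of genes with `|FC| >= 1.5`), the Wilcoxon test (fraction
#' of genes with `p < alpha`; should be ~`alpha`), and set enrichment on a
#' random gene set (fraction of replicates with `p_perm < alpha`).
#'
#' @param config a [simulation_config()] with `de_fraction = 0` and no
#'   modules.
#' @param n_reps number of seeded replicates (replicate `i` uses seed
#'   `config$seed + i`); 0 gives an empty report.
#' @param alpha nominal level (default 0.05).
#' @param gsea_set_size size of the random set scored per replicate.
#' @param n_perm permutations per enrichment test.
#' @return List with `n_reps`, `alpha`, observed `de_rate`, `wilcoxon_rate`,
#'   `gsea_rate`, and the per-replicate `gsea_p` vector.
#' @export
null_battery <- function(config, n_reps, alpha = 0.05, gsea_set_size = 20,
                         n_perm = 200) {
  stopifnot(inherits(config, "sim_config"))
  if (config$de_fraction > 0 || length(config$module_specs) > 0) {
    stop2("null battery needs a config with no injected effects")
  }
  if (n_reps == 0) {
    return(list(n_reps = 0L, alpha = alpha, de_rate = numeric(0),
                wilcoxon_rate = numeric(0), gsea_rate = numeric(0),
                gsea_p = numeric(0)))
  }
  de_hits <- wx_hits <- n_tests <- 0
  gsea_p <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + i
    sim <- simulate_expression(cfg)
    de <- run_diffexp(sim$matrix)
    de_hits <- de_hits + sum(de$is_de)
    wx_hits <- wx_hits + sum(de$wilcoxon_p < alpha)
    n_tests <- n_tests + nrow(de)
    ranked <- rank_genes(de)
    rand_set <- local_seed(cfg$seed + 500000L,
                           sample(ranked$symbols, gsea_set_size))
    gsea_p[i] <- permutation_test(ranked, rand_set, n_perm = n_perm,
                                  seed = cfg$seed + 1000000L)$p_perm
  }
  list(n_reps = as.integer(n_reps), alpha = alpha,
       de_rate = de_hits / n_tests, wilcoxon_rate = wx_hits / n_tests,
       gsea_rate = mean(gsea_p < alpha), gsea_p = gsea_p)
}
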
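test_that("genes rank by descending fold change with lexicographic ties", {
  de <- data.frame(gene_symbol = c("A", "B", "C"),
                   signed_fc = c(2, -3, 1.2))
  rl <- rank_genes(de)
  expect_equal(rl$symbols, c("A", "C", "B"))
  expect_equal(rl$scores, c(2, 1.2, -3))
  # all-equal scores: lexicographic order
  tie <- data.frame(gene_symbol = c("Z", "M", "A"), signed_fc = c(1, 1, 1))
  expect_equal(rank_genes(tie)$symbols, c("A", "M", "Z"))
  dup <- data.frame(gene_symbol = c("A", "A"), signed_fc = c(1, 2))
  expect_error(rank_genes(dup), "duplicate")
})

test_that("the most up-in-old published gene ranks last", {
  rl <- rank_genes(load_table2_fixture())
  expect_equal(rl$symbols[rl$N], "SPP1")
})

test_that("enrichment score handles the boundary and worked cases", {
  rl <- simple_ranking(10)
  expect_equal(enrichment_score(rl, "r01")$es, 1)    # singleton at top
  expect_equal(enrichment_score(rl, "r10")$es, -1)   # singleton at bottom
  # hits at ranks {1,3,5}: +1/3 per hit, -1/7 per miss, peak after rank 5
  expect_equal(enrichment_score(rl, c("r01", "r03", "r05"))$es, 5 / 7)
  # no overlap: skipped with a warning, not an error
  expect_warning(res <- enrichment_score(rl, "absent"), "no overlap")
  expect_true(is.na(res$es))
  # full-universe set is undefined
  expect_error(enrichment_score(rl, sprintf("r%02d", 1:10)), "whole universe")
})

test_that("enrichment score is bounded, reversal-antisymmetric, and its trace closes", {
  withr::with_seed(31, {
    for (i in 1:30) {
      N <- sample(5:40, 1)
      scores <- sort(rnorm(N), decreasing = TRUE)
      de <- data.frame(gene_symbol = sprintf("g%02d", 1:N), signed_fc = scores)
      rl <- rank_genes(de)
      set <- sample(rl$symbols, sample(1:(N - 1), 1))
      for (mode in c("unweighted", "weighted")) {
        sc <- enrichment_score(rl, set, mode)
        expect_gte(sc$es, -1); expect_lte(sc$es, 1)
      }
      # unweighted trace is conservative: ends at exactly 0
      sc <- enrichment_score(rl, set)
      expect_equal(sc$running_sum[N], 0, tolerance = 1e-12)
      # reversing the ranking negates the unweighted ES (when the extreme
      # excursion is unique in magnitude; an exact +m/-m tie falls to the
      # first-occurrence tie-break and only |ES| is preserved)
      rev_rl <- structure(list(symbols = rev(rl$symbols),
                               scores = rev(rl$scores), N = N),
                          class = "ranked_list")
      rev_es <- enrichment_score(rev_rl, set)$es
      expect_equal(abs(rev_es), abs(sc$es), tolerance = 1e-12)
      peak <- max(abs(sc$running_sum))
      tied <- min(sc$running_sum) < -peak + 1e-9 &&
        max(sc$running_sum) > peak - 1e-9
      if (!tied) expect_equal(rev_es, -sc$es, tolerance = 1e-12)
    }
  })
})

test_that("enrichment score matches the brute-force oracle on random instances", {
  withr::with_seed(32, {
    for (i in 1:40) {
      N <- sample(4:30, 1)
      rl <- simple_ranking(N)
      k <- sample(1:(N - 1), 1)
      pos <- sort(sample(N, k))
      set <- rl$symbols[pos]
      hit <- seq_len(N) %in% pos
      expect_equal(enrichment_score(rl, set)$es, oracle_es(hit),
                   tolerance = 1e-12)
      expect_equal(enrichment_score(rl, set, "weighted")$es,
                   oracle_es(hit, abs(rl$scores)), tolerance = 1e-12)
      # fast positions-only path used in permutations agrees with the trace
      expect_equal(stromage:::es_from_positions(pos, N), oracle_es(hit),
                   tolerance = 1e-12)
      expect_equal(stromage:::es_from_positions(pos, N, abs(rl$scores)[pos]),
                   oracle_es(hit, abs(rl$scores)), tolerance = 1e-12)
    }
  })
})

test_that("weighted ES agrees with fgsea's statistic", {
  withr::with_seed(33, {
    for (i in 1:10) {
      N <- 50
      scores <- sort(rnorm(N, sd = 2), decreasing = TRUE)
      de <- data.frame(gene_symbol = sprintf("g%02d", 1:N), signed_fc = scores)
      rl <- rank_genes(de)
      pos <- sort(sample(N, 8))
      es <- enrichment_score(rl, rl$symbols[pos], "weighted")$es
      ref <- fgsea::calcGseaStat(setNames(rl$scores, rl$symbols),
                                 selectedStats = pos, gseaParam = 1)
      expect_equal(es, ref, tolerance = 1e-8)
    }
  })
})

test_that("exhaustive gene-label permutation matches enumeration on a singleton", {
  rl <- simple_ranking(6)
  res <- permutation_test(rl, "r01", exact = TRUE)
  # |ES| is maximal (=1) for the singleton at rank 1 and at rank 6: p = 2/6
  expect_equal(res$p_perm, oracle_exhaustive_perm_p(rl$scores, 1))
  expect_equal(res$p_perm, 2 / 6)
  expect_equal(res$n_perm_used, 6)
})

test_that("sampled permutation p agrees with the 15-outcome exhaustive oracle", {
  rl <- simple_ranking(6)
  set <- c("r01", "r02")
  p_ex <- oracle_exhaustive_perm_p(rl$scores, c(1, 2))
  expect_equal(permutation_test(rl, set, exact = TRUE)$p_perm, p_ex)
  n_perm <- 1000
  p_samp <- permutation_test(rl, set, n_perm = n_perm, seed = 9)$p_perm
  se <- sqrt(p_ex * (1 - p_ex) / n_perm)
  expect_lt(abs(p_samp - p_ex), 3 * se + 2 / (n_perm + 1))
})

test_that("permutation p-values are valid and reproducible", {
  rl <- simple_ranking(100)
  set <- sprintf("r%02d", c(2, 5, 8, 11, 90))
  r1 <- permutation_test(rl, set, n_perm = 200, seed = 4)
  r2 <- permutation_test(rl, set, n_perm = 200, seed = 4)
  expect_identical(r1, r2)
  expect_gt(r1$p_perm, 0)
  expect_lte(r1$p_perm, 1)
  expect_error(permutation_test(rl, set, n_perm = 50, seed = 1), ">= 100")
})

test_that("phenotype permutations re-derive the ranking from shuffled labels", {
  sim <- simulate_expression(simulation_config(
    n_genes = 60, n_young = 4, n_old = 4, de_fraction = 0, seed = 12))
  de <- run_diffexp(sim$matrix)
  rl <- rank_genes(de)
  set <- de$gene_symbol[1:6]
  res <- permutation_test(rl, set, n_perm = 100, seed = 2,
                          scheme = "phenotype", m = sim$matrix)
  expect_gt(res$p_perm, 0)
  expect_lte(res$p_perm, 1)
  expect_error(permutation_test(rl, set, n_perm = 100, seed = 2,
                                scheme = "phenotype"), "expression matrix")
})

test_that("BH adjustment reproduces step-up hand computations", {
  one <- data.frame(set_name = "s", p_perm = 0.04)
  expect_equal(fdr_adjust(one)$q_fdr, 0.04)
  four <- data.frame(set_name = letters[1:4], p_perm = c(0.01, 0.02, 0.03, 0.04))
  expect_equal(fdr_adjust(four)$q_fdr, rep(0.04, 4))
  all1 <- data.frame(set_name = letters[1:3], p_perm = c(1, 1, 1))
  expect_equal(fdr_adjust(all1)$q_fdr, rep(1, 3))
  # step-up: q monotone non-decreasing in p
  withr::with_seed(34, {
    p <- runif(20)
    q <- fdr_adjust(data.frame(set_name = paste0("s", 1:20), p_perm = p))$q_fdr
    expect_false(is.unsorted(q[order(p)]))
  })
})

test_that("run_gsea detects a coordinated sub-threshold module with negative ES", {
  spec <- list(list(name = "module", size = 20, shift = 0.6, direction = "old"))
  sim <- simulate_expression(simulation_config(
    n_genes = 400, module_specs = spec, de_fraction = 0, seed = 8))
  de <- run_diffexp(sim$matrix)
  res <- run_gsea(de, sim$sets, n_perm = 500, seed = 3)
  expect_equal(res$set_name, "module")
  expect_lt(res$es, 0)          # up in old -> negative by convention
  expect_lt(res$p_perm, 0.05)
  expect_gte(res$q_fdr, res$p_perm)
  # determinism given the seed
  res2 <- run_gsea(de, sim$sets, n_perm = 500, seed = 3)
  expect_equal(as.data.frame(res), as.data.frame(res2))
})

test_that("run_gsea stays calibrated on null data", {
  hits <- 0; reps <- 10
  for (i in seq_len(reps)) {
    sim <- simulate_expression(simulation_config(
      n_genes = 200, de_fraction = 0, seed = 100 + i))
    de <- run_diffexp(sim$matrix)
    set <- withr::with_seed(200 + i, sample(de$gene_symbol, 15))
    res <- run_gsea(de, list(nullset = set), n_perm = 200, seed = 300 + i)
    hits <- hits + (res$p_perm < 0.05)
  }
  expect_lte(hits, 1)  # >= 90% of null replicates non-significant
})

test_that("sets below min_hits are skipped and reported", {
  rl_de <- data.frame(gene_symbol = sprintf("g%02d", 1:30),
                      signed_fc = seq(3, -3, length.out = 30))
  sets <- list(big = sprintf("g%02d", c(1, 4, 7, 9)),
               tiny = c("g01", "absent1", "absent2"))
  expect_message(res <- run_gsea(rl_de, sets, n_perm = 100, seed = 1),
                 "skipped 1 set")
  expect_equal(res$set_name, "big")
  expect_equal(attr(res, "skipped"), "tiny")
  expect_error(suppressMessages(
    run_gsea(rl_de, list(gone = c("x1", "x2", "x3")), n_perm = 100, seed = 1)),
    "no gene set overlaps")
})
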
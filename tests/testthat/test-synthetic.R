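test_that("simulation is bit-identical under a fixed seed and leaves RNG alone", {
  cfg <- simulation_config(n_genes = 100, de_fraction = 0.05, seed = 77)
  a <- simulate_expression(cfg)
  withr::with_seed(1, runif(3))  # unrelated RNG use in between
  b <- simulate_expression(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)
  # global RNG state untouched by the generator
  before <- withr::with_seed(99, runif(1))
  set.seed(99); invisible(simulate_expression(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("config validation enforces the design constraints", {
  expect_error(simulation_config(n_genes = 10, seed = 1,
                                 module_specs = list(list(name = "m", size = 20,
                                                          shift = 1, direction = "old"))),
               "exceed")
  expect_error(simulation_config(seed = 1, n_young = 1), "n_young")
  expect_error(simulation_config(seed = 1, de_fraction = 0.1, de_log2fc = 0),
               "non-zero")
  expect_error(simulation_config(n_genes = 10), "seed is required")
})

test_that("injected DE genes come out near their target fold change", {
  # de_log2fc = 1 (linear FC 2) at tiny noise: recovered signed FC in [-2.1,-1.9]
  sim <- simulate_expression(simulation_config(
    n_genes = 300, noise_sd = 0.01, de_fraction = 0.05, de_log2fc = 1, seed = 15))
  de <- run_diffexp(sim$matrix)
  tr <- sim$truth$de_genes
  fc <- de$signed_fc[match(tr$gene_symbol, de$gene_symbol)]
  up_old <- tr$true_log2fc_old > 0
  expect_true(all(fc[up_old] > -2.1 & fc[up_old] < -1.9))
  expect_true(all(fc[!up_old] > 1.9 & fc[!up_old] < 2.1))
  # empirical mean |log2 FC| converges to the injected effect
  expect_equal(mean(abs(log2(abs(fc)))), 1, tolerance = 0.1)
})

test_that("strong effects are recovered at realistic noise (detection rate)", {
  # |log2 FC| = log2(3), noise sd 0.3, 9v8 design: >= 95% pass |FC| >= 1.5
  sim <- simulate_expression(simulation_config(
    n_genes = 1000, de_fraction = 0.04, de_log2fc = log2(3), seed = 16))
  de <- run_diffexp(sim$matrix)
  called <- de$gene_symbol[de$is_de]
  rate <- mean(sim$truth$de_genes$gene_symbol %in% called)
  expect_gte(rate, 0.95)
})

test_that("probe-level output collapses back to the gene profiles", {
  cfg <- simulation_config(n_genes = 40, probes_per_gene = 3, noise_sd = 0.2,
                           de_fraction = 0, seed = 17)
  sim <- simulate_expression(cfg)
  expect_equal(nrow(sim$matrix$values), 120)
  expect_equal(length(sim$matrix$symbols), 120)
  cm <- collapse_probes(sim$matrix)
  expect_equal(nrow(cm$values), 40)
  expect_setequal(rownames(cm$values), unique(sim$matrix$symbols))
})

test_that("module injection drives enrichment in the stated direction", {
  spec <- list(list(name = "up_in_old_mod", size = 20, shift = 0.6,
                    direction = "old"),
               list(name = "up_in_young_mod", size = 15, shift = 0.6,
                    direction = "young"))
  sim <- simulate_expression(simulation_config(
    n_genes = 500, module_specs = spec, de_fraction = 0, seed = 18))
  res <- run_gsea(run_diffexp(sim$matrix), sim$sets, n_perm = 500, seed = 2)
  expect_lt(res$es[res$set_name == "up_in_old_mod"], 0)
  expect_gt(res$es[res$set_name == "up_in_young_mod"], 0)
})

test_that("null battery reports calibrated error rates", {
  cfg <- simulation_config(n_genes = 150, de_fraction = 0, seed = 500)
  rep <- null_battery(cfg, n_reps = 25, alpha = 0.05, n_perm = 100)
  # Wilcoxon: compare against the exact attainable null rate for a 9v8 design
  # (the discrete exact p-value distribution cannot hit 0.05 exactly)
  u <- 0:(9 * 8)
  p_of_u <- vapply(u, function(x)
    min(1, 2 * min(pwilcox(x, 9, 8), 1 - pwilcox(x - 1, 9, 8))), numeric(1))
  exact_rate <- sum(dwilcox(u, 9, 8)[p_of_u < 0.05])
  n_tests <- 25 * 150
  ci <- qnorm(0.995) * sqrt(exact_rate * (1 - exact_rate) / n_tests)
  expect_lt(abs(rep$wilcoxon_rate - exact_rate), ci)
  # fold-change false-call rate under the null is small
  expect_lt(rep$de_rate, 0.05)
  # enrichment false-positive rate on random sets stays near nominal
  expect_lte(rep$gsea_rate, 0.25)
  expect_error(null_battery(simulation_config(n_genes = 10, de_fraction = 0.5,
                                              seed = 1), 2),
               "no injected effects")
})

test_that("a zero-replicate battery yields an empty report without failure", {
  cfg <- simulation_config(n_genes = 50, de_fraction = 0, seed = 1)
  rep <- null_battery(cfg, n_reps = 0)
  expect_equal(rep$n_reps, 0L)
  expect_length(rep$gsea_p, 0)
})
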
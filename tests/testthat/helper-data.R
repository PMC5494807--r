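# Small in-code fixtures shared across tests.

# A tiny symbol-level matrix with the given per-group gene means and no noise.
tiny_matrix <- function(young_means, old_means, n_young = 2, n_old = 2,
                        genes = sprintf("G%02d", seq_along(young_means))) {
  vals <- cbind(matrix(rep(young_means, n_young), ncol = n_young),
                matrix(rep(old_means, n_old), ncol = n_old))
  dimnames(vals) <- list(genes,
                         c(paste0("y", seq_len(n_young)),
                           paste0("o", seq_len(n_old))))
  expression_matrix(vals, rep(c("young", "old"), c(n_young, n_old)))
}

# A ranked list with symbols r1 (top) .. rN (bottom) and scores N..1.
simple_ranking <- function(N) {
  rank_genes(data.frame(gene_symbol = sprintf("r%02d", seq_len(N)),
                        signed_fc = seq(N, 1)))
}

write_tsv_matrix <- function(vals, path) {
  write.table(data.frame(id = rownames(vals), vals, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
}
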
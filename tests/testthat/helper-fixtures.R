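## Shared fixtures: small hypothesis tables and one scaled-down count
## simulation + engine run used by several test files.

make_hypothesis_table <- function(genes, n_per_gene, p) {
  data.frame(gene = rep(genes, times = n_per_gene),
             hypothesis = unlist(lapply(n_per_gene, function(k)
               paste0("h", seq_len(k)))),
             p = p, stringsAsFactors = FALSE)
}

## one replicate of the scaled-down factorial count simulation analysed by
## the built-in engine; returns the p-value tables plus truth
engine_replicate <- function(seed, n_genes = 2000, n_per_group = 5) {
  k <- n_genes / 2000
  cfg <- dge_config(n_genes = n_genes, n_per_group = n_per_group,
                    n_constant = round(300 * k), n_t1 = round(150 * k),
                    n_t2 = round(150 * k), n_interaction = round(150 * k),
                    seed = seed)
  sim <- simulate_dge_counts(cfg)
  counts <- filter_low_counts(sim$counts)
  X <- stats::model.matrix(~ treatment * time, data = sim$design)
  contrasts <- list(t1 = c(0, 1, 0, 0), t2 = c(0, 1, 0, 1),
                    interaction = c(0, 0, 0, 1))
  ft <- feature_tests(counts, X, contrasts)
  c(ft, list(truth = sim$truth, truth_long = sim$truth_long))
}
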
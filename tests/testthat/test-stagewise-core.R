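## Two-stage testing engine: BH screening, alpha_II, MSRB confirmation.

## independent step-up oracle for BH, written directly from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  out <- numeric(m)
  out[ord] <- pmin(1, adj)
  out
}

test_that("bh_adjust matches the step-up definition and handles edge cases", {
  expect_equal(bh_adjust(0.5), 0.5)                     # m = 1 identity
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  u <- rep(0.37, 6)
  expect_equal(bh_adjust(u), u)                         # ties at every rank
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(numeric(0)), "length")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("screening populates G, R and alpha_II correctly", {
  one <- screen_genes(data.frame(gene = "g1", p = 0.04), alpha_i = 0.05)
  expect_equal(one$R, 1L)
  expect_equal(one$alpha_ii, 0.05)

  none <- screen_genes(data.frame(gene = paste0("g", 1:10), p = rep(1, 10)),
                       alpha_i = 0.05)
  expect_equal(none$R, 0L)
  expect_equal(none$alpha_ii, 0)
  expect_false(any(none$genes$rejected))

  expect_error(screen_genes(data.frame(gene = c("a", "a"), p = c(0.1, 0.2))),
               "duplicate")
})

test_that("screening any-rejection rate under the global null is level-bounded", {
  ## under the global null BH controls the FWER of 'any rejection' at alpha
  set.seed(7)
  n_rep <- 10000
  any_rej <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    any_rej[i] <- min(p.adjust(runif(100), "BH")) <= 0.05
  }
  rate <- mean(any_rej)
  se <- sqrt(rate * (1 - rate) / n_rep)
  expect_lte(rate, 0.05 + 3 * max(se, 1e-4))
})

test_that("confirmation_alpha is R*alpha/G with validation", {
  expect_equal(confirmation_alpha(10, 10, 0.07), 0.07)
  expect_equal(confirmation_alpha(0, 1000, 0.05), 0)
  expect_equal(confirmation_alpha(40, 100, 0.05), 0.02)
  expect_error(confirmation_alpha(11, 10, 0.05), "exceed")
})

test_that("t-sequences encode the logical constraints of each context", {
  expect_equal(shaffer_t_sequence(5, "dtu"), c(3L, 3L, 3L, 2L, 1L))
  expect_equal(shaffer_t_sequence(4, "dte"), c(3L, 3L, 2L, 1L))
  expect_equal(shaffer_t_sequence(3, "holm"), c(3L, 2L, 1L))
  expect_equal(shaffer_t_sequence(2, "dtu"), c(0L, 0L))
  expect_equal(shaffer_t_sequence(1, "dte"), 0L)
  expect_equal(shaffer_t_sequence(3, "dge_2x2"), rep(1L, 3))
  expect_equal(shaffer_t_sequence(4, "dge_2x2_avg"), rep(1L, 4))
  expect_equal(shaffer_t_sequence(6, "screened_free"), c(5L, 5L, 4L, 3L, 2L, 1L))
  expect_error(shaffer_t_sequence(4, "dge_2x2"), "3 hypotheses")
  expect_error(shaffer_t_sequence(3, "dge_2x2_avg"), "4 hypotheses")
  ## validity: t(j) <= n - j + 1 in every context
  for (ctx in c("holm", "screened_free", "dte", "dtu")) {
    for (n in 2:10) {
      t_seq <- shaffer_t_sequence(n, ctx)
      expect_true(all(t_seq <= n - seq_len(n) + 1), info = ctx)
    }
  }
})

test_that("msrb_adjust with the Holm t-sequence equals textbook Holm", {
  set.seed(11)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    p <- runif(n)
    expect_identical(msrb_adjust(p, shaffer_t_sequence(n, "holm")),
                     p.adjust(p, "holm"))
  }
})

test_that("msrb_adjust honours unit and zero divisors", {
  expect_equal(msrb_adjust(c(0.01, 0.02, 0.3), c(1, 1, 1)),
               c(0.01, 0.02, 0.3))           # no within-gene correction
  expect_equal(msrb_adjust(c(0.9, 0.8), c(0L, 0L)), c(0, 0))  # auto-confirm
  expect_error(msrb_adjust(c(0.1, 0.2), c(1)), "length")
})

test_that("MSRB rejections are a superset of Holm rejections for valid t", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(2:10, 1)
    p <- runif(n)
    t_holm <- shaffer_t_sequence(n, "holm")
    ## random valid t-sequence: t(j) <= n - j + 1
    t_rand <- vapply(seq_len(n), function(j) sample(0:(n - j + 1), 1),
                     integer(1))
    alpha <- runif(1, 0.01, 0.2)
    expect_true(all((msrb_adjust(p, t_holm) <= alpha) <=
                      (msrb_adjust(p, t_rand) <= alpha)))
  }
})

test_that("confirmation respects screening and reproduces a manual trace", {
  tab <- make_hypothesis_table(c("g1", "g2", "g3"), c(3, 3, 3),
                               c(0.001, 0.2, 0.01,
                                 0.004, 0.5, 0.6,
                                 0.9, 0.8, 0.7))
  scr <- screen_genes(data.frame(gene = c("g1", "g2", "g3"),
                                 p = c(0.001, 0.01, 0.9)), alpha_i = 0.05)
  ## manual: BH adj = (0.003, 0.015, 0.9) -> R = 2, alpha_II = 2*0.05/3
  expect_equal(scr$R, 2L)
  expect_equal(scr$alpha_ii, 0.1 / 3)

  res <- confirm_genes(tab, scr, context = "dge_2x2")
  ## g1: p = (0.001, 0.2, 0.01), t = 1 -> reject p <= 0.0333: h1, h3
  ## g2: only 0.004 rejected; g3 failed screening -> nothing
  expect_equal(res$rejected,
               c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_true(all(res$padj_stagewise[!res$passed_screening] == 1))
  ## hypotheses of screened-out genes never rejected regardless of p
  expect_false(any(res$rejected & !res$passed_screening))
})

test_that("with R = G the confirmation equals a per-gene FWER test at alpha_I", {
  set.seed(17)
  tab <- make_hypothesis_table(paste0("g", 1:20), rep(4, 20), runif(80))
  scr <- screen_genes(data.frame(gene = paste0("g", 1:20),
                                 p = rep(0.0001, 20)), alpha_i = 0.05)
  expect_equal(scr$R, 20L)
  res <- confirm_genes(tab, scr, context = "holm")
  for (g in paste0("g", 1:20)) {
    rows <- res[res$gene == g, ]
    expect_equal(rows$rejected, p.adjust(rows$p, "holm") <= 0.05)
  }
})

test_that("stage-wise adjusted p-values reproduce two-stage decisions", {
  set.seed(19)
  for (alpha in c(0.01, 0.05, 0.2)) {
    tab <- make_hypothesis_table(paste0("g", 1:50),
                                 sample(1:6, 50, replace = TRUE),
                                 rbeta(1, 1, 1))
    tab$p <- rbeta(nrow(tab), 0.5, 1)
    scr_p <- data.frame(gene = paste0("g", 1:50), p = rbeta(50, 0.5, 1))
    res <- stage_wise_test(tab, scr_p, alpha_i = alpha, context = "screened_free")
    expect_identical(res$rejected, res$padj_stagewise <= alpha)
    expect_true(all(res$padj_stagewise >= 0 & res$padj_stagewise <= 1))
  }
})

test_that("missing p-values are dropped from the family with a warning", {
  tab <- make_hypothesis_table("g1", 3, c(0.01, NA, 0.02))
  scr <- screen_genes(data.frame(gene = "g1", p = 0.001), 0.05)
  expect_warning(res <- confirm_genes(tab, scr, "holm"), "missing")
  expect_equal(nrow(res), 2L)   # n_g reduced to 2; Holm divisors (2, 1)
  expect_equal(res$padj_within, pmin(1, p.adjust(c(0.01, 0.02), "holm")))
})

test_that("unknown genes in the confirmation table are rejected", {
  tab <- make_hypothesis_table(c("g1", "gX"), c(1, 1), c(0.1, 0.2))
  scr <- screen_genes(data.frame(gene = "g1", p = 0.01), 0.05)
  expect_error(confirm_genes(tab, scr), "absent")
})

test_that("gene_level_fdp handles degenerate and mixed cases", {
  truth <- data.frame(gene = rep(c("g1", "g2", "g3"), each = 2),
                      hypothesis = rep(c("h1", "h2"), 3),
                      is_null = c(TRUE, TRUE,  FALSE, TRUE,  FALSE, FALSE))
  tab <- make_hypothesis_table(c("g1", "g2", "g3"), c(2, 2, 2),
                               c(0.001, 0.9, 0.001, 0.001, 0.3, 0.4))
  names(tab$p) <- NULL
  ## no gene passes screening -> FDP 0
  scr0 <- screen_genes(data.frame(gene = c("g1", "g2", "g3"), p = rep(1, 3)),
                       0.05)
  res0 <- suppressMessages(confirm_genes(tab, scr0, "holm"))
  expect_equal(gene_level_fdp(res0, truth), 0)

  ## all three pass: g1 fully null (FP), g2 falsely rejects h2 (FP),
  ## g3 no false rejection (not FP)
  scr <- screen_genes(data.frame(gene = c("g1", "g2", "g3"),
                                 p = c(1e-5, 1e-5, 1e-5)), 0.05)
  res <- confirm_genes(tab, scr, "holm")
  expect_true(res$rejected[res$gene == "g2" & res$hypothesis == "h2"])
  expect_equal(gene_level_fdp(res, truth), 2 / 3)
  expect_error(gene_level_fdp(res, truth[truth$gene != "g2", ]), "missing")
})

test_that("gene_level_fdp agrees with brute-force enumeration", {
  set.seed(23)
  for (i in 1:20) {
    n_genes <- sample(3:12, 1)
    genes <- paste0("g", seq_len(n_genes))
    n_per <- sample(1:4, n_genes, replace = TRUE)
    tab <- make_hypothesis_table(genes, n_per, rbeta(sum(n_per), 0.4, 1))
    truth <- data.frame(gene = tab$gene, hypothesis = tab$hypothesis,
                        is_null = runif(nrow(tab)) < 0.5)
    scr_p <- data.frame(gene = genes, p = rbeta(n_genes, 0.4, 1))
    res <- suppressMessages(
      stage_wise_test(tab, scr_p, alpha_i = 0.2, context = "holm"))
    ## brute force: loop genes, recompute discovery and false-rejection flags
    disc <- fp <- 0
    for (g in genes) {
      rows <- res[res$gene == g, ]
      if (!any(rows$passed_screening)) next
      disc <- disc + 1
      nulls <- truth$is_null[truth$gene == g][match(rows$hypothesis,
                 truth$hypothesis[truth$gene == g])]
      if (all(nulls) || any(rows$rejected & nulls)) fp <- fp + 1
    }
    expected <- if (disc == 0) 0 else fp / disc
    expect_equal(gene_level_fdp(res, truth), expected)
  }
})

test_that("OFDR is controlled under valid null p-values", {
  ## screening p ~ U(0,1) for null genes, confirmation nulls ~ U(0,1),
  ## alternatives stochastically smaller; mean FDP over replicates must not
  ## exceed alpha_I by more than 3 Monte-Carlo SEs
  set.seed(29)
  n_genes <- 400
  genes <- paste0("g", seq_len(n_genes))
  for (alpha in c(0.01, 0.05, 0.10)) {
    fdp <- vapply(1:30, function(r) {
      null_gene <- seq_len(n_genes) <= n_genes / 2
      n_per <- rep(3L, n_genes)
      truth_null <- rep(null_gene, times = n_per)
      ## partly-true genes: one hypothesis of each non-null gene stays null
      truth_null[!rep(null_gene, times = n_per) &
                   unlist(lapply(n_per, seq_len)) == 1L] <- TRUE
      p <- ifelse(truth_null, runif(sum(n_per)), rbeta(sum(n_per), 0.1, 1))
      tab <- make_hypothesis_table(genes, n_per, p)
      truth <- data.frame(gene = tab$gene, hypothesis = tab$hypothesis,
                          is_null = truth_null)
      scr <- data.frame(gene = genes,
                        p = ifelse(null_gene, runif(n_genes),
                                   rbeta(n_genes, 0.1, 1)))
      res <- suppressMessages(
        stage_wise_test(tab, scr, alpha_i = alpha, context = "screened_free"))
      gene_level_fdp(res, truth)
    }, numeric(1))
    mc <- ofdr_over_replicates(fdp)
    expect_lte(mc$mean, alpha + 3 * max(mc$se, 1e-8))
  }
})
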
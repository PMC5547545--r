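## Transcript-level count simulator for DTU and DTE evaluation: Dirichlet
## isoform usage around baseline proportions, DTU via proportion flipping
## (a random non-identity permutation of the selected transcripts' baseline
## proportions in condition 2, conserving the gene total), and DTE via
## truncated-exponential fold changes applied to all transcripts of a gene.

#' Simulate a transcriptome structure
#'
#' Draws per-gene transcript counts from a shifted negative-binomial-like
#' discrete law, log-normal expected gene counts, baseline usage
#' proportions from a symmetric Dirichlet, and records the mean-dispersion
#' function used for the NB count draws. These parametric defaults stand in
#' for empirically estimated abundances; an empirical table can be supplied
#' through the `abundance` argument.
#'
#' @param n_genes number of genes.
#' @param tx_model list(size, mu): transcripts per gene are
#'   1 + NegBinom(size, mu); defaults give a mean around 2.8 isoforms.
#' @param abundance list(meanlog, sdlog) for the log-normal expected gene
#'   count, or a data.frame with columns `gene_count` (and optionally
#'   `n_tx`) to resample.
#' @param prop_shape symmetric Dirichlet shape for baseline usage
#'   proportions; values < 1 favour dominant isoforms. Default 0.7.
#' @param concentration Dirichlet concentration for per-sample usage around
#'   the baseline proportions (larger = less biological usage variability);
#'   must be > 0. Default 100.
#' @param dispersion list(a0, a1): transcript-level NB dispersion
#'   phi(mu) = a0 + a1 / mu.
#' @param seed integer seed.
#' @return an object of class `tx_structure`: list with `transcripts`
#'   (data.frame gene, transcript, baseline_prop), `genes` (data.frame
#'   gene, n_tx, gene_count), `concentration`, `dispersion`.
#' @export
simulate_structure <- function(n_genes, tx_model = list(size = 2, mu = 1.8),
                               abundance = list(meanlog = log(50), sdlog = 1.5),
                               prop_shape = 0.7, concentration = 100,
                               dispersion = list(a0 = 0.05, a1 = 5),
                               seed = 1L) {
  stopifnot(n_genes >= 1, prop_shape > 0)
  if (concentration <= 0) stop("concentration must be > 0")
  set.seed(seed)
  if (is.data.frame(abundance)) {
    idx <- sample.int(nrow(abundance), n_genes, replace = TRUE)
    gene_count <- abundance$gene_count[idx]
    n_tx <- if ("n_tx" %in% names(abundance)) as.integer(abundance$n_tx[idx])
            else 1L + stats::rnbinom(n_genes, size = tx_model$size,
                                     mu = tx_model$mu)
  } else {
    gene_count <- stats::rlnorm(n_genes, abundance$meanlog, abundance$sdlog)
    n_tx <- 1L + stats::rnbinom(n_genes, size = tx_model$size,
                                mu = tx_model$mu)
  }
  gene <- sprintf("gene%05d", seq_len(n_genes))
  tx_gene <- rep(gene, times = n_tx)
  transcript <- sprintf("%s.tx%d", tx_gene,
                        unlist(lapply(n_tx, seq_len), use.names = FALSE))
  baseline <- unlist(lapply(n_tx, function(k) {
    as.numeric(rdirichlet(1L, rep(prop_shape, k)))
  }), use.names = FALSE)
  structure(list(
    transcripts = data.frame(gene = tx_gene, transcript = transcript,
                             baseline_prop = baseline,
                             stringsAsFactors = FALSE),
    genes = data.frame(gene = gene, n_tx = as.integer(n_tx),
                       gene_count = gene_count, stringsAsFactors = FALSE),
    concentration = concentration, dispersion = dispersion
  ), class = "tx_structure")
}

## Threshold below which a baseline proportion is treated as an unexpressed
## isoform for DTU eligibility.
.expressed_prop <- 0.01

#' Assign differential transcript usage truth
#'
#' Selects `n_dtu` genes at random from those eligible (expected gene count
#' above `min_gene_count` and at least two expressed isoforms, i.e.
#' baseline proportion > 0.01). For each selected gene,
#' k = max(2, Binomial(n_tx, 1/3)) transcripts (capped at the number of
#' expressed isoforms) are differentially used: their condition-2 baseline
#' proportions are a random non-identity permutation of the condition-1
#' proportions (a swap when k = 2), so the gene's expected total is
#' conserved across conditions.
#'
#' @param structure a `tx_structure` from [simulate_structure()].
#' @param n_dtu number of DTU genes.
#' @param min_gene_count eligibility threshold on expected gene count;
#'   default 5.
#' @param seed integer seed.
#' @return an object of class `tx_truth`: list with `genes` (data.frame
#'   gene, is_dtu, is_dte) and `transcripts` (data.frame gene, transcript,
#'   differentially_used, fold_change, prop_cond1, prop_cond2).
#' @export
assign_dtu_truth <- function(structure, n_dtu = 1000, min_gene_count = 5,
                             seed = 1L) {
  stopifnot(inherits(structure, "tx_structure"))
  set.seed(seed)
  tx <- structure$transcripts
  genes <- structure$genes
  expressed <- tx$baseline_prop > .expressed_prop
  n_expressed <- tapply(expressed, tx$gene, sum)[genes$gene]
  eligible <- genes$gene_count > min_gene_count & n_expressed >= 2L
  if (sum(eligible) < n_dtu) {
    stop("only ", sum(eligible), " genes satisfy the DTU eligibility filter",
         " (expected gene count > ", min_gene_count,
         " and >= 2 expressed isoforms); ", n_dtu, " requested")
  }
  dtu_genes <- sample(genes$gene[eligible], n_dtu)

  prop1 <- tx$baseline_prop
  prop2 <- tx$baseline_prop
  used <- logical(nrow(tx))
  tx_idx <- split(seq_len(nrow(tx)), tx$gene)
  for (g in dtu_genes) {
    idx <- tx_idx[[g]]
    expr_idx <- idx[expressed[idx]]
    k <- max(2L, stats::rbinom(1L, size = length(idx), prob = 1 / 3))
    k <- min(k, length(expr_idx))
    sel <- if (length(expr_idx) == k) expr_idx else sample(expr_idx, k)
    perm <- .random_derangementish(k)
    prop2[sel] <- prop1[sel][perm]
    used[sel] <- TRUE
  }
  out <- list(
    genes = data.frame(gene = genes$gene,
                       is_dtu = genes$gene %in% dtu_genes,
                       is_dte = FALSE, stringsAsFactors = FALSE),
    transcripts = data.frame(gene = tx$gene, transcript = tx$transcript,
                             differentially_used = used, fold_change = 1,
                             prop_cond1 = prop1, prop_cond2 = prop2,
                             stringsAsFactors = FALSE)
  )
  class(out) <- "tx_truth"
  out
}

## Uniformly random non-identity permutation of 1..k (k >= 2); for k = 2
## this is always the swap.
.random_derangementish <- function(k) {
  stopifnot(k >= 2L)
  if (k == 2L) return(c(2L, 1L))
  repeat {
    perm <- sample.int(k)
    if (any(perm != seq_len(k))) return(perm)
  }
}

#' Assign differential transcript expression truth
#'
#' Selects `n_dte` genes from those not already flagged DTU; every
#' transcript of a selected gene receives a fold change with magnitude
#' drawn from a truncated exponential law on \[`fc_model$lower`,
#' `fc_model$upper`\] with rate `fc_model$rate`, applied as the drawn value
#' for half of the genes and its reciprocal for the other half (directions
#' balanced across genes, ties toward up).
#'
#' @param structure a `tx_structure`.
#' @param truth a `tx_truth` from [assign_dtu_truth()] (or of the same
#'   shape with no DTU genes).
#' @param n_dte number of DTE genes.
#' @param fc_model list(rate, lower, upper) of the truncated exponential;
#'   defaults rate 1 on \[1, 3\]. Degenerate bounds (a, a) make every fold
#'   change equal to a.
#' @param seed integer seed.
#' @return the updated `tx_truth`.
#' @export
assign_dte_truth <- function(structure, truth, n_dte = 1000,
                             fc_model = list(rate = 1, lower = 1, upper = 3),
                             seed = 2L) {
  stopifnot(inherits(structure, "tx_structure"), inherits(truth, "tx_truth"))
  set.seed(seed)
  candidates <- truth$genes$gene[!truth$genes$is_dtu]
  if (length(candidates) < n_dte) {
    stop("only ", length(candidates), " genes without DTU available; ",
         n_dte, " DTE genes requested (sets must not overlap)")
  }
  dte_genes <- sample(candidates, n_dte)
  magnitude <- rtruncexp(n_dte, rate = fc_model$rate,
                         lower = fc_model$lower, upper = fc_model$upper)
  up <- rep(c(TRUE, FALSE), length.out = n_dte)
  fc_gene <- ifelse(up, magnitude, 1 / magnitude)
  names(fc_gene) <- dte_genes

  truth$genes$is_dte <- truth$genes$gene %in% dte_genes
  is_dte_tx <- truth$transcripts$gene %in% dte_genes
  truth$transcripts$fold_change[is_dte_tx] <-
    fc_gene[truth$transcripts$gene[is_dte_tx]]
  truth
}

#' Truncated exponential draws
#'
#' Inverse-CDF sampling from an exponential law with the given rate,
#' truncated to \[lower, upper\]. Degenerate bounds return the common value.
#'
#' @param n number of draws.
#' @param rate exponential rate (> 0).
#' @param lower,upper truncation bounds, lower <= upper.
#' @return numeric vector of length `n`.
#' @export
rtruncexp <- function(n, rate = 1, lower = 1, upper = 3) {
  stopifnot(n >= 0, rate > 0, lower <= upper)
  if (lower == upper) return(rep(lower, n))
  u <- stats::runif(n)
  span <- 1 - exp(-rate * (upper - lower))
  lower - log(1 - u * span) / rate
}

#' Simulate transcript-level NB counts
#'
#' For every sample, per-gene usage proportions are drawn from a Dirichlet
#' centred on the condition-appropriate baseline proportions (condition 2
#' uses the flipped proportions of DTU genes) with the structure's
#' concentration. The transcript mean is expected gene count x usage x DTE
#' fold change (condition 2 only), and counts are NB with dispersion
#' phi(mu) = a0 + a1 / mu.
#'
#' @param structure a `tx_structure`.
#' @param truth a `tx_truth`.
#' @param n_per_condition samples per condition (>= 2); default 5.
#' @param seed integer seed.
#' @return list with `counts` (transcripts x samples matrix), `tx2gene`
#'   (data.frame transcript, gene), `design` (data.frame sample,
#'   condition), and `truth` (echoed).
#' @export
simulate_transcript_counts <- function(structure, truth, n_per_condition = 5,
                                       seed = 3L) {
  stopifnot(inherits(structure, "tx_structure"), inherits(truth, "tx_truth"),
            n_per_condition >= 2)
  set.seed(seed)
  tx <- truth$transcripts
  gene_count <- structure$genes$gene_count
  names(gene_count) <- structure$genes$gene
  conc <- structure$concentration
  a0 <- structure$dispersion$a0
  a1 <- structure$dispersion$a1

  n_samp <- 2L * n_per_condition
  condition <- rep(c(1L, 2L), each = n_per_condition)
  sample_id <- sprintf("cond%d_rep%d", condition,
                       rep(seq_len(n_per_condition), times = 2L))
  counts <- matrix(0L, nrow = nrow(tx), ncol = n_samp,
                   dimnames = list(tx$transcript, sample_id))
  for (s in seq_len(n_samp)) {
    base <- if (condition[s] == 1L) tx$prop_cond1 else tx$prop_cond2
    ## Dirichlet per gene via normalised gammas, vectorised over all genes
    gam <- stats::rgamma(nrow(tx), shape = conc * base)
    totals <- rowsum(gam, tx$gene)
    usage <- gam / totals[tx$gene, 1L]
    mu <- gene_count[tx$gene] * usage
    if (condition[s] == 2L) mu <- mu * tx$fold_change
    if (any(mu < 0)) stop("negative transcript means")
    phi <- a0 + a1 / pmax(mu, 1e-8)
    draw <- integer(nrow(tx))
    pos <- mu > 0
    draw[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = 1 / phi[pos])
    counts[, s] <- draw
  }
  list(counts = counts,
       tx2gene = data.frame(transcript = tx$transcript, gene = tx$gene,
                            stringsAsFactors = FALSE),
       design = data.frame(sample = sample_id,
                           condition = factor(paste0("c", condition)),
                           stringsAsFactors = FALSE),
       truth = truth)
}

#' Per-sample usage proportions for one gene
#'
#' Exposes the Dirichlet usage draw used by the count simulator: proportions
#' for `n` samples around the baseline `base` with the given concentration.
#' As the concentration grows the draws converge to the baseline.
#'
#' @param n number of samples.
#' @param base baseline proportions (sum to 1).
#' @param concentration Dirichlet concentration (> 0).
#' @return `n x length(base)` matrix of proportions.
#' @export
sample_usage <- function(n, base, concentration = 100) {
  stopifnot(concentration > 0, all(base >= 0),
            isTRUE(all.equal(sum(base), 1)))
  rdirichlet(n, concentration * base)
}
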
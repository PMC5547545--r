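## Gene-level aggregation of transcript-level p-values: the Sidak-style
## per-gene p-value and the q-value rule
##   q*(theta) = sum_g [1 - (1 - theta)^{n_g}] / R(theta)
## evaluated at the observed per-gene minima.

#' Sidak-style gene-level p-value
#'
#' Probability that at least one of n_g independent uniform p-values falls at
#' or below `min_p`: 1 - (1 - min_p)^n_g. Used as the per-gene screening
#' p-value implied by the minimum transcript-level p-value.
#'
#' @param min_p minimum transcript-level p-value(s) in \[0, 1\].
#' @param n_g transcript count(s), >= 1; recycled against `min_p`.
#' @return gene-level p-value(s).
#' @export
sidak_gene_pvalue <- function(min_p, n_g) {
  .check_probabilities(min_p, "min_p")
  stopifnot(all(n_g >= 1), all(n_g == floor(n_g)))
  1 - (1 - min_p)^n_g
}

#' Gene-level q-values from transcript-level p-values
#'
#' For each gene the evidence is summarised by theta_g, the minimum
#' transcript-level p-value. Rejecting all genes with theta_g <= theta
#' controls the FDR at
#' q*(theta) = \[sum over all genes of 1 - (1 - theta)^{n_g}\] / R(theta),
#' with R(theta) the number of genes rejected at threshold theta. The gene
#' q-value is the minimum of q*(theta) over observed candidate thresholds
#' theta >= theta_g (a running minimum from the largest threshold downward),
#' clipped at 1. With one transcript per gene this reduces exactly to BH.
#'
#' @param table hypothesis table: data.frame with columns `gene`,
#'   `hypothesis`, `p` (transcript-level p-values).
#' @return data.frame with one row per gene: `gene`, `n_g`, `theta`
#'   (minimum transcript p), `qvalue`.
#' @export
per_gene_qvalue <- function(table) {
  .check_hypothesis_table(table)
  if (anyNA(table$p)) {
    warning("dropping ", sum(is.na(table$p)), " missing p-values")
    table <- table[!is.na(table$p), , drop = FALSE]
  }
  if (nrow(table) == 0L) stop("no p-values to aggregate")
  gene <- as.character(table$gene)
  theta_g <- tapply(table$p, gene, min)
  n_g <- tapply(table$p, gene, length)
  genes <- names(theta_g)
  G <- length(genes)

  ord <- order(theta_g)
  theta_sorted <- theta_g[ord]
  ## candidate thresholds: the sorted observed theta_g; R(theta_c) for the
  ## c-th candidate is the number of theta_g <= theta_c, i.e. the index of
  ## the last tie at that value
  r_of <- seq_len(G)
  ties <- rev(!duplicated(rev(theta_sorted)))  # last occurrence of each value
  r_at_value <- rev(cummin(rev(ifelse(ties, r_of, Inf))))
  numer <- vapply(theta_sorted,
                  function(th) sum(1 - (1 - th)^n_g), numeric(1))
  qstar <- numer / r_at_value
  ## gene q-value: min of q*(theta) over thresholds >= theta_g
  q_sorted <- pmin(1, rev(cummin(rev(qstar))))
  qvalue <- numeric(G)
  qvalue[ord] <- q_sorted

  data.frame(gene = genes, n_g = as.integer(n_g), theta = as.numeric(theta_g),
             qvalue = qvalue, row.names = NULL, stringsAsFactors = FALSE)
}
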
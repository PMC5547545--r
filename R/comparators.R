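## Reference procedures used for benchmarking the stage-wise method:
## conventional per-contrast BH, and the Jiang-Doerge two-stage method with
## an FDR level split between its stages (4/5 - 1/5 by default).

#' Conventional per-contrast BH analysis
#'
#' BH FDR control applied separately within each named contrast at level
#' `alpha`; a gene is flagged when any of its hypotheses is rejected in any
#' contrast. This is the standard analysis against which gene-level OFDR
#' inflation is measured.
#'
#' @param table data.frame with columns `gene`, `hypothesis`, `contrast`,
#'   `p`. If `contrast` is absent, `hypothesis` labels are used as contrast
#'   labels (one family per hypothesis name).
#' @param alpha per-contrast FDR level; default 0.05.
#' @return an object of class `comparator_result`: data.frame with columns
#'   `gene`, `hypothesis`, `contrast`, `p`, `padj`, `rejected`; attributes
#'   `method`, `alpha`, and `gene_rejected` (named logical, any rejection
#'   per gene).
#' @export
conventional_analysis <- function(table, alpha = 0.05) {
  if (!"contrast" %in% names(table)) table$contrast <- table$hypothesis
  .check_hypothesis_table(table)
  table$gene <- as.character(table$gene)
  table$hypothesis <- as.character(table$hypothesis)
  table$contrast <- as.character(table$contrast)
  padj <- numeric(nrow(table))
  for (idx in split(seq_len(nrow(table)), table$contrast)) {
    padj[idx] <- bh_adjust(table$p[idx])
  }
  rejected <- padj <= alpha
  out <- data.frame(gene = table$gene, hypothesis = table$hypothesis,
                    contrast = table$contrast, p = table$p,
                    padj = padj, rejected = rejected,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "conventional"
  attr(out, "alpha") <- alpha
  attr(out, "gene_rejected") <- c(tapply(rejected, out$gene, any))
  class(out) <- c("comparator_result", "data.frame")
  out
}

#' Jiang-Doerge two-stage analysis
#'
#' Stage 1 applies BH to the per-gene screening p-values at a fraction
#' (default 4/5) of the total level; stage 2 pools all confirmation
#' p-values of the passing genes into a single family and applies BH at the
#' remaining fraction (default 1/5). Because the level is split, stage-1
#' rejections are always a subset of the screening rejections of the
#' stage-wise method run at the full level on the same inputs.
#'
#' @param table hypothesis table: data.frame with columns `gene`,
#'   `hypothesis`, `p` (confirmation p-values).
#' @param screening data.frame with columns `gene`, `p` (one screening
#'   p-value per gene).
#' @param alpha total FDR level; default 0.05.
#' @param split two positive fractions summing to 1: the shares of `alpha`
#'   spent on screening and confirmation; default `c(4, 1)/5`.
#' @return a `comparator_result` as in [conventional_analysis()], with
#'   attributes `alpha_screen`, `alpha_confirm` and `screen_rejected`
#'   (named logical per gene).
#' @export
jiang_doerge <- function(table, screening, alpha = 0.05, split = c(4, 1) / 5) {
  .check_hypothesis_table(table)
  stopifnot(length(split) == 2L, all(split > 0),
            isTRUE(all.equal(sum(split), 1)))
  scr <- screen_genes(screening, alpha_i = split[1L] * alpha)
  passed <- structure(scr$genes$rejected, names = scr$genes$gene)
  table$gene <- as.character(table$gene)
  table$hypothesis <- as.character(table$hypothesis)
  missing_genes <- setdiff(table$gene, names(passed))
  if (length(missing_genes)) {
    stop("genes absent from the screening table: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  in_stage2 <- passed[table$gene]
  padj <- rep(1, nrow(table))
  if (any(in_stage2)) {
    padj[in_stage2] <- bh_adjust(table$p[in_stage2])
  }
  rejected <- in_stage2 & padj <= split[2L] * alpha
  out <- data.frame(gene = table$gene, hypothesis = table$hypothesis,
                    p = table$p, padj = padj, rejected = unname(rejected),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "jiang_doerge"
  attr(out, "alpha") <- alpha
  attr(out, "alpha_screen") <- split[1L] * alpha
  attr(out, "alpha_confirm") <- split[2L] * alpha
  attr(out, "screen_rejected") <- passed
  attr(out, "gene_rejected") <- c(tapply(out$rejected, out$gene, any))
  class(out) <- c("comparator_result", "data.frame")
  out
}
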
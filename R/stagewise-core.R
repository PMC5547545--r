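## Two-stage testing engine: BH screening, confirmation-level adjustment
## alpha_II = R * alpha_I / G, and within-gene FWER control by Holm or
## Shaffer's modified sequentially rejective Bonferroni (MSRB) with
## context-specific logical constraints.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort ascending, multiply the i-th smallest p-value
#' by m/i, enforce monotonicity by a running minimum from the largest rank,
#' clip at 1, and return in input order.
#'
#' @param p numeric vector of p-values in \[0, 1\], length >= 1.
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  .check_probabilities(p)
  stats::p.adjust(p, method = "BH")
}

#' Screen genes with BH FDR control
#'
#' Stage I of the two-stage procedure: the per-gene omnibus (screening)
#' p-values are BH-adjusted and a gene passes screening when its adjusted
#' p-value is at most `alpha_i`. The number of screening rejections R sets
#' the confirmation-stage significance level alpha_II = R * alpha_I / G.
#'
#' @param screening data.frame with columns `gene` (unique identifiers) and
#'   `p` (one screening p-value per gene). A gene-level q-value table from
#'   [per_gene_qvalue()] can be used directly by renaming `qvalue` to `p`,
#'   with the convention that a gene is screened in when q <= alpha_I.
#' @param alpha_i target OFDR level in (0, 1); default 0.05.
#' @return an object of class `screening_result`: a list with `genes`
#'   (data.frame gene, p, padj, rejected), and scalars `G`, `R`, `alpha_i`,
#'   `alpha_ii`.
#' @seealso [confirm_genes()], [stage_wise_test()]
#' @export
screen_genes <- function(screening, alpha_i = 0.05) {
  if (!is.data.frame(screening) || !all(c("gene", "p") %in% names(screening))) {
    stop("screening must be a data.frame with columns gene and p")
  }
  if (anyDuplicated(screening$gene)) {
    stop("duplicate gene ids in screening table")
  }
  if (!is.numeric(alpha_i) || length(alpha_i) != 1L ||
      alpha_i <= 0 || alpha_i >= 1) {
    stop("alpha_i must be a single value in (0, 1)")
  }
  .check_probabilities(screening$p, "screening p-values")
  padj <- bh_adjust(screening$p)
  rejected <- padj <= alpha_i
  G <- nrow(screening)
  R <- sum(rejected)
  out <- list(
    genes = data.frame(gene = as.character(screening$gene),
                       p = screening$p, padj = padj, rejected = rejected,
                       stringsAsFactors = FALSE),
    G = G, R = R, alpha_i = alpha_i,
    alpha_ii = confirmation_alpha(R, G, alpha_i)
  )
  class(out) <- "screening_result"
  out
}

#' @export
print.screening_result <- function(x, ...) {
  cat("Screening stage: ", x$R, " of ", x$G,
      " genes pass at BH FDR alpha_I = ", x$alpha_i,
      " (alpha_II = ", signif(x$alpha_ii, 4), ")\n", sep = "")
  invisible(x)
}

#' Confirmation-stage significance level
#'
#' The BH-adjusted significance level carried from the screening stage:
#' alpha_II = R * alpha_I / G, where R is the number of screening rejections
#' out of G screened genes.
#'
#' @param R number of screening rejections, 0 <= R <= G.
#' @param G number of screened genes, >= 1.
#' @param alpha_i screening-stage FDR level.
#' @return the confirmation level R * alpha_i / G.
#' @export
confirmation_alpha <- function(R, G, alpha_i) {
  stopifnot(length(R) == 1L, length(G) == 1L, G >= 1, R >= 0)
  if (R > G) stop("R cannot exceed G")
  R * alpha_i / G
}

#' Shaffer MSRB threshold-divisor sequence
#'
#' The sequence t(1), ..., t(n_g) of divisors used by the modified
#' sequentially rejective Bonferroni procedure: the j-th smallest within-gene
#' p-value is compared to alpha_II / t(j), where t(j) is the maximum number
#' of hypotheses that can still be simultaneously true given that the j-1
#' smaller ones are false. A value of 0 encodes a vacuous threshold (the
#' hypothesis is rejected automatically once the gene passes screening).
#'
#' Contexts encode the logical constraints of common designs:
#' \describe{
#'   \item{`holm`}{no constraints: t(j) = n_g - j + 1 (Holm's method).}
#'   \item{`screened_free`}{a gene past screening has at least one effect, so
#'     t(1) = n_g - 1; from the second p-value on the procedure is Holm.}
#'   \item{`dge_2x2`}{2x2 factorial DGE with hypotheses (effect at time 1,
#'     effect at time 2, interaction), n_g = 3: at most one null can survive
#'     screening, so t = (1, 1, 1) and no within-gene correction is needed.}
#'   \item{`dge_2x2_avg`}{as `dge_2x2` plus an average-fold-change contrast
#'     (n_g = 4); the added contrast does not alter the FWER argument, so all
#'     t(j) = 1.}
#'   \item{`dte`}{differential transcript expression: same as
#'     `screened_free`; a single-transcript gene is auto-confirmed (t = 0).}
#'   \item{`dtu`}{differential transcript usage: usage changes must be
#'     compensated, so at least two transcripts are differentially used;
#'     t(1) = t(2) = n_g - 2, then Holm. With n_g = 2 both transcripts are
#'     confirmed automatically (t = (0, 0)).}
#' }
#'
#' @param n_g number of hypotheses for the gene.
#' @param context one of `"holm"`, `"screened_free"`, `"dge_2x2"`,
#'   `"dge_2x2_avg"`, `"dte"`, `"dtu"`.
#' @return integer vector of length `n_g`.
#' @export
shaffer_t_sequence <- function(n_g, context = c("holm", "screened_free",
                                                "dge_2x2", "dge_2x2_avg",
                                                "dte", "dtu")) {
  context <- match.arg(context)
  stopifnot(length(n_g) == 1L, n_g >= 1, n_g == floor(n_g))
  n_g <- as.integer(n_g)
  holm_tail <- function(from) if (from > n_g) integer(0) else
    (n_g - from + 1L):1L
  switch(context,
    holm = n_g:1L,
    screened_free = ,
    dte = {
      if (n_g == 1L) 0L else c(n_g - 1L, holm_tail(2L))
    },
    dge_2x2 = {
      if (n_g != 3L) stop("context dge_2x2 requires exactly 3 hypotheses per gene")
      rep(1L, 3L)
    },
    dge_2x2_avg = {
      if (n_g != 4L) stop("context dge_2x2_avg requires exactly 4 hypotheses per gene")
      rep(1L, 4L)
    },
    dtu = {
      if (n_g < 2L) stop("context dtu requires at least 2 transcripts per gene")
      if (n_g == 2L) c(0L, 0L) else c(n_g - 2L, n_g - 2L, holm_tail(3L))
    }
  )
}

#' MSRB within-gene adjusted p-values
#'
#' Step-down adjustment associated with the sequentially rejective procedure
#' that compares the j-th smallest p-value to alpha / t(j): the sorted
#' p-values are multiplied by their divisors and a running maximum makes
#' "adjusted p <= alpha" equivalent to the sequential rejection rule. A
#' divisor of 0 yields an adjusted value of 0 (automatic rejection). Sorting
#' is stable with ties broken by `ids` when supplied.
#'
#' @param p within-gene p-values.
#' @param t divisor sequence from [shaffer_t_sequence()]; same length as `p`.
#' @param ids optional hypothesis identifiers used as a deterministic
#'   tie-break in the within-gene ordering.
#' @return adjusted p-values in input order.
#' @export
msrb_adjust <- function(p, t, ids = NULL) {
  .check_probabilities(p, "within-gene p-values")
  if (length(p) != length(t)) {
    stop("p and t must have the same length")
  }
  if (any(t < 0)) stop("t-sequence values must be >= 0")
  ord <- if (is.null(ids)) order(p) else order(p, ids)
  adj_sorted <- cummax(pmin(1, p[ord] * t))
  adj <- numeric(length(p))
  adj[ord] <- adj_sorted
  adj
}

#' Confirmation stage of the two-stage procedure
#'
#' Tests the individual hypotheses of every gene that passed screening,
#' controlling the within-gene FWER at alpha_II by the MSRB procedure with
#' the given context. Hypotheses of genes that failed screening are never
#' rejected. Stage-wise adjusted p-values on the alpha_I scale are reported
#' as min(1, within-gene adjusted p * G / R) for passing genes and 1
#' otherwise, so that "stage-wise adjusted p <= alpha_I" reproduces the
#' two-stage decision exactly.
#'
#' @param table hypothesis table: data.frame with columns `gene`,
#'   `hypothesis`, `p`. Missing p-values are dropped from the gene's family
#'   with a warning (they do not inflate n_g).
#' @param screening a `screening_result` from [screen_genes()]; every gene in
#'   `table` must appear in it.
#' @param context MSRB context passed to [shaffer_t_sequence()].
#' @return an object of class `stagewise_result`: data.frame with columns
#'   `gene`, `hypothesis`, `p`, `padj_within` (within-gene FWER-adjusted),
#'   `padj_stagewise` (alpha_I scale), `passed_screening`, `rejected`;
#'   attributes `alpha_i`, `alpha_ii`, `G`, `R`, `context`.
#' @export
confirm_genes <- function(table, screening, context = "holm") {
  .check_hypothesis_table(table)
  if (!inherits(screening, "screening_result")) {
    stop("screening must be a screening_result from screen_genes()")
  }
  table$gene <- as.character(table$gene)
  table$hypothesis <- as.character(table$hypothesis)
  missing_genes <- setdiff(table$gene, screening$genes$gene)
  if (length(missing_genes)) {
    stop("genes absent from the screening result: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  if (anyNA(table$p)) {
    warning("dropping ", sum(is.na(table$p)),
            " hypotheses with missing p-values from their genes' families")
    table <- table[!is.na(table$p), , drop = FALSE]
  }
  G <- screening$G
  R <- screening$R
  alpha_ii <- screening$alpha_ii
  if (R == 0L) {
    message("no gene passed screening; confirmation stage is vacuous")
  }
  passed <- structure(screening$genes$rejected, names = screening$genes$gene)

  split_idx <- split(seq_len(nrow(table)), table$gene)
  padj_within <- numeric(nrow(table))
  for (idx in split_idx) {
    g <- table$gene[idx[1L]]
    t_seq <- shaffer_t_sequence(length(idx), context)
    padj_within[idx] <- msrb_adjust(table$p[idx], t_seq,
                                    ids = table$hypothesis[idx])
  }
  gene_passed <- passed[table$gene]
  scale <- if (R > 0L) G / R else Inf
  padj_stagewise <- ifelse(gene_passed, pmin(1, padj_within * scale), 1)
  rejected <- gene_passed & padj_within <= alpha_ii

  out <- data.frame(
    gene = table$gene, hypothesis = table$hypothesis, p = table$p,
    padj_within = padj_within, padj_stagewise = padj_stagewise,
    passed_screening = unname(gene_passed), rejected = unname(rejected),
    stringsAsFactors = FALSE
  )
  attr(out, "alpha_i") <- screening$alpha_i
  attr(out, "alpha_ii") <- alpha_ii
  attr(out, "G") <- G
  attr(out, "R") <- R
  attr(out, "context") <- context
  class(out) <- c("stagewise_result", "data.frame")
  out
}

#' Run the full two-stage procedure
#'
#' Convenience wrapper: [screen_genes()] on the screening table followed by
#' [confirm_genes()] on the hypothesis table.
#'
#' @inheritParams confirm_genes
#' @param screening data.frame with columns `gene`, `p` (one row per gene).
#' @param alpha_i target OFDR level.
#' @return a `stagewise_result` (the screening result is attached as
#'   attribute `screening`).
#' @export
stage_wise_test <- function(table, screening, alpha_i = 0.05,
                            context = "holm") {
  scr <- screen_genes(screening, alpha_i)
  res <- confirm_genes(table, scr, context)
  attr(res, "screening") <- scr
  res
}

#' Gene-level false discovery proportion
#'
#' A false positive gene is a screening-stage discovery that is either fully
#' null (its screening null was true) or has at least one confirmation-stage
#' rejection of a true null hypothesis. The FDP is the number of false
#' positive genes over the number of screening discoveries (0 when there are
#' none).
#'
#' @param result a `stagewise_result` from [confirm_genes()].
#' @param truth data.frame with columns `gene`, `hypothesis`, `is_null`
#'   (logical truth per individual hypothesis); a gene's screening null is
#'   true iff all its hypothesis nulls are true. Must cover every gene in the
#'   result.
#' @return the gene-level FDP.
#' @export
gene_level_fdp <- function(result, truth) {
  cls <- classify_discovered_genes(result, truth)
  if (cls$n_discovered == 0L) return(0)
  (cls$fully_null + cls$partly_true) / cls$n_discovered
}

## Shared classification of screening discoveries into true positives,
## fully-null false positives and partly-true false positives.
classify_discovered_genes <- function(result, truth) {
  stopifnot(inherits(result, "stagewise_result"))
  if (!all(c("gene", "hypothesis", "is_null") %in% names(truth))) {
    stop("truth must have columns gene, hypothesis, is_null")
  }
  truth$gene <- as.character(truth$gene)
  truth$hypothesis <- as.character(truth$hypothesis)
  missing <- setdiff(unique(result$gene), truth$gene)
  if (length(missing)) {
    stop("truth records missing for genes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  key <- function(g, h) paste(g, h, sep = "\r")
  is_null <- structure(truth$is_null, names = key(truth$gene, truth$hypothesis))
  null_by_gene <- tapply(truth$is_null, truth$gene, all)

  discovered <- unique(result$gene[result$passed_screening])
  hyp_null <- is_null[key(result$gene, result$hypothesis)]
  if (anyNA(hyp_null)) {
    stop("truth records missing for some (gene, hypothesis) pairs")
  }
  false_rej <- result$rejected & hyp_null
  false_rej_by_gene <- tapply(false_rej, result$gene, any)

  fully_null <- sum(null_by_gene[discovered], na.rm = FALSE)
  partly_true <- sum(!null_by_gene[discovered] &
                       false_rej_by_gene[discovered])
  list(n_discovered = length(discovered),
       fully_null = as.integer(fully_null),
       partly_true = as.integer(partly_true))
}
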
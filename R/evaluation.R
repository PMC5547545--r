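## Performance metrics over replicated simulations: FDP/TPR curves with
## nominal working points, OFDR estimation across replicates, and the
## decomposition of gene-level false positives into fully-null and
## partly-true genes.

#' FDP-TPR performance curve
#'
#' Cumulative false discovery proportion and true positive rate along a
#' ranking of tested units (most to least significant). When the truth
#' contains no true alternatives the TPR is degenerate; it is reported as 0
#' with the attribute `degenerate_tpr = TRUE`.
#'
#' @param ids unit identifiers ordered from most to least significant.
#' @param is_null named logical: TRUE for true-null units; must cover every
#'   id.
#' @return data.frame with columns `k` (rejection-list size), `fdp`, `tpr`;
#'   attribute `degenerate_tpr`.
#' @export
fdp_tpr_curve <- function(ids, is_null) {
  if (anyDuplicated(ids)) stop("ranking ids must be unique")
  null_flags <- is_null[ids]
  if (anyNA(null_flags)) {
    stop("truth missing for ids: ",
         paste(utils::head(ids[is.na(null_flags)], 5), collapse = ", "))
  }
  n_alt <- sum(!is_null)
  k <- seq_along(ids)
  fp <- cumsum(null_flags)
  tp <- cumsum(!null_flags)
  out <- data.frame(k = k, fdp = fp / k,
                    tpr = if (n_alt > 0) tp / n_alt else 0)
  attr(out, "degenerate_tpr") <- n_alt == 0
  out
}

#' TPR at matched empirical FDP levels
#'
#' For each requested FDP level, the highest TPR attained by any prefix of
#' the ranking whose empirical FDP does not exceed the level; NA when no
#' prefix qualifies.
#'
#' @param curve output of [fdp_tpr_curve()].
#' @param fdp_levels numeric vector of FDP levels.
#' @return numeric vector of TPRs, named by level.
#' @export
tpr_at_fdp <- function(curve, fdp_levels = c(0.01, 0.05, 0.1)) {
  out <- vapply(fdp_levels, function(f) {
    ok <- curve$fdp <= f
    if (!any(ok)) NA_real_ else max(curve$tpr[ok])
  }, numeric(1))
  names(out) <- fdp_levels
  out
}

#' Working point of a rejection rule
#'
#' Empirical FDP and TPR of a fixed rejection set, with the Boolean flag
#' `filled` marking whether the empirical FDP is at or below the nominal
#' level (the plotting convention for attained error control).
#'
#' @param rejected logical rejection flags.
#' @param is_null logical truth flags, same length.
#' @param nominal nominal level of the rule.
#' @return data.frame with one row: `nominal`, `fdp`, `tpr`, `filled`.
#' @export
working_point <- function(rejected, is_null, nominal = 0.05) {
  stopifnot(length(rejected) == length(is_null))
  n_rej <- sum(rejected)
  fdp <- if (n_rej > 0) sum(rejected & is_null) / n_rej else 0
  n_alt <- sum(!is_null)
  tpr <- if (n_alt > 0) sum(rejected & !is_null) / n_alt else 0
  data.frame(nominal = nominal, fdp = fdp, tpr = tpr,
             filled = fdp <= nominal)
}

#' OFDR estimate over replicated simulations
#'
#' Mean and Monte-Carlo standard error of the gene-level FDP across
#' replicates. The FDR/OFDR is the expectation of the FDP, estimated by the
#' replicate mean.
#'
#' @param results either a numeric vector of per-replicate gene-level FDPs,
#'   or a list of `stagewise_result` objects (then `truths` is required).
#' @param truths list of truth tables matching `results` when results are
#'   `stagewise_result` objects.
#' @return list with `mean`, `se` (0 for a single replicate), `n`, and the
#'   per-replicate `fdp` vector.
#' @export
ofdr_over_replicates <- function(results, truths = NULL) {
  if (is.numeric(results)) {
    fdp <- results
  } else {
    if (length(results) == 0L) stop("no replicates supplied")
    if (is.null(truths) || length(truths) != length(results)) {
      stop("truths must match results one-to-one")
    }
    fdp <- mapply(gene_level_fdp, results, truths)
  }
  if (length(fdp) == 0L) stop("no replicates supplied")
  se <- if (length(fdp) > 1L) stats::sd(fdp) / sqrt(length(fdp)) else 0
  list(mean = mean(fdp), se = se, n = length(fdp), fdp = fdp)
}

#' Decompose gene-level false positives
#'
#' Splits the false positive genes of a result into (1) fully-null genes
#' (the screening null itself was true) and (2) partly-true genes (some
#' effect exists, but a true null hypothesis within the gene was falsely
#' rejected). The two counts sum to the numerator of [gene_level_fdp()].
#'
#' For a `stagewise_result`, a discovered gene is one that passed
#' screening. For a `comparator_result`, a discovered gene is one with at
#' least one rejected hypothesis.
#'
#' @param result a `stagewise_result` or `comparator_result`.
#' @param truth data.frame with columns `gene`, `hypothesis`, `is_null`.
#' @return named integer vector `c(fully_null = , partly_true = )` with
#'   attribute `n_discovered`.
#' @export
decompose_false_positive_genes <- function(result, truth) {
  if (inherits(result, "stagewise_result")) {
    cls <- classify_discovered_genes(result, truth)
  } else if (inherits(result, "comparator_result")) {
    cls <- .classify_comparator(result, truth)
  } else {
    stop("result must be a stagewise_result or comparator_result")
  }
  out <- c(fully_null = cls$fully_null, partly_true = cls$partly_true)
  attr(out, "n_discovered") <- cls$n_discovered
  out
}

## Comparator analogue of classify_discovered_genes: discovery = any
## rejected hypothesis in the gene.
.classify_comparator <- function(result, truth) {
  truth$gene <- as.character(truth$gene)
  truth$hypothesis <- as.character(truth$hypothesis)
  key <- function(g, h) paste(g, h, sep = "\r")
  is_null <- structure(truth$is_null, names = key(truth$gene, truth$hypothesis))
  null_by_gene <- tapply(truth$is_null, truth$gene, all)
  hyp_null <- is_null[key(result$gene, result$hypothesis)]
  if (anyNA(hyp_null)) stop("truth records missing for some hypotheses")
  rej_by_gene <- tapply(result$rejected, result$gene, any)
  false_by_gene <- tapply(result$rejected & hyp_null, result$gene, any)
  discovered <- names(rej_by_gene)[rej_by_gene]
  list(n_discovered = length(discovered),
       fully_null = as.integer(sum(null_by_gene[discovered])),
       partly_true = as.integer(sum(!null_by_gene[discovered] &
                                      false_by_gene[discovered])))
}

#' Gene-level FDP of a comparator analysis
#'
#' Same definition as [gene_level_fdp()] with discovery meaning "any
#' hypothesis of the gene rejected".
#'
#' @param result a `comparator_result`.
#' @param truth data.frame with columns `gene`, `hypothesis`, `is_null`.
#' @return the gene-level FDP.
#' @export
comparator_gene_fdp <- function(result, truth) {
  stopifnot(inherits(result, "comparator_result"))
  cls <- .classify_comparator(result, truth)
  if (cls$n_discovered == 0L) return(0)
  (cls$fully_null + cls$partly_true) / cls$n_discovered
}
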
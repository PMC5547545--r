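## Minimal per-feature testing engine: CPM filtering, median-of-ratios size
## factors, ordinary least squares on log2(CPM + 0.5) with per-contrast
## t-tests and an omnibus F-test. Deliberately plain (no moderation, no NB
## dispersion estimation): the stage-wise machinery accepts externally
## computed p-value tables from any fitting tool.

#' Filter features on counts per million
#'
#' Keeps features with CPM above `cpm_threshold` in at least `min_samples`
#' samples; feature order is preserved. CPM uses raw library sizes (column
#' sums).
#'
#' @param counts non-negative integer matrix (features x samples).
#' @param cpm_threshold CPM cut-off; default 2.
#' @param min_samples minimum number of samples above the cut-off; default 2.
#' @return the filtered count matrix.
#' @export
filter_low_counts <- function(counts, cpm_threshold = 2, min_samples = 2) {
  .check_count_matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("all library sizes must be > 0")
  cpm <- sweep(counts, 2L, lib, "/") * 1e6
  keep <- rowSums(cpm > cpm_threshold) >= min_samples
  if (!any(keep)) stop("filtering removed all features")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample factors computed as the median ratio of each sample's counts
#' to the geometric-mean reference, over features nonzero in every sample.
#' When no feature is nonzero in all samples, falls back to library-size
#' factors (normalised column sums) with a warning.
#'
#' @param counts non-negative count matrix.
#' @return positive numeric vector of size factors, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  .check_count_matrix(counts)
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos)) {
    warning("no feature is nonzero in all samples; ",
            "falling back to library-size factors")
    sf <- colSums(counts)
    return(sf / exp(mean(log(sf))))
  }
  ref <- exp(rowMeans(log(counts[all_pos, , drop = FALSE])))
  apply(counts[all_pos, , drop = FALSE], 2L,
        function(col) stats::median(col / ref))
}

#' Per-feature linear-model tests
#'
#' Fits an ordinary least squares model to log2(CPM + 0.5) of
#' size-factor-normalised counts for every feature, then computes t-tests
#' for each named contrast and an F-test over the omnibus contrast set (the
#' screening test of the global null that none of the contrasts is active).
#' With a single omnibus contrast the F statistic is exactly the squared t.
#'
#' @param counts count matrix (features x samples).
#' @param design numeric design matrix (samples x coefficients), full rank.
#' @param contrasts named list of numeric contrast vectors over the
#'   coefficients; none may be all zero.
#' @param omnibus character vector naming the contrasts in the omnibus
#'   F-test; default all contrasts.
#' @param size_factors optional positive per-sample factors; estimated by
#'   [estimate_size_factors()] when NULL.
#' @return list with `table` (data.frame gene, hypothesis, contrast, p —
#'   the long-format hypothesis table, one row per feature x contrast) and
#'   `screening` (data.frame gene, p — the omnibus F p-values).
#' @export
feature_tests <- function(counts, design, contrasts,
                          omnibus = names(contrasts), size_factors = NULL) {
  .check_count_matrix(counts)
  X <- as.matrix(design)
  if (nrow(X) != ncol(counts)) {
    stop("design must have one row per sample")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  df_resid <- nrow(X) - ncol(X)
  if (df_resid < 2L) stop("at least 2 residual degrees of freedom required")
  if (is.null(names(contrasts)) || any(!nzchar(names(contrasts)))) {
    stop("contrasts must be a named list")
  }
  for (nm in names(contrasts)) {
    cvec <- contrasts[[nm]]
    if (length(cvec) != ncol(X)) {
      stop("contrast '", nm, "' length does not match the design")
    }
    if (all(cvec == 0)) stop("contrast '", nm, "' is all zeros")
  }
  if (!all(omnibus %in% names(contrasts))) {
    stop("omnibus names unknown contrasts: ",
         paste(setdiff(omnibus, names(contrasts)), collapse = ", "))
  }
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (any(size_factors <= 0)) stop("size factors must be positive")

  norm <- sweep(counts, 2L, size_factors, "/")
  y <- log2(sweep(norm, 2L, colSums(norm), "/") * 1e6 + 0.5)

  xtx_inv <- chol2inv(qr.R(qrX))
  beta <- t(qr.coef(qrX, t(y)))                    # features x coefficients
  resid <- y - beta %*% t(X)
  s2 <- rowSums(resid^2) / df_resid
  genes <- rownames(counts)
  if (is.null(genes)) genes <- sprintf("feature%05d", seq_len(nrow(counts)))

  tabs <- lapply(names(contrasts), function(nm) {
    cvec <- contrasts[[nm]]
    est <- drop(beta %*% cvec)
    se <- sqrt(s2 * drop(t(cvec) %*% xtx_inv %*% cvec))
    p <- 2 * stats::pt(-abs(est / se), df = df_resid)
    data.frame(gene = genes, hypothesis = nm, contrast = nm,
               p = pmax(p, .Machine$double.xmin), stringsAsFactors = FALSE)
  })
  table <- do.call(rbind, tabs)

  L <- do.call(rbind, contrasts[omnibus])
  ## logically dependent contrasts (e.g. t2 = t1 + interaction) make L
  ## row-rank deficient; the global F-test is on the row space, so reduce
  ## to an orthonormal basis first
  qrL <- qr(t(L))
  q <- qrL$rank
  L <- t(qr.Q(qrL)[, seq_len(q), drop = FALSE])
  M_inv <- solve(L %*% xtx_inv %*% t(L))
  B <- beta %*% t(L)                               # features x q
  fstat <- rowSums((B %*% M_inv) * B) / (q * s2)
  p_f <- stats::pf(fstat, q, df_resid, lower.tail = FALSE)
  screening <- data.frame(gene = genes,
                          p = pmax(p_f, .Machine$double.xmin),
                          stringsAsFactors = FALSE)
  list(table = table, screening = screening)
}
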
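## Internal validation helpers shared across modules.

.check_probabilities <- function(p, what = "p-values") {
  if (length(p) == 0L) {
    stop(what, " must have length >= 1", call. = FALSE)
  }
  if (!is.numeric(p)) {
    stop(what, " must be numeric", call. = FALSE)
  }
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop(what, " must lie in [0, 1]; offending values: ",
         paste(utils::head(signif(p[bad], 4), 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(p)
}

.check_hypothesis_table <- function(table) {
  required <- c("gene", "hypothesis", "p")
  if (!is.data.frame(table) || !all(required %in% names(table))) {
    stop("hypothesis table must be a data.frame with columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  key <- paste(table$gene, table$hypothesis, sep = "\r")
  if (anyDuplicated(key)) {
    stop("(gene, hypothesis) pairs must be unique", call. = FALSE)
  }
  .check_probabilities(table$p[!is.na(table$p)], "hypothesis p-values")
  invisible(table)
}

.check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix (features x samples)", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  invisible(counts)
}

#' Draw from a Dirichlet distribution
#'
#' Random draws on the simplex via normalised gamma variates. Zero entries in
#' `alpha` are structural zeros: the corresponding proportions are exactly 0
#' in every draw.
#'
#' @param n number of draws.
#' @param alpha non-negative concentration vector; at least one entry > 0.
#' @return an `n x length(alpha)` matrix; each row sums to 1.
#' @export
rdirichlet <- function(n, alpha) {
  stopifnot(n >= 1, length(alpha) >= 1, all(alpha >= 0))
  if (all(alpha == 0)) stop("at least one Dirichlet parameter must be > 0")
  x <- matrix(0, nrow = n, ncol = length(alpha))
  pos <- alpha > 0
  x[, pos] <- matrix(stats::rgamma(n * sum(pos), shape = alpha[pos]),
                     nrow = n, byrow = TRUE)
  sweep(x, 1L, rowSums(x), "/")
}
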
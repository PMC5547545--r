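## Delimited-text I/O for the tables exchanged between modules, plus the
## structured run-summary sidecar.

#' Read a long-format hypothesis table
#'
#' Tab- or comma-delimited text with a header; columns `gene`, `hypothesis`
#' and `pvalue` (or `p`) are required, extra columns (e.g. `contrast`) are
#' kept.
#'
#' @param path file path.
#' @param sep field separator; guessed from the first line when NULL.
#' @return data.frame with columns `gene`, `hypothesis`, `p`, ...
#' @export
read_hypothesis_table <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if ("pvalue" %in% names(tab) && !"p" %in% names(tab)) {
    names(tab)[names(tab) == "pvalue"] <- "p"
  }
  .check_hypothesis_table(tab)
  tab
}

#' Write a stage-wise result with its run summary
#'
#' The per-hypothesis table is written as tab-delimited text (columns gene,
#' hypothesis, p, p_screen_adj, p_confirm_adj_alphaI_scale, rejected); the
#' run summary (G, R, alpha_I, alpha_II, context) goes to a JSON sidecar
#' `<path>.summary.json`.
#'
#' @param result a `stagewise_result`.
#' @param path output file path.
#' @return invisibly, the sidecar path.
#' @export
write_stagewise_result <- function(result, path) {
  stopifnot(inherits(result, "stagewise_result"))
  scr <- attr(result, "screening")
  padj_screen <- if (!is.null(scr)) {
    structure(scr$genes$padj, names = scr$genes$gene)[result$gene]
  } else NA_real_
  out <- data.frame(gene = result$gene, hypothesis = result$hypothesis,
                    p = result$p, p_screen_adj = as.numeric(padj_screen),
                    p_confirm_adj_alphaI_scale = result$padj_stagewise,
                    rejected = result$rejected)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- paste0(path, ".summary.json")
  jsonlite::write_json(
    list(G = attr(result, "G"), R = attr(result, "R"),
         alpha_I = attr(result, "alpha_i"),
         alpha_II = attr(result, "alpha_ii"),
         context = attr(result, "context"),
         screening_rule = "BH-adjusted screening p (or gene q-value) <= alpha_I"),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a count matrix from delimited text
#'
#' First column = feature identifiers, remaining columns = integer counts
#' per sample.
#'
#' @inheritParams read_hypothesis_table
#' @return integer matrix with feature rownames.
#' @export
read_count_matrix <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  counts <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(counts) <- tab[[1L]]
  storage.mode(counts) <- "integer"
  .check_count_matrix(counts)
  counts
}

#' Write a count matrix as delimited text
#'
#' @param counts matrix with feature rownames.
#' @param path output path.
#' @param id_col name of the identifier column; default "feature".
#' @export
write_count_matrix <- function(counts, path, id_col = "feature") {
  out <- data.frame(rownames(counts), counts, check.names = FALSE)
  names(out)[1L] <- id_col
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
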
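#' Read a transcript-to-GO annotation map
#'
#' @param path TSV with columns `transcript_id`, `term_id`; optionally a
#'   second file of term names can be joined downstream.
#' @return data.frame annotation map (one row per transcript-term pair,
#'   duplicates removed).
#' @export
read_annotation_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("transcript_id", "term_id") %in% colnames(df)))
    stop("expected columns transcript_id, term_id")
  unique(df[, c("transcript_id", "term_id")])
}

#' Hypergeometric over-representation test
#'
#' For every term annotated to at least one background transcript, the
#' one-sided upper-tail hypergeometric probability of seeing at least the
#' observed number of study hits:
#' P(X >= k), X ~ Hypergeometric(N, K, n), with N the annotated
#' background size, K the background transcripts carrying the term, n the
#' annotated study size and k the study transcripts carrying the term.
#' Terms with k = 0 are reported with p = 1. Bonferroni correction uses
#' m = number of tested terms (those with K >= 1).
#'
#' When transcript lengths are supplied and the study/background mean
#' lengths differ by more than 20%, a warning flags possible
#' transcript-length bias (this test is unweighted).
#'
#' @param study character vector of study transcript ids (must be a
#'   subset of `background`).
#' @param background character vector of background transcript ids.
#' @param annot annotation map (`transcript_id`, `term_id`).
#' @param alpha adjusted-p significance level for the `enriched` flag
#'   (default 0.05).
#' @param lengths optional named transcript lengths for the bias check.
#' @return data.frame sorted by adjusted p: `term_id`, `k`, `n`, `K`, `N`,
#'   `p_raw`, `p_adj`, `enriched`.
#' @export
hypergeometric_enrich <- function(study, background, annot, alpha = 0.05,
                                  lengths = NULL) {
  extra <- setdiff(study, background)
  if (length(extra))
    stop("study transcripts outside background: ",
         paste(utils::head(extra, 5), collapse = ", "),
         if (length(extra) > 5) sprintf(" (and %d more)", length(extra) - 5))
  annotated <- unique(annot$transcript_id)
  bg <- intersect(unique(background), annotated)
  st <- intersect(unique(study), annotated)
  N <- length(bg); n <- length(st)
  if (!is.null(lengths) && n > 0 && N > 0) {
    ml_st <- mean(lengths[st], na.rm = TRUE)
    ml_bg <- mean(lengths[bg], na.rm = TRUE)
    if (is.finite(ml_st) && is.finite(ml_bg) &&
        abs(ml_st - ml_bg) / ml_bg > 0.20)
      warning("study/background mean transcript lengths differ by >20%; ",
              "this unweighted test may carry length bias")
  }
  a_bg <- annot[annot$transcript_id %in% bg, ]
  K_tab <- table(a_bg$term_id)
  terms <- names(K_tab)
  a_st <- a_bg[a_bg$transcript_id %in% st, ]
  k_tab <- table(factor(a_st$term_id, levels = terms))
  K <- as.integer(K_tab); k <- as.integer(k_tab)
  p_raw <- hyper_upper_tail(k, K, n, N)
  res <- data.frame(term_id = terms, k = k, n = n, K = K, N = N,
                    p_raw = p_raw, stringsAsFactors = FALSE)
  res <- bonferroni(res)
  res$enriched <- res$p_adj <= alpha
  res[order(res$p_adj, res$p_raw, res$term_id), , drop = FALSE]
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' X ~ Hypergeometric(N, K, n): k study hits among n draws from a
#' background of N with K marked. Vectorized over `k`, `K`.
#'
#' @param k observed hits (>= 0).
#' @param K background transcripts carrying the term.
#' @param n study size.
#' @param N background size.
#' @return P(X >= k); exactly 1 when k = 0.
#' @export
hyper_upper_tail <- function(k, K, n, N) {
  ifelse(k == 0, 1, stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE))
}

#' Bonferroni adjustment over the tested terms
#'
#' p_adj = min(1, p_raw * m) with m defaulting to the number of result
#' rows (the terms annotated in the background, i.e. the testable-term
#' universe).
#'
#' @param results enrichment result data.frame with column `p_raw`.
#' @param m number of tests (default `nrow(results)`).
#' @return `results` with a `p_adj` column.
#' @export
bonferroni <- function(results, m = nrow(results)) {
  stopifnot(m >= 1 || nrow(results) == 0)
  results$p_adj <- pmin(1, results$p_raw * m)
  results
}

#' Write an enrichment result table as TSV
#' @param results enrichment data.frame.
#' @param path output path.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
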
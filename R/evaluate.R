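#' Spearman rank correlation between predicted and observed efficiencies
#'
#' Pearson correlation of mid-ranks (average ranks under ties).  Constant
#' input is signalled as an error rather than silently returned as 0 or NA.
#'
#' @param pred,obs Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_cor <- function(pred, obs) {
  if (length(pred) != length(obs)) {
    gl_abort(sprintf("length mismatch: %d vs %d", length(pred), length(obs)),
             "length_mismatch")
  }
  if (length(pred) < 3L) {
    gl_abort("need at least 3 observations", "length_mismatch")
  }
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    gl_abort("rank correlation is undefined for a constant vector",
             "degenerate_input")
  }
  stats::cor(pred, obs, method = "spearman")
}

#' Normalized discounted cumulative gain of a predicted ranking
#'
#' Guides are placed in stable descending order of `pred`; the DCG of the
#' observed relevances in that order, with gain `rel_i` and discount
#' `log2(i + 1)`, is divided by the DCG of the ideal (descending-relevance)
#' order.  Negative relevances are shifted to be nonnegative by subtracting
#' the minimum (only applied when a negative value is present).  An
#' exponential-gain variant (`2^rel - 1`) is available via `gain`.
#'
#' @param pred Predicted scores (only their order matters).
#' @param obs Observed relevances.
#' @param k Optional cutoff: only the top `k` predicted positions contribute
#'   (default: full list).
#' @param gain `"linear"` (default) or `"exponential"`.
#' @return Value in \[0, 1\]; exactly 1 for an ideal-order prediction.
#' @export
ndcg <- function(pred, obs, k = NULL, gain = c("linear", "exponential")) {
  gain <- match.arg(gain)
  if (length(pred) != length(obs)) {
    gl_abort(sprintf("length mismatch: %d vs %d", length(pred), length(obs)),
             "length_mismatch")
  }
  n <- length(obs)
  if (!n) gl_abort("empty input", "length_mismatch")
  if (is.null(k)) k <- n
  if (k < 1L || k > n) gl_abort(sprintf("k = %d outside 1..%d", k, n), "bad_bounds")
  rel <- if (min(obs) < 0) obs - min(obs) else obs
  if (all(rel == 0)) {
    gl_abort("all relevances are zero after the nonnegativity shift; nDCG is undefined",
             "all_zero_relevance")
  }
  g <- if (gain == "linear") rel else 2^rel - 1
  disc <- 1 / log2(seq_len(k) + 1)
  dcg <- sum(g[order(-pred)][seq_len(k)] * disc)
  idcg <- sum(sort(g, decreasing = TRUE)[seq_len(k)] * disc)
  dcg / idcg
}

#' Ranking-quality report for one dataset
#'
#' Computes the two ranking metrics used to judge guide-efficiency
#' predictions — Spearman correlation (general agreement) and nDCG
#' (top-of-list quality) — in a long-format table ready for aggregation
#' across datasets or export via [utils::write.csv()].
#'
#' @inheritParams ndcg
#' @param dataset Label recorded in the report.
#' @return Data frame with columns `metric, value, n, dataset`.
#' @export
evaluation_report <- function(pred, obs, dataset = "dataset", k = NULL) {
  data.frame(metric = c("spearman", "ndcg"),
             value = c(spearman_cor(pred, obs), ndcg(pred, obs, k = k)),
             n = length(pred), dataset = dataset,
             stringsAsFactors = FALSE)
}
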
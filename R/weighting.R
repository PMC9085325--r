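#' Term-frequency weighting
#'
#' Normalizes each document's token counts by the document's total token count,
#' pooled over all n-gram orders: entry `(j, i)` becomes
#' `n_ij / sum_k n_kj`. Rows of documents with no tokens are left all zero.
#'
#' @param counts Sparse documents-by-tokens count matrix from [count_matrix()].
#' @param per_order Logical; if `TRUE`, normalize within each n-gram order
#'   separately (each order's token frequencies sum to 1 per document) instead
#'   of pooling all orders into one bag. Default `FALSE` (pooled).
#' @return Sparse feature matrix of the same shape; every row sums to 1 (or 0
#'   for an empty document), per order if `per_order`.
#' @export
tf <- function(counts, per_order = FALSE) {
  if (!per_order) {
    rs <- Matrix::rowSums(counts)
    return(Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% counts)
  }
  lens <- nchar(colnames(counts))
  out <- counts
  for (n in unique(lens)) {
    cols <- which(lens == n)
    rs <- Matrix::rowSums(counts[, cols, drop = FALSE])
    out[, cols] <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*%
      counts[, cols, drop = FALSE]
  }
  out
}

#' Relevance-frequency weights
#'
#' Supervised per-token weights for a binary problem. For token `t_i`, with
#' `a` = number of positive-class training documents containing the token and
#' `c` = the same count in the negative class,
#' `rf_i = log2(2 + a / max(1, c))`. Presence means count > 0; raw frequencies
#' are not used. Every `rf` is >= 1, non-decreasing in `a` and (for `c >= 1`)
#' non-increasing in `c`.
#'
#' @param counts Training count matrix (documents x tokens).
#' @param labels Class labels, one per document; exactly two distinct values.
#' @param positive_class The label treated as the positive category.
#' @return An `rf_weights` object: list with `rf`, `a`, `c`, `P`, `N`,
#'   `positive_class`.
#' @export
rf_weights <- function(counts, labels, positive_class) {
  labels <- as.character(labels)
  if (length(labels) != nrow(counts)) stop_domain("one label per document required")
  if (length(unique(labels)) < 2) {
    stop_domain("relevance frequency needs both a positive and a negative class")
  }
  if (!positive_class %in% labels) {
    stop_domain("positive_class not present among labels")
  }
  pos <- labels == positive_class
  presence <- counts > 0
  a <- Matrix::colSums(presence[pos, , drop = FALSE])
  c_ <- Matrix::colSums(presence[!pos, , drop = FALSE])
  structure(
    list(
      rf = log2(2 + a / pmax(1, c_)),
      a = a, c = c_,
      P = sum(pos), N = sum(!pos),
      positive_class = positive_class
    ),
    class = "rf_weights"
  )
}

# Per-token TF-RF multiplier: log2(2 + (N/P) * a / max(1, c)). The
# negative-to-positive document ratio N/P compensates class imbalance; it
# multiplies a/max(1,c) inside the logarithm.
tf_rf_factor <- function(rfw) {
  stopifnot(inherits(rfw, "rf_weights"))
  if (rfw$P == 0) stop_domain("no positive training documents")
  log2(2 + (rfw$N / rfw$P) * rfw$a / pmax(1, rfw$c))
}

#' TF-RF weighting
#'
#' Multiplies each document's TF row by the per-token imbalance-adjusted
#' relevance factor `log2(2 + (N/P) * a / max(1, c))`, where `P` and `N` are
#' the positive/negative training-document totals. With balanced classes
#' (`N = P`) this reduces to `tf * rf`. A token absent from every training
#' document gets factor `log2(2) = 1`, so its TF-RF equals its TF.
#'
#' @inheritParams rf_weights
#' @param weights Optional precomputed [rf_weights()] (e.g. when weighting test
#'   documents with training-derived factors, which avoids leakage). When
#'   supplied, `labels` and `positive_class` are ignored.
#' @param per_order Passed to [tf()].
#' @return Sparse feature matrix, entrywise `tf * factor`; always >= TF.
#' @export
tf_rf <- function(counts, labels = NULL, positive_class = NULL,
                  weights = NULL, per_order = FALSE) {
  if (is.null(weights)) {
    weights <- rf_weights(counts, labels, positive_class)
  }
  tf(counts, per_order = per_order) %*% Matrix::Diagonal(x = tf_rf_factor(weights))
}
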
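#' Rank-sum significance filter
#'
#' Tests each feature column with a two-sided Wilcoxon rank-sum (Mann-Whitney)
#' test comparing its values in the two classes, using the normal approximation
#' with tie correction and continuity correction. Features with `p < alpha`
#' pass the filter ("valid features"); the rest are discarded before ranking.
#' A column constant across both groups has no evidence of a location shift and
#' gets `p = 1` (never selected) rather than an error.
#'
#' The filter runs on the weighted feature matrix, not raw counts, so the
#' weighting mode (TF vs TF-RF) can change which features survive.
#'
#' Implemented as a vectorized pass over columns for speed inside
#' cross-validation folds; it agrees with `stats::wilcox.test(..., exact =
#' FALSE, correct = TRUE)` and, in accept/reject decisions at small group
#' sizes, with the exact permutation test.
#'
#' @param X Feature matrix (documents x features), dense or sparse.
#' @param labels Class labels, exactly two distinct values, >= 2 documents per
#'   class.
#' @param alpha Significance level; default 0.05.
#' @param adjust P-value adjustment method passed to [stats::p.adjust()]
#'   before thresholding; default `"none"` (raw p < alpha, as the selection
#'   procedure specifies). `"BH"` gives a Benjamini-Hochberg variant.
#' @return List with `p_values` (length = number of features) and `valid_mask`
#'   (logical, `p < alpha` after any adjustment).
#' @export
ranksum_filter <- function(X, labels, alpha = 0.05, adjust = "none") {
  labels <- as.character(labels)
  if (length(unique(labels)) != 2) {
    stop_domain("rank-sum filter requires exactly two classes")
  }
  if (min(table(labels)) < 2) {
    stop_domain("rank-sum filter requires at least two documents per class")
  }
  Xd <- as.matrix(X)
  g1 <- labels == sort(unique(labels))[1]
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  p <- apply(Xd, 2, function(col) {
    r <- rank(col)
    w <- sum(r[g1])
    ties <- table(col)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    diff <- w - mu
    # continuity correction toward the null
    z <- (diff - sign(diff) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  })
  p <- stats::p.adjust(p, method = adjust)
  list(p_values = unname(p), valid_mask = unname(p < alpha))
}

#' Expected cross-entropy feature scores
#'
#' Scores each feature by
#' `ECE_i = p(t_i) * sum_j p(C_j | t_i) * log2( p(C_j | t_i) / p(C_j) )`,
#' i.e. the document frequency of the token times the Kullback-Leibler
#' divergence of the class posterior given the token from the class prior.
#' Presence (count > 0), not weighted values, defines "containing the token".
#' Terms with zero posterior contribute 0; a feature present in no document
#' scores 0; a feature whose posterior equals the prior (e.g. present in every
#' document) scores 0. Scores are always >= 0.
#'
#' @param X Feature or count matrix (documents x features); only `X > 0` is
#'   used.
#' @param labels Class labels (two or more classes).
#' @return Numeric vector of ECE scores, one per feature.
#' @export
ece_scores <- function(X, labels) {
  labels <- as.character(labels)
  if (nrow(X) == 0) stop_domain("empty training set")
  presence <- as.matrix(X > 0) * 1
  n <- nrow(presence)
  n_t <- colSums(presence)                  # documents containing each token
  p_t <- n_t / n
  classes <- sort(unique(labels))
  ece <- numeric(ncol(presence))
  for (cl in classes) {
    prior <- mean(labels == cl)
    n_t_c <- colSums(presence[labels == cl, , drop = FALSE])
    post <- ifelse(n_t > 0, n_t_c / n_t, 0)
    term <- ifelse(post > 0, post * log2(post / prior), 0)
    ece <- ece + term
  }
  unname(p_t * ece)
}

#' Retain the top fraction of valid features by ECE
#'
#' Sorts the features passing the rank-sum filter by ECE score, descending
#' (ties broken by vocabulary column order), and keeps
#' `max(1, floor(fraction * n_valid))` of them. Typical retention fractions
#' are 1.0, 0.75, 0.5 and 0.25.
#'
#' @param p_values,valid_mask Output of [ranksum_filter()].
#' @param ece Output of [ece_scores()].
#' @param fraction Retained proportion in (0, 1].
#' @param alpha Significance level used (recorded in the result).
#' @return A `selection_result`: list with `p_values`, `ece`, `valid_mask`,
#'   `selected` (ordered column indices), `alpha`, `fraction`. When no feature
#'   is valid, `selected` is empty and a warning is raised.
#' @export
select_top_fraction <- function(p_values, ece, valid_mask, fraction,
                                alpha = 0.05) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop_domain("fraction must lie in (0, 1]")
  }
  valid_idx <- which(valid_mask)
  if (length(valid_idx) == 0) {
    warning("no features passed the rank-sum filter; selection is empty")
    selected <- integer(0)
  } else {
    ord <- valid_idx[order(-ece[valid_idx], valid_idx)]
    k <- max(1L, floor(fraction * length(valid_idx)))
    selected <- ord[seq_len(k)]
  }
  structure(
    list(p_values = p_values, ece = ece, valid_mask = valid_mask,
         selected = selected, alpha = alpha, fraction = fraction),
    class = "selection_result"
  )
}

#' Two-step feature selection
#'
#' Runs the rank-sum filter at level `alpha` on the weighted feature matrix,
#' scores the features by expected cross-entropy on document presence, and
#' retains the top `fraction` of valid features. This is refit inside every
#' cross-validation training fold; it must never see test documents.
#'
#' @inheritParams ranksum_filter
#' @inheritParams select_top_fraction
#' @return A `selection_result` (see [select_top_fraction()]).
#' @export
select_features <- function(X, labels, alpha = 0.05, fraction = 1,
                            adjust = "none") {
  flt <- ranksum_filter(X, labels, alpha = alpha, adjust = adjust)
  ece <- ece_scores(X, labels)
  select_top_fraction(flt$p_values, ece, flt$valid_mask, fraction, alpha = alpha)
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", sum(x$valid_mask), "valid of", length(x$p_values),
      "features;", length(x$selected), "selected (fraction", x$fraction, ")\n")
  invisible(x)
}

#' Write a selection audit table
#'
#' TSV with one row per feature: token, rank-sum p-value, ECE score and
#' whether the feature was retained.
#'
#' @param sel A `selection_result`.
#' @param vocab The `vocabulary` whose columns were selected.
#' @param path Output TSV path.
#' @export
write_selection <- function(sel, vocab, path) {
  stopifnot(inherits(sel, "selection_result"), inherits(vocab, "vocabulary"))
  utils::write.table(
    data.frame(
      token = vocab$tokens,
      p_value = sel$p_values,
      ece = sel$ece,
      selected = seq_along(vocab$tokens) %in% sel$selected
    ),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
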
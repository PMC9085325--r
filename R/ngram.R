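#' Extract row-wise n-gram tokens from a character matrix
#'
#' Slides a window of length `n` from left to right along every row of the
#' character matrix, for each requested order `n`, and counts the resulting
#' tokens over the whole matrix. Windows have stride 1, never wrap across row
#' ends, and are never taken in the column direction: a token is a horizontal
#' run of `n` adjacent quantization letters. A row of width `W` contributes
#' `W - n + 1` tokens of order `n` (none when `W < n`).
#'
#' @param cm Character matrix from [quantize()].
#' @param orders Integer vector, a non-empty subset of `1:3`. Defaults to all
#'   three orders, bounding the vocabulary at `16 + 16^2 + 16^3 = 4368` tokens.
#' @return A `token_counts` object: list with `counts` (named integer vector,
#'   token -> occurrence count) and `total_tokens`.
#' @examples
#' cm <- quantize(matrix(0:15 * 16, 1, 16))
#' extract_tokens(cm, orders = 2)
#' @export
extract_tokens <- function(cm, orders = c(1L, 2L, 3L)) {
  check_char_matrix(cm)
  orders <- check_orders(orders)
  w <- ncol(cm)
  row_strings <- apply(cm, 1, paste0, collapse = "")
  pieces <- list()
  for (n in orders) {
    if (w < n) next
    starts <- seq_len(w - n + 1L)
    for (s in row_strings) {
      pieces[[length(pieces) + 1L]] <- substring(s, starts, starts + n - 1L)
    }
  }
  token_counts_from_vector(unlist(pieces))
}

check_orders <- function(orders) {
  if (length(orders) == 0) stop_domain("orders must be a non-empty subset of 1:3")
  orders <- sort(unique(as.integer(orders)))
  if (any(is.na(orders)) || !all(orders %in% 1:3)) {
    stop_domain("orders must be a non-empty subset of 1:3")
  }
  orders
}

token_counts_from_vector <- function(tokens) {
  if (length(tokens) == 0) {
    return(new_token_counts(integer(0)))
  }
  tab <- table(tokens)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  new_token_counts(counts)
}

new_token_counts <- function(counts) {
  structure(
    list(counts = counts, total_tokens = sum(counts)),
    class = "token_counts"
  )
}

#' @export
print.token_counts <- function(x, ...) {
  cat("<token_counts>", length(x$counts), "distinct tokens,",
      x$total_tokens, "total occurrences\n")
  invisible(x)
}

#' Tokenize a batch of gray images
#'
#' Convenience wrapper: quantizes each image and extracts its row-wise n-gram
#' token counts. Extraction is strictly per-image, so it can be done once for a
#' whole dataset without any train/test leakage.
#'
#' @param images List of gray-image matrices.
#' @inheritParams extract_tokens
#' @return List of `token_counts`, one per image.
#' @export
tokenize_images <- function(images, orders = c(1L, 2L, 3L)) {
  lapply(images, function(img) extract_tokens(quantize(img), orders = orders))
}

#' Build the training-set vocabulary
#'
#' The feature space is fixed by the training set: the vocabulary is the union
#' of all tokens observed in the training documents, ordered deterministically
#' by token length and then byte-wise lexicographically. Tokens never seen in
#' training are not representable, so unseen test-time tokens are dropped when
#' documents are projected onto the vocabulary.
#'
#' @param train_docs Non-empty list of `token_counts` (training documents).
#' @return A `vocabulary` object: list with `tokens` (ordered character vector).
#' @export
build_vocabulary <- function(train_docs) {
  if (length(train_docs) == 0) stop_domain("need at least one training document")
  tokens <- unique(unlist(lapply(train_docs, function(d) names(d$counts))))
  if (is.null(tokens)) tokens <- character(0)
  ord <- order(nchar(tokens), tokens, method = "radix")
  structure(list(tokens = tokens[ord]), class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary>", length(x$tokens), "tokens\n")
  invisible(x)
}

#' @export
length.vocabulary <- function(x) length(x$tokens)

#' Document-by-token count matrix
#'
#' Projects token-count documents onto a fixed vocabulary: entry `(j, i)` is
#' the occurrence count of vocabulary token `i` in document `j`. Tokens absent
#' from the vocabulary contribute nothing (the unseen-token rule). Stored
#' sparse.
#'
#' @param vocab A [build_vocabulary()] result.
#' @param docs List of `token_counts`.
#' @return A sparse `dgCMatrix` (documents x tokens) with tokens as column
#'   names.
#' @export
count_matrix <- function(vocab, docs) {
  stopifnot(inherits(vocab, "vocabulary"))
  nv <- length(vocab$tokens)
  ii <- integer(0); jj <- integer(0); xx <- integer(0)
  for (d in seq_along(docs)) {
    counts <- docs[[d]]$counts
    idx <- match(names(counts), vocab$tokens)
    keep <- !is.na(idx)
    if (any(keep)) {
      ii <- c(ii, rep.int(d, sum(keep)))
      jj <- c(jj, idx[keep])
      xx <- c(xx, counts[keep])
    }
  }
  Matrix::sparseMatrix(
    i = ii, j = jj, x = as.numeric(xx),
    dims = c(length(docs), nv),
    dimnames = list(NULL, vocab$tokens)
  )
}

#' Serialize vocabulary and count/feature matrices
#'
#' The vocabulary is written as a two-column TSV (`token`, `index`, 0-based);
#' matrices go to MatrixMarket format with the vocabulary TSV and a document-id
#' list alongside, so a feature store round-trips exactly.
#'
#' @param vocab A `vocabulary`.
#' @param path Output file path.
#' @return `path`, invisibly (writers); the reconstructed object (readers).
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "vocabulary"))
  utils::write.table(
    data.frame(token = vocab$tokens, index = seq_along(vocab$tokens) - 1L),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "integer"))
  structure(list(tokens = df$token[order(df$index)]), class = "vocabulary")
}

#' @rdname write_vocabulary
#' @param m Sparse documents-by-tokens matrix.
#' @param doc_ids Optional character vector of document identifiers.
#' @export
write_feature_store <- function(m, vocab, path, doc_ids = NULL) {
  Matrix::writeMM(methods::as(methods::as(m, "generalMatrix"), "TsparseMatrix"),
                  paste0(path, ".mtx"))
  write_vocabulary(vocab, paste0(path, ".vocab.tsv"))
  if (is.null(doc_ids)) doc_ids <- sprintf("doc%04d", seq_len(nrow(m)))
  writeLines(doc_ids, paste0(path, ".docs.txt"))
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_feature_store <- function(path) {
  m <- methods::as(Matrix::readMM(paste0(path, ".mtx")), "CsparseMatrix")
  vocab <- read_vocabulary(paste0(path, ".vocab.tsv"))
  doc_ids <- readLines(paste0(path, ".docs.txt"))
  colnames(m) <- vocab$tokens
  list(matrix = m, vocab = vocab, doc_ids = doc_ids)
}
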
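# Independent oracles and fixture builders shared across the suite.

# Brute-force row-wise n-gram enumerator: an explicit double loop over rows
# and window start positions, written independently of extract_tokens().
brute_force_tokens <- function(cm, orders = 1:3) {
  out <- character(0)
  for (i in seq_len(nrow(cm))) {
    for (n in orders) {
      w <- ncol(cm)
      if (w < n) next
      for (s in seq_len(w - n + 1)) {
        out <- c(out, paste0(cm[i, s:(s + n - 1)], collapse = ""))
      }
    }
  }
  out
}

# A token_counts object flattened back into a sorted token multiset.
token_multiset <- function(tc) {
  sort(rep(names(tc$counts), tc$counts))
}

random_char_matrix <- function(nr, nc) {
  matrix(sample(quant_alphabet(), nr * nc, replace = TRUE), nr, nc)
}

# Exact two-sided rank-sum permutation p-value: enumerate every assignment of
# the pooled ranks to group 1 and count rank sums at least as far from the
# null mean as observed.
exact_ranksum_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ws <- utils::combn(n, n1, function(ix) sum(r[ix]))
  mean(abs(ws - mu) >= abs(obs - mu) - 1e-9)
}

# Small separable two-class dataset used by several classifier tests.
small_binary_dataset <- function(n_per_class = 15, shape = c(16, 16), seed = 7) {
  make_dataset(demo_class_specs(2), n_per_class, shape = shape, seed = seed)
}
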
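test_that("rank-sum p-values match the reference normal-approximation test", {
  set.seed(101)
  labels <- rep(c("a", "b"), each = 12)
  X <- cbind(
    matrix(sample(0:6, 24 * 5, replace = TRUE), 24, 5),
    matrix(runif(24 * 5), 24, 5)
  )
  flt <- ranksum_filter(X, labels)
  for (j in seq_len(ncol(X))) {
    ref <- suppressWarnings(
      stats::wilcox.test(X[labels == "a", j], X[labels == "b", j],
                         exact = FALSE, correct = TRUE)$p.value
    )
    expect_equal(flt$p_values[j], ref, tolerance = 1e-12)
  }
})

test_that("degenerate columns get p = 1 and are never valid", {
  labels <- rep(c("a", "b"), each = 4)
  X <- cbind(rep(1, 8),                  # constant everywhere
             rep(c(1, 2, 3, 4), 2))      # identical samples in both groups
  flt <- ranksum_filter(X, labels)
  expect_equal(flt$p_values[1], 1)
  expect_gt(flt$p_values[2], 0.9)
  expect_false(any(flt$valid_mask))
})

test_that("complete separation at n = m = 4 matches the exact permutation p", {
  x <- c(1, 2, 3, 4); y <- c(10, 11, 12, 13)
  p_exact <- exact_ranksum_p(x, y)
  expect_equal(p_exact, 2 / choose(8, 4) * 1)   # only the two extreme splits
  flt <- ranksum_filter(matrix(c(x, y), ncol = 1), rep(c("a", "b"), each = 4))
  # approximation and exact test agree on rejection at alpha = 0.05
  expect_lt(flt$p_values[1], 0.05)
  expect_lt(p_exact, 0.05)
})

test_that("rank-sum accept/reject decisions track the exact permutation oracle", {
  set.seed(202)
  agree <- 0L; n_cases <- 200L
  for (i in seq_len(n_cases)) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    shift <- if (i %% 2 == 0) runif(1, 0, 2) else 0
    x <- runif(n1); y <- runif(n2) + shift
    p_approx <- ranksum_filter(matrix(c(x, y), ncol = 1),
                               rep(c("a", "b"), c(n1, n2)))$p_values
    p_exact <- exact_ranksum_p(x, y)
    agree <- agree + ((p_approx < 0.05) == (p_exact < 0.05))
  }
  expect_gte(agree / n_cases, 0.95)
})

test_that("ranksum_filter validates its inputs", {
  X <- matrix(runif(12), 6, 2)
  expect_error(ranksum_filter(X, rep("a", 6)), "two classes")
  expect_error(ranksum_filter(X, c("a", rep("b", 5))), "two documents")
})

test_that("ece follows p(t) times the posterior-prior KL divergence", {
  labels <- rep(c("c1", "c2"), each = 4)
  X <- cbind(
    rep(1, 8),                    # present everywhere: posterior = prior
    c(1, 1, 0, 0, 0, 0, 0, 0),    # only in half of class 1
    rep(0, 8)                     # absent everywhere
  )
  e <- ece_scores(X, labels)
  expect_equal(e[1], 0)
  expect_equal(e[2], 0.25 * log2(2))   # p(t) = 1/4, posterior (1, 0)
  expect_equal(e[3], 0)
})

test_that("ece scores are always nonnegative, also with three classes", {
  set.seed(33)
  labels <- rep(c("c1", "c2", "c3"), each = 5)
  for (i in 1:25) {
    X <- matrix(rbinom(15 * 8, 1, 0.4), 15, 8)
    expect_true(all(ece_scores(X, labels) >= -1e-12))
  }
})

test_that("top-fraction retention floors at one feature and sorts by ece", {
  p <- c(0.01, 0.02, 0.03, 0.2)
  ece <- c(0.1, 0.9, 0.5, 2.0)
  valid <- p < 0.05
  sel_all <- select_top_fraction(p, ece, valid, fraction = 1)
  expect_equal(sel_all$selected, c(2L, 3L, 1L))   # ece descending, valid only
  sel_half <- select_top_fraction(p, ece, valid, fraction = 0.5)
  expect_equal(sel_half$selected, 2L)             # floor(1.5) = 1
  sel_q <- select_top_fraction(p, ece, valid, fraction = 0.25)
  expect_equal(sel_q$selected, 2L)                # max(1, floor(0.75))
  expect_error(select_top_fraction(p, ece, valid, fraction = 0), "fraction")
  expect_warning(
    empty <- select_top_fraction(p, ece, rep(FALSE, 4), fraction = 1),
    "no features"
  )
  expect_length(empty$selected, 0)
})

test_that("ece ties break deterministically by column order", {
  p <- rep(0.01, 4); ece <- c(0.5, 0.5, 0.5, 0.5)
  sel <- select_top_fraction(p, ece, rep(TRUE, 4), fraction = 0.5)
  expect_equal(sel$selected, c(1L, 2L))
})

test_that("rank-sum pass rate on exchangeable labels is near alpha", {
  spec <- class_spec("null", background_bins = 0:7, motif = c(9L, 10L, 11L),
                     motif_rate = 0)
  imgs <- lapply(seq_len(60), function(i) make_image(spec, 24, 24, seed = 500 + i))
  docs <- tokenize_images(imgs)
  vocab <- build_vocabulary(docs)
  X <- tf(count_matrix(vocab, docs))
  labels <- rep(c("g1", "g2"), 30)
  flt <- ranksum_filter(X, labels, alpha = 0.05)
  expect_gte(length(flt$p_values), 500)
  expect_gte(mean(flt$valid_mask), 0.01)
  expect_lte(mean(flt$valid_mask), 0.10)
})

test_that("selection audit TSV records every feature", {
  ds <- small_binary_dataset(n_per_class = 6, shape = c(8, 12), seed = 3)
  docs <- tokenize_images(ds$images)
  vocab <- build_vocabulary(docs)
  X <- tf(count_matrix(vocab, docs))
  sel <- select_features(X, ds$labels, fraction = 0.5)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_selection(sel, vocab, path)
  audit <- read.delim(path)
  expect_equal(nrow(audit), length(vocab))
  expect_equal(sum(audit$selected), length(sel$selected))
  expect_setequal(audit$token[audit$selected], vocab$tokens[sel$selected])
})
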
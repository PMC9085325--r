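# Minimal seeded feed-forward network for the backpropagation classifier:
# tanh hidden layers, sigmoid output, squared-error loss, full-batch gradient
# descent. Written in-package because the configured topology has several
# hidden layers; the network is tiny (default 3-6-3 hidden units), so plain R
# matrix algebra is ample.

mlp_init <- function(sizes, seed) {
  with_seed(seed, {
    lapply(seq_len(length(sizes) - 1), function(l) {
      list(
        W = matrix(stats::rnorm(sizes[l] * sizes[l + 1], sd = 1 / sqrt(sizes[l])),
                   sizes[l], sizes[l + 1]),
        b = numeric(sizes[l + 1])
      )
    })
  })
}

mlp_forward <- function(layers, X) {
  acts <- list(X)
  nl <- length(layers)
  for (l in seq_len(nl)) {
    z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    acts[[l + 1]] <- if (l < nl) tanh(z) else 1 / (1 + exp(-z))
  }
  acts
}

mlp_train <- function(X, y, hidden = c(3, 6, 3), epochs = 100, goal = 1e-5,
                      learning_rate = 0.01, seed = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  sizes <- c(ncol(X), hidden, 1L)
  layers <- mlp_init(sizes, seed)
  n <- nrow(X)
  for (ep in seq_len(epochs)) {
    acts <- mlp_forward(layers, X)
    out <- acts[[length(acts)]]
    err <- out - y
    mse <- mean(err^2)
    if (mse <= goal) break
    # output layer: d(mse)/dz = 2/n * err * sigmoid'(z)
    delta <- (2 / n) * err * out * (1 - out)
    for (l in rev(seq_along(layers))) {
      gW <- crossprod(acts[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(layers[[l]]$W)) * (1 - acts[[l]]^2)
      }
      layers[[l]]$W <- layers[[l]]$W - learning_rate * gW
      layers[[l]]$b <- layers[[l]]$b - learning_rate * gb
    }
  }
  structure(list(layers = layers, sizes = sizes), class = "ngram_mlp")
}

mlp_score <- function(model, X) {
  acts <- mlp_forward(model$layers, as.matrix(X))
  as.numeric(acts[[length(acts)]])
}
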
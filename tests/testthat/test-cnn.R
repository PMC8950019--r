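# Engine-level checks against brute-force oracles, then training behaviour.

brute_conv <- function(x, W, b, kernel, pad) {
  h <- dim(x)[1]; w <- dim(x)[2]; cc <- dim(x)[3]; oc <- length(b)
  xp <- array(0, dim = c(h + 2 * pad, w + 2 * pad, cc))
  xp[pad + seq_len(h), pad + seq_len(w), ] <- x
  oh <- h + 2 * pad - kernel + 1; ow <- w + 2 * pad - kernel + 1
  out <- array(0, dim = c(oh, ow, oc))
  for (k in seq_len(oc)) for (i in seq_len(oh)) for (j in seq_len(ow)) {
    s <- 0; m <- 0
    for (ci in seq_len(cc)) for (kj in seq_len(kernel)) for (ki in seq_len(kernel)) {
      m <- m + 1
      s <- s + W[m, k] * xp[i + ki - 1, j + kj - 1, ci]
    }
    out[i, j, k] <- s + b[k]
  }
  out
}

brute_pool <- function(x, k) {
  h <- dim(x)[1]; w <- dim(x)[2]; cc <- dim(x)[3]
  oh <- h %/% k; ow <- w %/% k
  out <- array(0, dim = c(oh, ow, cc))
  for (ci in seq_len(cc)) for (i in seq_len(oh)) for (j in seq_len(ow))
    out[i, j, ci] <- max(x[(i - 1) * k + seq_len(k), (j - 1) * k + seq_len(k), ci])
  out
}

test_that("convolution layers equal a scalar-loop oracle", {
  set.seed(21)
  for (pad in c(0L, 1L)) {
    net <- mitransfer:::build_network(
      c(6, 6, 2),
      list(mitransfer:::layer_conv(3, 4, pad = pad)), seed = 77)
    L <- net$layers[[1]]
    x <- array(rnorm(72), dim = c(6, 6, 2))
    got <- mitransfer:::conv_forward(as.numeric(x), L)$out
    want <- brute_conv(x, L$Wmat, L$b, 3, pad)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("max pooling equals a sliding-window maximum oracle", {
  set.seed(22)
  net <- mitransfer:::build_network(c(6, 6, 3),
                                    list(mitransfer:::layer_pool(2)), seed = 1)
  x <- array(rnorm(108), dim = c(6, 6, 3))
  got <- mitransfer:::pool_forward(as.numeric(x), net$layers[[1]])$out
  expect_equal(got, brute_pool(x, 2), tolerance = 0)
  # odd input size: trailing row/column dropped
  net5 <- mitransfer:::build_network(c(5, 5, 1),
                                     list(mitransfer:::layer_pool(2)), seed = 1)
  x5 <- array(rnorm(25), dim = c(5, 5, 1))
  got5 <- mitransfer:::pool_forward(as.numeric(x5), net5$layers[[1]])$out
  expect_equal(got5, brute_pool(x5[1:4, 1:4, , drop = FALSE], 2), tolerance = 0)
})

test_that("ReLU and softmax behave pointwise as defined", {
  x <- c(-2, -0.5, 0, 0.5, 3)
  expect_equal(pmax(x, 0), c(0, 0, 0, 0.5, 3))        # h(x) = max(0, x)
  z <- c(0.3, -1.2)
  s <- mitransfer:::softmax(z)
  expect_equal(s, exp(z) / sum(exp(z)), tolerance = 1e-14)
  expect_equal(sum(s), 1, tolerance = 1e-14)
  # large logits do not overflow
  expect_equal(sum(mitransfer:::softmax(c(1000, 999))), 1, tolerance = 1e-12)
})

test_that("backpropagation matches finite differences", {
  set.seed(23)
  layers <- list(mitransfer:::layer_conv(3, 2, pad = 1),
                 mitransfer:::layer_relu(),
                 mitransfer:::layer_pool(2),
                 mitransfer:::layer_dense(2))
  net <- mitransfer:::build_network(c(4, 4, 1), layers, seed = 11)
  x <- array(rnorm(16), dim = c(4, 4, 1)); y <- 1L
  fw <- mitransfer:::net_forward(net, x)
  p <- mitransfer:::softmax(fw$logits)
  g <- mitransfer:::net_backward(net, fw$caches, p, c(1, 0))
  lossfun <- function(n) {
    -log(mitransfer:::softmax(mitransfer:::net_forward(n, x)$logits)[y])
  }
  eps <- 1e-6
  for (i in c(1, 4)) {
    W <- net$layers[[i]]$Wmat
    for (j in seq_len(min(8, length(W)))) {
      n2 <- net
      n2$layers[[i]]$Wmat[j] <- W[j] + eps; up <- lossfun(n2)
      n2$layers[[i]]$Wmat[j] <- W[j] - eps; dn <- lossfun(n2)
      expect_equal(g[[i]]$dW[j], (up - dn) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("an all-zero grid with zero biases scores both classes equally", {
  net <- mitransfer:::build_network(
    c(4, 4, 1),
    list(mitransfer:::layer_conv(3, 4, pad = 1), mitransfer:::layer_relu(),
         mitransfer:::layer_pool(2), mitransfer:::layer_dense(2)), seed = 3)
  logits <- mitransfer:::net_forward(net, array(0, dim = c(4, 4, 1)))$logits
  expect_equal(mitransfer:::softmax(logits), c(0.5, 0.5), tolerance = 1e-14)
})

test_that("training is deterministic and fits a separable fixture perfectly", {
  set.seed(5)
  n <- 20
  grids <- lapply(seq_len(n), function(i) {
    cls <- ((i - 1) %% 2) + 1
    base <- matrix(rnorm(16, 0, 0.3), 4, 4) + ifelse(cls == 1, 1.5, -1.5)
    reshape_features(as.numeric(t(base)))
  })
  labs <- rep(c("class1", "class2"), n / 2)
  cfg <- cnn_config(learning_rate = 0.05, epochs = 30, seed = 2)
  m1 <- train_cnn(grids, labs, cfg)
  m2 <- train_cnn(grids, labs, cfg)
  expect_identical(m1$net, m2$net)
  expect_identical(m1$training_log, m2$training_log)
  expect_equal(length(m1$training_log), 30L)
  pred <- predict(m1, grids)
  expect_equal(mean(pred$labels == labs), 1)
  expect_equal(unname(rowSums(pred$scores)), rep(1, n), tolerance = 1e-6)
})

test_that("the published training recipe is the default configuration", {
  cfg <- cnn_config()
  expect_equal(cfg$learning_rate, 0.4)
  expect_equal(cfg$epochs, 160L)
  expect_equal(cfg$batch_size, 1L)
})

test_that("prediction handles empty input and rejects single-class training", {
  set.seed(6)
  grids <- lapply(1:4, function(i) reshape_features(rnorm(16)))
  m <- train_cnn(grids, c("class1", "class2", "class1", "class2"),
                 cnn_config(epochs = 2, learning_rate = 0.05, seed = 1))
  empty <- predict(m, list())
  expect_length(empty$labels, 0)
  expect_equal(nrow(empty$scores), 0)
  expect_error(train_cnn(grids, rep("class1", 4), cnn_config(epochs = 1)),
               "both classes")
})
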
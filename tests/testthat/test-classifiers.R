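test_that("feature grids fill row-major with zero padding and round-trip", {
  g <- reshape_features(seq_len(100), grid_side = 10)
  expect_equal(dim(g$grid), c(10L, 10L))
  expect_equal(g$pad_count, 0L)
  expect_equal(g$grid[1, ], as.numeric(1:10))       # row-major fill

  g14 <- reshape_features(seq_len(14), grid_side = 4)
  expect_equal(g14$pad_count, 2L)
  expect_equal(g14$grid[4, 3:4], c(0, 0))
  expect_equal(flatten_grid(g14), as.numeric(1:14))

  # default side is the smallest fitting square
  expect_equal(dim(reshape_features(rnorm(14))$grid), c(4L, 4L))
  expect_error(reshape_features(seq_len(17), grid_side = 4), "cannot hold")
})

test_that("the SVM baseline separates 1-D classes and is deterministic", {
  set.seed(31)
  f <- matrix(c(rnorm(20, -1, 0.1), rnorm(20, 1, 0.1)), ncol = 1)
  labs <- rep(c("class1", "class2"), each = 20)
  m <- train_svm_baseline(f, labs)
  held <- matrix(c(-0.9, 1.1, -1.2, 0.8), ncol = 1)
  pr <- predict(m, held)
  expect_equal(pr$labels, c("class1", "class2", "class1", "class2"))
  expect_equal(unname(rowSums(pr$scores)), rep(1, 4), tolerance = 1e-6)

  m2 <- train_svm_baseline(f, labs)
  expect_equal(m$svm$coefs, m2$svm$coefs)
  expect_identical(predict(m, held), predict(m2, held))
  expect_error(train_svm_baseline(f, rep("class1", 40)), "both classes")
})

test_that("a linear SVM cannot solve XOR (matching the exhaustive threshold bound)", {
  xor_f <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  xor_f <- xor_f[rep(1:4, each = 10), ] + matrix(rnorm(80, 0, 0.02), 40, 2)
  labs <- rep(c("class1", "class1", "class2", "class2"), each = 10)
  m <- train_svm_baseline(xor_f, labs, kernel = "linear")
  acc <- mean(predict(m, xor_f)$labels == labs)
  # oracle: best single-feature threshold achieves at most 0.75 on XOR
  best <- 0
  for (j in 1:2) for (th in sort(xor_f[, j])) {
    p <- xor_f[, j] <= th
    best <- max(best, mean((p == (labs == "class1"))), mean(p == (labs == "class2")))
  }
  expect_lte(best, 0.75 + 1e-9)
  expect_lte(acc, 0.75)
})

test_that("the fine-tuning network has the described depth and a 2-way softmax", {
  arch <- ftcnn_architecture(input_side = 32, kernels = c(5, 3, 3, 3, 3, 3),
                             channels = c(8, 8, 8, 16, 16, 32),
                             pads = c(2, 1, 1, 1, 1, 1))
  types <- vapply(arch, `[[`, character(1), "type")
  expect_equal(sum(types == "conv"), 6L)
  expect_equal(sum(types == "pool"), 5L)
  net <- mitransfer:::build_network(c(32, 32, 1), arch, seed = 1)
  expect_equal(net$output_units, 2L)
  # standard convolution arithmetic at the described 250x250 scale
  sizes <- c(250, 242, 121, 113, 105, 52, 48, 24, 24, 12, 6)
  shape <- c(250, 250, 1)
  for (L in ftcnn_architecture()) {
    if (L$type == "conv") shape <- c(shape[1] + 2 * L$pad - L$kernel + 1,
                                     shape[2] + 2 * L$pad - L$kernel + 1,
                                     L$out_channels)
    if (L$type == "pool") shape <- c(shape[1] %/% 2, shape[2] %/% 2, shape[3])
  }
  expect_equal(shape[1:2], c(6, 6))
})

test_that("frozen layers are bit-identical after fine-tuning", {
  bm <- make_transfer_benchmark(1, 1, base = tiny_model(),
                                n_trials_per_class = 6, trial_len_s = 1, seed = 3)
  m <- train_ftcnn_baseline(bm$source, bm$target, freeze_depth = 5,
                            epochs = 2, batch_size = 4, seed = 9)
  expect_length(m$frozen_layers, 5L)
  for (i in m$frozen_layers) {
    expect_identical(m$net$layers[[i]]$Wmat, m$pretrain_net$layers[[i]]$Wmat)
    expect_identical(m$net$layers[[i]]$b, m$pretrain_net$layers[[i]]$b)
  }
  # an unfrozen parameterized layer did change
  dense_i <- length(m$net$layers)
  expect_false(identical(m$net$layers[[dense_i]]$Wmat,
                         m$pretrain_net$layers[[dense_i]]$Wmat))

  m0 <- train_ftcnn_baseline(bm$source, bm$target, freeze_depth = 0,
                             epochs = 1, batch_size = 4, seed = 9)
  expect_length(m0$frozen_layers, 0L)
  expect_error(train_ftcnn_baseline(bm$source, bm$target, freeze_depth = 8,
                                    epochs = 1, seed = 9),
               "exceeds the .* parameterized layers")
})

test_that("trial rendering averages the time axis and interpolates channels", {
  X <- matrix(rep(c(1, 3), each = 8), 2, 8, byrow = TRUE)  # ch1 = 1, ch2 = 3
  img <- mitransfer:::render_trial_image(X, 4)
  expect_equal(dim(img), c(4, 4, 1))
  expect_equal(img[1, , 1], rep(1, 4))        # first channel row
  expect_equal(img[4, , 1], rep(3, 4))        # last channel row
  expect_true(all(img[2, , 1] > 1 & img[2, , 1] < 3))
  # block averaging: a spike is averaged into its window, not point-sampled
  Xs <- matrix(0, 2, 8); Xs[1, 3] <- 8
  img2 <- mitransfer:::render_trial_image(Xs, 4)
  expect_equal(img2[1, 2, 1], 4)              # window {3,4} mean = 8/2
})
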
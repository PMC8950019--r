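# helpers: labeled two-class sets with controllable covariance structure
labeled_set <- function(n = 10, M = 4, N = 80, seed = 1, contrast = 3) {
  mitransfer:::with_seed(seed, {
    A1 <- diag(c(rep(sqrt(contrast), M %/% 2), rep(1, M - M %/% 2)))
    A2 <- diag(c(rep(1, M %/% 2), rep(sqrt(contrast), M - M %/% 2)))
    R <- qr.Q(qr(matrix(rnorm(M * M), M)))   # shared mixing rotation
    trialset(lapply(seq_len(n), function(i) {
      cls <- if (i %% 2 == 1) "class1" else "class2"
      A <- if (cls == "class1") A1 else A2
      trial(R %*% A %*% matrix(rnorm(M * N), M, N), label = cls, fs = 100)
    }))
  })
}

test_that("class mean covariance is trace-normalized and hand-checkable", {
  X <- matrix(c(1, 0, 2, 1, 0, 1), 2, 3)
  t1 <- trial(X, label = "class1", fs = 100)
  ts <- trialset(list(t1, trial(X, label = "class1", fs = 100)))
  C <- class_mean_covariance(ts, "class1")
  expect_equal(sum(diag(C)), 1, tolerance = 1e-10)
  # identical trials: same as the single-trial normalized covariance
  expect_equal(C, matrix(c(5, 2, 2, 2), 2, 2) / 7, tolerance = 1e-12)

  # two distinct trials, hand-computed average
  Y <- matrix(c(1, 1, 0, 1, 1, 0), 2, 3)     # rows (1,0,1), (1,1,0)
  ts2 <- trialset(list(t1, trial(Y, label = "class1", fs = 100)))
  SY <- Y %*% t(Y)
  expect_equal(class_mean_covariance(ts2, "class1"),
               (matrix(c(5, 2, 2, 2), 2, 2) / 7 + SY / sum(diag(SY))) / 2,
               tolerance = 1e-12)
  expect_error(class_mean_covariance(ts2, "class2"), "no trials")
})

test_that("already-diagonal class covariances give axis-aligned filters", {
  ts <- trialset(list(
    diag_cov_trial(c(0.8, 0.2), "class1"),
    diag_cov_trial(c(0.2, 0.8), "class2")))
  fit <- fit_csp(ts, m_pairs = 1)
  expect_equal(sort(fit$eigvals_class1, decreasing = TRUE), c(0.8, 0.2),
               tolerance = 1e-8)
  # each filter row is proportional to a coordinate axis
  Wn <- abs(fit$W / sqrt(rowSums(fit$W^2)))
  expect_equal(sort(apply(Wn, 1, max)), c(1, 1), tolerance = 1e-8)
})

test_that("indistinguishable classes yield eigenvalues near one half", {
  ts <- labeled_set(n = 60, M = 4, N = 120, seed = 8, contrast = 1)
  fit <- fit_csp(ts)
  expect_true(all(abs(fit$eigvals_class1 - 0.5) < 0.1))
})

test_that("the decomposition satisfies the whitening and eigen-sum identities", {
  for (seed in 1:5) {
    ts <- labeled_set(n = 12, M = 5, N = 90, seed = seed)
    fit <- fit_csp(ts, m_pairs = 2)
    d <- fit$decomposition
    M <- 5
    expect_lt(norm(d$P %*% d$Cc %*% t(d$P) - diag(M), "F"), 1e-8)
    expect_lt(max(abs(d$lambda1 + d$lambda2 - 1)), 1e-8)
    expect_true(all(d$lambda1 >= -1e-10 & d$lambda1 <= 1 + 1e-10))
    # simultaneous diagonalization of both class covariances
    D1 <- d$W_full %*% d$C1 %*% t(d$W_full)
    D2 <- d$W_full %*% d$C2 %*% t(d$W_full)
    expect_lt(max(abs(D1[upper.tri(D1)]), abs(D1[lower.tri(D1)])), 1e-8)
    expect_lt(max(abs(D2[upper.tri(D2)]), abs(D2[lower.tri(D2)])), 1e-8)
    expect_equal(qr(fit$W)$rank, 4L)
  }
})

test_that("fitted filters match an independent generalized-eigenproblem oracle", {
  for (seed in 1:20) {
    M <- sample(3:6, 1)
    ts <- labeled_set(n = 14, M = M, N = 100, seed = 100 + seed)
    fit <- fit_csp(ts)
    d <- fit$decomposition
    # oracle: eigenvectors of Cc^{-1} C1 (generalized problem C1 v = mu Cc v)
    ev <- eigen(solve(d$Cc) %*% d$C1)
    ord <- order(Re(ev$values), decreasing = TRUE)
    V <- Re(ev$vectors[, ord, drop = FALSE])
    for (r in seq_len(M)) {
      w <- d$W_full[r, ]
      v <- V[, r]
      cosim <- abs(sum(w * v)) / sqrt(sum(w^2) * sum(v^2))
      expect_gt(cosim, 1 - 1e-6)
    }
    expect_equal(d$lambda1, Re(ev$values[ord]), tolerance = 1e-8)
  }
})

test_that("projection is an exact matrix product", {
  ts <- labeled_set(n = 4, M = 3, N = 30, seed = 2)
  fit <- fit_csp(ts, m_pairs = 1)
  t1 <- ts$trials[[1]]
  expect_equal(csp_project(fit, t1), fit$W %*% t1$data)

  # identity-filter bank selects channels; zero trial projects to zero
  bank <- structure(list(W = diag(2), m_pairs = 1L, n_channels = 2L),
                    class = "mi_csp")
  tz <- trial(matrix(0, 2, 6), fs = 100)
  expect_identical(csp_project(bank, tz), matrix(0, 2, 6))
  th <- trial(matrix(c(1, 3, 2, 4), 2, 2), fs = 100)
  expect_equal(csp_project(bank, th), th$data)
  W2 <- matrix(c(1, 0, 1, 1), 2, 2, byrow = TRUE)
  bank2 <- structure(list(W = W2, m_pairs = 1L, n_channels = 2L), class = "mi_csp")
  expect_equal(csp_project(bank2, th), W2 %*% th$data)  # hand: rows (3,6),(4,6)
  expect_error(csp_project(bank, trial(matrix(0, 3, 6), fs = 100)), "channels")
})

test_that("log-variance features normalize exactly as specified", {
  # rows with population variances 3 and 1 -> features log .75, log .25
  bank <- structure(list(W = diag(2), m_pairs = 1L, n_channels = 2L),
                    class = "mi_csp")
  a <- sqrt(3)
  t1 <- trial(rbind(c(-a, a), c(-1, 1)), fs = 100)
  expect_equal(extract_features(bank, t1), c(log(0.75), log(0.25)),
               tolerance = 1e-12)

  # equal variances -> every feature log(1/2m)
  t2 <- trial(rbind(c(-1, 1), c(1, -1)), fs = 100)
  expect_equal(extract_features(bank, t2), rep(log(0.5), 2), tolerance = 1e-12)

  # random case against a scalar re-computation oracle
  ts <- labeled_set(n = 6, M = 4, N = 50, seed = 31)
  fit <- fit_csp(ts)
  fv <- extract_features(fit, ts$trials[[3]])
  Z <- fit$W %*% ts$trials[[3]]$data
  v <- numeric(nrow(Z))
  for (r in seq_len(nrow(Z))) {
    mu <- sum(Z[r, ]) / ncol(Z)
    v[r] <- sum((Z[r, ] - mu)^2) / ncol(Z)
  }
  expect_equal(fv, log(v / sum(v)), tolerance = 1e-12)
  expect_equal(sum(exp(fv)), 1, tolerance = 1e-10)

  tz <- trial(matrix(0, 4, 10), fs = 100)
  expect_error(extract_features(fit, tz), "zero-variance")
})

test_that("feature tables preserve order and separate the classes", {
  ts <- labeled_set(n = 30, M = 4, N = 100, seed = 44)
  fit <- fit_csp(ts)
  tab <- featurize_trialset(fit, ts)
  expect_equal(dim(tab$features), c(30L, 4L))
  expect_identical(tab$labels, labels_of(ts))

  # permutation equivariance
  perm <- rev(seq_len(30))
  ts_perm <- ts; ts_perm$trials <- ts$trials[perm]
  tab_perm <- featurize_trialset(fit, ts_perm)
  expect_equal(tab_perm$features, tab$features[perm, ])

  # brute-force best single threshold on feature 1 beats chance comfortably
  f1 <- tab$features[, 1]
  y <- tab$labels == "class1"
  accs <- vapply(sort(f1), function(th)
    max(mean((f1 <= th) == y), mean((f1 > th) == y)), numeric(1))
  expect_gt(max(accs), 0.8)
})

test_that("CSP features are invariant to channel mixing after refitting", {
  # Trace normalization of each trial covariance makes the invariance exact
  # only for trace-preserving (orthogonal, possibly scaled) transforms; for
  # general invertible mixing the per-trial normalizers change and the
  # invariance is approximate.
  ts <- labeled_set(n = 20, M = 4, N = 120, seed = 55)
  f1 <- featurize_trialset(fit_csp(ts), ts)$features

  Q <- qr.Q(qr(matrix(sin(1:16 * 2.3), 4, 4)))    # orthogonal, times a scalar
  ts_o <- ts
  ts_o$trials <- lapply(ts$trials, function(t) { t$data <- 1.7 * Q %*% t$data; t })
  f_o <- featurize_trialset(fit_csp(ts_o), ts_o)$features
  expect_equal(f1, f_o, tolerance = 1e-6)

  Tmat <- matrix(c(2, 0.3, -0.5, 0.1,
                   0.2, 1.5, 0.4, -0.3,
                   0, 0.2, 1.2, 0.5,
                   0.4, -0.1, 0.3, 0.9), 4, 4, byrow = TRUE)
  ts_g <- ts
  ts_g$trials <- lapply(ts$trials, function(t) { t$data <- Tmat %*% t$data; t })
  f_g <- featurize_trialset(fit_csp(ts_g), ts_g)$features
  expect_equal(f1, f_g, tolerance = 0.15)
})

test_that("invalid CSP requests fail loudly", {
  ts <- labeled_set(n = 6, M = 4, N = 40, seed = 3)
  expect_error(fit_csp(ts, m_pairs = 3), "exceeds the channel count")
  unlab <- random_trialset(n = 4, M = 4, N = 40)
  expect_error(fit_csp(unlab), "both classes")
})
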
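# Shared fixtures, built in code at test time.

# Small random trial set (nondegenerate, unlabeled by default).
random_trialset <- function(n = 6, M = 3, N = 64, fs = 100, seed = 1,
                            labels = NULL, subjects = NULL) {
  if (is.null(labels)) labels <- rep("unlabeled", n)
  if (is.null(subjects)) subjects <- rep("s1", n)
  mitransfer:::with_seed(seed, {
    trialset(lapply(seq_len(n), function(i)
      trial(matrix(rnorm(M * N), M, N), label = labels[i],
            subject = subjects[i], fs = fs)))
  })
}

# Compact subject model: 4 channels, 2 band-limited sources with strong
# ERD-style contrast; cheap enough for per-test simulation.
tiny_model <- function(noise_sd = 0.3, seed = 5) {
  mixing <- mitransfer:::with_seed(seed, {
    A <- matrix(rnorm(8), 4, 2)
    sweep(A, 2, sqrt(colSums(A^2)), "/")
  })
  subject_model(mixing, bands = rbind(c(8, 12), c(13, 22)),
                var_class1 = c(4, 1), var_class2 = c(1, 3),
                noise_sd = noise_sd, fs = 100)
}

# Strongly separable 15-channel model for classifier sanity runs.
separable_model <- function() {
  mixing <- mitransfer:::with_seed(42, {
    A <- matrix(rnorm(15 * 3), 15, 3)
    sweep(A, 2, sqrt(colSums(A^2)), "/") * sqrt(5)
  })
  subject_model(mixing, bands = rbind(c(8, 12), c(13, 22), c(8, 22)),
                var_class1 = c(8, 0.5, 1), var_class2 = c(0.5, 5, 1),
                noise_sd = 0.2, fs = 100)
}

# Trials whose trace-normalized covariance is exactly the given diagonal.
diag_cov_trial <- function(d, label, fs = 100) {
  M <- length(d)
  N <- 2 * M
  Q <- qr.Q(qr(matrix(seq_len(N * M) %% 7 + cos(seq_len(N * M)), N, M)))
  trial(diag(sqrt(d), M) %*% t(Q), label = label, fs = fs)
}

# FFT band energy of a real signal between lo and hi Hz (inclusive).
fft_band_energy <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  half <- f <= fs / 2
  sum(p[half & f >= lo & f <= hi])
}
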
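# Discrete wavelet band denoising.
#
# Denoising is pure band selection: each channel is decomposed with an
# orthogonal decimated DWT, rhythm-relevant detail bands are retained, all
# other coefficients are zeroed, and the signal is reconstructed. No
# coefficient shrinkage is applied. Boundaries are handled by periodic
# extension, so the transform is exactly orthogonal and reconstruction with
# all bands retained is exact to machine precision.

# Orthonormal scaling filters, full double precision. g is derived as the
# quadrature mirror g[n] = (-1)^n h[L-1-n].
WAVELET_FILTERS <- list(
  haar = c(0.70710678118654746, 0.70710678118654746),
  db6 = c(0.11154074335010947, 0.49462389039845306, 0.75113390802109536,
          0.31525035170919763, -0.22626469396543983, -0.12976686756726194,
          0.097501605587323043, 0.027522865530305727, -0.03158203931748603,
          0.00055384220116149613, 0.0047772575109455108,
          -0.0010773010853084796))

qmf <- function(h) rev(h) * (-1)^(seq_along(h) - 1)

#' Nominal dyadic frequency bands of a wavelet decomposition
#'
#' Detail level `D_k` nominally covers `(fs/2^(k+1), fs/2^k)` Hz and the
#' approximation `A_n` covers `(0, fs/2^(n+1))` Hz.
#'
#' @param fs sampling rate, Hz.
#' @param n_levels decomposition depth.
#' @return A data frame with columns `level` (`"D1"`..`"Dn"`, `"An"`),
#'   `low_hz`, `high_hz`.
#' @export
wavelet_bands <- function(fs, n_levels) {
  k <- seq_len(n_levels)
  data.frame(
    level = c(paste0("D", k), paste0("A", n_levels)),
    low_hz = c(fs / 2^(k + 1), 0),
    high_hz = c(fs / 2^k, fs / 2^(n_levels + 1)),
    stringsAsFactors = FALSE)
}

auto_levels <- function(fs, low_cut = 6.25) {
  # deepest level such that the approximation band tops out at <= low_cut
  max(1L, ceiling(log2(fs / low_cut)) - 1L)
}

#' Configure the wavelet band-denoising step
#'
#' The default retains the detail levels whose nominal dyadic band overlaps
#' the mu/beta range (6.25-25 Hz at 100 Hz sampling: levels `D2` and `D3` of
#' a 3-level decomposition, nominal 6.25-25 Hz). The decomposition depth is
#' derived from `fs` when `n_levels = "auto"` so that the approximation band
#' falls below the retained range.
#'
#' @param fs sampling rate, Hz.
#' @param wavelet `"db6"` (default) or `"haar"`.
#' @param n_levels integer depth, or `"auto"`.
#' @param retained_hz numeric length-2 frequency interval in Hz; levels whose
#'   nominal band overlaps it with positive length are retained. Ignored when
#'   `retained_levels` is given.
#' @param retained_levels explicit character vector of levels, e.g.
#'   `c("D2", "D3")` or `"A3"`.
#' @return An object of class `mi_wavelet_config`.
#' @export
wavelet_config <- function(fs, wavelet = "db6", n_levels = "auto",
                           retained_hz = c(6.25, 25), retained_levels = NULL) {
  wavelet <- match.arg(wavelet, names(WAVELET_FILTERS))
  if (identical(n_levels, "auto")) n_levels <- auto_levels(fs)
  n_levels <- as.integer(n_levels)
  if (n_levels < 1L) stop("`n_levels` must be >= 1")
  bands <- wavelet_bands(fs, n_levels)
  if (is.null(retained_levels)) {
    overlap <- pmin(bands$high_hz, retained_hz[2]) - pmax(bands$low_hz, retained_hz[1])
    retained_levels <- bands$level[overlap > 0]
  } else {
    bad <- setdiff(retained_levels, bands$level)
    if (length(bad) > 0L)
      stop("invalid retained level(s) ", paste(bad, collapse = ", "),
           "; valid levels: ", paste(bands$level, collapse = ", "))
  }
  structure(list(wavelet = wavelet, n_levels = n_levels, fs = fs,
                 retained_levels = retained_levels, bands = bands),
            class = "mi_wavelet_config")
}

#' @export
print.mi_wavelet_config <- function(x, ...) {
  cat(sprintf("<mi_wavelet_config> %s, %d levels @ %g Hz\n",
              x$wavelet, x$n_levels, x$fs))
  kept <- x$bands$level %in% x$retained_levels
  cat(sprintf("  %s %-3s %6.3g-%.3g Hz\n",
              ifelse(kept, "keep", "drop"), x$bands$level,
              x$bands$low_hz, x$bands$high_hz), sep = "")
  invisible(x)
}

# One periodic analysis step: x (length N, even) -> approx/detail (N/2 each).
dwt_step <- function(x, h, g) {
  N <- length(x)
  L <- length(h)
  # idx[k, m] = (2(k-1) + (m-1)) mod N, 1-based
  idx <- (outer(2L * (seq_len(N %/% 2L) - 1L), seq_len(L) - 1L, "+") %% N) + 1L
  Xs <- matrix(x[idx], nrow = N %/% 2L)
  list(approx = as.numeric(Xs %*% h), detail = as.numeric(Xs %*% g))
}

# Inverse of dwt_step (exact, by orthogonality).
idwt_step <- function(approx, detail, h, g) {
  N <- 2L * length(approx)
  L <- length(h)
  x <- numeric(N)
  k2 <- 2L * (seq_along(approx) - 1L)
  for (m in seq_len(L)) {
    pos <- ((k2 + (m - 1L)) %% N) + 1L
    acc <- approx * h[m] + detail * g[m]
    if (N >= 2L * L) {
      x[pos] <- x[pos] + acc          # positions are distinct
    } else {
      for (u in unique(pos)) x[u] <- x[u] + sum(acc[pos == u])
    }
  }
  x
}

#' Decompose one channel into a wavelet coefficient pyramid
#'
#' Decimated orthogonal DWT with periodic boundary handling. The signal
#' length must be divisible by `2^n_levels` and long enough to hold the
#' filter at the deepest level.
#'
#' @param x numeric vector (one channel).
#' @param cfg an [wavelet_config()].
#' @return An object of class `mi_wavelet_pyramid` with per-level detail
#'   coefficients `D1..Dn` (fine to coarse) and the approximation `An`.
#' @export
wavelet_decompose <- function(x, cfg) {
  stopifnot(inherits(cfg, "mi_wavelet_config"))
  h <- WAVELET_FILTERS[[cfg$wavelet]]
  g <- qmf(h)
  N <- length(x)
  n <- cfg$n_levels
  max_depth <- 0L
  len <- N
  while (len %% 2L == 0L && len %/% 2L >= 1L && len >= length(h)) {
    max_depth <- max_depth + 1L
    len <- len %/% 2L
  }
  if (N %% 2L^n != 0L || max_depth < n)
    stop(sprintf("signal of length %d supports at most %d decomposition levels (requested %d)",
                 N, max_depth, n))
  details <- vector("list", n)
  names(details) <- paste0("D", seq_len(n))
  cur <- as.numeric(x)
  for (lev in seq_len(n)) {
    st <- dwt_step(cur, h, g)
    details[[lev]] <- st$detail
    cur <- st$approx
  }
  structure(list(details = details, approx = cur, n = N, cfg = cfg),
            class = "mi_wavelet_pyramid")
}

#' Reconstruct a signal from selected bands of a pyramid
#'
#' Coefficients of levels not in `retained_levels` are zeroed before the
#' inverse transform; retaining every level reproduces the input exactly.
#'
#' @param pyramid an `mi_wavelet_pyramid`.
#' @param retained_levels character vector of levels to keep; defaults to the
#'   configuration the pyramid was built with. An empty set returns a zero
#'   vector with a warning.
#' @return Numeric vector of the original length.
#' @export
band_reconstruct <- function(pyramid, retained_levels = NULL) {
  stopifnot(inherits(pyramid, "mi_wavelet_pyramid"))
  cfg <- pyramid$cfg
  if (is.null(retained_levels)) retained_levels <- cfg$retained_levels
  valid <- c(names(pyramid$details), paste0("A", cfg$n_levels))
  bad <- setdiff(retained_levels, valid)
  if (length(bad) > 0L)
    stop("invalid retained level(s) ", paste(bad, collapse = ", "))
  if (length(retained_levels) == 0L) {
    warning("empty retained set: reconstruction is the zero vector")
    return(numeric(pyramid$n))
  }
  h <- WAVELET_FILTERS[[cfg$wavelet]]
  g <- qmf(h)
  n <- cfg$n_levels
  keep_a <- paste0("A", n) %in% retained_levels
  cur <- if (keep_a) pyramid$approx else numeric(length(pyramid$approx))
  for (lev in rev(seq_len(n))) {
    d <- pyramid$details[[lev]]
    if (!paste0("D", lev) %in% retained_levels) d <- numeric(length(d))
    cur <- idwt_step(cur, d, h, g)
  }
  cur
}

#' Wavelet band-denoise every channel of every trial
#'
#' Applies [wavelet_decompose()] + [band_reconstruct()] per channel and per
#' trial, preserving shape, labels and metadata. With the default
#' configuration this retains the mu/beta rhythm range and suppresses slow
#' drifts and high-frequency noise.
#'
#' @param ts an `mi_trialset`.
#' @param cfg an [wavelet_config()]; its `fs` must match the trial set's.
#' @return A denoised `mi_trialset` of identical shape.
#' @export
denoise_trialset <- function(ts, cfg) {
  stopifnot(inherits(ts, "mi_trialset"), inherits(cfg, "mi_wavelet_config"))
  if (cfg$fs != ts$fs)
    stop(sprintf("config fs (%g) does not match trial set fs (%g)", cfg$fs, ts$fs))
  for (i in seq_along(ts$trials)) {
    X <- ts$trials[[i]]$data
    for (ch in seq_len(nrow(X))) {
      X[ch, ] <- tryCatch(
        band_reconstruct(wavelet_decompose(X[ch, ], cfg)),
        error = function(e)
          stop(sprintf("trial %d, channel %d: %s", i, ch, conditionMessage(e)),
               call. = FALSE))
    }
    ts$trials[[i]]$data <- X
  }
  ts
}
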
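# Common spatial patterns (CSP) for two-class motor imagery.
#
# CSP finds spatial filters that maximize the projected variance of one
# class while minimizing the other's. The classical construction: average
# trace-normalized class covariances C1, C2; whiten the composite Cc =
# C1 + C2 with P = lambda^(-1/2) U^T from its eigendecomposition; the
# whitened class covariances S1 = P C1 P^T and S2 = P C2 P^T then share
# eigenvectors B with eigenvalue matrices summing to the identity, so the
# projection W = B^T P simultaneously diagonalizes both class covariances.
# Filters are ranked by the class-1 eigenvalue; the extreme filters (largest
# and smallest) are the most discriminative.

#' Class-average trace-normalized covariance
#'
#' Mean over a class's trials of `X X^T / trace(X X^T)`. Trace normalization
#' makes trials contribute equally regardless of amplitude; the result has
#' unit trace.
#'
#' @param ts a labeled `mi_trialset`.
#' @param label `"class1"` or `"class2"`.
#' @return Symmetric M x M matrix with trace 1.
#' @export
class_mean_covariance <- function(ts, label) {
  stopifnot(inherits(ts, "mi_trialset"))
  label <- match.arg(label, c("class1", "class2"))
  idx <- which(labels_of(ts) == label)
  if (length(idx) == 0L) stop("no trials with label ", label)
  covs <- lapply(ts$trials[idx], function(t) {
    S <- tcrossprod(t$data)
    S / sum(diag(S))
  })
  Reduce(`+`, covs) / length(covs)
}

#' Fit a CSP spatial filter bank
#'
#' Runs the full decomposition (class covariances, composite
#' eigendecomposition, whitening, simultaneous diagonalization) and retains
#' the `m_pairs` most discriminative filter pairs: the first and last
#' `m_pairs` rows of the full projection matrix ordered by descending
#' class-1 eigenvalue.
#'
#' @param ts a labeled `mi_trialset` containing both classes.
#' @param m_pairs number of filter pairs to keep; `2 * m_pairs <= M`.
#'   Default keeps the maximum, `floor(M / 2)`.
#' @param eigen_floor_rel relative floor on composite-covariance eigenvalues.
#' @return An object of class `mi_csp` (the filter bank) with the full
#'   decomposition in `$decomposition`: `C1`, `C2`, `Cc`, `Uc`, `lambda_c`,
#'   `P`, `S1`, `S2`, `B`, `lambda1`, `lambda2`, and `W_full` (all M rows).
#'   The bank itself carries `W` (2 m_pairs rows), `m_pairs`,
#'   `eigvals_class1` and `n_channels`.
#' @export
fit_csp <- function(ts, m_pairs = NULL, eigen_floor_rel = 1e-12) {
  stopifnot(inherits(ts, "mi_trialset"))
  M <- ts$n_channels
  if (is.null(m_pairs)) m_pairs <- M %/% 2L
  if (2L * m_pairs > M)
    stop(sprintf("2 * m_pairs = %d exceeds the channel count M = %d", 2L * m_pairs, M))
  labs <- labels_of(ts)
  if (!all(c("class1", "class2") %in% labs))
    stop("CSP is supervised: the trial set must contain both classes")
  C1 <- class_mean_covariance(ts, "class1")
  C2 <- class_mean_covariance(ts, "class2")
  Cc <- C1 + C2
  ec <- eigen((Cc + t(Cc)) / 2, symmetric = TRUE)    # descending eigenvalues
  vals <- pmax(ec$values, eigen_floor_rel * max(ec$values))
  if (min(vals) <= 0)
    stop("composite covariance is singular; more trials or channels removal needed")
  P <- vals^(-0.5) * t(ec$vectors)                    # whitening, P Cc P^T = I
  S1 <- P %*% C1 %*% t(P)
  S2 <- P %*% C2 %*% t(P)
  eb <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)     # shared eigenvectors
  B <- eb$vectors                                     # ordered by lambda1 desc
  lambda1 <- eb$values
  lambda2 <- 1 - lambda1
  W_full <- t(B) %*% P
  keep <- c(seq_len(m_pairs), M - m_pairs + seq_len(m_pairs))
  decomposition <- list(C1 = C1, C2 = C2, Cc = Cc,
                        Uc = ec$vectors, lambda_c = ec$values,
                        P = P, S1 = S1, S2 = S2, B = B,
                        lambda1 = lambda1, lambda2 = lambda2, W_full = W_full)
  structure(list(W = W_full[keep, , drop = FALSE], m_pairs = as.integer(m_pairs),
                 eigvals_class1 = lambda1[keep], n_channels = M,
                 decomposition = decomposition),
            class = "mi_csp")
}

#' @export
print.mi_csp <- function(x, ...) {
  cat(sprintf("<mi_csp> %d filter pairs on %d channels\n", x$m_pairs, x$n_channels))
  cat("  class-1 eigenvalues of retained filters:\n   ",
      paste(sprintf("%.3f", x$eigvals_class1), collapse = " "), "\n")
  invisible(x)
}

#' Project a trial through the filter bank
#'
#' @param bank an `mi_csp`.
#' @param t an `mi_trial` with matching channel count.
#' @return Numeric matrix `2 m_pairs x N` of spatially filtered signals.
#' @export
csp_project <- function(bank, t) {
  stopifnot(inherits(bank, "mi_csp"), inherits(t, "mi_trial"))
  if (nrow(t$data) != bank$n_channels)
    stop(sprintf("trial has %d channels, filter bank expects %d",
                 nrow(t$data), bank$n_channels))
  bank$W %*% t$data
}

#' Log-variance CSP features of one trial
#'
#' Each retained filter contributes `log(var(Z_r) / sum_j var(Z_j))` where
#' `var` is the population (1/N, mean-removed) variance of the projected
#' row. The exponentials of a feature vector therefore sum to 1.
#'
#' @param bank an `mi_csp`.
#' @param t an `mi_trial`.
#' @return Numeric vector of length `2 * m_pairs`.
#' @export
extract_features <- function(bank, t) {
  Z <- csp_project(bank, t)
  v <- apply(Z, 1L, function(z) mean((z - mean(z))^2))
  if (any(v == 0))
    stop("zero-variance projected row(s) ", paste(which(v == 0), collapse = ", "),
         ": log-variance feature undefined")
  log(v / sum(v))
}

#' Feature table for a whole trial set
#'
#' @param bank an `mi_csp`.
#' @param ts an `mi_trialset`.
#' @return A list with `features` (n x 2 m_pairs matrix, rows in trial
#'   order), `labels` and `subjects` (character vectors).
#' @export
featurize_trialset <- function(bank, ts) {
  stopifnot(inherits(ts, "mi_trialset"))
  feats <- t(vapply(seq_along(ts$trials), function(i) {
    tryCatch(extract_features(bank, ts$trials[[i]]),
             error = function(e) stop(sprintf("trial %d: %s", i, conditionMessage(e)),
                                      call. = FALSE))
  }, numeric(2L * bank$m_pairs)))
  list(features = feats, labels = labels_of(ts), subjects = subjects_of(ts))
}
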
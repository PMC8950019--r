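# Euclidean-space data alignment (EA).
#
# Each domain is whitened by the inverse square root of its mean trial
# covariance R = (1/n) sum_i X_i X_i^T. After aligning a domain with its own
# reference, the mean covariance of the aligned trials is the identity, so
# source and target domains share the same mean spatial covariance — the
# covariance-level domain shift is removed. EA is unsupervised: it never
# reads labels.

#' Trial covariance matrix
#'
#' The raw (unnormalized) spatial covariance `X %*% t(X)` of one trial. No
#' `1/N` factor and no trace normalization are applied: alignment is
#' invariant to a global scalar, so the raw product keeps the self-alignment
#' identity exact.
#'
#' @param t an `mi_trial`.
#' @return Symmetric positive semidefinite M x M matrix.
#' @export
trial_covariance <- function(t) {
  stopifnot(inherits(t, "mi_trial"))
  if (any(!is.finite(t$data))) stop("trial data contains non-finite values")
  tcrossprod(t$data)
}

#' Fit an alignment model (reference covariance) on a domain
#'
#' Computes the domain's reference matrix — the mean of the trial
#' covariances — and its inverse symmetric square root by eigendecomposition.
#' Eigenvalues are floored at `eigen_floor_rel` times the largest eigenvalue
#' to guard against near-singular references from few trials.
#'
#' @param ts an `mi_trialset` (labels are never read).
#' @param eigen_floor_rel relative eigenvalue floor (default `1e-10`).
#' @return An object of class `mi_alignment` with fields `reference`,
#'   `inv_sqrt`, `n_trials`, `eigen_floor` (the absolute floor applied).
#' @export
fit_alignment <- function(ts, eigen_floor_rel = 1e-10) {
  stopifnot(inherits(ts, "mi_trialset"))
  n <- length(ts$trials)
  M <- ts$n_channels
  total_samples <- sum(vapply(ts$trials, function(t) ncol(t$data), integer(1)))
  if (total_samples <= M)
    stop("too few samples to form a nonsingular reference covariance; supply more data")
  reference <- Reduce(`+`, lapply(ts$trials, trial_covariance)) / n
  e <- eigen((reference + t(reference)) / 2, symmetric = TRUE)
  floor_abs <- eigen_floor_rel * max(e$values)
  vals <- pmax(e$values, floor_abs)
  if (max(vals) <= 0)
    stop("reference covariance is numerically singular beyond repair; supply more data")
  inv_sqrt <- e$vectors %*% (vals^(-0.5) * t(e$vectors))
  inv_sqrt <- (inv_sqrt + t(inv_sqrt)) / 2
  structure(list(reference = reference, inv_sqrt = inv_sqrt,
                 n_trials = n, eigen_floor = floor_abs),
            class = "mi_alignment")
}

#' @export
print.mi_alignment <- function(x, ...) {
  cat(sprintf("<mi_alignment> %d x %d reference from %d trials (eigen floor %.3g)\n",
              nrow(x$reference), ncol(x$reference), x$n_trials, x$eigen_floor))
  invisible(x)
}

#' Align a domain's trials with a fitted alignment model
#'
#' Left-multiplies every trial by the model's inverse square-root reference.
#' Labels and metadata are untouched. When the model was fitted on the same
#' trial set, the mean covariance of the output is the identity matrix.
#'
#' @param ts an `mi_trialset`.
#' @param model an `mi_alignment` of matching channel dimension.
#' @return The aligned `mi_trialset`.
#' @export
align_trialset <- function(ts, model) {
  stopifnot(inherits(ts, "mi_trialset"), inherits(model, "mi_alignment"))
  if (nrow(model$inv_sqrt) != ts$n_channels)
    stop(sprintf("alignment model dimension (%d) does not match channel count (%d)",
                 nrow(model$inv_sqrt), ts$n_channels))
  map_trials(ts, function(X) model$inv_sqrt %*% X)
}

# Fit-and-align one or more domains with their own references. Per-subject
# alignment (the default for a multi-subject target domain) fits one
# reference per subject.
#' Align each subject of a domain with its own reference
#'
#' Convenience wrapper: fits [fit_alignment()] separately per subject (the
#' standard protocol when a domain pools several subjects) and aligns each
#' subject's trials with its own model. Set `per_subject = FALSE` to fit one
#' joint reference for the whole set.
#'
#' @param ts an `mi_trialset`.
#' @param per_subject align each subject with its own reference?
#' @param eigen_floor_rel passed to [fit_alignment()].
#' @return The aligned `mi_trialset` (trial order preserved).
#' @export
align_domain <- function(ts, per_subject = TRUE, eigen_floor_rel = 1e-10) {
  stopifnot(inherits(ts, "mi_trialset"))
  if (!per_subject) return(align_trialset(ts, fit_alignment(ts, eigen_floor_rel)))
  subj <- subjects_of(ts)
  for (id in unique(subj)) {
    idx <- which(subj == id)
    sub <- subset_trials(ts, idx)
    aligned <- align_trialset(sub, fit_alignment(sub, eigen_floor_rel))
    ts$trials[idx] <- aligned$trials
  }
  ts
}
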
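# t-SNE domain-shift diagnostic.
#
# Exact (O(n^2)) t-distributed stochastic neighbor embedding: Gaussian
# input affinities with per-point perplexity calibration by bisection,
# Student-t low-dimensional kernel, gradient descent with momentum and
# early exaggeration. Deterministic for a fixed seed. This is a visual
# diagnostic for how strongly source and target feature clouds overlap
# before and after alignment, not part of the classification path.

# Calibrate conditional Gaussian affinities to a target perplexity.
tsne_affinities <- function(X, perplexity) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        p <- p / sp
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' t-SNE embedding of source and target feature vectors
#'
#' Embeds pooled source and target CSP feature vectors in 2D so the degree
#' of domain overlap can be inspected (the classical before/after-alignment
#' picture). Deterministic per seed.
#'
#' @param source_features numeric matrix, source feature vectors in rows.
#' @param target_features numeric matrix, target feature vectors in rows
#'   (same width).
#' @param seed integer seed.
#' @param perplexity Gaussian perplexity (effective neighbor count).
#' @param n_iter gradient-descent iterations.
#' @param source_labels,target_labels optional class tags carried through.
#' @return An object of class `mi_tsne`: a data frame `embedding` with
#'   columns `dim1`, `dim2`, `domain`, `label`, plus the call settings.
#' @export
tsne_diagnostic <- function(source_features, target_features, seed = 1,
                            perplexity = 30, n_iter = 400,
                            source_labels = NULL, target_labels = NULL) {
  X <- rbind(as.matrix(source_features), as.matrix(target_features))
  n <- nrow(X)
  if (n < 10L) stop("t-SNE diagnostic needs at least 10 feature vectors")
  perplexity <- min(perplexity, floor((n - 1) / 3))
  P <- tsne_affinities(X, perplexity)
  Y <- with_seed(seed, matrix(stats::rnorm(n * 2, 0, 1e-4), n, 2))
  G <- matrix(0, n, 2)   # momentum buffer
  gains <- matrix(1, n, 2)
  for (iter in seq_len(n_iter)) {
    ex <- if (iter <= 100) 4 else 1
    D2 <- as.matrix(stats::dist(Y))^2
    Qnum <- 1 / (1 + D2); diag(Qnum) <- 0
    Q <- pmax(Qnum / sum(Qnum), 1e-12)
    L <- (ex * P - Q) * Qnum
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (iter <= 250) 0.5 else 0.8
    gains <- pmax(ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8), 0.01)
    G <- mom * G - 200 * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  domain <- c(rep("source", nrow(as.matrix(source_features))),
              rep("target", nrow(as.matrix(target_features))))
  label <- c(if (is.null(source_labels)) rep(NA_character_, sum(domain == "source"))
             else as.character(source_labels),
             if (is.null(target_labels)) rep(NA_character_, sum(domain == "target"))
             else as.character(target_labels))
  structure(list(embedding = data.frame(dim1 = Y[, 1], dim2 = Y[, 2],
                                        domain = domain, label = label,
                                        stringsAsFactors = FALSE),
                 perplexity = perplexity, n_iter = n_iter, seed = seed),
            class = "mi_tsne")
}

#' @export
print.mi_tsne <- function(x, ...) {
  cat(sprintf("<mi_tsne> %d points (perplexity %g, %d iterations, seed %d)\n",
              nrow(x$embedding), x$perplexity, x$n_iter, x$seed))
  invisible(x)
}

#' Plot a t-SNE domain diagnostic
#'
#' Source points are drawn as open circles, target points as filled
#' triangles; classes are colored when labels are present.
#'
#' @param x an `mi_tsne`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mi_tsne <- function(x, ...) {
  e <- x$embedding
  cls <- factor(ifelse(is.na(e$label), "unlabeled", e$label))
  cols <- c(class1 = "#1b6ca8", class2 = "#2e8b57", unlabeled = "#888888")
  graphics::plot(e$dim1, e$dim2,
                 col = cols[as.character(cls)],
                 pch = ifelse(e$domain == "source", 1, 17),
                 xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  graphics::legend("topright", bty = "n",
                   legend = c("source", "target", levels(cls)),
                   pch = c(1, 17, rep(15, nlevels(cls))),
                   col = c("black", "black", cols[levels(cls)]))
  invisible(x)
}
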
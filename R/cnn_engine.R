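# Minimal deterministic CNN engine (forward + backprop + SGD), base R.
#
# Layers operate on h x w x c arrays. Convolutions use im2col with index
# maps precomputed at network-build time; max-pooling caches argmax indices
# for the backward pass. Training is plain stochastic gradient descent with
# a fixed, seed-derived initialization and per-epoch shuffling, so a run is
# bit-reproducible from its seed. The output layer is a 2-way softmax
# trained with cross-entropy.

# ---- layer constructors (internal descriptors) ----

layer_conv <- function(kernel, out_channels, pad = (kernel - 1L) %/% 2L)
  list(type = "conv", kernel = as.integer(kernel),
       out_channels = as.integer(out_channels), pad = as.integer(pad))
layer_relu <- function() list(type = "relu")
layer_pool <- function(k = 2L) list(type = "pool", k = as.integer(k))
layer_dense <- function(units) list(type = "dense", units = as.integer(units))

# Build index map for im2col on a padded (H, W, C) volume.
build_conv_maps <- function(in_shape, kernel, pad) {
  h <- in_shape[1]; w <- in_shape[2]; cc <- in_shape[3]
  H <- h + 2L * pad; W <- w + 2L * pad
  oh <- H - kernel + 1L; ow <- W - kernel + 1L
  if (oh < 1L || ow < 1L)
    stop(sprintf("conv kernel %d too large for %dx%d input (pad %d)", kernel, h, w, pad))
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  cols <- vector("list", kernel * kernel * cc)
  m <- 0L
  for (ci in seq_len(cc)) for (kj in seq_len(kernel)) for (ki in seq_len(kernel)) {
    m <- m + 1L
    cols[[m]] <- (ci - 1L) * H * W + (oj + kj - 2L) * H + (oi + ki - 1L)
  }
  idx <- do.call(cbind, cols)
  # map from padded linear indices back into the unpadded volume (0 = padding)
  inner <- array(0L, dim = c(H, W, cc))
  inner[pad + seq_len(h), pad + seq_len(w), ] <-
    seq_len(h * w * cc)
  list(idx = idx, out_shape = c(oh, ow, NA), padded_len = H * W * cc,
       inner = as.integer(inner), pad_dims = c(H, W, cc))
}

build_pool_maps <- function(in_shape, k) {
  h <- in_shape[1]; w <- in_shape[2]; cc <- in_shape[3]
  oh <- h %/% k; ow <- w %/% k
  if (oh < 1L || ow < 1L) stop("pooling window larger than its input")
  oi <- rep(seq_len(oh), times = ow)
  oj <- rep(seq_len(ow), each = oh)
  cols <- vector("list", k * k)
  m <- 0L
  for (kj in seq_len(k)) for (ki in seq_len(k)) {
    m <- m + 1L
    cols[[m]] <- ((oj - 1L) * k + kj - 1L) * h + (oi - 1L) * k + ki
  }
  # region index map for ONE channel; channel offset added at use time
  list(idx = do.call(cbind, cols), out_shape = c(oh, ow, cc), per_ch = h * w)
}

# Instantiate a network: resolve shapes, index maps and initial parameters.
build_network <- function(input_shape, layers, seed) {
  shape <- input_shape
  net <- vector("list", length(layers))
  with_seed(seed, {
    for (i in seq_along(layers)) {
      L <- layers[[i]]
      if (L$type == "conv") {
        maps <- build_conv_maps(shape, L$kernel, L$pad)
        fan_in <- L$kernel^2 * shape[3]
        L$Wmat <- matrix(stats::rnorm(fan_in * L$out_channels, 0, sqrt(2 / fan_in)),
                         fan_in, L$out_channels)
        L$b <- numeric(L$out_channels)
        L$maps <- maps
        shape <- c(maps$out_shape[1:2], L$out_channels)
      } else if (L$type == "pool") {
        L$maps <- build_pool_maps(shape, L$k)
        shape <- L$maps$out_shape
      } else if (L$type == "dense") {
        fan_in <- prod(shape)
        L$Wmat <- matrix(stats::rnorm(fan_in * L$units, 0, sqrt(1 / fan_in)),
                         L$units, fan_in)
        L$b <- numeric(L$units)
        shape <- c(1L, 1L, L$units)
      }
      L$out_shape <- shape
      net[[i]] <- L
    }
  })
  list(layers = net, input_shape = input_shape, output_units = shape[3])
}

# ---- forward / backward ----

conv_forward <- function(x, L) {
  maps <- L$maps
  if (L$pad > 0L) {
    xpad <- numeric(maps$padded_len)
    keep <- maps$inner > 0L
    xpad[which(keep)] <- x[maps$inner[keep]]
  } else xpad <- as.numeric(x)
  patches <- matrix(xpad[maps$idx], nrow = nrow(maps$idx))
  out <- patches %*% L$Wmat
  out <- sweep(out, 2L, L$b, "+")
  list(out = array(out, dim = c(maps$out_shape[1:2], L$out_channels)),
       patches = patches)
}

conv_backward <- function(dout, cache, L) {
  maps <- L$maps
  dmat <- matrix(dout, nrow = nrow(maps$idx))       # positions x out_channels
  dW <- crossprod(cache$patches, dmat)
  db <- colSums(dmat)
  dpatch <- dmat %*% t(L$Wmat)                      # positions x (k*k*c)
  dxpad <- numeric(maps$padded_len)
  for (m in seq_len(ncol(dpatch))) {
    col <- maps$idx[, m]
    dxpad[col] <- dxpad[col] + dpatch[, m]
  }
  keep <- maps$inner > 0L
  dx <- numeric(sum(keep))
  dx[maps$inner[keep]] <- dxpad[which(keep)]
  list(dx = dx, dW = dW, db = db)
}

pool_forward <- function(x, L) {
  maps <- L$maps
  oh <- maps$out_shape[1]; ow <- maps$out_shape[2]; cc <- maps$out_shape[3]
  out <- numeric(oh * ow * cc)
  arg <- integer(oh * ow * cc)
  npos <- nrow(maps$idx)
  for (ch in seq_len(cc)) {
    offs <- (ch - 1L) * maps$per_ch
    vals <- matrix(x[maps$idx + offs], nrow = npos)
    amax <- max.col(vals, ties.method = "first")
    sel <- cbind(seq_len(npos), amax)
    rng <- (ch - 1L) * npos + seq_len(npos)
    out[rng] <- vals[sel]
    arg[rng] <- maps$idx[sel] + offs
  }
  list(out = array(out, dim = c(oh, ow, cc)), argmax = arg)
}

pool_backward <- function(dout, cache, in_len) {
  dx <- numeric(in_len)
  d <- as.numeric(dout)
  # argmax indices are distinct (disjoint pooling windows)
  dx[cache$argmax] <- d
  dx
}

net_forward <- function(net, x, keep_cache = TRUE) {
  caches <- if (keep_cache) vector("list", length(net$layers)) else NULL
  cur <- as.numeric(x)
  for (i in seq_along(net$layers)) {
    L <- net$layers[[i]]
    if (L$type == "conv") {
      fc <- conv_forward(cur, L)
      if (keep_cache) caches[[i]] <- list(patches = fc$patches, in_len = length(cur))
      cur <- as.numeric(fc$out)
    } else if (L$type == "relu") {
      if (keep_cache) caches[[i]] <- list(mask = cur > 0)
      cur <- pmax(cur, 0)
    } else if (L$type == "pool") {
      pf <- pool_forward(cur, L)
      if (keep_cache) caches[[i]] <- list(argmax = pf$argmax, in_len = length(cur))
      cur <- as.numeric(pf$out)
    } else if (L$type == "dense") {
      if (keep_cache) caches[[i]] <- list(x = cur)
      cur <- as.numeric(L$Wmat %*% cur + L$b)
    }
  }
  list(logits = cur, caches = caches)
}

softmax <- function(z) { e <- exp(z - max(z)); e / sum(e) }

# Backprop of cross-entropy loss; returns per-layer parameter gradients.
net_backward <- function(net, caches, probs, y_onehot) {
  grads <- vector("list", length(net$layers))
  d <- probs - y_onehot
  for (i in rev(seq_along(net$layers))) {
    L <- net$layers[[i]]
    if (L$type == "dense") {
      grads[[i]] <- list(dW = d %o% caches[[i]]$x, db = d)
      d <- as.numeric(t(L$Wmat) %*% d)
    } else if (L$type == "pool") {
      d <- pool_backward(d, caches[[i]], caches[[i]]$in_len)
    } else if (L$type == "relu") {
      d <- d * caches[[i]]$mask
    } else if (L$type == "conv") {
      cb <- conv_backward(d, caches[[i]], L)
      grads[[i]] <- list(dW = cb$dW, db = cb$db)
      d <- cb$dx
    }
  }
  grads
}

# One SGD update over a mini-batch of sample indices. The averaged gradient
# is norm-clipped: a single extreme step (easy to trigger with batch size 1
# near a saturated softmax) can otherwise switch every ReLU off at once and
# permanently flatline the network.
sgd_batch <- function(net, X_list, y, batch_idx, lr, trainable, clip_norm) {
  nb <- length(batch_idx)
  acc <- NULL
  loss <- 0
  for (s in batch_idx) {
    fw <- net_forward(net, X_list[[s]])
    p <- softmax(fw$logits)
    yoh <- numeric(net$output_units); yoh[y[s]] <- 1
    loss <- loss - log(max(p[y[s]], 1e-300))
    g <- net_backward(net, fw$caches, p, yoh)
    if (is.null(acc)) acc <- g else {
      for (i in seq_along(g)) if (!is.null(g[[i]])) {
        acc[[i]]$dW <- acc[[i]]$dW + g[[i]]$dW
        acc[[i]]$db <- acc[[i]]$db + g[[i]]$db
      }
    }
  }
  scale <- 1 / nb
  if (is.finite(clip_norm)) {
    gnorm <- 0
    for (i in seq_along(acc)) if (!is.null(acc[[i]]))
      gnorm <- gnorm + sum((acc[[i]]$dW * scale)^2) + sum((acc[[i]]$db * scale)^2)
    gnorm <- sqrt(gnorm)
    if (gnorm > clip_norm) scale <- scale * clip_norm / gnorm
  }
  for (i in seq_along(net$layers)) {
    if (!is.null(acc[[i]]) && trainable[i]) {
      net$layers[[i]]$Wmat <- net$layers[[i]]$Wmat - lr * acc[[i]]$dW * scale
      net$layers[[i]]$b <- net$layers[[i]]$b - lr * acc[[i]]$db * scale
    }
  }
  list(net = net, loss = loss / nb)
}

# Full training loop. `trainable` marks layers whose parameters update
# (FALSE = frozen, for fine-tuning).
train_network <- function(net, X_list, y, lr, epochs, batch_size, seed,
                          trainable = rep(TRUE, length(net$layers)),
                          clip_norm = 1) {
  n <- length(X_list)
  log_ <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        batch <- ord[start:min(start + batch_size - 1L, n)]
        st <- sgd_batch(net, X_list, y, batch, lr, trainable, clip_norm)
        net <- st$net
        if (!is.finite(st$loss))
          stop(sprintf("non-finite training loss at epoch %d; lower the learning rate", ep))
        ep_loss <- ep_loss + st$loss; nb <- nb + 1L
      }
      log_[ep] <- ep_loss / nb
    }
  })
  list(net = net, training_log = log_)
}

net_predict_probs <- function(net, X_list) {
  t(vapply(X_list, function(x) softmax(net_forward(net, x, keep_cache = FALSE)$logits),
           numeric(net$output_units)))
}
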
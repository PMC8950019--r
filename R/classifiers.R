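# Classifiers: the proposed small 2D CNN on reshaped CSP features, a
# CSP+SVM margin baseline, and a fine-tuning CNN baseline trained on
# image-rendered raw trials.

#' Reshape a CSP feature vector into a square grid
#'
#' Row-major fill into a `grid_side x grid_side` matrix, trailing cells
#' zero-padded, as expected by the 2D convolutional classifier. Flattening
#' the grid row-major and dropping the padding recovers the vector exactly.
#'
#' @param fv numeric feature vector.
#' @param grid_side side length; `grid_side^2 >= length(fv)`. Default is the
#'   smallest square that fits the vector.
#' @return An object of class `mi_feature_grid` with fields `grid` and
#'   `pad_count`.
#' @export
reshape_features <- function(fv, grid_side = NULL) {
  fv <- as.numeric(fv)
  if (is.null(grid_side)) grid_side <- ceiling(sqrt(length(fv)))
  if (grid_side^2 < length(fv))
    stop(sprintf("grid %dx%d cannot hold %d features", grid_side, grid_side, length(fv)))
  pad <- grid_side^2 - length(fv)
  grid <- matrix(c(fv, numeric(pad)), nrow = grid_side, byrow = TRUE)
  structure(list(grid = grid, pad_count = as.integer(pad)),
            class = "mi_feature_grid")
}

#' Flatten a feature grid back to the original vector
#' @param fg an `mi_feature_grid`.
#' @return The feature vector with padding removed.
#' @export
flatten_grid <- function(fg) {
  stopifnot(inherits(fg, "mi_feature_grid"))
  v <- as.numeric(t(fg$grid))
  if (fg$pad_count > 0L) v <- v[seq_len(length(v) - fg$pad_count)]
  v
}

#' Configuration of the small 2D CNN classifier
#'
#' Defaults follow the published recipe where it is explicit — learning rate
#' 0.4, 160 epochs, batch size 1 — and the smallest standard choices where it
#' is not: two 3x3 convolutions with 8 and 16 channels, each followed by
#' ReLU and 2x2 max-pooling, then a fully connected 2-way softmax. The
#' default learning rate is unusually large for SGD; it is workable on the
#' bounded log-variance features but should be lowered for other inputs.
#'
#' @param conv_specs list of `c(kernel, channels)` pairs for the two
#'   convolutional layers.
#' @param pool max-pooling window (stride equal to window).
#' @param learning_rate SGD step size.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param clip_norm gradient-norm clip applied to each (averaged) SGD step;
#'   `Inf` disables clipping. Clipping keeps large-step recipes (batch size
#'   1 with a big learning rate) from collapsing the ReLU network.
#' @param seed integer seed controlling initialization and data order.
#' @return An object of class `mi_cnn_config`.
#' @export
cnn_config <- function(conv_specs = list(c(3, 8), c(3, 16)), pool = 2,
                       learning_rate = 0.4, epochs = 160, batch_size = 1,
                       clip_norm = 1, seed = 1) {
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0)
    stop("need epochs >= 1, batch_size >= 1, learning_rate > 0")
  structure(list(conv_specs = conv_specs, pool = as.integer(pool),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), clip_norm = clip_norm,
                 seed = as.integer(seed)),
            class = "mi_cnn_config")
}

label_to_int <- function(labels) {
  y <- match(labels, c("class1", "class2"))
  if (any(is.na(y))) stop("all training labels must be class1 or class2")
  y
}

grids_to_arrays <- function(grids) {
  lapply(grids, function(g) {
    m <- if (inherits(g, "mi_feature_grid")) g$grid else g
    array(as.numeric(m), dim = c(nrow(m), ncol(m), 1L))
  })
}

#' Train the proposed 2D CNN on reshaped CSP features
#'
#' @param grids list of `mi_feature_grid`s (or numeric matrices of one
#'   shared shape).
#' @param labels character labels (`class1`/`class2`), one per grid.
#' @param cfg an [cnn_config()].
#' @return An object of class `mi_model` with `kind = "csp_cnn"`, the fitted
#'   network, the per-epoch `training_log`, the config snapshot and seed.
#' @export
train_cnn <- function(grids, labels, cfg = cnn_config()) {
  stopifnot(inherits(cfg, "mi_cnn_config"))
  X <- grids_to_arrays(grids)
  if (length(unique(vapply(X, function(x) paste(dim(x), collapse = "x"),
                           character(1)))) != 1L)
    stop("all feature grids must share one shape")
  y <- label_to_int(labels)
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  side <- dim(X[[1L]])[1:2]
  layers <- list()
  cur <- side
  for (cs in cfg$conv_specs) {
    layers <- c(layers, list(layer_conv(cs[1], cs[2]), layer_relu()))
    cur <- cur + 2L * ((cs[1] - 1L) %/% 2L) - cs[1] + 1L
    # pooling is skipped once the map is smaller than the window (tiny
    # grids from low channel counts would otherwise collapse to nothing)
    if (all(cur %/% cfg$pool >= 1L)) {
      layers <- c(layers, list(layer_pool(cfg$pool)))
      cur <- cur %/% cfg$pool
    }
  }
  layers <- c(layers, list(layer_dense(2L)))
  net <- build_network(c(side, 1L), layers, seed = derive_seed(cfg$seed, "init"))
  tr <- train_network(net, X, y, lr = cfg$learning_rate, epochs = cfg$epochs,
                      batch_size = cfg$batch_size, clip_norm = cfg$clip_norm,
                      seed = derive_seed(cfg$seed, "order"))
  structure(list(kind = "csp_cnn", net = tr$net, training_log = tr$training_log,
                 grid_side = side[1], config = cfg, seed = cfg$seed),
            class = "mi_model")
}

#' @export
print.mi_model <- function(x, ...) {
  cat(sprintf("<mi_model> kind=%s", x$kind))
  if (!is.null(x$training_log))
    cat(sprintf(", %d epochs, final loss %.4f",
                length(x$training_log), x$training_log[length(x$training_log)]))
  cat("\n")
  invisible(x)
}

#' Predict class labels and scores
#'
#' Dispatches on the model kind: CSP-feature CNNs take feature grids (or
#' vectors, reshaped with the training grid side), the SVM baseline takes
#' raw feature vectors, and the fine-tuning CNN takes `mi_trial`s or an
#' `mi_trialset`. Scores are softmax (or SVM probability) values summing
#' to 1 per row.
#'
#' @param object an `mi_model`.
#' @param newdata inputs matching the model kind.
#' @param ... unused.
#' @return A list with `labels` (character) and `scores` (n x 2 matrix,
#'   columns class1/class2).
#' @export
predict.mi_model <- function(object, newdata, ...) {
  if (length(newdata) == 0L)
    return(list(labels = character(0),
                scores = matrix(numeric(0), 0, 2,
                                dimnames = list(NULL, c("class1", "class2")))))
  probs <- switch(object$kind,
    csp_cnn = {
      if (is.matrix(newdata))  # feature-vector matrix: reshape rows
        newdata <- lapply(seq_len(nrow(newdata)), function(i)
          reshape_features(newdata[i, ], object$grid_side))
      X <- grids_to_arrays(newdata)
      net_predict_probs(object$net, X)
    },
    csp_svm = {
      if (!is.matrix(newdata)) newdata <- do.call(rbind, newdata)
      colnames(newdata) <- object$feature_names
      p <- attr(stats::predict(object$svm, newdata, probability = TRUE),
                "probabilities")
      p[, c("class1", "class2"), drop = FALSE]
    },
    ft_cnn = {
      trials <- if (inherits(newdata, "mi_trialset")) newdata$trials else newdata
      X <- lapply(trials, function(t)
        render_trial_image(scale_image(rectify(t$data)), object$input_side))
      net_predict_probs(object$net, X)
    },
    stop("unknown model kind: ", object$kind))
  probs <- probs / rowSums(probs)
  colnames(probs) <- c("class1", "class2")
  list(labels = c("class1", "class2")[max.col(probs, ties.method = "first")],
       scores = probs)
}

#' Train the CSP+SVM baseline
#'
#' Margin classifier over raw (unreshaped) log-variance CSP feature vectors,
#' via `e1071::svm` with probability estimates. Deterministic for a fixed
#' seed (probability calibration uses internal cross-validation).
#'
#' @param features numeric matrix (n x d) or list of feature vectors.
#' @param labels character labels, both classes present.
#' @param kernel,cost passed to `e1071::svm`.
#' @param seed seed for the probability-calibration shuffle.
#' @return An `mi_model` of kind `"csp_svm"`.
#' @export
train_svm_baseline <- function(features, labels, kernel = "linear", cost = 1,
                               seed = 1) {
  if (!is.matrix(features)) features <- do.call(rbind, features)
  y <- factor(labels, levels = c("class1", "class2"))
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  fit <- with_seed(seed,
    e1071::svm(features, y, kernel = kernel, cost = cost,
               probability = TRUE, scale = FALSE))
  structure(list(kind = "csp_svm", svm = fit,
                 feature_names = colnames(features), seed = seed),
            class = "mi_model")
}

# Resample a channels x samples matrix to side x side. The (typically long)
# time axis is reduced by block averaging — anti-aliased resampling, so each
# pixel is the local mean rather than a point sample — and the channel axis
# is stretched by linear interpolation.
render_trial_image <- function(X, side) {
  h <- nrow(X); w <- ncol(X)
  if (w >= side) {
    edges <- round(seq(0, w, length.out = side + 1))
    Xt <- vapply(seq_len(side), function(j)
      rowMeans(X[, (edges[j] + 1L):edges[j + 1L], drop = FALSE]),
      numeric(h))                       # h x side
  } else {
    ci <- seq(1, w, length.out = side)
    c0 <- floor(ci); c1 <- pmin(c0 + 1, w); fc <- ci - c0
    Xt <- X[, c0, drop = FALSE] * rep(1 - fc, each = h) +
      X[, c1, drop = FALSE] * rep(fc, each = h)
  }
  ri <- seq(1, h, length.out = side)
  r0 <- floor(ri); r1 <- pmin(r0 + 1, h); fr <- ri - r0
  out <- Xt[r0, , drop = FALSE] * (1 - fr) + Xt[r1, , drop = FALSE] * fr
  array(out, dim = c(side, side, 1L))
}

#' Fine-tuning CNN architecture
#'
#' A deeper image CNN in the published pattern — six convolutional layers
#' and five max-pooling layers followed by a fully connected 2-way softmax.
#' The printed layer table of the original description is internally
#' inconsistent, so shapes here follow standard convolution arithmetic
#' (stride 1, the stated paddings); the realized shapes are recorded on the
#' built model. `input_side = 250` with kernel sizes (11, 11, 11, 7, 3, 3)
#' reproduces the described scale; smaller configurations keep the same
#' 6-conv/5-pool pattern for tractable experiments.
#'
#' @param input_side input image side length.
#' @param kernels integer vector of 6 convolution kernel sizes.
#' @param channels integer vector of 6 convolution channel counts.
#' @param pads integer vector of 6 zero-paddings (the described network
#'   pads every convolution by 1; scaled-down variants typically want
#'   "same" padding `(kernel - 1) / 2` to keep enough spatial extent for
#'   all five pooling stages).
#' @return A list of layer descriptors for the training engine.
#' @export
ftcnn_architecture <- function(input_side = 250,
                               kernels = c(11, 11, 11, 7, 3, 3),
                               channels = c(32, 32, 32, 64, 128, 128),
                               pads = rep(1L, 6L)) {
  stopifnot(length(kernels) == 6L, length(channels) == 6L, length(pads) == 6L)
  cv <- function(i) list(layer_conv(kernels[i], channels[i], pad = pads[i]),
                         layer_relu())
  c(cv(1), list(layer_pool(2L)),
    cv(2), cv(3), list(layer_pool(2L)),
    cv(4), list(layer_pool(2L)),
    cv(5), list(layer_pool(2L)),
    cv(6), list(layer_pool(2L)),
    list(layer_dense(2L)))
}

#' Train the fine-tuning CNN baseline
#'
#' Pretrains the deep image CNN on the labeled source domain (trials
#' bilinearly rendered to `input_side x input_side` images), then freezes
#' the first `freeze_depth` parameterized layers and retrains the rest on
#' the target training trials. Frozen parameters are bit-identical before
#' and after fine-tuning.
#'
#' @param source labeled source `mi_trialset`.
#' @param target_train labeled target training `mi_trialset`.
#' @param arch layer list from [ftcnn_architecture()].
#' @param input_side rendering size (must match the arch's intended input).
#' @param freeze_depth number of leading parameterized (convolutional)
#'   layers to freeze during fine-tuning; 0 means continued training.
#' @param learning_rate,epochs,batch_size,seed training settings. The
#'   pretraining phase uses `learning_rate`; fine-tuning uses the (usually
#'   smaller) `finetune_lr` so the retrained head adapts without washing
#'   out the pretrained representation.
#' @param finetune_lr fine-tuning step size (default `learning_rate / 5`).
#' @return An `mi_model` of kind `"ft_cnn"`.
#' @export
train_ftcnn_baseline <- function(source, target_train,
                                 arch = ftcnn_architecture(input_side = 32,
                                                           kernels = c(5, 3, 3, 3, 3, 3),
                                                           channels = c(8, 8, 8, 16, 16, 32),
                                                           pads = c(2, 1, 1, 1, 1, 1)),
                                 input_side = 32, freeze_depth = 5,
                                 learning_rate = 0.05, epochs = 30,
                                 batch_size = 8, seed = 1,
                                 finetune_lr = learning_rate / 5) {
  stopifnot(inherits(source, "mi_trialset"), inherits(target_train, "mi_trialset"))
  param_layers <- which(vapply(arch, function(L) L$type %in% c("conv", "dense"),
                               logical(1)))
  if (freeze_depth > length(param_layers))
    stop(sprintf("freeze_depth %d exceeds the %d parameterized layers",
                 freeze_depth, length(param_layers)))
  render_set <- function(ts) lapply(ts$trials, function(t)
    render_trial_image(scale_image(rectify(t$data)), input_side))
  Xs <- render_set(source); ys <- label_to_int(labels_of(source))
  Xt <- render_set(target_train); yt <- label_to_int(labels_of(target_train))
  if (length(unique(ys)) < 2L || length(unique(yt)) < 2L)
    stop("both domains must contain both classes")
  net <- build_network(c(input_side, input_side, 1L), arch,
                       seed = derive_seed(seed, "ft-init"))
  pre <- train_network(net, Xs, ys, lr = learning_rate, epochs = epochs,
                       batch_size = batch_size, seed = derive_seed(seed, "ft-pre"))
  trainable <- rep(TRUE, length(arch))
  if (freeze_depth > 0L) trainable[param_layers[seq_len(freeze_depth)]] <- FALSE
  ft <- train_network(pre$net, Xt, yt, lr = finetune_lr, epochs = epochs,
                      batch_size = batch_size, seed = derive_seed(seed, "ft-tune"),
                      trainable = trainable)
  structure(list(kind = "ft_cnn", net = ft$net,
                 pretrain_net = pre$net,
                 training_log = c(pre$training_log, ft$training_log),
                 frozen_layers = if (freeze_depth > 0L)
                   param_layers[seq_len(freeze_depth)] else integer(0),
                 input_side = input_side, seed = seed),
            class = "mi_model")
}

# Rectify an EEG trial to its amplitude envelope. Motor-imagery classes
# differ in band power, i.e. in the amplitude of spatial patterns; the
# rectified (absolute-value) signal exposes that amplitude to a conv net's
# averaging layers, whereas point-sampling the raw sign-symmetric
# oscillation would hide it.
rectify <- function(X) abs(X)

# Normalize a trial image to zero mean / unit scale so deep-CNN inputs are
# on a stable numeric range regardless of amplitude.
scale_image <- function(X) {
  s <- stats::sd(as.numeric(X))
  if (s == 0) return(X * 0)
  (X - mean(X)) / s
}
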
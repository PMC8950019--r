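# End-to-end pipeline: denoise -> align -> CSP -> classify -> evaluate.

#' Configure an end-to-end pipeline run
#'
#' @param method classifier: `"csp_cnn"` (proposed), `"csp_svm"`, `"ft_cnn"`.
#' @param regime `"source_trained_transfer"` trains on labeled source trials
#'   only and evaluates on every labeled target trial (the unsupervised
#'   transfer protocol); `"target_split_80_20"` additionally moves a random
#'   80% of each target subject's trials into the training set and tests on
#'   the remaining 20%.
#' @param denoise apply wavelet band denoising?
#' @param wavelet optional [wavelet_config()]; built from the data's `fs`
#'   when `NULL`.
#' @param align apply Euclidean alignment? (`FALSE` gives the ablated
#'   pipeline used as a control.)
#' @param per_subject_align fit one alignment reference per subject (the
#'   default) rather than one per domain.
#' @param m_pairs CSP filter pairs; `NULL` keeps the maximum `floor(M/2)`.
#' @param grid_side CNN input grid side; `NULL` uses the smallest square
#'   that holds the feature vector.
#' @param cnn an [cnn_config()] for the proposed classifier; its seed is
#'   overridden by a seed derived from `seed`.
#' @param ftcnn list of overrides for [train_ftcnn_baseline()] (e.g.
#'   `input_side`, `epochs`, `learning_rate`).
#' @param svm list of overrides for [train_svm_baseline()].
#' @param train_frac target training fraction for the 80/20 regime.
#' @param eigen_floor_rel eigenvalue floor for alignment and CSP.
#' @param seed master seed; all stage seeds are derived from it.
#' @return An object of class `mi_pipeline_config`.
#' @export
pipeline_config <- function(method = c("csp_cnn", "csp_svm", "ft_cnn"),
                            regime = c("source_trained_transfer",
                                       "target_split_80_20"),
                            denoise = TRUE, wavelet = NULL,
                            align = TRUE, per_subject_align = TRUE,
                            m_pairs = NULL, grid_side = NULL,
                            cnn = cnn_config(), ftcnn = list(), svm = list(),
                            train_frac = 0.8, eigen_floor_rel = 1e-10,
                            seed = 1) {
  structure(list(method = match.arg(method), regime = match.arg(regime),
                 denoise = denoise, wavelet = wavelet, align = align,
                 per_subject_align = per_subject_align,
                 m_pairs = m_pairs, grid_side = grid_side, cnn = cnn,
                 ftcnn = ftcnn, svm = svm, train_frac = train_frac,
                 eigen_floor_rel = eigen_floor_rel, seed = as.integer(seed)),
            class = "mi_pipeline_config")
}

method_tag <- function(method, align) {
  base <- switch(method, csp_cnn = "CSP-CNN", csp_svm = "CSP-SVM",
                 ft_cnn = "ftCNN")
  paste0(if (align) "EA-" else "noEA-", base)
}

# Order-insensitive fingerprint of a trial set's numeric content; equal
# data implies equal fingerprints, so classifier runs sharing preprocessing
# can assert they saw bit-identical inputs.
trialset_checksum <- function(ts) {
  v <- unlist(lapply(ts$trials, function(t) t$data), use.names = FALSE)
  sprintf("%.17g|%.17g|%d", sum(v), sum(v * seq_along(v) %% 1009), length(v))
}

# Shared preprocessing: wavelet band denoising then per-domain alignment.
preprocess_domains <- function(source, target, cfg) {
  t0 <- proc.time()[["elapsed"]]
  if (cfg$denoise) {
    wcfg <- if (is.null(cfg$wavelet)) wavelet_config(fs = source$fs) else cfg$wavelet
    source <- denoise_trialset(source, wcfg)
    target <- denoise_trialset(target, wcfg)
  }
  t1 <- proc.time()[["elapsed"]]
  if (cfg$align) {
    source <- align_domain(source, per_subject = cfg$per_subject_align,
                           eigen_floor_rel = cfg$eigen_floor_rel)
    target <- align_domain(target, per_subject = cfg$per_subject_align,
                           eigen_floor_rel = cfg$eigen_floor_rel)
  }
  t2 <- proc.time()[["elapsed"]]
  list(source = source, target = target,
       timings = c(denoise_s = t1 - t0, align_s = t2 - t1))
}

# Split target trial indices into train/test per the evaluation regime.
regime_split <- function(target, cfg) {
  labs <- labels_of(target)
  labeled <- which(labs %in% c("class1", "class2"))
  if (length(labeled) == 0L)
    stop("the evaluation regime requires labeled target trials")
  if (cfg$regime == "source_trained_transfer")
    return(list(train = integer(0), test = labeled))
  subj <- subjects_of(target)
  train <- integer(0)
  with_seed(derive_seed(cfg$seed, "split"), {
    for (id in unique(subj[labeled])) {
      idx <- labeled[subj[labeled] == id]
      n_train <- floor(cfg$train_frac * length(idx))
      train <- c(train, sort(sample(idx, n_train)))
    }
  })
  list(train = train, test = setdiff(labeled, train))
}

train_eval_classifier <- function(pre, train_target_idx, test_idx, cfg) {
  source <- pre$source; target <- pre$target
  seed <- derive_seed(cfg$seed, paste0("clf-", cfg$method))
  if (cfg$method %in% c("csp_cnn", "csp_svm")) {
    train_ts <- source
    if (length(train_target_idx) > 0L) {
      train_ts <- trialset(c(source$trials, target$trials[train_target_idx]),
                           channel_names = source$channel_names, role = "source")
    }
    bank <- fit_csp(train_ts, m_pairs = cfg$m_pairs,
                    eigen_floor_rel = cfg$eigen_floor_rel)
    ftr <- featurize_trialset(bank, train_ts)
    fte <- featurize_trialset(bank, subset_trials(target, test_idx))
    if (cfg$method == "csp_cnn") {
      gside <- if (is.null(cfg$grid_side)) ceiling(sqrt(ncol(ftr$features)))
               else cfg$grid_side
      to_grids <- function(F) lapply(seq_len(nrow(F)), function(i)
        reshape_features(F[i, ], gside))
      cnn <- cfg$cnn; cnn$seed <- seed
      model <- train_cnn(to_grids(ftr$features), ftr$labels, cnn)
      pred <- predict(model, to_grids(fte$features))
    } else {
      model <- do.call(train_svm_baseline,
                       c(list(features = ftr$features, labels = ftr$labels,
                              seed = seed), cfg$svm))
      pred <- predict(model, fte$features)
    }
  } else {  # ft_cnn on image-rendered trials
    if (length(train_target_idx) == 0L)
      train_target_idx <- which(labels_of(target) %in% c("class1", "class2") &
                                  !seq_along(target$trials) %in% test_idx)
    if (length(train_target_idx) == 0L)
      stop("the fine-tuning baseline needs labeled target training trials; ",
           "use regime target_split_80_20")
    tgt_train <- subset_trials(target, train_target_idx)
    model <- do.call(train_ftcnn_baseline,
                     c(list(source = source, target_train = tgt_train,
                            seed = seed), cfg$ftcnn))
    pred <- predict(model, subset_trials(target, test_idx))
  }
  list(model = model, pred = pred)
}

#' Run the full transfer pipeline and evaluate on the target domain
#'
#' Denoises both domains, aligns each domain (per subject by default) with
#' its own reference covariance, fits CSP and the chosen classifier on the
#' labeled training trials, and reports per-target-subject accuracy. In the
#' `source_trained_transfer` regime no target label is ever used for
#' fitting; labels enter only the accuracy bookkeeping. Fully reproducible
#' from `cfg$seed`.
#'
#' @param source labeled source `mi_trialset`.
#' @param target target `mi_trialset` (labeled trials are evaluated).
#' @param cfg an [pipeline_config()].
#' @return An object of class `mi_eval_report`.
#' @export
run_pipeline <- function(source, target, cfg = pipeline_config()) {
  stopifnot(inherits(source, "mi_trialset"), inherits(target, "mi_trialset"),
            inherits(cfg, "mi_pipeline_config"))
  if (source$n_channels != target$n_channels || source$fs != target$fs)
    stop("source and target must share channel geometry and sampling rate")
  t0 <- proc.time()[["elapsed"]]
  pre <- preprocess_domains(source, target, cfg)
  split <- regime_split(pre$target, cfg)
  fit <- train_eval_classifier(pre, split$train, split$test, cfg)
  report <- build_report(pre$target, split$test, fit$pred, cfg,
                         checksum = trialset_checksum(pre$target),
                         timings = c(pre$timings,
                                     total_s = proc.time()[["elapsed"]] - t0))
  report
}

build_report <- function(target, test_idx, pred, cfg, checksum, timings) {
  truth <- labels_of(target)[test_idx]
  subj <- subjects_of(target)[test_idx]
  per <- do.call(rbind, lapply(unique(subj), function(id) {
    sel <- subj == id
    conf <- table(factor(truth[sel], levels = c("class1", "class2")),
                  factor(pred$labels[sel], levels = c("class1", "class2")))
    data.frame(subject = id, n_test = sum(sel),
               correct = sum(diag(conf)),
               accuracy_pct = 100 * sum(diag(conf)) / sum(sel),
               tp1 = conf[1, 1], fn1 = conf[1, 2],
               fp1 = conf[2, 1], tn1 = conf[2, 2],
               stringsAsFactors = FALSE)
  }))
  structure(list(method = method_tag(cfg$method, cfg$align),
                 regime = cfg$regime,
                 test_idx = test_idx,
                 predictions = pred$labels,
                 scores = pred$scores,
                 per_subject = per,
                 overall_accuracy_pct = 100 * sum(per$correct) / sum(per$n_test),
                 input_checksum = checksum,
                 config = cfg, seed = cfg$seed, timings = timings),
            class = "mi_eval_report")
}

#' @export
print.mi_eval_report <- function(x, ...) {
  cat(sprintf("<mi_eval_report> %s (%s regime, seed %d)\n",
              x$method, x$regime, x$seed))
  cat(sprintf("  overall accuracy: %.1f%% on %d test trials\n",
              x$overall_accuracy_pct, sum(x$per_subject$n_test)))
  for (i in seq_len(nrow(x$per_subject)))
    cat(sprintf("  %-6s %5.1f%%  (%d/%d)\n", x$per_subject$subject[i],
                x$per_subject$accuracy_pct[i], x$per_subject$correct[i],
                x$per_subject$n_test[i]))
  invisible(x)
}

#' @export
summary.mi_eval_report <- function(object, ...) {
  cat(sprintf("Method %s, regime %s\n", object$method, object$regime))
  print(object$per_subject[, c("subject", "n_test", "correct", "accuracy_pct")],
        row.names = FALSE)
  cat(sprintf("Overall: %.2f%%   (stage timings: %s)\n",
              object$overall_accuracy_pct,
              paste(sprintf("%s=%.2fs", names(object$timings), object$timings),
                    collapse = ", ")))
  invisible(object)
}

#' Run the proposed method and both baselines on identical aligned inputs
#'
#' Preprocessing (denoise + align) and the target train/test split are
#' computed once and shared, so the three classifiers see bit-identical
#' inputs; each report carries a checksum of the aligned target data as
#' evidence. The fine-tuning baseline needs labeled target training data,
#' so it is evaluated only under the 80/20 regime.
#'
#' @param source,target as in [run_pipeline()].
#' @param cfg an [pipeline_config()]; its `method` field is ignored.
#' @return A named list of three `mi_eval_report`s
#'   (`csp_cnn`, `csp_svm`, `ft_cnn`).
#' @export
compare_methods <- function(source, target, cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "mi_pipeline_config"))
  pre <- preprocess_domains(source, target, cfg)
  split <- regime_split(pre$target, cfg)
  checksum <- trialset_checksum(pre$target)
  out <- list()
  for (m in c("csp_cnn", "csp_svm", "ft_cnn")) {
    cfg_m <- cfg; cfg_m$method <- m
    t0 <- proc.time()[["elapsed"]]
    fit <- train_eval_classifier(pre, split$train, split$test, cfg_m)
    out[[m]] <- build_report(pre$target, split$test, fit$pred, cfg_m,
                             checksum = checksum,
                             timings = c(pre$timings,
                                         total_s = proc.time()[["elapsed"]] - t0))
  }
  out
}
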
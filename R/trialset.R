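#' @keywords internal
"_PACKAGE"

# Allowed label tokens for two-class motor imagery plus unlabeled target data.
LABEL_TOKENS <- c("class1", "class2", "unlabeled")

#' Construct a single epoched EEG trial
#'
#' A trial is one epoched motor-imagery recording: a channels-by-samples
#' matrix in microvolts together with its class label, subject identifier and
#' sampling rate. Covariance-based operations (alignment, CSP) require at
#' least two channels and at least as many samples as channels.
#'
#' @param data numeric matrix, channels (M) x samples (N), microvolts.
#' @param label one of `"class1"`, `"class2"`, `"unlabeled"`.
#' @param subject subject identifier (coerced to character).
#' @param fs sampling rate in Hz.
#' @return An object of class `mi_trial`.
#' @export
trial <- function(data, label = "unlabeled", subject = "s1", fs) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric channels x samples matrix")
  if (any(!is.finite(data)))
    stop("trial data contains non-finite values")
  if (nrow(data) < 2L)
    stop("a trial needs at least 2 channels (M >= 2)")
  if (ncol(data) < nrow(data))
    stop("a trial needs at least as many samples as channels (N >= M)")
  label <- match.arg(label, LABEL_TOKENS)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz")
  structure(
    list(data = unname(data), label = label,
         subject = as.character(subject), fs = as.numeric(fs)),
    class = "mi_trial")
}

#' @export
print.mi_trial <- function(x, ...) {
  cat(sprintf("<mi_trial> %d channels x %d samples @ %g Hz, label=%s, subject=%s\n",
              nrow(x$data), ncol(x$data), x$fs, x$label, x$subject))
  invisible(x)
}

#' Construct an ordered collection of trials (a domain)
#'
#' A trial set groups trials that share channel geometry and sampling rate,
#' e.g. all trials of the source domain or of one target subject.
#'
#' @param trials list of [trial()] objects (at least one).
#' @param channel_names character vector of length M; defaults to
#'   `ch1..chM`.
#' @param role `"source"`, `"target"` or `"unassigned"`.
#' @return An object of class `mi_trialset`.
#' @export
trialset <- function(trials, channel_names = NULL,
                     role = c("unassigned", "source", "target")) {
  role <- match.arg(role)
  if (!is.list(trials) || length(trials) < 1L)
    stop("`trials` must be a non-empty list of mi_trial objects")
  if (!all(vapply(trials, inherits, logical(1), "mi_trial")))
    stop("all elements of `trials` must be mi_trial objects")
  M <- nrow(trials[[1L]]$data)
  fs <- trials[[1L]]$fs
  for (i in seq_along(trials)) {
    if (nrow(trials[[i]]$data) != M)
      stop(sprintf("trial %d has %d channels but the set has %d: channel counts must agree",
                   i, nrow(trials[[i]]$data), M))
    if (trials[[i]]$fs != fs)
      stop(sprintf("trial %d has fs=%g but the set has fs=%g", i, trials[[i]]$fs, fs))
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(M))
  if (length(channel_names) != M)
    stop("`channel_names` must have one name per channel")
  structure(
    list(trials = trials, channel_names = as.character(channel_names),
         role = role, fs = fs, n_channels = M),
    class = "mi_trialset")
}

#' @export
print.mi_trialset <- function(x, ...) {
  labs <- labels_of(x)
  cat(sprintf("<mi_trialset> %d trials, %d channels @ %g Hz, role=%s\n",
              length(x$trials), x$n_channels, x$fs, x$role))
  cat("  labels: ", paste(sprintf("%s=%d", names(table(labs)), table(labs)),
                          collapse = ", "), "\n", sep = "")
  cat("  subjects: ", paste(unique(subjects_of(x)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
length.mi_trialset <- function(x) length(x$trials)

#' Trial labels of a trial set
#' @param ts an `mi_trialset`.
#' @return character vector of label tokens, one per trial.
#' @export
labels_of <- function(ts) vapply(ts$trials, function(t) t$label, character(1))

#' Subject ids of a trial set
#' @param ts an `mi_trialset`.
#' @return character vector of subject ids, one per trial.
#' @export
subjects_of <- function(ts) vapply(ts$trials, function(t) t$subject, character(1))

# Apply a function over trial data matrices, keeping metadata.
map_trials <- function(ts, f) {
  ts$trials <- lapply(ts$trials, function(t) { t$data <- f(t$data); t })
  ts
}

# Subset a trialset by trial index, preserving order.
subset_trials <- function(ts, idx, role = ts$role) {
  if (length(idx) == 0L) stop("cannot build an empty trial set")
  trialset(ts$trials[idx], channel_names = ts$channel_names, role = role)
}

#' Extract an epoch from a continuous multichannel recording
#'
#' Cuts a fixed-length window out of a continuous channels-by-samples matrix,
#' `offset_s` seconds after a cue. Sample indices are 0-based and the window
#' is half-open: the epoch covers samples `start, ..., start + N - 1` with
#' `start = cue_sample + round(offset_s * fs)` and `N = round(duration_s * fs)`.
#' The standard cue-paradigm choice is a 4 s window starting 0.5 s after the
#' cue, which at 512 Hz gives N = 2048 samples.
#'
#' @param continuous numeric matrix, channels x samples.
#' @param cue_sample 0-based sample index of the cue.
#' @param offset_s non-negative offset from the cue, seconds.
#' @param duration_s epoch duration, seconds.
#' @param fs sampling rate, Hz.
#' @param label,subject passed to [trial()].
#' @return An `mi_trial` with `N = round(duration_s * fs)` samples.
#' @export
extract_epoch <- function(continuous, cue_sample, offset_s, duration_s, fs,
                          label = "unlabeled", subject = "s1") {
  if (!is.matrix(continuous)) stop("`continuous` must be a channels x samples matrix")
  if (offset_s < 0 || duration_s < 0) stop("`offset_s` and `duration_s` must be >= 0")
  if (cue_sample < 0) stop("`cue_sample` must be a 0-based index >= 0")
  start <- cue_sample + round(offset_s * fs)      # 0-based
  n <- round(duration_s * fs)
  total <- ncol(continuous)
  if (start + n > total)
    stop(sprintf(
      "epoch window [%d, %d) exceeds recording of %d samples (subject %s, overhang %d samples)",
      start, start + n, total, subject, start + n - total))
  trial(continuous[, (start + 1L):(start + n), drop = FALSE],
        label = label, subject = subject, fs = fs)
}

#' Split a trial set into source and target domains by subject
#'
#' Assigns every trial to the source or target domain according to its
#' subject id, preserving trial order within each domain. The canonical
#' cross-subject protocol pools the first group of subjects as the labeled
#' source domain and holds out the remaining subjects as the target domain.
#'
#' @param ts an `mi_trialset`.
#' @param source_subjects,target_subjects disjoint character vectors of
#'   subject ids present in `ts`. `target_subjects` may be empty (with a
#'   warning).
#' @return A list with elements `source` and `target` (`NULL` target when
#'   `target_subjects` is empty).
#' @export
split_domains <- function(ts, source_subjects, target_subjects) {
  source_subjects <- as.character(source_subjects)
  target_subjects <- as.character(target_subjects)
  if (length(intersect(source_subjects, target_subjects)) > 0L)
    stop("source and target subject lists must be disjoint")
  subj <- subjects_of(ts)
  unknown <- setdiff(c(source_subjects, target_subjects), unique(subj))
  if (length(unknown) > 0L)
    stop("unknown subject id(s): ", paste(unknown, collapse = ", "))
  src_idx <- which(subj %in% source_subjects)
  tgt_idx <- which(subj %in% target_subjects)
  if (length(src_idx) == 0L) stop("source domain would be empty")
  target <- NULL
  if (length(tgt_idx) == 0L) {
    warning("target subject list is empty; returning NULL target domain")
  } else {
    target <- subset_trials(ts, tgt_idx, role = "target")
  }
  list(source = subset_trials(ts, src_idx, role = "source"), target = target)
}
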
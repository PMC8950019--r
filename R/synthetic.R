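# Synthetic two-class motor-imagery EEG.
#
# Each latent source is band-pass-filtered Gaussian noise in its nominal
# rhythm band (mu 8-12 Hz, beta 13-22 Hz), scaled to a class-conditional
# variance — the ERD/ERS effect: motor imagery suppresses or enhances band
# power depending on the class. Sources are mixed into channels by a
# subject-specific mixing matrix; between-subject differences in the mixing
# produce the covariance domain shift that alignment is meant to remove.

#' Define a synthetic subject's generative model
#'
#' @param mixing numeric matrix channels x sources with full column rank
#'   (unitless gains).
#' @param bands numeric matrix sources x 2, nominal band of each source in Hz.
#' @param var_class1,var_class2 per-source signal variances (microvolt^2) under
#'   each class. At least one source must differ between classes, otherwise
#'   the classes are indistinguishable.
#' @param noise_sd standard deviation of additive broadband sensor noise
#'   (microvolts).
#' @param fs sampling rate, Hz.
#' @return An object of class `mi_subject_model`.
#' @export
subject_model <- function(mixing, bands, var_class1, var_class2,
                          noise_sd = 0.5, fs = 100) {
  mixing <- as.matrix(mixing)
  k <- ncol(mixing)
  if (qr(mixing)$rank < k) stop("`mixing` must have full column rank")
  bands <- matrix(as.numeric(bands), ncol = 2)
  if (nrow(bands) != k) stop("`bands` must have one (low, high) row per source")
  if (any(bands[, 1] <= 0) || any(bands[, 2] >= fs / 2) ||
      any(bands[, 2] <= bands[, 1]))
    stop("bands must satisfy 0 < low < high < fs/2")
  if (length(var_class1) != k || length(var_class2) != k)
    stop("class variance vectors must have one entry per source")
  if (any(var_class1 < 0) || any(var_class2 < 0)) stop("variances must be >= 0")
  if (all(var_class1 == var_class2))
    warning("all sources have equal class variances: classes are indistinguishable")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(
    list(mixing = unname(mixing), bands = unname(bands),
         var_class1 = as.numeric(var_class1), var_class2 = as.numeric(var_class2),
         noise_sd = noise_sd, fs = fs,
         n_channels = nrow(mixing), n_sources = k),
    class = "mi_subject_model")
}

#' Default synthetic subject: 15 channels, 3 band-limited sources
#'
#' Mirrors the geometry of a 15-electrode sensorimotor montage at a reduced
#' 100 Hz rate: one mu-band (8-12 Hz) source with strong ERD contrast
#' (variance 4 vs 1 across classes), one beta-band (13-22 Hz) source with
#' moderate contrast in the opposite direction (1 vs 2.5), and one
#' class-neutral mu/beta-wide distractor. The mixing matrix is drawn once
#' from the given seed.
#'
#' @param n_channels channel count.
#' @param fs sampling rate, Hz.
#' @param noise_sd broadband noise standard deviation, microvolts.
#' @param seed seed for the mixing matrix draw.
#' @return An `mi_subject_model`.
#' @export
default_subject_model <- function(n_channels = 15, fs = 100, noise_sd = 0.5,
                                  seed = 42) {
  mixing <- with_seed(seed, {
    A <- matrix(stats::rnorm(n_channels * 3), n_channels, 3)
    # normalize columns so source variances are on a comparable channel scale
    sweep(A, 2, sqrt(colSums(A^2)), "/") * sqrt(n_channels / 3)
  })
  subject_model(
    mixing,
    bands = rbind(c(8, 12), c(13, 22), c(8, 22)),
    var_class1 = c(4, 1.0, 1.5),
    var_class2 = c(1, 2.5, 1.5),
    noise_sd = noise_sd, fs = fs)
}

#' Specify a between-subject domain shift
#'
#' The shift rotates the channel space of the mixing matrix (random Givens
#' rotations with angles of typical magnitude `rotation_strength`) and
#' disperses per-channel gains multiplicatively within
#' `[1/gain_spread, gain_spread]`.
#'
#' @param rotation_strength standard deviation of the rotation angles,
#'   radians (>= 0).
#' @param gain_spread multiplicative per-channel gain dispersion (>= 1;
#'   1 means no gain perturbation).
#' @param seed integer seed making the shift reproducible.
#' @return An object of class `mi_shift_spec`.
#' @export
shift_spec <- function(rotation_strength = 0.4, gain_spread = 1.5, seed = 1) {
  if (rotation_strength < 0) stop("`rotation_strength` must be >= 0")
  if (gain_spread < 1) stop("`gain_spread` must be >= 1")
  structure(list(rotation_strength = rotation_strength,
                 gain_spread = gain_spread, seed = as.integer(seed)),
            class = "mi_shift_spec")
}

#' Apply a domain shift to a subject model
#'
#' Returns a new model whose mixing matrix is `G %*% Q %*% mixing`, with `Q`
#' a random rotation composed of Givens rotations in random channel planes
#' (angles ~ Normal(0, rotation_strength)) and `G` a diagonal gain matrix
#' with entries `gain_spread^u`, `u ~ Uniform(-1, 1)`. Band powers and noise
#' are unchanged. Deterministic in `spec$seed`.
#'
#' @param model an `mi_subject_model`.
#' @param spec an `mi_shift_spec`.
#' @return A shifted `mi_subject_model`.
#' @export
apply_shift <- function(model, spec) {
  stopifnot(inherits(model, "mi_subject_model"), inherits(spec, "mi_shift_spec"))
  M <- model$n_channels
  mixing <- with_seed(spec$seed, {
    A <- model$mixing
    if (spec$rotation_strength > 0) {
      planes <- matrix(sample.int(M, 2 * M, replace = TRUE), ncol = 2)
      planes <- planes[planes[, 1] != planes[, 2], , drop = FALSE]
      angles <- stats::rnorm(nrow(planes), 0, spec$rotation_strength)
      Q <- diag(M)
      for (r in seq_len(nrow(planes))) {
        i <- planes[r, 1]; j <- planes[r, 2]
        c_ <- cos(angles[r]); s_ <- sin(angles[r])
        Gi <- diag(M)
        Gi[i, i] <- c_; Gi[j, j] <- c_; Gi[i, j] <- -s_; Gi[j, i] <- s_
        Q <- Gi %*% Q
      }
      A <- Q %*% A
    }
    if (spec$gain_spread > 1) {
      g <- spec$gain_spread^stats::runif(M, -1, 1)
      A <- g * A
    }
    A
  })
  out <- model
  out$mixing <- mixing
  out
}

# Band-pass filter white noise into a source signal; zero-phase 4th-order
# Butterworth applied forward-backward so the band edges are not phase-shifted.
bandpass_noise <- function(n, band, fs) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, stats::rnorm(n))
}

#' Simulate labeled motor-imagery trials for one subject
#'
#' Generates `n_trials_per_class` trials per class. For each trial every
#' source is band-pass-filtered Gaussian noise rescaled to its
#' class-conditional variance, mixed into channels by the subject's mixing
#' matrix, plus white sensor noise. Fully reproducible from `seed`.
#'
#' @param model an `mi_subject_model`.
#' @param n_trials_per_class trials per class (>= 1).
#' @param trial_len_s trial duration in seconds; `trial_len_s * fs` must be
#'   at least the channel count.
#' @param seed integer seed.
#' @param subject subject id recorded on the trials.
#' @return An `mi_trialset` with `2 * n_trials_per_class` labeled trials,
#'   classes interleaved.
#' @export
simulate_subject <- function(model, n_trials_per_class, trial_len_s = 4,
                             seed = 1, subject = "s1") {
  stopifnot(inherits(model, "mi_subject_model"))
  if (n_trials_per_class < 1) stop("`n_trials_per_class` must be >= 1")
  n <- round(trial_len_s * model$fs)
  if (n < model$n_channels)
    stop("trial too short: trial_len_s * fs must be >= channel count")
  if (all(model$var_class1 == model$var_class2))
    warning("degenerate model: classes have identical source variances")
  k <- model$n_sources
  with_seed(seed, {
    trials <- vector("list", 2L * n_trials_per_class)
    for (i in seq_len(n_trials_per_class)) {
      for (cls in 1:2) {
        v <- if (cls == 1) model$var_class1 else model$var_class2
        S <- matrix(0, k, n)
        for (s in seq_len(k)) {
          if (v[s] > 0) {
            x <- bandpass_noise(n, model$bands[s, ], model$fs)
            sd_emp <- sqrt(mean((x - mean(x))^2))
            S[s, ] <- x / sd_emp * sqrt(v[s])
          }
        }
        X <- model$mixing %*% S
        if (model$noise_sd > 0)
          X <- X + matrix(stats::rnorm(length(X), 0, model$noise_sd),
                          nrow(X), ncol(X))
        trials[[2L * (i - 1L) + cls]] <-
          trial(X, label = paste0("class", cls), subject = subject, fs = model$fs)
      }
    }
    trialset(trials)
  })
}

#' Build a multi-subject source/target transfer benchmark
#'
#' Every subject receives an independently shifted copy of the base model
#' (shift seeds derived from `seed`), then simulates its own trials. Target
#' labels are included so transfer accuracy can be evaluated; the pipeline's
#' transfer regime never shows them to the classifier.
#'
#' @param n_source_subjects,n_target_subjects subject counts (>= 1).
#' @param shift an `mi_shift_spec`; its `seed` field is ignored in favour of
#'   per-subject seeds derived from `seed`.
#' @param base an `mi_subject_model`.
#' @param n_trials_per_class trials per class per subject.
#' @param trial_len_s trial length, seconds.
#' @param seed master seed.
#' @return A list with `source` and `target` `mi_trialset`s (subject ids
#'   `s1..`, `t1..`).
#' @export
make_transfer_benchmark <- function(n_source_subjects, n_target_subjects,
                                    shift = shift_spec(),
                                    base = default_subject_model(),
                                    n_trials_per_class = 50,
                                    trial_len_s = 4, seed = 1) {
  if (n_source_subjects < 1 || n_target_subjects < 1)
    stop("subject counts must be >= 1")
  sim_domain <- function(prefix, count, role) {
    sets <- lapply(seq_len(count), function(i) {
      id <- paste0(prefix, i)
      m <- apply_shift(base, shift_spec(shift$rotation_strength,
                                        shift$gain_spread,
                                        seed = derive_seed(seed, paste0("shift-", id))))
      simulate_subject(m, n_trials_per_class, trial_len_s,
                       seed = derive_seed(seed, paste0("sim-", id)), subject = id)
    })
    trials <- do.call(c, lapply(sets, function(s) s$trials))
    ts <- trialset(trials, role = role)
    ts
  }
  list(source = sim_domain("s", n_source_subjects, "source"),
       target = sim_domain("t", n_target_subjects, "target"))
}
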
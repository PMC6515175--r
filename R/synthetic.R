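# Synergy-based synthetic sEMG simulator. Interference-pattern EMG is
# modelled as band-limited Gaussian noise (20-95 Hz at fs = 200) whose
# amplitude is modulated, channel by channel, by a class-specific
# nonnegative combination of muscle-synergy activation patterns under a
# trapezoidal bout profile — the standard amplitude-modulated-noise
# surrogate for surface EMG. The structure mirrors the NinaPro DB5
# protocol: multiple subjects, repeated movement bouts interleaved with
# rest, 16 channels at 200 Hz, per-sample labels with 0 = rest.

#' Muscle-synergy channel patterns
#'
#' Builds `K` nonnegative channel patterns, each dominated by a distinct
#' channel (max-normalized to 1) over a low random background, so patterns
#' are well separated (pairwise cosine < 0.5).
#'
#' @param K number of synergies (1..`n_channels`).
#' @param n_channels number of recording channels (default 16).
#' @param seed integer seed.
#' @return matrix of class `synergy_basis`, `K x n_channels`, rows
#'   max-normalized.
#' @export
make_synergy_basis <- function(K, n_channels = 16L, seed = 1L) {
  if (K < 1L || K > n_channels) {
    stop("`K` must be between 1 and n_channels (", n_channels, ")", call. = FALSE)
  }
  with_seed(seed, {
    dominant <- sample.int(n_channels, K)
    patterns <- matrix(runif(K * n_channels, 0, 0.15), K, n_channels)
    patterns[cbind(seq_len(K), dominant)] <- 1
    patterns <- patterns / apply(patterns, 1L, max)
    structure(patterns, class = c("synergy_basis", "matrix"), dominant = dominant)
  })
}

#' Synthetic recording specification
#'
#' Defaults mirror the NinaPro DB5 structure at a size where the full
#' pipeline is exercised: 10 subjects, 6 repetitions of each movement,
#' 16 channels at 200 Hz, movement bouts interleaved with rest. The
#' low-noise defaults (rest baseline `noise_sd = 0.02` against activation
#' amplitude 2, i.e. a rest envelope about 1% of the peak movement envelope
#' on dominant channels) emulate clean recordings in which rest is close to
#' a zero linear envelope, and give well-separated classes.
#'
#' @param n_classes number of movement classes (labels `1..n_classes`;
#'   rest is label 0).
#' @param K number of synergies.
#' @param samples_per_repetition movement-bout length in samples (default
#'   192 = three 64-sample windows per bout).
#' @param repetitions movement repetitions per subject (default 6).
#' @param n_subjects number of subjects (default 10).
#' @param noise_sd baseline (rest) noise standard deviation.
#' @param subject_gain_jitter log-normal sd of per-subject-per-channel gain.
#' @param activation_amp peak amplitude of the synergy activation.
#' @param fs sampling rate in Hz (default 200).
#' @param n_channels channel count (default 16).
#' @param seed master seed.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 3L, K = 3L, samples_per_repetition = 192L,
                           repetitions = 6L, n_subjects = 10L, noise_sd = 0.02,
                           subject_gain_jitter = 0.1, activation_amp = 2,
                           fs = 200, n_channels = 16L, seed = 1L) {
  stopifnot(n_classes >= 1L, K >= 1L, noise_sd > 0, subject_gain_jitter >= 0)
  structure(list(n_classes = as.integer(n_classes), K = as.integer(K),
                 samples_per_repetition = as.integer(samples_per_repetition),
                 repetitions = as.integer(repetitions),
                 n_subjects = as.integer(n_subjects), noise_sd = noise_sd,
                 subject_gain_jitter = subject_gain_jitter,
                 activation_amp = activation_amp, fs = fs,
                 n_channels = as.integer(n_channels), seed = as.integer(seed)),
            class = "synthetic_spec")
}

# trapezoidal activation profile: 25% ramp up, 50% hold, 25% ramp down
trapezoid_profile <- function(n) {
  ramp <- max(1L, round(0.25 * n))
  hold <- n - 2L * ramp
  c(seq(0, 1, length.out = ramp + 1L)[-1L],
    rep(1, max(0L, hold)),
    seq(1, 0, length.out = ramp + 1L)[-1L])[seq_len(n)]
}

# class -> synergy mixing matrix: class g driven by synergy ((g-1) mod K)+1
# with a small contribution from the next synergy
class_mixing <- function(n_classes, K) {
  mix <- matrix(0, n_classes, K)
  for (g in seq_len(n_classes)) {
    mix[g, ((g - 1L) %% K) + 1L] <- 1
    if (K > 1L) mix[g, (g %% K) + 1L] <- mix[g, (g %% K) + 1L] + 0.15
  }
  mix
}

# band-limited (20-95 Hz) unit-variance Gaussian carrier
emg_carrier <- function(n, n_channels, fs) {
  white <- matrix(rnorm(n * n_channels), n, n_channels)
  bp <- butterworth_filter(white, fs, 20, "high")
  bp <- butterworth_filter(bp, fs, min(95, fs / 2 - 1), "low")
  sweep(bp, 2L, apply(bp, 2L, sd), `/`)
}

#' Simulate raw synthetic sEMG recordings
#'
#' One recording per subject. Each repetition cycles through every movement
#' class as a rest bout followed by a movement bout of
#' `samples_per_repetition` samples; during a movement of class g the
#' carrier amplitude follows the class's synergy combination times a
#' trapezoidal profile times the subject's per-channel gain, on top of the
#' rest baseline.
#'
#' @param spec a [synthetic_spec()].
#' @param basis a [make_synergy_basis()] matrix (`K x n_channels`).
#' @return list of [raw_recording()] objects, one per subject.
#' @export
simulate_recording <- function(spec, basis) {
  stopifnot(inherits(spec, "synthetic_spec"))
  basis <- unclass(basis)
  stopifnot(nrow(basis) == spec$K, ncol(basis) == spec$n_channels)
  mix <- class_mixing(spec$n_classes, spec$K)
  chan_amp <- mix %*% basis  # n_classes x n_channels
  bout <- spec$samples_per_repetition
  prof <- trapezoid_profile(bout)
  n_total <- spec$repetitions * spec$n_classes * 2L * bout
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_subjects), function(subj) {
      gain <- exp(rnorm(spec$n_channels, sd = spec$subject_gain_jitter))
      amp <- matrix(spec$noise_sd, n_total, spec$n_channels)
      labels <- integer(n_total)
      pos <- 0L
      for (rep_i in seq_len(spec$repetitions)) {
        for (g in seq_len(spec$n_classes)) {
          pos <- pos + bout  # rest bout: baseline only
          rows <- (pos + 1L):(pos + bout)
          amp[rows, ] <- spec$noise_sd +
            spec$activation_amp * outer(prof, chan_amp[g, ] * gain)
          labels[rows] <- g
          pos <- pos + bout
        }
      }
      samples <- emg_carrier(n_total, spec$n_channels, spec$fs) * amp
      raw_recording(samples, spec$fs, labels, subject = subj)
    })
  })
}

#' Build a segmented synthetic dataset
#'
#' Runs [simulate_recording()] through the envelope pipeline
#' ([linear_envelope()], [segment_envelope()]) and balances the rest class,
#' returning model-ready 64 x 16 examples together with the generating
#' ground truth for recovery tests.
#'
#' @param spec a [synthetic_spec()].
#' @param window,stride segmentation parameters (defaults 64 / 64).
#' @return list with `examples` (tibble: `window`, `label`, `subject`) and
#'   `truth` (list: `basis`, `mixing`, `spec`).
#' @export
make_synthetic_dataset <- function(spec = synthetic_spec(), window = 64L, stride = 64L) {
  basis <- make_synergy_basis(spec$K, spec$n_channels, seed = spec$seed)
  recs <- simulate_recording(spec, basis)
  segs <- lapply(recs, function(rec) {
    env <- linear_envelope(rec)
    segment_envelope(env, rec$labels, rec$subject, window = window, stride = stride)
  })
  examples <- dplyr::bind_rows(segs)
  examples <- balance_rest_class(examples, seed = spec$seed + 1L)
  list(examples = examples,
       truth = list(basis = basis, mixing = class_mixing(spec$n_classes, spec$K),
                    spec = spec))
}
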
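#' Raw multi-channel sEMG recording
#'
#' Container for a continuous multi-channel surface EMG recording with
#' per-sample gesture labels. NinaPro Database 5 recordings have 16 channels
#' at 200 Hz with labels 0 (rest) to 52; other channel counts are accepted.
#'
#' @param samples numeric matrix, samples x channels.
#' @param fs sampling rate in Hz.
#' @param labels integer vector of per-sample gesture ids (0 = rest), same
#'   length as `nrow(samples)`.
#' @param subject integer subject id.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(samples, fs, labels, subject = 1L) {
  samples <- as_window_matrix(samples)
  if (length(labels) != nrow(samples)) {
    stop("`labels` must have one entry per sample (got ", length(labels),
         " labels for ", nrow(samples), " samples)", call. = FALSE)
  }
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  structure(
    list(samples = samples, fs = fs, labels = as.integer(labels),
         subject = as.integer(subject)),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d samples x %d channels @ %g Hz, subject %d, %d label classes\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$subject,
              length(unique(x$labels))))
  invisible(x)
}

#' sEMG envelope signal
#'
#' Nonnegative linear-envelope signal, the amplitude profile of rectified
#' and smoothed sEMG.
#'
#' @param values nonnegative numeric matrix, samples x channels.
#' @param fs sampling rate in Hz.
#' @return an object of class `envelope_signal`.
#' @export
envelope_signal <- function(values, fs) {
  values <- as_window_matrix(values)
  if (any(values < 0)) stop("envelope values must be nonnegative", call. = FALSE)
  structure(list(values = values, fs = fs), class = "envelope_signal")
}

#' Zero-phase Butterworth filtering
#'
#' Filters every channel independently with a 4th-order Butterworth filter
#' applied forward and backward (`signal::filtfilt`), giving a zero-phase
#' response. The effective magnitude response is the square of the
#' single-pass filter's.
#'
#' @param x numeric matrix (samples x channels) or vector.
#' @param fs sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz; must be below the Nyquist `fs/2`.
#' @param mode `"high"` or `"low"` pass.
#' @param order filter order (default 4).
#' @return filtered matrix of the same shape as the input.
#' @export
butterworth_filter <- function(x, fs, cutoff, mode = c("high", "low"), order = 4L) {
  mode <- match.arg(mode)
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  x <- as_window_matrix(x)
  if (cutoff >= fs / 2) {
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)", cutoff, fs / 2),
         call. = FALSE)
  }
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  # filtfilt needs enough samples to run the filter in both directions
  min_len <- 3L * (order + 1L)
  if (nrow(x) <= min_len) {
    stop(sprintf("signal too short for order-%d zero-phase filtering: %d samples (need > %d)",
                 order, nrow(x), min_len), call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = mode)
  n <- nrow(x)
  # odd-reflection padding confines the zero-initial-condition transient of
  # the forward-backward pass to the padding (decayed < 1e-8 by ~150 samples
  # for these designs)
  pad <- min(n - 1L, 200L)
  out <- apply(x, 2L, function(col) {
    padded <- c(2 * col[1L] - col[(pad + 1L):2L],
                col,
                2 * col[n] - col[(n - 1L):(n - pad)])
    signal::filtfilt(bf, padded)[(pad + 1L):(pad + n)]
  })
  out <- matrix(out, nrow = n, ncol = ncol(x))
  if (vec) out[, 1L] else out
}

#' Full-wave rectification
#'
#' @param x numeric matrix or vector.
#' @return elementwise absolute value, shape preserved.
#' @export
rectify <- function(x) abs(x)

#' Centered moving average
#'
#' Smooths each channel with an arithmetic moving average of `window`
#' points. The window is centered (for even lengths, `window %/% 2` points
#' before and the remainder after the current sample) and the edges are
#' replicated so the output has the same length as the input.
#'
#' @param x numeric matrix (samples x channels) or vector.
#' @param window number of samples to average (default 10).
#' @return smoothed matrix/vector of the same shape.
#' @export
moving_average <- function(x, window = 10L) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  x <- as_window_matrix(x)
  window <- as.integer(window)
  if (window < 1L) stop("`window` must be >= 1", call. = FALSE)
  n <- nrow(x)
  if (window > n) {
    stop(sprintf("moving-average window (%d) exceeds signal length (%d)", window, n),
         call. = FALSE)
  }
  left <- window %/% 2L
  right <- window - 1L - left
  padded <- rbind(
    x[rep(1L, left), , drop = FALSE],
    x,
    x[rep(n, right), , drop = FALSE]
  )
  cs <- apply(padded, 2L, function(col) cumsum(c(0, col)))
  out <- (cs[(window + 1L):(window + n), , drop = FALSE] - cs[1L:n, , drop = FALSE]) / window
  if (vec) out[, 1L] else out
}

#' sEMG linear envelope
#'
#' Standard linear-envelope pipeline: 10 Hz high-pass (movement-artefact
#' removal), full-wave rectification, 10-point moving average, 30 Hz
#' low-pass. All filters are zero-phase 4th-order Butterworth. Small
#' negative overshoot from the final low-pass is clipped to zero so the
#' envelope is nonnegative.
#'
#' @param recording a [raw_recording()].
#' @param highpass_cutoff high-pass cutoff in Hz (default 10).
#' @param lowpass_cutoff low-pass cutoff in Hz (default 30).
#' @param ma_window moving-average length in samples (default 10).
#' @return an [envelope_signal()] with the same length and channel count.
#' @export
linear_envelope <- function(recording, highpass_cutoff = 10, lowpass_cutoff = 30,
                            ma_window = 10L) {
  stopifnot(inherits(recording, "raw_recording"))
  x <- butterworth_filter(recording$samples, recording$fs, highpass_cutoff, "high")
  x <- rectify(x)
  x <- moving_average(x, ma_window)
  x <- butterworth_filter(x, recording$fs, lowpass_cutoff, "low")
  envelope_signal(pmax(x, 0), recording$fs)
}

#' Segment an envelope into fixed-size labelled windows
#'
#' Cuts the envelope into windows of `window` samples advanced by `stride`
#' samples (default: non-overlapping 64-sample windows). Each window is
#' labelled with the majority per-sample gesture id; windows whose majority
#' is tied are discarded, as is any trailing partial window.
#'
#' @param envelope an [envelope_signal()] or a samples x channels matrix.
#' @param labels integer per-sample gesture ids.
#' @param subject integer subject id attached to every window.
#' @param window window length in samples (default 64).
#' @param stride hop between window starts (default `window`).
#' @return a tibble with list-column `window` (each a `window x channels`
#'   matrix), integer `label` and `subject`.
#' @export
segment_envelope <- function(envelope, labels, subject = 1L, window = 64L, stride = 64L) {
  values <- if (inherits(envelope, "envelope_signal")) envelope$values else as_window_matrix(envelope)
  window <- as.integer(window); stride <- as.integer(stride)
  if (length(labels) != nrow(values)) {
    stop("`labels` length must match the number of envelope samples", call. = FALSE)
  }
  n <- nrow(values)
  if (n < window) {
    return(tibble::tibble(window = list(), label = integer(), subject = integer()))
  }
  starts <- seq(1L, n - window + 1L, by = stride)
  wins <- vector("list", length(starts))
  labs <- integer(length(starts))
  keep <- logical(length(starts))
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + window - 1L)
    tab <- table(labels[idx])
    top <- which(tab == max(tab))
    if (length(top) > 1L) next  # ambiguous majority: drop the window
    wins[[k]] <- values[idx, , drop = FALSE]
    labs[k] <- as.integer(names(tab)[top])
    keep[k] <- TRUE
  }
  tibble::tibble(
    window = wins[keep],
    label = labs[keep],
    subject = rep(as.integer(subject), sum(keep))
  )
}

#' Subsample the rest class to balance a segmented dataset
#'
#' Rest windows (label 0) vastly outnumber movement windows in protocols
#' that interleave rest between movements. This randomly subsamples the
#' rest class down to the median per-class count of the non-rest classes
#' (no-op if rest is already at or below that target). Non-rest examples
#' are untouched; the draw is deterministic given `seed`.
#'
#' @param examples tibble from [segment_envelope()] (columns `window`,
#'   `label`, `subject`).
#' @param seed integer seed for the subsampling draw.
#' @return the balanced tibble.
#' @export
balance_rest_class <- function(examples, seed = 1L) {
  stopifnot(is.data.frame(examples), nrow(examples) > 0L)
  rest <- which(examples$label == 0L)
  counts <- table(examples$label[examples$label != 0L])
  if (length(counts) == 0L || length(rest) == 0L) return(examples)
  target <- floor(median(as.numeric(counts)))
  if (length(rest) <= target) return(examples)
  keep_rest <- with_seed(seed, sort(sample(rest, target)))
  keep <- sort(c(keep_rest, which(examples$label != 0L)))
  examples[keep, , drop = FALSE]
}
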
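#' Filtering configuration
#'
#' Cutoffs for the standard preprocessing chain: 0.3 Hz high-pass, 70 Hz
#' low-pass and a 50 Hz notch, realized as zero-phase (forward-backward)
#' recursive filters -- a 4th-order band-pass implemented as an order-2
#' high-pass plus order-2 low-pass cascade, and an order-2 band-stop notch.
#' Zero-phase filtering avoids the phase distortion that would otherwise
#' leak into the entropy estimates.
#'
#' @param notch_hz Mains frequency to suppress.
#' @param highpass_hz High-pass cutoff (drift/DC removal).
#' @param lowpass_hz Low-pass cutoff (EMG suppression).
#' @param notch_halfwidth_hz Half-width of the band-stop notch.
#' @param order Order of each recursive section.
#' @param zero_phase Apply forward-backward filtering.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(notch_hz = 50, highpass_hz = 0.3, lowpass_hz = 70,
                          notch_halfwidth_hz = 2, order = 2,
                          zero_phase = TRUE) {
  if (highpass_hz <= 0 || lowpass_hz <= highpass_hz)
    stop("invalid band ordering: need 0 < highpass < lowpass")
  if (notch_hz <= highpass_hz || notch_hz >= lowpass_hz)
    stop("notch frequency must lie inside the pass band")
  structure(list(notch_hz = notch_hz, highpass_hz = highpass_hz,
                 lowpass_hz = lowpass_hz,
                 notch_halfwidth_hz = notch_halfwidth_hz,
                 order = order, zero_phase = zero_phase),
            class = "filter_config")
}

# filter one numeric series; shared by apply_filters and the generator's
# calibration transform
filter_series <- function(x, cfg, fs) {
  nyq <- fs / 2
  if (cfg$lowpass_hz >= nyq)
    stop("lowpass cutoff must be below the Nyquist frequency")
  run <- function(x, flt)
    if (cfg$zero_phase) signal::filtfilt(flt, x) else
      as.numeric(signal::filter(flt, x))
  hp <- signal::butter(cfg$order, cfg$highpass_hz / nyq, type = "high")
  lp <- signal::butter(cfg$order, cfg$lowpass_hz / nyq, type = "low")
  bs <- signal::butter(cfg$order,
                       c(cfg$notch_hz - cfg$notch_halfwidth_hz,
                         cfg$notch_hz + cfg$notch_halfwidth_hz) / nyq,
                       type = "stop")
  run(run(run(x, hp), lp), bs)
}

#' Apply the preprocessing filters to a recording
#'
#' @param rec An `eeg_recording`.
#' @param cfg A [filter_config()].
#' @return A filtered `eeg_recording` of identical shape.
#' @export
apply_filters <- function(rec, cfg = filter_config()) {
  out <- rec
  for (i in seq_len(nrow(rec$signal)))
    out$signal[i, ] <- filter_series(rec$signal[i, ], cfg, rec$fs)
  out
}

#' Select the analysis segment of a recording
#'
#' Discards a configurable initial noisy portion, then returns a contiguous
#' block of exactly `n_points` samples per channel (65.536 s at 500 Hz for
#' the default 32,768 points).  If the recording is long enough for the
#' block but not for the full discard, the discard is shortened; a recording
#' shorter than `n_points` is an error.
#'
#' @param rec An `eeg_recording`.
#' @param n_points Number of consecutive samples to keep.
#' @param discard_s Initial portion to discard, in seconds.
#' @return An `eeg_recording` of exactly `n_points` samples.
#' @export
select_segment <- function(rec, n_points = 32768L, discard_s = 2) {
  n <- ncol(rec$signal)
  if (n < n_points)
    stop(sprintf("recording too short: %d samples < %d required",
                 n, n_points))
  discard <- min(round(discard_s * rec$fs), n - n_points)
  out <- rec
  out$signal <- rec$signal[, (discard + 1):(discard + n_points), drop = FALSE]
  out
}

#' Cut a recording into non-overlapping epochs
#'
#' Either a fixed number of segments (`n_segments`, equal length
#' `floor(n / n_segments)`, trailing remainder discarded) or a fixed epoch
#' duration (`epoch_s`, e.g. 1 s epochs at 500 Hz give 500-sample epochs).
#'
#' @param rec An `eeg_recording`.
#' @param n_segments Number of equal-length segments.
#' @param epoch_s Alternatively, a fixed epoch duration in seconds
#'   (overrides `n_segments` when given).
#' @return List of `eeg_epoch` objects, ordered and non-overlapping.
#' @export
segment_epochs <- function(rec, n_segments = 60L, epoch_s = NULL) {
  n <- ncol(rec$signal)
  if (!is.null(epoch_s)) {
    len <- floor(epoch_s * rec$fs)
    n_segments <- n %/% len
    if (n_segments < 1) stop("recording shorter than one epoch")
  } else {
    if (n_segments < 1) stop("n_segments must be >= 1")
    if (n < n_segments) stop("fewer samples than requested segments")
    len <- n %/% n_segments
  }
  lapply(seq_len(n_segments), function(k) {
    cols <- ((k - 1) * len + 1):(k * len)
    new_epoch(rec$signal[, cols, drop = FALSE], start = cols[1],
              fs = rec$fs, condition = rec$condition,
              patient_id = rec$patient_id, index = k)
  })
}

#' Screen epochs for montage-wide entropy inflation
#'
#' Automated stand-in for visual artifact rejection: EMG contamination
#' inflates ApEn across the whole montage, so epochs whose montage-mean ApEn
#' exceeds the recording's mean by more than `k` SDs are excluded.  Refuses
#' recordings where more than half the epochs would be excluded.
#'
#' @param frames List of `apen_frame` objects from one recording (>= 5).
#' @param k SD multiplier for the exclusion threshold.
#' @return List with `kept` and `excluded` (1-based frame indices) and
#'   `threshold`.
#' @export
entropy_inflation_screen <- function(frames, k = 3) {
  if (length(frames) < 5) stop("need at least 5 frames to screen")
  means <- vapply(frames, function(f) mean(as.numeric(f)), numeric(1))
  thr <- mean(means) + k * sd(means)
  excluded <- which(means > thr)
  if (length(excluded) > length(frames) / 2)
    stop("quality error: more than half of the epochs are entropy-inflated; ",
         "recording looks contaminated")
  list(kept = setdiff(seq_along(frames), excluded), excluded = excluded,
       threshold = thr)
}
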
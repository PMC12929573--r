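#' Construct a multichannel EEG recording
#'
#' The basic signal container: a 16 x n matrix of microvolt samples with
#' sampling-rate and montage metadata, one per patient-condition.
#'
#' @param signal Numeric matrix, channels x samples (rows in montage order).
#' @param fs Sampling rate in Hz.
#' @param channels Ordered channel labels; must be 16 unique labels from
#'   [doc_montage()].
#' @param condition `"resting"` or `"music"`.
#' @param patient_id Opaque patient identifier.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs = 500, channels = doc_montage(),
                          condition = c("resting", "music"),
                          patient_id = "P000") {
  condition <- match.arg(condition)
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("signal must be a numeric matrix (channels x samples)")
  if (nrow(signal) != 16L)
    stop("recording must have exactly 16 channels, got ", nrow(signal))
  if (length(channels) != 16L || anyDuplicated(channels) > 0)
    stop("channels must be 16 unique labels")
  if (!all(channels %in% doc_montage()))
    stop("channel labels must come from the fixed 10-20 montage set")
  structure(list(signal = signal, fs = fs, channels = channels,
                 condition = condition, patient_id = patient_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d ch x %d samples @ %g Hz (%.3f s)\n",
              x$patient_id, x$condition, nrow(x$signal), ncol(x$signal),
              x$fs, ncol(x$signal) / x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `eeg_recording`.
#' @return Length in seconds (`n_samples / fs`).
#' @export
recording_duration <- function(rec) ncol(rec$signal) / rec$fs

# One analysis epoch: a channels x L block cut from a parent recording.
new_epoch <- function(signal, start, fs, condition, patient_id, index) {
  structure(list(signal = signal, start = start, fs = fs,
                 condition = condition, patient_id = patient_id,
                 index = index),
            class = "eeg_epoch")
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %s [%s] #%d: %d ch x %d samples (start %d)\n",
              x$patient_id, x$condition, x$index, nrow(x$signal),
              ncol(x$signal), x$start))
  invisible(x)
}
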
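# Minimal EDF (European Data Format) I/O for 16-channel recordings:
# ASCII headers, 1-second data records, little-endian 16-bit samples with
# linear physical scaling.  Covers exactly the dialect this package writes
# (identical sampling rate on all channels); not a general-purpose reader.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' 16-bit samples with physical range +/- 500 uV and digital range
#' -32768..32767, one-second data records.  Samples beyond the last whole
#' second are dropped (EDF stores an integer number of fixed-length
#' records).
#'
#' @param rec An `eeg_recording` (microvolt units).
#' @param path Output file path.
#' @param phys_range Physical scaling range in uV.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path, phys_range = c(-500, 500)) {
  ns <- nrow(rec$signal)
  spr <- as.integer(rec$fs)            # samples per record per signal
  n_rec <- ncol(rec$signal) %/% spr
  if (n_rec < 1) stop("recording shorter than one EDF record")
  con <- file(path, "wb")
  on.exit(close(con))

  header <- paste0(
    pad_field("0", 8),
    pad_field(rec$patient_id, 80),
    pad_field(paste("condition:", rec$condition), 80),
    pad_field("01.01.24", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),
    pad_field(ns, 4))
  writeChar(header, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, pad_field, "", width = width),
                    collapse = ""), con, eos = NULL)
  field(rec$channels, 16)
  field(rep("", ns), 80)                      # transducer
  field(rep("uV", ns), 8)
  field(rep(phys_range[1], ns), 8)
  field(rep(phys_range[2], ns), 8)
  field(rep(-32768L, ns), 8)
  field(rep(32767L, ns), 8)
  field(rep("HP:0.3Hz LP:70Hz N:50Hz", ns), 80)
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)

  gain <- 65535 / diff(phys_range)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    block <- rec$signal[, cols, drop = FALSE]
    dig <- round((block - phys_range[1]) * gain) - 32768
    dig <- pmin(pmax(dig, -32768), 32767)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return An `eeg_recording` (condition taken from the recording-id header
#'   field when present).
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                  # version
  patient_id <- rd(80)
  rec_id <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  per_sig <- function(width)
    vapply(seq_len(ns), function(i) rd(width), "")
  labels <- per_sig(16)
  per_sig(80)
  per_sig(8)                             # dimension
  pmin_ <- as.numeric(per_sig(8))
  pmax_ <- as.numeric(per_sig(8))
  dmin_ <- as.numeric(per_sig(8))
  dmax_ <- as.numeric(per_sig(8))
  per_sig(80)
  spr <- as.integer(per_sig(8))
  per_sig(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / rec_dur
  total <- n_rec * spr[1]
  sig <- matrix(0, nrow = ns, ncol = total)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little", signed = TRUE)
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (i in seq_len(ns)) {
      gain <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
      sig[i, cols] <- (block[, i] - dmin_[i]) * gain + pmin_[i]
    }
  }
  rownames(sig) <- labels
  condition <- if (grepl("music", rec_id)) "music" else "resting"
  eeg_recording(sig, fs = fs, channels = labels, condition = condition,
                patient_id = patient_id)
}
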
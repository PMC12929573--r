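#' Approximate-entropy parameters
#'
#' Bundles the ApEn parameterization used across the pipeline: embedding
#' length `m = 2`, tolerance `r` equal to 20% of the series SD, and a
#' sliding-window length capped at 4096 samples.
#'
#' @param m Embedding (template) length, >= 1.
#' @param r_coeff Tolerance as a fraction of the series SD, in (0, 1].
#' @param window_len Sliding-window length in samples; values above 4096 are
#'   capped at 4096.
#' @param step Window step in samples; defaults to a non-overlapping step
#'   equal to `window_len`.
#' @return A list of class `apen_params`.
#' @export
apen_params <- function(m = 2, r_coeff = 0.2, window_len = 4096,
                        step = window_len) {
  if (m < 1) stop("m must be >= 1")
  if (r_coeff <= 0 || r_coeff > 1) stop("r_coeff must be in (0, 1]")
  window_len <- min(window_len, 4096L)
  if (window_len <= m + 1) stop("window_len must exceed m + 1")
  if (step < 1) stop("step must be >= 1")
  structure(list(m = as.integer(m), r_coeff = r_coeff,
                 window_len = as.integer(window_len),
                 step = as.integer(step)),
            class = "apen_params")
}

#' Tolerance for ApEn template matching
#'
#' Computes `r_coeff * SD(x)`, using the population SD (divide by n).  A
#' constant series yields a zero tolerance, which downstream code treats as
#' the fully regular
#' degenerate case.
#'
#' @param x Numeric series of length >= 2.
#' @param r_coeff Fraction of the SD, default 0.20.
#' @return Tolerance in the amplitude units of `x`.
#' @export
apen_tolerance <- function(x, r_coeff = 0.2) {
  if (length(x) < 2) stop("series must have length >= 2 to define a tolerance")
  r_coeff * sqrt(mean((x - mean(x))^2))
}

#' Approximate entropy of a series
#'
#' Classical ApEn (Pincus): `Phi^m(r) - Phi^(m+1)(r)` with
#' `Phi^k = (L-k+1)^-1 sum_i log C_i^k(r)`, where `C_i^k(r)` is the fraction
#' of templates of length `k` within Chebyshev distance `r` of template `i`,
#' self-matches included.  Zero for perfectly regular series; larger for
#' irregular ones.  A zero tolerance returns 0 by the degenerate-input rule.
#'
#' @param x Numeric series, length > m + 1, all finite.
#' @param m Embedding length.
#' @param r Tolerance in amplitude units; if `NULL`, computed as
#'   `r_coeff * SD(x)` (population SD).
#' @param r_coeff Used only when `r` is `NULL`.
#' @return Non-negative scalar.
#' @export
approximate_entropy <- function(x, m = 2, r = NULL, r_coeff = 0.2) {
  if (length(x) <= m + 1)
    stop("series too short: need length > m + 1")
  if (any(!is.finite(x))) stop("non-finite samples in input series")
  if (is.null(r)) r <- apen_tolerance(x, r_coeff)
  apen_cpp(as.numeric(x), as.integer(m), r)
}

#' Sliding-window approximate entropy
#'
#' One ApEn value per window start `1, 1+step, 1+2*step, ...` for as long as
#' a full window fits.  The tolerance is recomputed per window from that
#' window's own SD.
#'
#' @param x Numeric series.
#' @param params An [apen_params()] object.
#' @return Numeric vector of per-window ApEn values, with window starts
#'   (1-based) as the `starts` attribute.
#' @export
sliding_apen <- function(x, params = apen_params()) {
  wl <- min(params$window_len, 4096L)
  n <- length(x)
  if (wl > n) stop("window_len exceeds series length")
  starts <- seq.int(1L, n - wl + 1L, by = params$step)
  vals <- vapply(starts, function(s) {
    w <- x[s:(s + wl - 1L)]
    approximate_entropy(w, m = params$m, r = apen_tolerance(w, params$r_coeff))
  }, numeric(1))
  attr(vals, "starts") <- starts
  vals
}

#' Channel-wise ApEn of one epoch
#'
#' Computes one ApEn value per channel of a 16-channel epoch, with the
#' tolerance taken per channel from that channel's samples in the epoch.
#'
#' @param epoch An `eeg_epoch` (16 x L block).
#' @param params An [apen_params()] object.
#' @return An `apen_frame`: named numeric vector of 16 values in montage
#'   order, carrying `patient_id`, `condition` and `epoch` attributes.
#' @export
channel_apen <- function(epoch, params = apen_params()) {
  sig <- epoch$signal
  if (nrow(sig) != 16L)
    stop("montage error: epoch must have exactly 16 channels")
  vals <- vapply(seq_len(nrow(sig)), function(i) {
    w <- sig[i, ]
    approximate_entropy(w, m = params$m, r = apen_tolerance(w, params$r_coeff))
  }, numeric(1))
  names(vals) <- rownames(sig) %||% doc_montage()
  structure(vals, class = "apen_frame",
            patient_id = epoch$patient_id, condition = epoch$condition,
            epoch = epoch$index)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Frames as a long-format table
#'
#' @param frames List of `apen_frame` objects.
#' @return data.frame with columns `patient_id`, `condition`, `epoch`,
#'   `channel`, `apen` (one row per channel per frame).
#' @export
frames_to_df <- function(frames) {
  if (length(frames) == 0)
    return(data.frame(patient_id = character(), condition = character(),
                      epoch = integer(), channel = character(),
                      apen = numeric()))
  do.call(rbind, lapply(frames, function(f) {
    data.frame(patient_id = attr(f, "patient_id") %||% NA_character_,
               condition = attr(f, "condition") %||% NA_character_,
               epoch = attr(f, "epoch") %||% NA_integer_,
               channel = names(f), apen = as.numeric(f),
               stringsAsFactors = FALSE)
  }))
}

#' Mean ApEn over epochs
#'
#' Per-channel and montage-wide means over a set of frames, optionally
#' restricted to one condition and/or one channel.
#'
#' @param frames List of `apen_frame` objects (or a long data.frame from
#'   [frames_to_df()]).
#' @param channel Optional channel label to extract a single mean.
#' @param condition Optional condition filter (`"resting"`/`"music"`).
#' @return If `channel` is given, a scalar; otherwise a list with
#'   `per_channel` (named vector) and `overall` (montage-wide mean).
#' @export
patient_mean_apen <- function(frames, channel = NULL, condition = NULL) {
  df <- if (is.data.frame(frames)) frames else frames_to_df(frames)
  if (!is.null(condition)) df <- df[df$condition == condition, , drop = FALSE]
  if (nrow(df) == 0) stop("empty frame selection")
  per <- tapply(df$apen, df$channel, mean)
  per <- per[intersect(doc_montage(), names(per))]
  if (!is.null(channel)) {
    if (!channel %in% names(per)) stop("channel not present in frames: ", channel)
    return(unname(per[[channel]]))
  }
  list(per_channel = per, overall = mean(df$apen))
}
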
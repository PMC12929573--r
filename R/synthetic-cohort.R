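#' Reference group-level ApEn summary table
#'
#' Published group summary statistics for a 76-patient DOC training cohort:
#' per electrode and condition, mean +/- SD of the channel-mean ApEn in the
#' VS/UWS (n = 39) and MCS (n = 37) groups, with the one-way ANOVA F and
#' p-value.  These values parameterize the synthetic generator (they are its
#' per-channel complexity targets) and drive the 15-feature screening
#' arithmetic.
#'
#' @return data.frame with columns `electrode`, `condition`, `mean_vs`,
#'   `sd_vs`, `mean_mcs`, `sd_mcs`, `F`, `p`.
#' @export
reference_apen_table <- function() {
  path <- system.file("extdata", "reference_group_apen.csv",
                      package = "docapen", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' MIX-family test series
#'
#' A deterministic 10 Hz sinusoid whose samples are independently replaced by
#' i.i.d. uniform noise with probability `p` -- the classical MIX(p) family,
#' whose expected ApEn increases monotonically with `p`.  The result is
#' standardized to zero mean and unit variance.
#'
#' @param p Replacement probability in \[0, 1\].
#' @param n Series length, >= 100.
#' @param seed Optional integer seed (the caller's RNG stream is preserved).
#' @param freq Carrier frequency in Hz.
#' @param fs Nominal sampling rate in Hz.
#' @return Numeric series of length `n`, zero mean, unit variance.
#' @export
mix_series <- function(p, n, seed = NULL, freq = 10, fs = 500) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop("p must be a single value in [0, 1]")
  if (n < 100) stop("n must be >= 100")
  with_seed(seed, {
    s <- sqrt(2) * sin(2 * pi * freq * (0:(n - 1)) / fs)
    z <- runif(n, -sqrt(3), sqrt(3))
    mask <- runif(n) < p
    x <- ifelse(mask, z, s)
    sdev <- sqrt(mean((x - mean(x))^2))
    if (sdev > 0) (x - mean(x)) / sdev else x - mean(x)
  })
}

# package-local cache for p -> ApEn calibration curves
.calib_cache <- new.env(parent = emptyenv())

# Simulated mean ApEn of MIX(p) over a grid of p, monotonized.  `transform`
# lets the caller calibrate against the post-filtering signal the pipeline
# actually measures.
mix_apen_curve <- function(m = 2, r_coeff = 0.2, n = 1024, reps = 16,
                           seed = 1402, transform = identity,
                           transform_key = "id",
                           grid = seq(0, 1, by = 0.1)) {
  key <- paste(m, r_coeff, n, reps, seed, transform_key,
               paste(grid, collapse = ","), sep = "|")
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  # For a non-trivial transform (filtering), simulate on a padded series and
  # crop the center, mirroring the pipeline (filter the long recording, then
  # cut windows) and avoiding filter edge transients.
  pad <- if (identical(transform_key, "id")) 0L else 512L
  apen_at <- function(p) {
    mean(vapply(seq_len(reps), function(k) {
      x <- transform(mix_series(p, n + 2L * pad,
                                seed = derive_seed(seed, paste(p, k))))
      if (pad > 0) x <- x[(pad + 1):(pad + n)]
      approximate_entropy(x, m = m, r = apen_tolerance(x, r_coeff))
    }, numeric(1)))
  }
  vals <- vapply(grid, apen_at, numeric(1))
  vals <- cummax(vals)  # enforce monotonicity against simulation jitter
  curve <- list(p = grid, apen = vals)
  .calib_cache[[key]] <- curve
  curve
}

#' Calibrate a MIX weight to a target ApEn
#'
#' Inverts the monotone p -> expected-ApEn curve of the MIX family (estimated
#' by simulation and cached) so the generator can hit a requested channel
#' complexity.
#'
#' @param target_apen Target expected ApEn value.
#' @param m,r_coeff ApEn parameters used for the calibration.
#' @param n Series length used in calibration simulations.
#' @param reps Simulated series per grid point.
#' @param seed Seed for the calibration simulations.
#' @param transform Optional function applied to each simulated series before
#'   ApEn (e.g. the pipeline's band-pass filter), so the calibration matches
#'   what is measured downstream.
#' @param transform_key Cache key naming `transform`.
#' @return Weight `p` in \[0, 1\] whose simulated mean ApEn is close to
#'   `target_apen` (within about +/- 0.05).  Errors when the target lies
#'   outside the achievable range, naming the bounds.
#' @export
calibrate_complexity <- function(target_apen, m = 2, r_coeff = 0.2, n = 1024,
                                 reps = 16, seed = 1402,
                                 transform = identity, transform_key = "id") {
  curve <- mix_apen_curve(m, r_coeff, n, reps, seed, transform, transform_key)
  lo <- min(curve$apen); hi <- max(curve$apen)
  if (target_apen < lo || target_apen > hi)
    stop(sprintf(
      "target ApEn %.3f outside achievable MIX range [%.3f, %.3f]",
      target_apen, lo, hi))
  keep <- !duplicated(curve$apen)
  approx(curve$apen[keep], curve$p[keep], xout = target_apen,
         ties = "ordered")$y
}

#' Cohort generator configuration
#'
#' Defaults encode the study conditions the generator emulates: 500 Hz
#' 16-channel recordings of 70 s per condition, group-level channel targets
#' from [reference_apen_table()], a patient-level complexity offset (SD
#' `sigma_patient`) shared across channels and conditions, independent
#' per-channel jitter (SD `sigma_channel`), and a CRS-R coupling tuned to a
#' Spearman correlation of about 0.4 between mean ApEn and CRS-R total in
#' MCS (and none in VS/UWS).
#'
#' @param duration_s Recording length per condition in seconds (>= 66).
#' @param fs Sampling rate, Hz.
#' @param sigma_patient SD of the patient-level ApEn offset.
#' @param sigma_channel SD of the channel-level ApEn jitter.
#' @param amplitude_uv Signal scale in microvolts (SD of each channel).
#' @param line_noise_uv Amplitude of the injected 50 Hz mains component.
#' @param crs_gain Gain coupling the standardized patient offset into the
#'   MCS CRS-R total.
#' @param crs_noise_sd SD of the integer noise added to CRS-R totals.
#' @param calib_n,calib_reps Series length / replicates for calibration.
#' @param train_frac Fraction of each class assigned to the training split.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(duration_s = 70, fs = 500, sigma_patient = 0.06,
                          sigma_channel = 0.04, amplitude_uv = 30,
                          line_noise_uv = 5, crs_gain = 1, crs_noise_sd = 2,
                          calib_n = 546, calib_reps = 12, train_frac = 0.7) {
  structure(list(duration_s = duration_s, fs = fs,
                 sigma_patient = sigma_patient,
                 sigma_channel = sigma_channel,
                 amplitude_uv = amplitude_uv, line_noise_uv = line_noise_uv,
                 crs_gain = crs_gain, crs_noise_sd = crs_noise_sd,
                 calib_n = calib_n, calib_reps = calib_reps,
                 train_frac = train_frac),
            class = "cohort_config")
}

# group-level channel targets (named 16-vectors) for one label & condition
group_targets <- function(label, condition, tbl = reference_apen_table()) {
  sub <- tbl[tbl$condition == condition, , drop = FALSE]
  col <- if (label == "MCS") "mean_mcs" else "mean_vs"
  stats::setNames(sub[[col]], sub$electrode)[doc_montage()]
}

# the band-limiting transform used for calibration: the generator's channels
# are measured after the pipeline's filters, which lower the ApEn of the
# noise component
calibration_transform <- function(fs = 500) {
  function(x) filter_series(x, filter_config(), fs)
}

#' Generate one synthetic patient (both conditions)
#'
#' Builds two 16-channel recordings (resting, music) whose per-channel ApEn
#' tracks the supplied complexity profiles: each channel is a MIX(p) series
#' with `p` calibrated so the post-filter epoch-mean ApEn lands on the
#' channel's target, scaled to a physiological amplitude, with a small 50 Hz
#' mains component added (removed again by the notch filter downstream).
#'
#' @param meta List/1-row data.frame with at least `patient_id` and `label`.
#' @param profiles List with named 16-vectors `resting` and `music` of target
#'   ApEn values per channel.
#' @param duration_s Recording duration per condition (>= 66 s so one
#'   32,768-sample selection fits after the initial discard).
#' @param seed Integer seed; the same seed and meta reproduce the recordings
#'   exactly.
#' @param config A [cohort_config()].
#' @param emg_burst If `TRUE`, one epoch-length window (epoch 30 of the
#'   default segmentation) is replaced on all channels by high-amplitude
#'   broadband noise, emulating an EMG artifact for screening tests.
#' @return List with elements `resting` and `music` (`eeg_recording`s).
#' @export
generate_patient <- function(meta, profiles, duration_s = 70, seed = 1,
                             config = cohort_config(), emg_burst = FALSE) {
  if (duration_s < 66)
    stop("duration_s must be >= 66 so a 32,768-sample selection fits")
  n <- round(duration_s * config$fs)
  tf <- calibration_transform(config$fs)
  one <- function(condition) {
    targets <- profiles[[condition]]
    sig <- matrix(0, nrow = 16, ncol = n,
                  dimnames = list(doc_montage(), NULL))
    tvec <- (0:(n - 1)) / config$fs
    mains <- config$line_noise_uv * sin(2 * pi * 50 * tvec)
    curve <- mix_apen_curve(n = config$calib_n, reps = config$calib_reps,
                            transform = tf, transform_key = "bandpass")
    for (i in seq_len(16)) {
      tgt <- min(max(targets[i], min(curve$apen) + 1e-6),
                 max(curve$apen) - 1e-6)
      p <- calibrate_complexity(tgt, n = config$calib_n,
                                reps = config$calib_reps,
                                transform = tf, transform_key = "bandpass")
      ch_seed <- derive_seed(seed, paste(meta$patient_id, condition, i))
      sig[i, ] <- config$amplitude_uv * mix_series(p, n, seed = ch_seed) +
        mains
    }
    if (isTRUE(emg_burst)) {
      ep_len <- 32768L %/% 60L
      start <- 2L * config$fs + 29L * ep_len + 1L
      idx <- start:(start + ep_len - 1L)
      sig[, idx] <- matrix(
        with_seed(derive_seed(seed, paste(meta$patient_id, condition, "emg")),
                  rnorm(16 * ep_len, sd = 3 * config$amplitude_uv)),
        nrow = 16)
    }
    eeg_recording(sig, fs = config$fs, condition = condition,
                  patient_id = meta$patient_id)
  }
  list(resting = one("resting"), music = one("music"))
}

# integer CRS-R scores consistent with the class medians, with the MCS total
# coupled to the patient's standardized complexity offset
draw_crs <- function(label, z, config) {
  if (label == "MCS") {
    total <- 9 + round(config$crs_gain * z + rnorm(1, 0, config$crs_noise_sd))
    total <- min(max(total, 6), 14)
    auditory <- min(max(2 + round(rnorm(1, 0, 0.7)), 1), 4)
  } else {
    total <- min(max(4 + round(rnorm(1, 0, 1.5)), 0), 8)
    auditory <- min(max(1 + round(rnorm(1, 0, 0.5)), 0), 2)
  }
  list(total = as.integer(total), auditory = as.integer(auditory))
}

#' Generate a labeled synthetic cohort
#'
#' Draws `n_vs` VS/UWS and `n_mcs` MCS patients.  Each patient gets a
#' complexity offset shared across channels and conditions plus per-channel
#' jitter around the group-level targets, CRS-R scores coupled to that
#' offset (MCS only), and a stratified train/test split.
#'
#' @param n_vs,n_mcs Patients per class (>= 1).
#' @param config A [cohort_config()].
#' @param seed Master seed; everything (profiles, signals, scores, split) is
#'   derived from it.
#' @return A list of class `doc_cohort`: `meta` (data.frame with patient_id,
#'   label, crs_r_total, crs_r_auditory, age, sex, days_post_injury, split),
#'   `recordings` (per patient: list(resting, music)), `profiles`, `config`.
#' @export
generate_cohort <- function(n_vs, n_mcs, config = cohort_config(), seed = 1) {
  if (n_vs < 1 || n_mcs < 1) stop("n_vs and n_mcs must be >= 1")
  labels <- c(rep("VS_UWS", n_vs), rep("MCS", n_mcs))
  ids <- sprintf("P%03d", seq_along(labels))
  tbl <- reference_apen_table()

  meta_rows <- list(); profiles <- list(); recs <- list()
  for (k in seq_along(ids)) {
    pid <- ids[k]; lab <- labels[k]
    prof_seed <- derive_seed(seed, paste("profile", pid))
    draws <- with_seed(prof_seed, {
      delta <- rnorm(1, 0, config$sigma_patient)
      eps <- rnorm(16, 0, config$sigma_channel)
      crs <- draw_crs(lab, delta / config$sigma_patient, config)
      age <- round(min(max(rnorm(1, 62, 13), 19), 90))
      sex <- if (runif(1) < 0.68) "M" else "F"
      dpi <- round(exp(rnorm(1, log(80), 0.6)))
      list(delta = delta, eps = eps, crs = crs, age = age, sex = sex,
           dpi = dpi)
    })
    prof <- list(
      resting = group_targets(lab, "resting", tbl) + draws$delta + draws$eps,
      music   = group_targets(lab, "music", tbl) + draws$delta + draws$eps)
    profiles[[pid]] <- prof
    recs[[pid]] <- generate_patient(
      list(patient_id = pid, label = lab), prof,
      duration_s = config$duration_s,
      seed = derive_seed(seed, paste("signal", pid)), config = config)
    meta_rows[[k]] <- data.frame(
      patient_id = pid, label = lab,
      crs_r_total = draws$crs$total, crs_r_auditory = draws$crs$auditory,
      age = draws$age, sex = draws$sex, days_post_injury = draws$dpi,
      delta = draws$delta, stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta_rows)
  meta$split <- with_seed(derive_seed(seed, "split"), {
    split <- rep("test", nrow(meta))
    for (lab in unique(meta$label)) {
      idx <- which(meta$label == lab)
      n_train <- round(config$train_frac * length(idx))
      split[sample(idx, n_train)] <- "train"
    }
    split
  })
  structure(list(meta = meta, recordings = recs, profiles = profiles,
                 config = config, seed = seed),
            class = "doc_cohort")
}

#' @export
print.doc_cohort <- function(x, ...) {
  tab <- table(x$meta$label)
  cat(sprintf("<doc_cohort> %d patients (%s), %d recordings @ %g Hz\n",
              nrow(x$meta),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              2L * nrow(x$meta), x$config$fs))
  invisible(x)
}

#' Serialize a cohort to EDF files plus a metadata table
#'
#' Writes one EDF per patient-condition (16-bit samples, physical range
#' +/- 500 uV) and a `cohort.csv` with patient metadata and split labels.
#'
#' @param cohort A `doc_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the metadata CSV path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  for (pid in names(cohort$recordings)) {
    for (cond in c("resting", "music")) {
      write_edf(cohort$recordings[[pid]][[cond]],
                file.path(dir, sprintf("%s_%s.edf", pid, cond)))
    }
  }
  meta_path <- file.path(dir, "cohort.csv")
  write.csv(cohort$meta[, c("patient_id", "label", "crs_r_total",
                            "crs_r_auditory", "age", "sex",
                            "days_post_injury", "split")],
            meta_path, row.names = FALSE)
  invisible(meta_path)
}

#' Read a serialized cohort back
#'
#' @param dir Directory written by [write_cohort()].
#' @return A `doc_cohort` (without generator profiles).
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "cohort.csv")
  if (!file.exists(meta_path)) stop("missing metadata table: ", meta_path)
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  recs <- lapply(meta$patient_id, function(pid) {
    lapply(stats::setNames(c("resting", "music"), c("resting", "music")),
           function(cond) {
             path <- file.path(dir, sprintf("%s_%s.edf", pid, cond))
             if (!file.exists(path)) stop("missing EDF file: ", path)
             rec <- read_edf(path)
             rec$condition <- cond
             rec$patient_id <- pid
             rec
           })
  })
  names(recs) <- meta$patient_id
  structure(list(meta = meta, recordings = recs, profiles = NULL,
                 config = NULL, seed = NA),
            class = "doc_cohort")
}
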
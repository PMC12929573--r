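test_that("MIX series are standardized, seeded, and ordered in complexity", {
  x <- mix_series(0.5, 1000, seed = 3)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(x^2)), 1, tolerance = 1e-10)
  expect_identical(x, mix_series(0.5, 1000, seed = 3))
  expect_error(mix_series(-0.1, 1000), "\\[0, 1\\]")
  expect_error(mix_series(1.5, 1000), "\\[0, 1\\]")
  expect_error(mix_series(0.5, 50), ">= 100")

  x0 <- mix_series(0, 4096, seed = 1)
  x1 <- mix_series(1, 4096, seed = 1)
  a0 <- approximate_entropy(x0, 2, apen_tolerance(x0))
  a1 <- approximate_entropy(x1, 2, apen_tolerance(x1))
  expect_lt(a0, 0.3)           # pure sinusoid: nearly regular
  expect_gt(a1, a0)            # full noise replacement: strictly higher
  # oracle agreement on the noisy member (cross-checks the compiled path)
  expect_lt(abs(a1 - apen_oracle(x1, 2, apen_tolerance(x1))), 1e-12)
})

test_that("expected ApEn is monotone in the MIX weight", {
  apen_at <- function(p) {
    mean(vapply(1:6, function(k) {
      x <- mix_series(p, 1024, seed = 100 + k)
      approximate_entropy(x, 2, apen_tolerance(x))
    }, numeric(1)))
  }
  v <- vapply(c(0, 0.4, 1), apen_at, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("complexity calibration inverts the p -> ApEn curve", {
  simulate_mean <- function(p, n = 1024, reps = 20) {
    mean(vapply(seq_len(reps), function(k) {
      x <- mix_series(p, n, seed = 9000 + k)
      approximate_entropy(x, 2, apen_tolerance(x))
    }, numeric(1)))
  }
  p77 <- calibrate_complexity(0.77)
  m77 <- simulate_mean(p77)
  expect_gt(m77, 0.72); expect_lt(m77, 0.82)
  p60 <- calibrate_complexity(0.60)
  m60 <- simulate_mean(p60)
  expect_gt(m60, 0.55); expect_lt(m60, 0.65)
  expect_error(calibrate_complexity(0.01), "achievable")
  expect_error(calibrate_complexity(5), "achievable")
})

test_that("generated patients track their complexity profiles", {
  tbl <- reference_apen_table()
  prof <- list(resting = docapen:::group_targets("MCS", "resting", tbl),
               music = docapen:::group_targets("MCS", "music", tbl))
  recs <- generate_patient(list(patient_id = "T1", label = "MCS"), prof,
                           seed = 21)
  cfg <- pipeline_config()
  for (cond in c("resting", "music")) {
    frames <- recording_frames(recs[[cond]], cfg)
    cm <- recording_channel_means(frames, "T1", cond)
    err <- cm$mean_apen - prof[[cond]][cm$channel]
    expect_lt(max(abs(err)), 0.08)
  }
  # determinism: same seed and meta reproduce the signals exactly
  recs2 <- generate_patient(list(patient_id = "T1", label = "MCS"), prof,
                            seed = 21)
  expect_identical(recs$resting$signal, recs2$resting$signal)
  expect_identical(recs$music$signal, recs2$music$signal)
  expect_error(generate_patient(list(patient_id = "T1", label = "MCS"),
                                prof, duration_s = 30), ">= 66")
})

test_that("cohort structure, CRS-R ordering, and determinism hold", {
  cohort <- shared_cohort()      # 4 VS/UWS + 4 MCS, seed 77
  expect_s3_class(cohort, "doc_cohort")
  expect_equal(nrow(cohort$meta), 8)
  expect_equal(sum(lengths(cohort$recordings)), 16)  # two conditions each
  expect_true(all(cohort$meta$crs_r_total >= 0 &
                    cohort$meta$crs_r_total <= 23))
  expect_gt(median(cohort$meta$crs_r_total[cohort$meta$label == "MCS"]),
            median(cohort$meta$crs_r_total[cohort$meta$label == "VS_UWS"]))
  expect_true(all(table(cohort$meta$split, cohort$meta$label) > 0))

  # MCS profiles exceed VS/UWS on left-hemisphere channels (music)
  tbl <- reference_apen_table()
  lt <- left_channels()
  expect_true(all(docapen:::group_targets("MCS", "music", tbl)[lt] >
                    docapen:::group_targets("VS_UWS", "music", tbl)[lt]))

  cohort2 <- generate_cohort(4, 4, seed = 77)
  expect_identical(cohort$recordings$P001$resting$signal,
                   cohort2$recordings$P001$resting$signal)
  expect_identical(cohort$meta, cohort2$meta)
  expect_error(generate_cohort(0, 4), ">= 1")
})

test_that("EDF round trip preserves signals to within quantization", {
  cohort <- shared_cohort()
  rec <- cohort$recordings$P005$music
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  n <- ncol(back$signal)
  expect_equal(back$fs, rec$fs)
  expect_identical(back$channels, rec$channels)
  expect_identical(back$condition, "music")
  q <- 1000 / 65535
  expect_lt(max(abs(back$signal - rec$signal[, 1:n])), q)
  # ApEn of the round-tripped signal matches the in-memory one
  x0 <- rec$signal[3, 1:4096]
  x1 <- back$signal[3, 1:4096]
  expect_lt(abs(approximate_entropy(x0, 2, apen_tolerance(x0)) -
                  approximate_entropy(x1, 2, apen_tolerance(x1))), 0.01)
  unlink(path)
})

test_that("cohort serialization round-trips through EDF + CSV", {
  cohort <- generate_cohort(1, 1, cohort_config(duration_s = 66), seed = 5)
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_length(list.files(dir, pattern = "\\.edf$"), 4)
  back <- read_cohort(dir)
  expect_equal(back$meta$patient_id, cohort$meta$patient_id)
  expect_equal(back$meta$split, cohort$meta$split)
  cfg <- pipeline_config()
  f_mem <- recording_channel_means(
    recording_frames(cohort$recordings$P002$music, cfg), "P002", "music")
  f_rt <- recording_channel_means(
    recording_frames(back$recordings$P002$music, cfg), "P002", "music")
  expect_lt(max(abs(f_mem$mean_apen - f_rt$mean_apen)), 0.01)
  unlink(dir, recursive = TRUE)
})
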
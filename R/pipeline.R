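#' Pipeline configuration
#'
#' Everything one run needs: cohort sizes and master seed, epoch mode, ApEn
#' parameters, topomap options, CNN training profile, screening level,
#' evaluation settings and output directory.  All stage seeds are derived
#' deterministically from the master seed.
#'
#' @param n_vs,n_mcs Synthetic patients per class.
#' @param seed Master seed.
#' @param epoch_mode `"n60"` (60 equal segments of the 32,768-sample
#'   selection; the default, giving 120 topographies per patient),
#'   `"fixed1s"` or `"fixed2s"` (fixed-duration epochs).
#' @param apen An [apen_params()] object.
#' @param scale Topomap color scale.
#' @param topo_method Interpolation method (`"tps"`/`"idw"`).
#' @param reduce `"crop"` or `"resize"` for the 512 -> 256 step.
#' @param train A [train_config()] object.
#' @param alpha Screening level.
#' @param screen_k SD multiplier of the entropy-inflation screen.
#' @param positive Positive class (`"MCS"` by default).
#' @param granularity `"patient"` or `"image"` evaluation units.
#' @param aggregation Image-to-patient aggregation for the CNN.
#' @param cohort A [cohort_config()].
#' @param out_dir Optional output directory; when set, tables, reports and
#'   a config manifest are written there.
#' @param write_images Also write the PNG topo images (only with
#'   `out_dir`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_vs = 20, n_mcs = 20, seed = 1,
                            epoch_mode = c("n60", "fixed1s", "fixed2s"),
                            apen = apen_params(),
                            scale = c(0, 1.2), topo_method = "tps",
                            reduce = "crop",
                            train = train_config("desk"),
                            alpha = 0.05, screen_k = 3,
                            positive = "MCS",
                            granularity = c("patient", "image"),
                            aggregation = "mean",
                            cohort = cohort_config(),
                            out_dir = NULL, write_images = FALSE) {
  epoch_mode <- match.arg(epoch_mode)
  granularity <- match.arg(granularity)
  if (n_vs < 1 || n_mcs < 1) stop("cohort sizes must be >= 1")
  structure(list(n_vs = n_vs, n_mcs = n_mcs, seed = seed,
                 epoch_mode = epoch_mode, apen = apen, scale = scale,
                 topo_method = topo_method, reduce = reduce, train = train,
                 alpha = alpha, screen_k = screen_k, positive = positive,
                 granularity = granularity, aggregation = aggregation,
                 cohort = cohort, out_dir = out_dir,
                 write_images = write_images),
            class = "pipeline_config")
}

#' ApEn frames of one recording
#'
#' The preprocessing + extraction chain for a single recording: filter,
#' select the 32,768-sample analysis segment, cut epochs per the config's
#' epoch mode, and compute channel-wise ApEn per epoch.
#'
#' @param rec An `eeg_recording`.
#' @param config A [pipeline_config()].
#' @return List of `apen_frame` objects, one per epoch.
#' @export
recording_frames <- function(rec, config = pipeline_config()) {
  filt <- apply_filters(rec, filter_config())
  sel <- select_segment(filt, 32768L, discard_s = 2)
  epochs <- switch(config$epoch_mode,
                   n60 = segment_epochs(sel, n_segments = 60L),
                   fixed1s = segment_epochs(sel, epoch_s = 1),
                   fixed2s = segment_epochs(sel, epoch_s = 2))
  lapply(epochs, channel_apen, params = config$apen)
}

#' Per-recording channel means of a frame set
#'
#' @param frames List of `apen_frame`s from one recording.
#' @param patient_id,condition Identifiers carried into the rows.
#' @return data.frame with one row per channel (`patient_id`, `condition`,
#'   `channel`, `mean_apen`).
#' @export
recording_channel_means <- function(frames, patient_id, condition) {
  mat <- do.call(rbind, lapply(frames, as.numeric))
  colnames(mat) <- names(frames[[1]])
  data.frame(patient_id = patient_id, condition = condition,
             channel = colnames(mat), mean_apen = colMeans(mat),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' simulate -> preprocess -> ApEn -> topomap -> train/evaluate (CNN, SVM,
#' GRNN) -> report.  Deterministic under the config's master seed; when
#' `out_dir` is set, all tables, reports and a config manifest are written
#' there.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `doc_run`: cohort metadata, channel means,
#'   screening table, feature table, per-model [eval_report()]s, pairwise
#'   DeLong comparisons, CNN loss history, and stage timings.
#' @export
run_doc_pipeline <- function(config = pipeline_config()) {
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    timings[[name]] <<- t1 - t0
    t0 <<- t1
  }

  cohort <- generate_cohort(config$n_vs, config$n_mcs, config$cohort,
                            seed = derive_seed(config$seed, "cohort"))
  meta <- cohort$meta
  split <- stats::setNames(meta$split, meta$patient_id)
  if (any(table(factor(meta$split, levels = c("train", "test")),
                meta$label) == 0))
    stop("insufficiency error: a split is missing a class; ",
         "increase the cohort sizes")
  tick("simulate")

  input_size <- config$train$input_size
  factor_ <- 256L %/% input_size
  frames_df <- list(); ch_means <- list()
  images <- list(); image_meta <- list()
  for (pid in meta$patient_id) {
    frames_by_cond <- list()
    for (cond in c("resting", "music")) {
      frames <- recording_frames(cohort$recordings[[pid]][[cond]], config)
      scr <- entropy_inflation_screen(frames, k = config$screen_k)
      kept <- frames[scr$kept]
      frames_by_cond[[cond]] <- kept
      frames_df[[paste(pid, cond)]] <- frames_to_df(frames)
      ch_means[[paste(pid, cond)]] <-
        recording_channel_means(kept, pid, cond)
    }
    imgs <- images_per_patient(frames_by_cond, scale = config$scale,
                               method = config$topo_method,
                               reduce = config$reduce)
    for (im in imgs) {
      raster <- if (factor_ > 1) downscale_image(im$raster, factor_)
                else im$raster
      images[[length(images) + 1]] <- raster
      image_meta[[length(image_meta) + 1]] <- data.frame(
        patient_id = pid, condition = im$condition,
        label = meta$label[meta$patient_id == pid],
        split = split[[pid]], stringsAsFactors = FALSE)
    }
  }
  frames_df <- do.call(rbind, frames_df)
  ch_means <- do.call(rbind, ch_means)
  image_meta <- do.call(rbind, image_meta)
  rownames(frames_df) <- rownames(ch_means) <- rownames(image_meta) <- NULL
  tick("extract")

  # ANOVA screening on the training split only
  train_ids <- meta$patient_id[meta$split == "train"]
  screening <- screen_features(
    ch_means[ch_means$patient_id %in% train_ids, ],
    stats::setNames(meta$label, meta$patient_id), alpha = config$alpha)
  selected <- screening[screening$selected, c("electrode", "condition")]
  if (nrow(selected) == 0)
    stop("screening selected no features; nothing to train on")
  tick("screen")

  ft <- build_feature_table(ch_means, selected, split = split)
  y <- as.integer(meta$label == config$positive)
  names(y) <- meta$patient_id
  tr <- ft$patient_id %in% train_ids
  svm_fit <- train_svm(ft$x[tr, , drop = FALSE],
                       meta$label[match(ft$patient_id[tr], meta$patient_id)],
                       positive = config$positive)
  sigma <- select_sigma(ft$x[tr, , drop = FALSE], y[ft$patient_id[tr]])
  tick("baselines")

  cnn_cfg <- config$train
  cnn_cfg$seed <- derive_seed(config$seed, "cnn")
  img_tr <- image_meta$split == "train"
  cnn <- train_cnn(images[img_tr],
                   as.integer(image_meta$label[img_tr] == config$positive),
                   cfg = cnn_cfg)
  tick("train_cnn")

  test_ids <- meta$patient_id[meta$split == "test"]
  if (config$granularity == "patient") {
    units <- test_ids
    truth <- y[test_ids] == 1
    cnn_scores <- vapply(test_ids, function(pid) {
      idx <- which(image_meta$patient_id == pid)
      predict_patient(cnn, images[idx], aggregation = config$aggregation,
                      patient_id = pid)$probability
    }, numeric(1))
  } else {
    idx <- which(!img_tr)
    units <- sprintf("%s_img%d", image_meta$patient_id[idx],
                     seq_along(idx))
    truth <- image_meta$label[idx] == config$positive
    cnn_scores <- predict(cnn, images[idx])
  }
  svm_scores <- svm_fit$decision(ft$x[test_ids, , drop = FALSE])
  grnn_scores <- grnn_predict(ft$x[tr, , drop = FALSE], y[ft$patient_id[tr]],
                              ft$x[test_ids, , drop = FALSE], sigma)
  if (config$granularity == "image") {
    # replicate per-patient baseline scores over that patient's images
    rep_idx <- match(image_meta$patient_id[!img_tr], test_ids)
    svm_scores <- svm_scores[rep_idx]
    grnn_scores <- grnn_scores[rep_idx]
  }

  reports <- list(
    cnn = eval_report(cnn_scores, truth, threshold = 0.5, model = "CNN"),
    svm = eval_report(svm_scores, truth, threshold = 0, model = "SVM"),
    grnn = eval_report(grnn_scores, truth, threshold = 0.5, model = "GRNN"))
  pairs <- list(
    cnn_vs_svm = delong_test(cnn_scores, svm_scores, truth),
    cnn_vs_grnn = delong_test(cnn_scores, grnn_scores, truth),
    svm_vs_grnn = delong_test(svm_scores, grnn_scores, truth))
  tick("evaluate")

  run <- structure(list(
    config = config, meta = meta, channel_means = ch_means,
    frames = frames_df, screening = screening, features = ft,
    sigma = sigma, cnn_loss = cnn$loss_history, reports = reports,
    delong = pairs,
    scores = data.frame(unit = units, truth = truth, cnn = cnn_scores,
                        svm = svm_scores, grnn = grnn_scores,
                        row.names = NULL, stringsAsFactors = FALSE),
    timings = unlist(timings)),
    class = "doc_run")
  if (!is.null(config$out_dir))
    write_run(run, images = if (config$write_images) {
      keep <- !img_tr
      list(images = images[keep], meta = image_meta[keep, ])
    })
  run
}

#' @export
print.doc_run <- function(x, ...) {
  cat(sprintf("<doc_run> %d VS/UWS + %d MCS patients, seed %d\n",
              x$config$n_vs, x$config$n_mcs, x$config$seed))
  cat(sprintf("  screened features: %d of %d\n",
              sum(x$screening$selected), nrow(x$screening)))
  for (nm in names(x$reports))
    cat(sprintf("  %-5s AUC %.3f  accuracy %s\n", toupper(nm),
                x$reports[[nm]]$auc,
                ifelse(is.na(x$reports[[nm]]$metrics$accuracy), "NA",
                       sprintf("%.2f%%",
                               100 * x$reports[[nm]]$metrics$accuracy))))
  invisible(x)
}

# serialize a run's tables, reports and manifest into config$out_dir
write_run <- function(run, images = NULL) {
  dir <- run$config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  write.csv(run$meta, file.path(dir, "cohort.csv"), row.names = FALSE)
  write.csv(run$frames, file.path(dir, "frames.csv"), row.names = FALSE)
  write.csv(run$channel_means, file.path(dir, "channel_means.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(run$screening),
            file.path(dir, "screening.csv"), row.names = FALSE)
  write.csv(data.frame(patient_id = run$features$patient_id,
                       run$features$x, check.names = FALSE),
            file.path(dir, "features.csv"), row.names = FALSE)
  write.csv(run$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  # Table-4-shaped model x metric summary
  summ <- do.call(rbind, lapply(run$reports, function(r) {
    data.frame(model = r$model, auc = r$auc,
               auc_lo = r$auc_ci[1], auc_hi = r$auc_ci[2],
               t(vapply(c("accuracy", "sensitivity", "specificity",
                          "precision", "npv"),
                        function(nm) c(r$metrics[[nm]], r$ci[[nm]]),
                        numeric(3))),
               stringsAsFactors = FALSE)
  }))
  write.csv(summ, file.path(dir, "performance.csv"), row.names = FALSE)
  for (nm in names(run$reports)) {
    r <- run$reports[[nm]]
    jsonlite::write_json(
      list(model = r$model, n = r$n,
           confusion = unclass(r$confusion),
           metrics = r$metrics[c("accuracy", "sensitivity", "specificity",
                                 "precision", "npv", "f1")],
           ci = r$ci, auc = r$auc, auc_ci = r$auc_ci),
      file.path(dir, sprintf("report_%s.json", nm)),
      auto_unbox = TRUE, digits = NA, na = "null")
    write.csv(r$roc, file.path(dir, sprintf("roc_%s.csv", nm)),
              row.names = FALSE)
  }
  jsonlite::write_json(
    lapply(run$delong, function(d)
      list(auc_a = d$auc_a, auc_b = d$auc_b, z = d$z, p = d$p)),
    file.path(dir, "delong.json"), auto_unbox = TRUE, digits = NA)
  # config manifest with a stable hash of the serialized config
  cfg_json <- jsonlite::toJSON(unclass_deep(run$config), auto_unbox = TRUE,
                               digits = NA, null = "null", force = TRUE)
  manifest <- list(config = jsonlite::fromJSON(cfg_json),
                   config_hash = config_hash(run$config),
                   timings = as.list(run$timings))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (!is.null(images)) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (i in seq_along(images$images)) {
      m <- images$meta[i, ]
      png::writePNG(images$images[[i]],
                    file.path(img_dir, sprintf("%s_%s_%02d.png",
                                               m$patient_id, m$condition,
                                               i)))
    }
  }
  invisible(dir)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Stable hash of a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @return Character MD5 hash of the canonical JSON serialization.
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                           digits = NA, null = "null", force = TRUE)
  tmp <- tempfile()
  writeLines(json, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}
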
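#' One-way ANOVA from group summary statistics
#'
#' Reconstructs the classical between/within F statistic from per-group
#' sample sizes, means and SDs -- useful for checking published summary
#' tables without unit-level data.
#'
#' @param n,means,sds Vectors of group sizes, means and (sample) SDs.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_from_summary <- function(n, means, sds) {
  k <- length(n)
  if (k < 2) stop("need at least two groups")
  N <- sum(n)
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum((n - 1) * sds^2)
  df1 <- k - 1; df2 <- N - k
  Fstat <- (ssb / df1) / (ssw / df2)
  list(F = Fstat, df1 = df1, df2 = df2, p = pf(Fstat, df1, df2,
                                              lower.tail = FALSE))
}

#' ANOVA screening of electrode-condition mean-ApEn features
#'
#' One-way ANOVA (VS/UWS vs MCS) per electrode per condition on the
#' per-patient channel-mean ApEn; features with uncorrected p < alpha are
#' selected (Bonferroni adjustment over all tests is reported alongside but
#' does not drive the selection, mirroring standard screening practice).
#'
#' @param channel_means Long data.frame with columns `patient_id`,
#'   `condition`, `channel`, `mean_apen`.
#' @param labels Named vector/data.frame mapping `patient_id` to class
#'   labels (`"VS_UWS"` / `"MCS"`).
#' @param alpha Selection level.
#' @return data.frame of class `screening_result`: `electrode`, `condition`,
#'   group means/SDs, `F`, `p`, `p_bonferroni`, `selected`.
#' @export
screen_features <- function(channel_means, labels, alpha = 0.05) {
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$label, labels$patient_id)
  lab <- labels[channel_means$patient_id]
  if (length(unique(lab)) < 2)
    stop("statistics error: both classes must be present")
  combos <- unique(channel_means[, c("channel", "condition")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- channel_means[channel_means$channel == combos$channel[i] &
                           channel_means$condition == combos$condition[i], ]
    g <- factor(labels[sub$patient_id], levels = c("VS_UWS", "MCS"))
    if (min(table(g)) < 2)
      stop("statistics error: each group needs >= 2 patients")
    v <- sub$mean_apen
    if (stats::var(v) == 0) {
      Fstat <- 0; p <- 1
    } else {
      ft <- stats::anova(stats::lm(v ~ g))
      Fstat <- ft$`F value`[1]; p <- ft$`Pr(>F)`[1]
    }
    data.frame(electrode = combos$channel[i],
               condition = combos$condition[i],
               mean_vs = mean(v[g == "VS_UWS"]),
               sd_vs = sd(v[g == "VS_UWS"]),
               mean_mcs = mean(v[g == "MCS"]),
               sd_mcs = sd(v[g == "MCS"]),
               F = Fstat, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out$selected <- out$p < alpha
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Apply the selection rule to a published screening table
#'
#' @param tbl A table shaped like [reference_apen_table()].
#' @param alpha Selection level.
#' @return The table with a `selected` column (`p < alpha`).
#' @export
screen_reference_table <- function(tbl = reference_apen_table(),
                                   alpha = 0.05) {
  tbl$selected <- tbl$p < alpha
  tbl
}

#' Build the patients x features table for SVM/GRNN
#'
#' One column per selected (electrode, condition) pair holding the patient's
#' mean ApEn; columns are z-scored with statistics fitted on the training
#' rows only (no leakage into the test split).
#'
#' @param channel_means Long data.frame (`patient_id`, `condition`,
#'   `channel`, `mean_apen`).
#' @param selected data.frame with `electrode` and `condition` columns of
#'   the selected features (e.g. rows of [screen_features()] output).
#' @param split Named vector mapping `patient_id` to `"train"`/`"test"`;
#'   when `NULL`, standardization uses all rows.
#' @return List of class `feature_table`: `x` (matrix), `features`,
#'   `patient_id`, `split`, `center`, `scale`.
#' @export
build_feature_table <- function(channel_means, selected, split = NULL) {
  if (nrow(selected) == 0) stop("no features selected")
  pids <- unique(channel_means$patient_id)
  feats <- sprintf("%s_%s", selected$electrode, selected$condition)
  x <- matrix(NA_real_, nrow = length(pids), ncol = nrow(selected),
              dimnames = list(pids, feats))
  for (j in seq_len(nrow(selected))) {
    sub <- channel_means[channel_means$channel == selected$electrode[j] &
                           channel_means$condition == selected$condition[j], ]
    x[sub$patient_id, j] <- sub$mean_apen
  }
  if (anyNA(x)) {
    bad <- rownames(x)[apply(x, 1, anyNA)]
    stop("data error: patient(s) missing a condition/channel: ",
         paste(bad, collapse = ", "))
  }
  ref <- if (is.null(split)) rownames(x) else names(split)[split == "train"]
  ref <- intersect(rownames(x), ref)
  if (length(ref) >= 2) {
    ctr <- colMeans(x[ref, , drop = FALSE])
    scl <- apply(x[ref, , drop = FALSE], 2, sd)
    scl[scl == 0] <- 1
    x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  } else {
    ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))  # deferred
  }
  structure(list(x = x, features = feats, patient_id = pids,
                 split = split, center = ctr, scale = scl),
            class = "feature_table")
}

#' Train a maximum-margin linear SVM
#'
#' Thin wrapper over a linear soft-margin SVM (cost C = 1 by default) that
#' exposes a continuous decision score oriented so larger values favor the
#' positive class.
#'
#' @param x Feature matrix (rows = patients).
#' @param y Class labels (character or factor).
#' @param positive Positive-class label.
#' @param cost Soft-margin cost C.
#' @return List of class `doc_svm` with the fitted model and a
#'   `decision(newx)` function.
#' @export
train_svm <- function(x, y, positive = "MCS", cost = 1) {
  y <- as.character(y)
  if (length(unique(y)) < 2) stop("training error: single-class input")
  yf <- factor(y, levels = c(setdiff(unique(y), positive)[1], positive))
  fit <- e1071::svm(x, yf, kernel = "linear", cost = cost, scale = FALSE)
  decision <- function(newx) {
    pr <- predict(fit, newx, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # e1071 orients the score toward the first class named in the column
    sgn <- if (startsWith(colnames(dv)[1], paste0(positive, "/"))) 1 else -1
    as.numeric(dv[, 1]) * sgn
  }
  structure(list(fit = fit, positive = positive, decision = decision),
            class = "doc_svm")
}

#' GRNN prediction (Specht's generalized regression network)
#'
#' Normalized Gaussian-kernel regression over the training exemplars:
#' `Yhat(x) = sum_i y_i exp(-||x - x_i||^2 / (2 sigma^2)) /
#'            sum_i exp(-||x - x_i||^2 / (2 sigma^2))`.
#' With 0/1 targets the output is a class-membership score in \[0, 1\].
#' Exponents are stabilized by subtracting the per-query maximum, so the
#' sigma -> 0 limit returns the nearest neighbor's target exactly.
#'
#' @param train_x Training feature matrix.
#' @param train_y Numeric targets (0/1 for classification).
#' @param query Query matrix (or single vector).
#' @param sigma Kernel bandwidth, > 0.
#' @return Numeric predictions, one per query row, bounded by
#'   `range(train_y)`.
#' @export
grnn_predict <- function(train_x, train_y, query, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  train_x <- as.matrix(train_x)
  if (nrow(train_x) < 1) stop("need at least one training sample")
  if (is.null(dim(query))) query <- matrix(query, nrow = 1)
  query <- as.matrix(query)
  vapply(seq_len(nrow(query)), function(i) {
    d2 <- colSums((t(train_x) - query[i, ])^2)
    e <- -d2 / (2 * sigma^2)
    w <- exp(e - max(e))
    if (all(w == 0)) return(train_y[which.min(d2)])  # extreme underflow
    sum(w * train_y) / sum(w)
  }, numeric(1))
}

#' Select the GRNN bandwidth by leave-one-out accuracy
#'
#' Maximizes leave-one-out classification accuracy on the training split;
#' ties resolve to the smallest sigma.
#'
#' @param x Training feature matrix.
#' @param y 0/1 labels.
#' @param grid Candidate sigma values (non-empty).
#' @param threshold Decision threshold for accuracy.
#' @return The selected sigma.
#' @export
select_sigma <- function(x, y, grid = c(0.05, 0.1, 0.2, 0.3, 0.5, 0.8,
                                        1.2, 2, 3),
                         threshold = 0.5) {
  if (length(grid) == 0) stop("sigma grid must be non-empty")
  x <- as.matrix(x)
  grid <- sort(grid)
  acc <- vapply(grid, function(s) {
    pred <- vapply(seq_len(nrow(x)), function(i) {
      grnn_predict(x[-i, , drop = FALSE], y[-i], x[i, ], s)
    }, numeric(1))
    mean((pred > threshold) == (y == 1))
  }, numeric(1))
  grid[which.max(acc)]  # which.max takes the first (smallest) on ties
}
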
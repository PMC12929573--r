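#' Confusion matrix from predictions
#'
#' @param predicted Logical/0-1 vector (TRUE = predicted positive).
#' @param truth Logical/0-1 vector (TRUE = actual positive).
#' @return List of class `confusion_matrix` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_matrix <- function(predicted, truth) {
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  structure(list(TP = sum(predicted & truth),
                 FP = sum(predicted & !truth),
                 TN = sum(!predicted & !truth),
                 FN = sum(!predicted & truth)),
            class = "confusion_matrix")
}

#' Classification rates from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision (PPV) `TP/(TP+FP)`, NPV `TN/(TN+FN)` and F1
#' `2TP/(2TP+FP+FN)`.  Rates with a zero denominator are returned as `NA`
#' and named in the `undefined` element -- never silently reported as 0.
#'
#' @param cm A [confusion_matrix()] (or list with TP/FP/TN/FN).
#' @return List with the six rates, counts, and `undefined`.
#' @export
confusion_metrics <- function(cm) {
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  with(cm, {
    out <- list(
      accuracy = rate(TP + TN, TP + TN + FP + FN),
      sensitivity = rate(TP, TP + FN),
      specificity = rate(TN, TN + FP),
      precision = rate(TP, TP + FP),
      npv = rate(TN, TN + FN),
      f1 = rate(2 * TP, 2 * TP + FP + FN))
    out$undefined <- names(out)[vapply(out, is.na, logical(1))]
    out$counts <- list(TP = TP, FP = FP, TN = TN, FN = FN)
    out
  })
}

#' Exact (Clopper-Pearson) confidence interval for a proportion
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials.
#' @param level Confidence level.
#' @return `c(lower, upper)`.
#' @export
proportion_ci <- function(k, n, level = 0.95) {
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  a <- (1 - level) / 2
  lo <- if (k == 0) 0 else qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else qbeta(1 - a, k + 1, n - k)
  c(lower = lo, upper = hi)
}

#' ROC curve and AUC
#'
#' Curve points over all score thresholds; AUC by the trapezoid rule, which
#' equals the Mann-Whitney concordance probability with ties counted 1/2.
#'
#' @param scores Continuous classifier scores (larger = more positive).
#' @param labels Logical/0-1 truth (TRUE = positive).
#' @return List of class `roc_result`: `curve` (data.frame `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0)
    stop("statistics error: both classes must be present")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & labels) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !labels) / nn, numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_result")
}

# DeLong structural components: for each positive unit the mean of the
# Mann-Whitney kernel against all negatives, and vice versa
delong_components <- function(scores, labels) {
  xs <- scores[labels]; ys <- scores[!labels]
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(xs, function(x) mean(psi(x, ys)), numeric(1))
  v01 <- vapply(ys, function(y) mean(psi(xs, y)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated ROC curves
#'
#' The structural-component estimator of the covariance of two AUCs
#' computed on the same units; reports the z statistic and two-sided p for
#' the AUC difference, plus each model's AUC variance and normal-theory
#' confidence interval.
#'
#' @param scores_a,scores_b Paired score vectors from the two models.
#' @param labels Logical/0-1 truth.
#' @param level Confidence level for the AUC intervals.
#' @return List of class `delong_result`: `auc_a`, `auc_b`, `z`, `p`, `se`,
#'   `var_a`, `var_b`, `ci_a`, `ci_b`.
#' @export
delong_test <- function(scores_a, scores_b, labels, level = 0.95) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("parameter error: scores and labels must be paired (equal length)")
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0)
    stop("statistics error: both classes must be present")
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  # a class with a single unit contributes no estimable variance
  safe_cov <- function(m) if (nrow(m) >= 2) stats::cov(m) else
    matrix(0, 2, 2)
  s10 <- safe_cov(cbind(ca$v10, cb$v10))
  s01 <- safe_cov(cbind(ca$v01, cb$v01))
  var_a <- s10[1, 1] / np + s01[1, 1] / nn
  var_b <- s10[2, 2] / np + s01[2, 2] / nn
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / np +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / nn
  d <- ca$auc - cb$auc
  z <- if (var_diff > 0) d / sqrt(var_diff) else 0
  zq <- qnorm(1 - (1 - level) / 2)
  ci <- function(a, v) c(max(0, a - zq * sqrt(max(v, 0))),
                         min(1, a + zq * sqrt(max(v, 0))))
  structure(list(auc_a = ca$auc, auc_b = cb$auc, z = z,
                 p = 2 * pnorm(-abs(z)), se = sqrt(max(var_diff, 0)),
                 var_a = var_a, var_b = var_b,
                 ci_a = ci(ca$auc, var_a), ci_b = ci(cb$auc, var_b)),
            class = "delong_result")
}

#' Spearman rank correlation
#'
#' Midranks for ties; p from the t approximation.  Constant input returns
#' an undefined-correlation flag instead of an error.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return List with `rho`, `p`, and `defined`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, defined = FALSE))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, defined = TRUE)
}

#' One-way ANOVA with optional Bonferroni adjustment
#'
#' Classical between/within F test across `k >= 2` groups; the p-value is
#' multiplied by `bonferroni_k` (capped at 1) when the test is one of a
#' family.
#'
#' @param groups List of numeric vectors (each length >= 2).
#' @param bonferroni_k Size of the test family.
#' @return List with `F`, `df1`, `df2`, `p`, `p_adjusted`.
#' @export
anova_oneway <- function(groups, bonferroni_k = 1) {
  if (length(groups) < 2) stop("statistics error: need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("statistics error: each group needs >= 2 values")
  v <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (stats::var(v) == 0) {
    Fstat <- 0; p <- 1
    df1 <- length(groups) - 1; df2 <- length(v) - length(groups)
  } else {
    ft <- stats::anova(stats::lm(v ~ g))
    Fstat <- ft$`F value`[1]; p <- ft$`Pr(>F)`[1]
    df1 <- ft$Df[1]; df2 <- ft$Df[2]
  }
  list(F = Fstat, df1 = df1, df2 = df2, p = p,
       p_adjusted = min(1, p * bonferroni_k))
}

#' Full evaluation report for one model
#'
#' Confusion-matrix rates with exact binomial CIs, the ROC curve, and the
#' AUC with its DeLong normal-theory CI.
#'
#' @param scores Continuous scores (larger = more positive).
#' @param truth Logical/0-1 truth.
#' @param threshold Decision threshold on `scores`.
#' @param model Optional model name carried into the report.
#' @param level Confidence level.
#' @return List of class `eval_report`.
#' @export
eval_report <- function(scores, truth, threshold = 0.5, model = "model",
                        level = 0.95) {
  truth <- as.logical(truth)
  cm <- confusion_matrix(scores > threshold, truth)
  met <- confusion_metrics(cm)
  roc <- roc_auc(scores, truth)
  dl <- delong_test(scores, scores, truth, level = level)
  ci_of <- function(num, den)
    if (den > 0) proportion_ci(num, den, level) else c(NA_real_, NA_real_)
  with(cm, {
    cis <- list(
      accuracy = ci_of(TP + TN, TP + TN + FP + FN),
      sensitivity = ci_of(TP, TP + FN),
      specificity = ci_of(TN, TN + FP),
      precision = ci_of(TP, TP + FP),
      npv = ci_of(TN, TN + FN))
    structure(list(model = model, n = TP + TN + FP + FN,
                   confusion = cm, metrics = met, ci = cis,
                   roc = roc$curve, auc = roc$auc, auc_ci = dl$ci_a,
                   auc_var = dl$var_a, threshold = threshold,
                   level = level),
              class = "eval_report")
  })
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s (n = %d)\n", x$model, x$n))
  cat(sprintf("  AUC %.3f (%.3f, %.3f)\n", x$auc, x$auc_ci[1], x$auc_ci[2]))
  for (nm in c("accuracy", "sensitivity", "specificity", "precision",
               "npv")) {
    v <- x$metrics[[nm]]
    ci <- x$ci[[nm]]
    if (is.na(v)) cat(sprintf("  %-12s undefined (zero denominator)\n", nm))
    else cat(sprintf("  %-12s %.2f%% (%.2f%%, %.2f%%)\n", nm, 100 * v,
                     100 * ci[1], 100 * ci[2]))
  }
  if (!is.na(x$metrics$f1))
    cat(sprintf("  %-12s %.4f\n", "f1", x$metrics$f1))
  invisible(x)
}
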
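test_that("confusion-matrix rates match direct arithmetic", {
  cm <- list(TP = 17, FN = 2, TN = 10, FP = 1)
  m <- confusion_metrics(cm)
  expect_equal(m$accuracy, 0.9000, tolerance = 1e-4)
  expect_equal(m$sensitivity, 0.8947, tolerance = 1e-4)
  expect_equal(m$specificity, 0.9091, tolerance = 1e-4)
  expect_equal(m$precision, 0.9444, tolerance = 1e-4)
  expect_equal(m$npv, 0.8333, tolerance = 1e-4)
  expect_equal(m$f1, 0.9189, tolerance = 1e-4)

  perfect <- confusion_metrics(list(TP = 10, TN = 10, FP = 0, FN = 0))
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "precision", "npv", "f1")]) == 1))
  inverse <- confusion_metrics(list(TP = 0, TN = 0, FP = 5, FN = 5))
  expect_equal(inverse$accuracy, 0)
  expect_equal(inverse$f1, 0)
  # zero denominator -> flagged NA, not silent zero
  nopos <- confusion_metrics(list(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(nopos$sensitivity))
  expect_true("sensitivity" %in% nopos$undefined)
})

test_that("accuracy decomposes into prevalence-weighted sens/spec", {
  withr::with_seed(21, {
    for (i in 1:100) {
      cm <- list(TP = sample(0:30, 1), FP = sample(0:30, 1),
                 TN = sample(0:30, 1), FN = sample(0:30, 1))
      if (cm$TP + cm$FN == 0 || cm$TN + cm$FP == 0) next
      m <- confusion_metrics(cm)
      P <- cm$TP + cm$FN; N <- cm$TN + cm$FP
      expect_equal(m$accuracy,
                   (m$sensitivity * P + m$specificity * N) / (P + N))
    }
  })
})

test_that("trapezoid AUC equals Mann-Whitney concordance, with ties", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(0, 0, 0, 1, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 8), rep(c(0, 1), 4))$auc, 0.5)
  sc <- c(0.1, 0.4, 0.35, 0.8); lb <- c(0, 0, 1, 1)
  expect_equal(roc_auc(sc, lb)$auc, concordance_oracle(sc, lb))
  withr::with_seed(22, {
    for (i in 1:100) {
      n <- sample(6:25, 1)
      s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forced ties
      l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      expect_equal(roc_auc(s, l)$auc, concordance_oracle(s, l))
    }
  })
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("DeLong agrees with its structural components and with pROC", {
  withr::with_seed(23, {
    labels <- rep(c(TRUE, FALSE), each = 10)
    sa <- rnorm(20) + labels
    sb <- rnorm(20) + 0.5 * labels
    dl <- delong_test(sa, sb, labels)
    expect_equal(dl$auc_a, roc_auc(sa, labels)$auc)
    expect_equal(dl$auc_b, roc_auc(sb, labels)$auc)
    # identical curves: z = 0, p = 1
    same <- delong_test(sa, sa, labels)
    expect_equal(same$z, 0)
    expect_equal(same$p, 1)
    # invariance to monotone transforms of the scores
    dl2 <- delong_test(exp(sa), exp(sb), labels)
    expect_equal(dl$z, dl2$z, tolerance = 1e-12)
    expect_error(delong_test(sa, sb[-1], labels), "paired")

    # cross-check against an independent implementation
    ra <- pROC::roc(labels, sa, quiet = TRUE, direction = "<")
    rb <- pROC::roc(labels, sb, quiet = TRUE, direction = "<")
    ref <- pROC::roc.test(ra, rb, method = "delong")
    expect_equal(dl$p, ref$p.value, tolerance = 1e-9)
    expect_equal(sqrt(dl$var_a), sqrt(pROC::var(ra, method = "delong")),
                 tolerance = 1e-9)
  })
})

test_that("DeLong p is close to an exact permutation oracle at n = 12", {
  withr::with_seed(24, {
    labels <- rep(c(TRUE, FALSE), each = 6)
    base <- rnorm(12) + labels * 1.2
    sa <- base + rnorm(12, 0, 0.6)
    sb <- base + rnorm(12, 0, 0.9)
  })
  dl <- delong_test(sa, sb, labels)
  pp <- delong_perm_oracle(sa, sb, labels, B = 20000, seed = 7)
  # 20k-rep MC error is ~0.003; the remaining gap is the normal
  # approximation at n = 12
  expect_lt(abs(dl$p - pp), 0.06)
})

test_that("Clopper-Pearson intervals are exact at the boundaries and match Table-style CIs", {
  expect_equal(proportion_ci(30, 30)[["upper"]], 1)
  expect_equal(proportion_ci(0, 30)[["lower"]], 0)
  ci <- proportion_ci(27, 30)
  expect_equal(unname(round(ci, 3)), c(0.735, 0.979))
  ref <- stats::binom.test(27, 30)$conf.int
  expect_equal(unname(ci), as.numeric(ref), tolerance = 1e-12)
})

test_that("Spearman correlation uses midranks and flags constant input", {
  x <- 1:20
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, rev(x))$rho, -1)
  # tied example against the direct midrank formula
  a <- c(1, 2, 2, 3, 5, 5, 5, 8)
  b <- c(2, 1, 4, 4, 6, 7, 6, 9)
  expect_equal(spearman_cor(a, b)$rho,
               stats::cor(rank(a), rank(b)))
  flat <- spearman_cor(rep(1, 5), 1:5)
  expect_false(flat$defined)
  expect_true(is.na(flat$rho))
})

test_that("one-way ANOVA reduces to t^2 and Bonferroni caps at 1", {
  withr::with_seed(25, {
    g1 <- rnorm(12); g2 <- rnorm(12, 0.8)
    res <- anova_oneway(list(g1, g2))
    tt <- stats::t.test(g1, g2, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  })
  same <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  res32 <- anova_oneway(list(rnorm(5), rnorm(5)), bonferroni_k = 32)
  expect_equal(res32$p_adjusted, min(1, res32$p * 32))
  expect_equal(anova_oneway(list(c(1, 2), c(5, 6)),
                            bonferroni_k = 32)$p_adjusted,
               min(1, anova_oneway(list(c(1, 2), c(5, 6)))$p * 32))
  expect_error(anova_oneway(list(rnorm(3))), ">= 2 groups")
})

test_that("evaluation reports are internally consistent", {
  withr::with_seed(26, {
    truth <- rep(c(TRUE, FALSE), 15)
    scores <- runif(30) + truth * 0.7
  })
  rep_ <- eval_report(scores, truth, threshold = 0.5, model = "demo")
  expect_equal(rep_$n, 30)
  expect_equal(rep_$auc, roc_auc(scores, truth)$auc)
  expect_true(rep_$auc_ci[1] <= rep_$auc && rep_$auc <= rep_$auc_ci[2])
  for (nm in c("accuracy", "sensitivity", "specificity")) {
    v <- rep_$metrics[[nm]]
    expect_true(rep_$ci[[nm]][1] <= v && v <= rep_$ci[[nm]][2])
  }
  expect_output(print(rep_), "AUC")
})
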
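test_that("summary-statistic ANOVA reconstructs published F values", {
  # FP1 resting: n 39/37, means 0.60/0.72, SDs 0.14/0.18
  res <- anova_from_summary(c(39, 37), c(0.60, 0.72), c(0.14, 0.18))
  expect_lt(abs(res$F - 9.96), 1.5)   # printed summaries are rounded
  expect_lt(res$p, 0.05)
  same <- anova_from_summary(c(10, 10), c(0.5, 0.5), c(0.1, 0.1))
  expect_equal(same$F, 0)
})

test_that("the reference screening table selects 15 features at p < 0.05", {
  scr <- screen_reference_table()
  expect_equal(sum(scr$selected), 15)
  expect_equal(sum(scr$selected & scr$condition == "resting"), 7)
  expect_equal(sum(scr$selected & scr$condition == "music"), 8)
  expect_setequal(scr$electrode[scr$selected & scr$condition == "resting"],
                  c("FP1", "F3", "C3", "P3", "F7", "T3", "T5"))
  expect_setequal(scr$electrode[scr$selected & scr$condition == "music"],
                  c("FP1", "F3", "C3", "P3", "O1", "F7", "T3", "T5"))
})

test_that("ANOVA screening finds planted effects and rejects degenerate input", {
  elevated <- paste(c("FP1", "F3", "C3"), "music")
  syn <- synthetic_channel_means(20, 20, elevated = elevated, seed = 2)
  scr <- screen_features(syn$channel_means, syn$labels)
  expect_equal(nrow(scr), 32)
  hits <- scr[paste(scr$electrode, scr$condition) %in% elevated, ]
  expect_true(all(hits$selected))
  expect_lt(sum(scr$selected & !(paste(scr$electrode, scr$condition) %in%
                                   elevated)), 6)
  # identical group values -> F = 0, not selected
  flat <- syn$channel_means
  flat$mean_apen <- 0.5
  scr0 <- screen_features(flat, syn$labels)
  expect_true(all(scr0$F == 0) && all(!scr0$selected))
  one_cls <- syn$labels; one_cls[] <- "MCS"
  expect_error(screen_features(syn$channel_means, one_cls), "both classes")
})

test_that("screening is calibrated under label permutation", {
  syn <- synthetic_channel_means(20, 20, seed = 3)   # no planted effect
  counts <- withr::with_seed(8, {
    vapply(1:200, function(b) {
      perm <- stats::setNames(sample(syn$labels), names(syn$labels))
      sum(screen_features(syn$channel_means, perm)$selected)
    }, numeric(1))
  })
  # mean selected ~ alpha * 32 = 1.6; 200-replicate SE ~ 0.09
  expect_lt(abs(mean(counts) - 0.05 * 32), 0.4)
})

test_that("the feature table is 76 x 15 shaped and train-standardized", {
  syn <- synthetic_channel_means(39, 37, seed = 4)
  sel <- screen_reference_table()
  sel <- sel[sel$selected, c("electrode", "condition")]
  pids <- unique(syn$channel_means$patient_id)
  split <- stats::setNames(rep(c("train", "test"), c(60, 16)), pids)
  ft <- build_feature_table(syn$channel_means, sel, split)
  expect_equal(dim(ft$x), c(76L, 15L))
  tr <- ft$x[names(split)[split == "train"], ]
  expect_lt(max(abs(colMeans(tr))), 1e-12)
  expect_lt(max(abs(apply(tr, 2, sd) - 1)), 1e-12)

  # missing condition rows -> data error
  broken <- syn$channel_means[syn$channel_means$condition == "resting" |
                                syn$channel_means$patient_id != "S001", ]
  expect_error(build_feature_table(broken, sel, split), "missing a")
  # single patient: standardization deferred
  solo <- build_feature_table(
    syn$channel_means[syn$channel_means$patient_id == "S001", ], sel)
  expect_equal(nrow(solo$x), 1L)
})

test_that("the linear SVM separates, bisects, and is label-symmetric", {
  x <- rbind(matrix(rnorm(40, -2), ncol = 2), matrix(rnorm(40, 2), ncol = 2))
  y <- rep(c("VS_UWS", "MCS"), each = 20)
  fit <- train_svm(x, y, positive = "MCS")
  expect_true(all((fit$decision(x) > 0) == (y == "MCS")))

  # two points, one per class: the boundary is their perpendicular bisector
  x2 <- rbind(c(0, 0), c(2, 2))
  fit2 <- train_svm(x2, c("VS_UWS", "MCS"), positive = "MCS", cost = 1e4)
  mid <- matrix(c(1, 1), ncol = 2)
  expect_lt(abs(fit2$decision(mid)), 1e-6)
  along <- matrix(c(1.5, 1.5, 0.5, 0.5), ncol = 2, byrow = TRUE)
  d <- fit2$decision(along)
  expect_equal(d[1], -d[2], tolerance = 1e-6)
  expect_gt(d[1], 0)

  # flipping which class is positive negates the decision scores
  fit3 <- train_svm(x, y, positive = "VS_UWS")
  expect_equal(fit$decision(x), -fit3$decision(x), tolerance = 1e-8)
  expect_error(train_svm(x, rep("MCS", 40)), "single-class")
})

test_that("GRNN obeys its normalization, symmetry and nearest-neighbor limit", {
  expect_equal(grnn_predict(matrix(c(1, 2), 1), 1,
                            c(5, 5), sigma = 0.3), 1)
  x <- rbind(c(-1, 0), c(1, 0))
  expect_equal(grnn_predict(x, c(0, 1), c(0, 0), sigma = 0.5), 0.5)
  expect_error(grnn_predict(x, c(0, 1), c(0, 0), sigma = 0), "positive")

  withr::with_seed(12, {
    xtr <- matrix(rnorm(60), ncol = 3)
    ytr <- rep(c(0, 1), 10)
    q <- matrix(rnorm(150), ncol = 3)
    nn <- apply(q, 1, function(z)
      ytr[which.min(colSums((t(xtr) - z)^2))])
    pred <- grnn_predict(xtr, ytr, q, sigma = 1e-6)
    expect_equal(pred, nn)
    # convex combination: bounded by the target range
    pred2 <- grnn_predict(xtr, ytr, q, sigma = 0.8)
    expect_true(all(pred2 >= 0 & pred2 <= 1))
  })
})

test_that("sigma selection maximizes LOO accuracy with smallest-tie rule", {
  expect_equal(select_sigma(matrix(rnorm(20), ncol = 2), rep(c(0, 1), 5),
                            grid = 0.5), 0.5)
  withr::with_seed(13, {
    x <- rbind(matrix(rnorm(40, 0, 0.2), ncol = 2),
               matrix(rnorm(40, 5, 0.2), ncol = 2))
    y <- rep(c(0, 1), each = 20)
    s <- select_sigma(x, y, grid = c(0.1, 0.5, 1, 3, 10, 30))
    expect_lt(s, 7.2)  # below the inter-cluster distance
    # perfectly separable at every candidate: ties resolve to the smallest
    expect_equal(select_sigma(x, y, grid = c(0.5, 1, 2)), 0.5)
  })
  expect_error(select_sigma(matrix(1), 1, grid = numeric(0)), "non-empty")
})
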
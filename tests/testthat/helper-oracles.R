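# Independent oracles and shared fixtures for the test suite.

# Naive ApEn oracle: direct template counting over all pairs, Chebyshev
# distance, self-matches included.  Deliberately written from the defining
# formula (inner distance computation vectorized, outer loop explicit),
# independent of the package's compiled implementation.
apen_oracle <- function(x, m, r) {
  L <- length(x)
  phi <- function(k) {
    nt <- L - k + 1
    tmpl <- sapply(seq_len(k), function(u) x[u:(u + nt - 1)])
    tmpl <- matrix(tmpl, nrow = nt)
    acc <- 0
    for (i in seq_len(nt)) {
      d <- abs(tmpl - matrix(tmpl[i, ], nt, k, byrow = TRUE))
      cnt <- sum(apply(d, 1, max) <= r)
      acc <- acc + log(cnt / nt)
    }
    acc / nt
  }
  phi(m) - phi(m + 1)
}

# Mann-Whitney concordance (ties counted 1/2) by exhaustive pair counting.
concordance_oracle <- function(scores, labels) {
  labels <- as.logical(labels)
  xs <- scores[labels]; ys <- scores[!labels]
  tot <- 0
  for (x in xs) for (y in ys)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(xs) * length(ys))
}

# Paired-permutation oracle for the AUC difference of two models scored on
# the same units: model assignments are swapped per unit.
delong_perm_oracle <- function(sa, sb, labels, B = 20000, seed = 1) {
  auc <- function(s, l) {
    r <- rank(s)
    (sum(r[l]) - sum(l) * (sum(l) + 1) / 2) / (sum(l) * sum(!l))
  }
  d0 <- abs(auc(sa, labels) - auc(sb, labels))
  n <- length(sa)
  cnt <- 0
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      sw <- runif(n) < 0.5
      a2 <- ifelse(sw, sb, sa)
      b2 <- ifelse(sw, sa, sb)
      if (abs(auc(a2, labels) - auc(b2, labels)) >= d0 - 1e-12)
        cnt <- cnt + 1
    }
  })
  cnt / B
}

# random ApEn frame over the full montage
random_frame <- function(seed, lo = 0.4, hi = 0.9, patient_id = "PX",
                         condition = "resting", epoch = 1L) {
  v <- withr::with_seed(seed, runif(16, lo, hi))
  structure(stats::setNames(v, doc_montage()), class = "apen_frame",
            patient_id = patient_id, condition = condition, epoch = epoch)
}

# small synthetic image pair family for CNN tests: class 1 carries an
# intensity patch in the top rows
toy_image <- function(hot, size = 32, seed = 1) {
  withr::with_seed(seed, {
    a <- array(runif(size * size * 3, 0, 0.2), c(size, size, 3))
    if (hot) a[seq_len(size / 2), , 1] <- a[seq_len(size / 2), , 1] + 0.6
    a
  })
}

# one small shared cohort, generated once per test session
shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(4, 4, seed = 77)
    cache
  }
})

# long-format synthetic channel-means table with a known elevated set
synthetic_channel_means <- function(n_vs, n_mcs, elevated = NULL,
                                    effect = 0.12, sd = 0.05, seed = 1) {
  elevated <- elevated %||% character(0)
  pids <- sprintf("S%03d", seq_len(n_vs + n_mcs))
  labels <- c(rep("VS_UWS", n_vs), rep("MCS", n_mcs))
  rows <- list()
  withr::with_seed(seed, {
    for (i in seq_along(pids)) {
      for (cond in c("resting", "music")) {
        mu <- 0.65 + ifelse(labels[i] == "MCS" &
                              paste(doc_montage(), cond) %in% elevated,
                            effect, 0)
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = pids[i], condition = cond, channel = doc_montage(),
          mean_apen = rnorm(16, mu, sd), stringsAsFactors = FALSE)
      }
    }
  })
  list(channel_means = do.call(rbind, rows),
       labels = stats::setNames(labels, pids))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
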
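# Brute-force oracles for the confusion/ROC machinery.

confusion_oracle <- function(y, p) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(y)) {
    if (y[i] == 1 && p[i] == 1) tp <- tp + 1L
    if (y[i] == 0 && p[i] == 0) tn <- tn + 1L
    if (y[i] == 0 && p[i] == 1) fp <- fp + 1L
    if (y[i] == 1 && p[i] == 0) fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

auc_mann_whitney <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

test_that("confusion counts match an exhaustive loop oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(5:80, 1)
    y <- rbinom(n, 1, 0.5)
    p <- rbinom(n, 1, 0.5)
    cc <- confusion_counts(y, p)
    or <- confusion_oracle(y, p)
    expect_identical(c(tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn), or)
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, n)
  }
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cc[c("tp", "fn", "fp", "tn")]),
               c(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)),
               class = "ShapeMismatchError")
})

test_that("derived metrics obey their algebraic identities", {
  set.seed(7)
  for (rep in 1:20) {
    y <- rbinom(30, 1, 0.5)
    p <- rbinom(30, 1, 0.5)
    m <- compute_metrics(confusion_counts(y, p))
    expect_equal(m$accuracy, mean(y == p))
    expect_true(all(unlist(m[c("accuracy", "precision", "recall", "f1")]) >= 0))
    expect_true(all(unlist(m[c("accuracy", "precision", "recall", "f1")]) <= 1))
    if (m$precision + m$recall > 0) {
      expect_gte(m$f1 + 1e-12, min(m$precision, m$recall))
      expect_lte(m$f1 - 1e-12, max(m$precision, m$recall))
    }
    # invariant under a simultaneous permutation
    perm <- sample(length(y))
    m2 <- compute_metrics(confusion_counts(y[perm], p[perm]))
    expect_equal(as.data.frame(m), as.data.frame(m2))
  }
  # harmonic-mean fixed point and perfect prediction
  expect_equal(f1_score(0.7, 0.7), 0.7)
  mperf <- compute_metrics(confusion_counts(c(1, 0, 1), c(1, 0, 1)))
  expect_equal(mperf$counts$fp + mperf$counts$fn, 0)
  expect_equal(mperf$f1, 1)
})

test_that("0/0 metric cases return zero and are flagged", {
  m <- compute_metrics(confusion_counts(c(1, 1, 0), c(0, 0, 1)))
  expect_equal(m$precision, 0)
  expect_equal(m$recall, 0)
  expect_equal(m$f1, 0)
  expect_setequal(m$degenerate, c("f1"))
  m2 <- compute_metrics(confusion_counts(c(1, 1, 0), c(0, 0, 0)))
  expect_true("precision" %in% m2$degenerate)
})

test_that("ROC/AUC matches the all-pairs concordance oracle", {
  set.seed(11)
  for (rep in 1:5) {
    y <- rbinom(200, 1, 0.4)
    s <- round(runif(200), 1) # coarse scores force ties
    r <- roc_auc(y, s)
    expect_equal(r$auc, auc_mann_whitney(y, s), tolerance = 1e-9)
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(utils::tail(r$points$fpr, 1), 1)
    expect_equal(utils::tail(r$points$tpr, 1), 1)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    # score-reversal symmetry
    expect_equal(roc_auc(y, 1 - s)$auc, 1 - r$auc, tolerance = 1e-9)
  }
})

test_that("ROC agrees with an independent implementation and edge cases", {
  skip_if_not_installed("pROC")
  set.seed(3)
  y <- rbinom(150, 1, 0.5)
  s <- rnorm(150)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(roc_auc(y, s)$auc, ref, tolerance = 1e-9)
  # perfectly ranked scores
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_error(roc_auc(c(1, 1, 1), c(0.2, 0.3, 0.4)), class = "RocError")
})
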
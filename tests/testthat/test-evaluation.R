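test_that("stratified folds partition 60 sessions into 10 folds of 3+3", {
  labels <- rep(c("correct", "incorrect"), each = 30)
  folds <- make_folds(labels, 10L, seed = 1)
  expect_length(folds, 10L)
  expect_true(all(lengths(folds) == 6L))
  for (f in folds) expect_equal(sum(labels[f] == "correct"), 3L)
  expect_identical(sort(unlist(folds)), 1:60)          # partition
  expect_identical(folds, make_folds(labels, 10L, seed = 1))  # reproducible
  expect_false(identical(folds, make_folds(labels, 10L, seed = 2)))
  expect_error(make_folds(rep(c("correct", "incorrect"), c(31, 29)), 10L, 1),
               "divisible")
})

test_that("confusion metrics match their closed forms on random counts", {
  set.seed(123)
  for (i in 1:100) {
    cts <- as.list(setNames(sample(0:40, 4, replace = TRUE),
                            c("TP", "TN", "FP", "FN")))
    n <- with(cts, TP + TN + FP + FN)
    if (n == 0) next
    m <- classification_metrics(cts)
    expect_equal(m$accuracy, (cts$TP + cts$TN) / n)
    if (cts$TP + cts$FN > 0)
      expect_equal(m$sensitivity, cts$TP / (cts$TP + cts$FN))
    if (cts$TN + cts$FP > 0)
      expect_equal(m$specificity, cts$TN / (cts$TN + cts$FP))
  }
  cc <- confusion_counts(c("correct", "correct", "incorrect"),
                         c("correct", "incorrect", "incorrect"))
  expect_equal(unlist(cc), c(TP = 1L, TN = 1L, FP = 0L, FN = 1L))
})

test_that("Cohen's kappa agrees with an independent implementation", {
  expect_equal(cohen_kappa(list(TP = 30, TN = 30, FP = 0, FN = 0)), 1)
  expect_equal(cohen_kappa(list(TP = 15, TN = 15, FP = 15, FN = 15)), 0)
  oracle <- function(cts) {
    tab <- rbind(c(cts$TP, cts$FN), c(cts$FP, cts$TN))
    e1071::classAgreement(tab)$kappa
  }
  cts <- list(TP = 27, TN = 26, FP = 4, FN = 3)
  expect_equal(cohen_kappa(cts), oracle(cts), tolerance = 1e-12)
  set.seed(77)
  for (i in 1:50) {
    cts <- as.list(setNames(sample(1:30, 4, replace = TRUE),
                            c("TP", "TN", "FP", "FN")))
    expect_equal(cohen_kappa(cts), oracle(cts), tolerance = 1e-10)
  }
  # kappa = 1 only with an empty off-diagonal
  expect_lt(cohen_kappa(list(TP = 29, TN = 30, FP = 0, FN = 1)), 1)
  expect_equal(cohen_kappa(list(TP = 10, TN = 0, FP = 0, FN = 0)), 1)
  expect_error(cohen_kappa(list(TP = 0, TN = 0, FP = 0, FN = 0)), "no classified")
})

test_that("kappa interpretation bands follow the published cutpoints", {
  expect_identical(kappa_band(0.86), "almost perfect")
  expect_identical(kappa_band(0.45), "moderate")
  expect_identical(kappa_band(-0.1), "poor")
  expect_identical(kappa_band(0.8), "substantial")   # band is (0.8, 1]
  expect_identical(kappa_band(0.61), "substantial")
  expect_identical(kappa_band(0.21), "fair")
  expect_identical(kappa_band(0.05), "slight")
  expect_identical(kappa_band(0), "slight")
  expect_error(kappa_band(1.2), "\\[-1, 1\\]")
})

test_that("occurrence summaries count combinations and participants correctly", {
  fn <- feature_names()
  combos <- c(replicate(4, fn[c(1, 2)], simplify = FALSE),
              replicate(2, fn[c(2, 5)], simplify = FALSE),
              list(fn[7]))
  cb <- cboff(combos)
  expect_equal(unname(cb[fn[1]]), 4L)
  expect_equal(unname(cb[fn[2]]), 6L)
  expect_equal(unname(cb[fn[5]]), 2L)
  expect_equal(unname(cb[fn[7]]), 1L)
  expect_equal(sum(cb), 13L)

  by_part <- list(
    A = replicate(3, fn[1], simplify = FALSE),   # 3 occurrences: important
    B = replicate(2, fn[1], simplify = FALSE),   # exactly 2: not important
    C = replicate(10, fn[2], simplify = FALSE))
  pb <- pbofif(by_part)
  expect_equal(unname(pb[fn[1]]), 1L)
  expect_equal(unname(pb[fn[2]]), 1L)
  expect_equal(unname(pb[fn[3]]), 0L)
})

test_that("repeated CV classifies every session once per repetition, deterministically", {
  set.seed(202)
  fn <- feature_names()
  mk <- function(center, pid) {
    structure(list(
      features = matrix(rnorm(6 * 38, center, 0.2), 6, 38,
                        dimnames = list(NULL, fn)),
      timestamps = (0:5) / 15, participant_id = pid, exercise = "flexion",
      label = if (center > 0) "correct" else "incorrect",
      frame_rate = 15), class = "feature_series")
  }
  series <- c(lapply(1:10, function(i) mk(3, "P1")),
              lapply(1:10, function(i) mk(-3, "P1")))
  r <- run_repeated_cv(series, repetitions = 2, n_folds = 5, seed = 3,
                       select = FALSE)
  expect_s3_class(r, "cv_report")
  expect_equal(nrow(r$metrics), 2L)
  expect_true(all(rowSums(r$metrics[, c("TP", "TN", "FP", "FN")]) == 20L))
  expect_equal(r$metrics$accuracy, c(1, 1))  # trivially separable
  r2 <- run_repeated_cv(series, repetitions = 2, n_folds = 5, seed = 3,
                        select = FALSE)
  expect_identical(r$metrics, r2$metrics)
  # nested selection records one subset per fold and one combination per rep
  r3 <- run_repeated_cv(series, repetitions = 1, n_folds = 5, seed = 3,
                        select = TRUE, inner_max_per_class = 4L)
  expect_length(r3$subsets[[1]]$folds, 5L)
  expect_true(length(r3$subsets[[1]]$combination) >= 1L)
  expect_equal(r3$metrics$accuracy, 1)
})
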
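test_that("confusion matrices count every sample in the right cell", {
  cm <- confusion(rep(c("a", "b"), each = 5), rep(c("a", "b"), each = 5))
  expect_equal(unname(diag(cm)), c(5, 5))
  expect_equal(sum(cm), 10)

  # constant predictor: one nonzero column
  cm2 <- confusion(c("a", "b", "c"), rep("b", 3), c("a", "b", "c"))
  expect_equal(sum(colSums(cm2) > 0), 1)

  # totals match input length for random vectors (brute-force check)
  set.seed(1)
  for (k in 1:10) {
    yt <- sample(letters[1:4], 50, replace = TRUE)
    yp <- sample(letters[1:4], 50, replace = TRUE)
    cm3 <- confusion(yt, yp, letters[1:4])
    expect_equal(sum(cm3), 50)
    expect_equal(unname(cm3["a", "b"]), sum(yt == "a" & yp == "b"))
  }

  expect_error(confusion("a", "z", class_labels = c("a", "b")), "z")
})

test_that("accuracy and balanced accuracy follow their definitions", {
  cm <- matrix(c(5, 0, 0, 5), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(accuracy(cm), 1)
  expect_equal(balanced_accuracy(cm), 1)

  cm2 <- matrix(c(90, 40, 10, 60), 2)   # rows true: (90,10), (40,60)
  expect_equal(accuracy(cm2), 0.75)
  expect_equal(balanced_accuracy(cm2), 0.75)

  # class absent from the truth: averaged only over present classes
  cm3 <- matrix(c(8, 0, 2, 0), 2)
  expect_equal(balanced_accuracy(cm3), 0.8)

  expect_error(accuracy(matrix(0, 2, 2)), "empty")
})

test_that("multi-class MCC equals the one-hot correlation oracle", {
  expect_equal(mcc_multiclass(diag(c(3, 4, 5))), 1)
  expect_equal(mcc_multiclass(matrix(c(2, 2, 2, 2), 2)), 0)

  set.seed(7)
  for (k in 1:100) {
    cm <- matrix(rpois(9, 3), 3)
    if (sum(cm) == 0) next
    expect_equal(mcc_multiclass(cm), mcc_onehot_oracle(cm), tolerance = 1e-10)
  }

  # 2x2 case equals the classical binary formula
  for (k in 1:20) {
    cm <- matrix(rpois(4, 5) + 1, 2)
    tp <- cm[2, 2]; tn <- cm[1, 1]; fp <- cm[1, 2]; fn <- cm[2, 1]
    binary <- (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    expect_equal(mcc_multiclass(cm), binary, tolerance = 1e-12)
  }

  # constant predictor (degenerate denominator) -> 0 by convention
  expect_equal(mcc_multiclass(matrix(c(3, 4, 0, 0), 2)), 0)
})

test_that("the random baseline has 1/k expected accuracy and zero MCC", {
  # single-class training: every prediction is that class
  expect_true(all(random_baseline("u1", 100, seed = 1) == "u1"))

  truth <- rep(sprintf("u%02d", 1:10), each = 100)
  pred <- random_baseline(unique(truth), length(truth), seed = 3)
  m <- classification_metrics(truth, pred)
  expect_lt(abs(m["accuracy"] - 0.1), 3 * sqrt(0.1 * 0.9 / 1000))
  expect_lt(abs(m["mcc"]), 0.05)

  expect_identical(random_baseline(letters[1:5], 20, seed = 4),
                   random_baseline(letters[1:5], 20, seed = 4))
})

test_that("the one-sided Wilcoxon test is exact, including under ties", {
  # constant shift, n = 10: all differences tied -> p = 1/2^10
  a <- 1:10; b <- a + 1
  expect_equal(wilcoxon_one_sided(a, b), 1 / 1024, tolerance = 1e-12)

  # all-zero differences: p = 1 with a warning
  expect_warning(p <- wilcoxon_one_sided(a, a), "zero")
  expect_equal(p, 1)

  # untied case agrees with stats::wilcox.test exact p
  set.seed(5)
  for (k in 1:10) {
    x <- rnorm(12); y <- rnorm(12, 0.5)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, alternative = "less",
                         exact = TRUE)$p.value)
    expect_equal(wilcoxon_one_sided(x, y), ref, tolerance = 1e-10)
  }

  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(c(0.4, 0.9)), c(0.8, 1))
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "m must be")
})
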
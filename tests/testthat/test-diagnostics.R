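test_that("blood-pool grading follows the equal-or-greater rule", {
  expect_equal(classify_blood_pool_grade(3.86, 3.08)$label, "positive")
  expect_equal(classify_blood_pool_grade(1.24, 2.99)$label, "negative")
  expect_equal(classify_blood_pool_grade(2.5, 2.5)$label, "positive")
  # label is reproducible from the recorded inputs
  r <- classify_blood_pool_grade(1.7, 1.2, "s1", "10")
  expect_equal(classify_blood_pool_grade(r$inputs_used[["suv_myo"]],
                                         r$inputs_used[["suv_bp"]])$label,
               r$label)
})

test_that("%ID/mL thresholding is monotone with a positive boundary", {
  expect_equal(classify_pid(0.00488)$label, "positive")
  expect_equal(classify_pid(0.00139)$label, "negative")
  expect_equal(classify_pid(0.003)$label, "positive")     # boundary convention
  # lowering the threshold never flips positive -> negative
  set.seed(12)
  for (i in 1:30) {
    pid <- runif(1, 0, 0.01); th <- sort(runif(2, 0, 0.01), decreasing = TRUE)
    hi <- classify_pid(pid, th[1])$label
    lo <- classify_pid(pid, th[2])$label
    expect_false(hi == "positive" && lo == "negative")
  }
})

test_that("diagnostic performance counts and percentages are correct", {
  truth <- c(rep("positive", 8), rep("negative", 11))
  p <- diagnostic_performance(truth, truth)
  expect_equal(c(p$sensitivity, p$specificity, p$accuracy), c(100, 100, 100))
  inv <- ifelse(truth == "positive", "negative", "positive")
  p2 <- diagnostic_performance(inv, truth)
  expect_equal(c(p2$sensitivity, p2$specificity, p2$accuracy), c(0, 0, 0))
  # TP=3, FN=1, TN=10, FP=1 by direct counting
  pred <- c(rep(TRUE, 3), FALSE, rep(FALSE, 10), TRUE)
  tru <- c(rep(TRUE, 4), rep(FALSE, 11))
  p3 <- diagnostic_performance(pred, tru)
  expect_equal(p3$sensitivity, 75)
  expect_equal(p3$specificity, 90.9, tolerance = 1e-3)
  expect_equal(p3$accuracy, 86.7, tolerance = 1e-3)
  expect_equal(p3$TP + p3$FP + p3$TN + p3$FN, 15)
  expect_error(diagnostic_performance(character(0), character(0)), "empty")
})

test_that("confusion counts always conserve the sample size", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    pred <- runif(n) > 0.5; tru <- runif(n) > 0.5
    p <- diagnostic_performance(pred, tru)
    expect_equal(p$TP + p$FP + p$TN + p$FN, n)
  }
})

test_that("Cohen's kappa matches hand-computed tables and stays in [-1, 1]", {
  a <- c(rep("positive", 8), rep("negative", 11))
  expect_equal(cohen_kappa(a, a), 1)
  # 2x2 table a=4, b=1, c=1, d=4: p_o = 0.8, p_e = 0.5 -> kappa = 0.6
  x <- c(rep("P", 4), "P", "N", rep("N", 4))
  y <- c(rep("P", 4), "N", "P", rep("N", 4))
  expect_equal(cohen_kappa(x, y), 0.6)
  # chance-level agreement: p_o = p_e -> kappa = 0
  x0 <- c("P", "P", "N", "N")
  y0 <- c("P", "N", "P", "N")
  expect_equal(cohen_kappa(x0, y0), 0)
  # degenerate-but-perfect agreement is 1 with a flag
  k <- cohen_kappa(rep("P", 5), rep("P", 5))
  expect_equal(as.numeric(k), 1)
  expect_true(attr(k, "degenerate"))
  expect_error(cohen_kappa(character(0), character(0)), "empty")
})

test_that("kappa agrees with an independent implementation on random tables", {
  skip_if_not_installed("e1071")
  set.seed(14)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    a <- sample(c("P", "N"), n, replace = TRUE)
    b <- ifelse(runif(n) < 0.7, a, sample(c("P", "N"), n, replace = TRUE))
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    tab <- table(factor(a, c("N", "P")), factor(b, c("N", "P")))
    expect_equal(cohen_kappa(a, b), e1071::classAgreement(tab)$kappa,
                 tolerance = 1e-12)
  }
})

test_that("Welch's t from summaries reproduces the published BMI comparison", {
  r <- welch_t_from_summary(30.9, 5.6, 11, 26.4, 3.4, 8)
  expect_equal(r$t, 2.171, tolerance = 1e-3)
  expect_equal(round(r$p, 2), 0.04)
  same <- welch_t_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t_from_summary(1, 0, 5, 2, 1, 5), "sd > 0")
})

test_that("Welch's t from summaries matches t.test on reconstructed samples", {
  # two-point samples realise any (mean, sd) pair exactly: m +/- s/sqrt(2)
  set.seed(15)
  for (i in 1:10) {
    m <- runif(2, 0, 10); s <- runif(2, 0.5, 3)
    x <- m[1] + c(-1, 1) * s[1] / sqrt(2)
    y <- m[2] + c(-1, 1) * s[2] / sqrt(2)
    ref <- stats::t.test(x, y, var.equal = FALSE)
    got <- welch_t_from_summary(m[1], s[1], 2, m[2], s[2], 2)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(got$p, ref$p.value, tolerance = 1e-9)
  }
})
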
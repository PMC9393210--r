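# Confusion-matrix metric panel, repeated protocol, model comparison.

test_that("metric panel reproduces the benchmark-matrix arithmetic", {
  b <- benchmark_confusion_matrices()

  # combined model: whole row at 2-dp
  m <- classification_metrics(b$CNN_MLP)
  expect_equal(round(m$TPR, 2), 0.69)
  expect_equal(round(m$TNR, 2), 0.92)
  expect_equal(round(m$PPV, 2), 0.90)
  expect_equal(round(m$NPV, 2), 0.75)
  expect_equal(round(m$FPR, 2), 0.08)
  expect_equal(round(m$FNR, 2), 0.31)
  expect_equal(round(m$FDR, 2), 0.10)
  expect_equal(b$CNN_MLP$TP + b$CNN_MLP$TN, 2260)  # correct classifications

  # MLP matrix
  m2 <- classification_metrics(b$MLP)
  expect_equal(round(m2$TPR, 2), 0.70)
  expect_equal(round(m2$TNR, 2), 0.81)
  expect_equal(round(m2$PPV, 2), 0.79)
  expect_equal(round(m2$NPV, 2), 0.72)

  # CNN matrix
  m3 <- classification_metrics(b$CNN)
  expect_equal(round(m3$TPR, 2), 0.53)
  expect_equal(round(m3$TNR, 2), 0.80)
})

test_that("metric complementarity identities hold for random matrices", {
  set.seed(12)
  for (i in 1:20) {
    cm <- confusion_counts(TP = sample(0:500, 1), FN = sample(1:500, 1),
                           FP = sample(1:500, 1), TN = sample(0:500, 1))
    m <- classification_metrics(cm)
    expect_equal(m$TPR + m$FNR, 1)
    expect_equal(m$TNR + m$FPR, 1)
    if (!is.na(m$PPV)) expect_equal(m$PPV + m$FDR, 1)
  }
})

test_that("perfect and degenerate classifiers yield the expected panel", {
  truth <- rep(c(0, 1), each = 50)
  m <- classification_metrics(confusion_matrix(truth, truth),
                              scores = truth, truth = truth)
  expect_equal(m$TPR, 1); expect_equal(m$TNR, 1)
  expect_equal(m$PPV, 1); expect_equal(m$NPV, 1)
  expect_equal(m$FPR, 0); expect_equal(m$FNR, 0); expect_equal(m$FDR, 0)
  expect_equal(m$AUC, 1)

  # constant score: AUC 0.5 by the trapezoidal convention
  m5 <- classification_metrics(confusion_matrix(truth, rep(0, 100)),
                               scores = rep(0.4, 100), truth = truth)
  expect_equal(m5$AUC, 0.5)

  # zero denominators are undefined, not zero
  m0 <- classification_metrics(confusion_counts(0, 0, 3, 7))
  expect_true(is.na(m0$TPR))
  expect_true(is.na(m0$FNR))
})

test_that("AUC equals a hand-computed ranking example", {
  truth <- c(0, 0, 1, 1)
  scores <- c(0.1, 0.6, 0.4, 0.8)
  # pairs: (0.1,0.4)+ (0.1,0.8)+ (0.6,0.4)- (0.6,0.8)+ -> 3/4
  m <- classification_metrics(confusion_matrix(truth, c(0, 1, 0, 1)),
                              scores = scores, truth = truth)
  expect_equal(m$AUC, 0.75)
})

test_that("repeated protocol uses a fixed test set and reports run means", {
  set.seed(33)
  n <- 160
  X <- rbind(matrix(rnorm(n / 2 * 15, 0), n / 2),
             matrix(rnorm(n / 2 * 15, 2), n / 2))
  X <- pmin(pmax((X + 3) / 8, 0), 1)
  y <- rep(c(0, 1), each = n / 2)
  s <- repeated_protocol(mlp_spec(), X, y,
                         config = training_config(lr = 1e-3, max_epochs = 4,
                                                  seed = 5),
                         repetitions = 2, split_seed = 9)
  expect_length(s$accuracy, 2)
  expect_gte(mean(s$accuracy), min(s$accuracy))
  expect_lte(mean(s$accuracy), max(s$accuracy))
  expect_length(s$test_idx, round(n * 0.2))
  expect_error(repeated_protocol(mlp_spec(), X, y, repetitions = 1),
               "repetitions")
})

test_that("degenerate always-majority accuracy equals the majority fraction", {
  truth <- c(rep(0, 70), rep(1, 30))
  cm <- confusion_matrix(truth, rep(0, 100))
  m <- classification_metrics(cm)
  expect_equal(m$ACC, 0.7)
})

test_that("model comparison applies the t-test with the degenerate conventions", {
  a <- rep(0.8, 30)
  r <- compare_models(a, a)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$reject)

  set.seed(21)
  lo <- 0.70 + rnorm(30, sd = 0.01)
  hi <- 0.80 + rnorm(30, sd = 0.01)
  r2 <- compare_models(lo, hi, alpha = 0.01)
  expect_true(r2$reject)
  # agrees with the standard Welch t statistic
  tt <- t.test(lo, hi)
  expect_equal(r2$statistic, unname(tt$statistic))
  expect_equal(r2$p_value, tt$p.value)

  r3 <- compare_models(lo, hi, pooled = TRUE)
  expect_equal(r3$p_value, t.test(lo, hi, var.equal = TRUE)$p.value)

  expect_error(compare_models(lo, hi, alpha = 1.5), "alpha")
  expect_error(compare_models(lo, hi[1:10]), "repetition count")
})
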
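test_that("confusion counting enumerates correctly", {
  cc <- confusion(c("malignant", "benign", "malignant", "benign"),
                  c("malignant", "malignant", "benign", "benign"))
  expect_equal(cc$TP, 1); expect_equal(cc$FN, 1)
  expect_equal(cc$FP, 1); expect_equal(cc$TN, 1)
  allpos <- confusion(rep("malignant", 3), rep("malignant", 3))
  expect_equal(allpos$FP + allpos$FN, 0)
  expect_error(confusion(c("malignant", "weird"), c("benign", "benign")),
               "weird")
  expect_error(confusion("benign", character(0)), "equal")
})

test_that("basic metrics match hand-computed values and mark 0/0 undefined", {
  m <- basic_metrics(c(TP = 50, FP = 10, FN = 5, TN = 35))
  expect_equal(m$precision, 50 / 60, tolerance = 1e-12)
  expect_equal(round(m$precision, 4), 0.8333)
  expect_equal(round(m$sensitivity, 4), 0.9091)
  expect_equal(m$accuracy, 0.85)
  expect_equal(round(m$f1, 4), 0.8696)
  perf <- basic_metrics(c(TP = 5, FP = 0, FN = 0, TN = 5))
  expect_true(all(unlist(perf) == 1))
  none <- basic_metrics(c(TP = 0, FP = 0, FN = 2, TN = 8))
  expect_true(is.na(none$precision))
  expect_equal(none$accuracy, 0.8)
})

test_that("imbalance metrics match direct formulas and degenerate to NA/0", {
  m <- imbalance_metrics(c(TP = 50, FP = 10, FN = 5, TN = 35))
  expect_equal(m$mcc, (50 * 35 - 10 * 5) / sqrt(60 * 55 * 45 * 40),
               tolerance = 1e-12)
  expect_equal(round(m$mcc, 4), 0.6975)
  perf <- imbalance_metrics(c(TP = 9, FP = 0, FN = 0, TN = 1))
  expect_equal(unlist(perf), c(balanced_accuracy = 1, g_mean = 1, mcc = 1,
                               kappa = 1))
  onecls <- imbalance_metrics(c(TP = 5, FP = 5, FN = 0, TN = 0))
  expect_true(is.na(onecls$mcc))
  expect_equal(onecls$kappa, 0) # chance-level agreement
})

test_that("metrics agree with independent brute-force formulas on random counts", {
  withr::with_seed(17, {
    for (i in 1:1000) {
      tp <- rpois(1, 20); fp <- rpois(1, 8); fn <- rpois(1, 8); tn <- rpois(1, 30)
      if (tp + fp + fn + tn == 0) tn <- 1
      b <- basic_metrics(c(TP = tp, FP = fp, FN = fn, TN = tn))
      im <- imbalance_metrics(c(TP = tp, FP = fp, FN = fn, TN = tn))
      # independent transcription
      sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
      prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      expect_identical(b$sensitivity, sens)
      expect_identical(b$specificity, spec)
      expect_identical(b$precision, prec)
      expect_equal(b$accuracy, (tp + tn) / (tp + fp + fn + tn))
      if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
        expect_equal(b$f1, 2 * prec * sens / (prec + sens), tolerance = 1e-12)
      }
      if (!is.na(sens) && !is.na(spec)) {
        expect_equal(im$balanced_accuracy, (sens + spec) / 2, tolerance = 1e-12)
        expect_equal(im$g_mean, sqrt(sens * spec), tolerance = 1e-12)
        # AM-GM: the geometric mean never exceeds balanced accuracy
        expect_lte(im$g_mean, im$balanced_accuracy + 1e-12)
        # accuracy is the prevalence-weighted mix of sens and spec
        prev <- (tp + fn) / (tp + fp + fn + tn)
        expect_equal(b$accuracy, prev * sens + (1 - prev) * spec,
                     tolerance = 1e-12)
      }
      den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
      if (den > 0) {
        expect_equal(im$mcc, (tp * tn - fp * fn) / sqrt(den), tolerance = 1e-12)
        expect_gte(im$mcc, -1); expect_lte(im$mcc, 1)
      }
    }
  })
})

test_that("kappa agrees with e1071's independent implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(23, {
    for (i in 1:25) {
      tp <- rpois(1, 15); fp <- rpois(1, 6); fn <- rpois(1, 6); tn <- rpois(1, 25)
      tab <- matrix(c(tp, fn, fp, tn), 2, 2)
      if (sum(tab) == 0) next
      ours <- imbalance_metrics(c(TP = tp, FP = fp, FN = fn, TN = tn))$kappa
      ref <- e1071::classAgreement(tab)$kappa
      if (!is.na(ours) && is.finite(ref)) expect_equal(ours, ref, tolerance = 1e-12)
    }
  })
})

test_that("rank AUC handles separation, ties and the hand-worked example", {
  y <- c("malignant", "malignant", "benign", "benign")
  expect_equal(auc_rank(c(0.9, 0.8, 0.2, 0.1), y), 1)
  expect_equal(auc_rank(c(0.5, 0.5, 0.5, 0.5), y), 0.5)
  expect_equal(auc_rank(c(0.9, 0.4, 0.6, 0.1), y), 0.75) # 3 of 4 P-N pairs
  expect_true(is.na(auc_rank(c(0.1, 0.9), c("benign", "benign"))))
})

test_that("rank AUC equals trapezoidal ROC integration and pROC", {
  trapezoid_auc <- function(scores, labels) {
    pos <- labels == "malignant"
    th <- sort(unique(scores), decreasing = TRUE)
    tpr <- c(0, vapply(th, function(t) mean(scores[pos] >= t), numeric(1)), 1)
    fpr <- c(0, vapply(th, function(t) mean(scores[!pos] >= t), numeric(1)), 1)
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
  withr::with_seed(41, {
    for (i in 1:20) {
      n <- sample(10:60, 1)
      labels <- sample(c("malignant", "benign"), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      scores <- round(runif(n), 2) # ties on purpose
      expect_equal(auc_rank(scores, labels), trapezoid_auc(scores, labels),
                   tolerance = 1e-12)
    }
  })
  skip_if_not_installed("pROC")
  withr::with_seed(43, {
    labels <- sample(c("malignant", "benign"), 50, replace = TRUE)
    scores <- runif(50)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                          levels = c("benign", "malignant"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(auc_rank(scores, labels), ref, tolerance = 1e-12)
  })
})

test_that("swapping the positive class swaps sensitivity and specificity", {
  withr::with_seed(53, {
    pred <- sample(c("malignant", "benign"), 40, replace = TRUE)
    truth <- sample(c("malignant", "benign"), 40, replace = TRUE)
    a <- basic_metrics(confusion(pred, truth, positive = "malignant"))
    b <- basic_metrics(confusion(pred, truth, positive = "benign"))
    expect_equal(a$sensitivity, b$specificity)
    expect_equal(a$specificity, b$sensitivity)
    expect_equal(a$accuracy, b$accuracy)
  })
})

test_that("the assembled report carries every field and prints percents", {
  pred <- c("malignant", "benign", "benign", "malignant")
  truth <- c("malignant", "benign", "malignant", "benign")
  rep_ <- metrics_report(pred, truth, scores = c(0.9, 0.2, 0.4, 0.6))
  expect_s3_class(rep_, "metrics_report")
  need <- c("precision", "sensitivity", "specificity", "f1", "accuracy",
            "balanced_accuracy", "g_mean", "mcc", "kappa", "auc")
  expect_true(all(need %in% names(rep_)))
  df <- as.data.frame(rep_)
  expect_equal(nrow(df), length(need))
  out <- capture.output(print(rep_))
  expect_true(any(grepl("%", out)))
})
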
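# Confusion-matrix metric panel, repeated-training protocol and model
# comparison. Positive class = pathological (label 1).

#' Build a confusion matrix from labels and predictions
#'
#' @param truth Binary true labels (1 = pathological = positive).
#' @param pred Binary predicted labels.
#' @return Object of class `confusion_matrix`: named list TP, FN, FP, TN.
#' @export
confusion_matrix <- function(truth, pred) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred),
            all(truth %in% 0:1), all(pred %in% 0:1))
  structure(list(TP = sum(truth == 1 & pred == 1),
                 FN = sum(truth == 1 & pred == 0),
                 FP = sum(truth == 0 & pred == 1),
                 TN = sum(truth == 0 & pred == 0)),
            class = "confusion_matrix")
}

#' Construct a confusion matrix from counts
#'
#' @param TP,FN,FP,TN Non-negative integer counts (positive =
#'   pathological).
#' @return Object of class `confusion_matrix`.
#' @export
confusion_counts <- function(TP, FN, FP, TN) {
  stopifnot(TP >= 0, FN >= 0, FP >= 0, TN >= 0)
  structure(list(TP = TP, FN = FN, FP = FP, TN = TN),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("          pred+  pred-\ntrue+  TP=%5d FN=%5d\ntrue-  FP=%5d TN=%5d\n",
              x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Benchmark confusion matrices for the three architectures
#'
#' Reference single-run test-set confusion matrices (2800 examples,
#' balanced clinical CTG benchmark) for the standalone MLP, the standalone
#' CNN and the combined CNN+MLP classifier, used as worked examples for
#' the metric panel.
#'
#' @return Named list of three [confusion_counts()] objects: `MLP`,
#'   `CNN`, `CNN_MLP`.
#' @export
benchmark_confusion_matrices <- function() {
  list(MLP = confusion_counts(TP = 998, FN = 427, FP = 258, TN = 1117),
       CNN = confusion_counts(TP = 681, FN = 596, FP = 298, TN = 1225),
       CNN_MLP = confusion_counts(TP = 960, FN = 431, FP = 109, TN = 1300))
}

#' Classification metric panel
#'
#' The eight ratio metrics plus AUC. `TPR = TP/(TP+FN)` (sensitivity,
#' recall), `TNR = TN/(TN+FP)` (specificity), `PPV = TP/(TP+FP)`
#' (precision), `NPV = TN/(TN+FN)`, `FPR = FP/(FP+TN)`,
#' `FNR = FN/(TP+FN)`, `FDR = FP/(TP+FP)`,
#' `ACC = (TP+TN)/total`. A metric with a zero denominator is reported as
#' `NA` (undefined), never as 0. AUC is the trapezoidal area under the
#' ROC curve of the positive-class scores, when scores are supplied.
#'
#' @param cm A [confusion_matrix()] / [confusion_counts()] object.
#' @param scores Optional per-sample positive-class probabilities for AUC.
#' @param truth Binary true labels aligned with `scores`.
#' @return Named list of class `metrics_report`.
#' @export
classification_metrics <- function(cm, scores = NULL, truth = NULL) {
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  with(cm, {
    auc <- NA_real_
    if (!is.null(scores)) {
      stopifnot(!is.null(truth), length(scores) == length(truth))
      if (length(unique(truth)) == 2) {
        r <- pROC::roc(response = truth, predictor = scores,
                       levels = c(0, 1), direction = "<", quiet = TRUE)
        auc <- as.numeric(pROC::auc(r))
      }
    }
    structure(list(
      ACC = rat(TP + TN, TP + FN + FP + TN),
      TPR = rat(TP, TP + FN), TNR = rat(TN, TN + FP),
      PPV = rat(TP, TP + FP), NPV = rat(TN, TN + FN),
      FPR = rat(FP, FP + TN), FNR = rat(FN, TP + FN),
      FDR = rat(FP, TP + FP), AUC = auc,
      cm = cm), class = "metrics_report")
  })
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  v <- unlist(x[c("ACC", "TPR", "TNR", "PPV", "NPV", "FPR", "FNR", "FDR",
                  "AUC")])
  print(round(v, digits))
  invisible(x)
}

#' Repeated-training evaluation protocol
#'
#' The data are split once, 80/20 stratified, into a training pool and a
#' fixed test set; the model is then built and trained `repetitions`
#' times with distinct seeds, and the metric panel is computed on the
#' fixed test set after every run. The summary reports the per-run
#' accuracies and the mean of every metric.
#'
#' @param spec Model specification ([mlp_spec()], [cnn_spec()] or
#'   [combined_spec()]).
#' @param x Model inputs as for [train_model()].
#' @param y Binary labels.
#' @param config Base [training_config()]; each run uses
#'   `config$seed + run - 1`.
#' @param repetitions Number of training repetitions (>= 2; default 30).
#' @param train_fraction Fraction of data in the training pool (default
#'   0.8).
#' @param split_seed Seed for the single train/test split.
#' @return Object of class `repeated_run_summary`: `accuracy` (per run),
#'   `mean_metrics`, `reports` (per-run panels), `test_idx`.
#' @export
repeated_protocol <- function(spec, x, y, config = training_config(),
                              repetitions = 30, train_fraction = 0.8,
                              split_seed = 1L) {
  if (repetitions < 2)
    stop("at least 2 repetitions are required for a t-test")
  y <- as.integer(y)
  n <- length(y)
  set.seed(split_seed)
  test_idx <- integer(0)
  for (cl in c(0L, 1L)) {
    cand <- which(y == cl)
    test_idx <- c(test_idx, sample(cand, round(length(cand) * (1 - train_fraction))))
  }
  tr_idx <- setdiff(seq_len(n), test_idx)
  sub <- function(idx) {
    if (is.list(x) && !is.data.frame(x))
      list(features = if (!is.null(x$features)) x$features[idx, , drop = FALSE],
           images = if (!is.null(x$images)) x$images[, , , idx, drop = FALSE])
    else if (length(dim(x)) == 4) x[, , , idx, drop = FALSE]
    else x[idx, , drop = FALSE]
  }
  x_tr <- sub(tr_idx); x_te <- sub(test_idx)
  y_tr <- y[tr_idx]; y_te <- y[test_idx]

  reports <- vector("list", repetitions)
  acc <- numeric(repetitions)
  for (r in seq_len(repetitions)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    m <- build_model(spec, seed = cfg$seed)
    m <- train_model(m, x_tr, y_tr, cfg)
    p <- predict_proba(m, x_te)
    cmr <- confusion_matrix(y_te, as.integer(p[, 2] > p[, 1]))
    reports[[r]] <- classification_metrics(cmr, scores = p[, 2], truth = y_te)
    acc[r] <- reports[[r]]$ACC
  }
  keys <- c("ACC", "TPR", "TNR", "PPV", "NPV", "FPR", "FNR", "FDR", "AUC")
  mm <- vapply(keys, function(k)
    mean(vapply(reports, function(rp) rp[[k]], numeric(1)), na.rm = TRUE),
    numeric(1))
  structure(list(accuracy = acc, mean_metrics = as.list(mm),
                 reports = reports, test_idx = test_idx,
                 repetitions = repetitions),
            class = "repeated_run_summary")
}

#' @export
print.repeated_run_summary <- function(x, ...) {
  cat(sprintf("<repeated_run_summary> %d runs, mean accuracy %.3f (range %.3f-%.3f)\n",
              x$repetitions, mean(x$accuracy), min(x$accuracy),
              max(x$accuracy)))
  invisible(x)
}

#' Compare two repeated-run summaries with a t-test
#'
#' Two-sample t-test on the per-run accuracies (Welch by default; set
#' `pooled = TRUE` for the equal-variance test). The null hypothesis of
#' equal mean accuracy is rejected when `p < alpha`. When both samples
#' have zero variance, `p` is 1 if the means are equal and 0 otherwise
#' (degenerate convention).
#'
#' @param summary_a,summary_b [repeated_protocol()] results (or plain
#'   numeric accuracy vectors) with equal run counts.
#' @param alpha Significance level in (0, 1), default 0.01.
#' @param pooled Use the pooled-variance test instead of Welch's.
#' @return List with `statistic`, `p_value`, `reject`, `alpha`,
#'   `mean_a`, `mean_b`.
#' @export
compare_models <- function(summary_a, summary_b, alpha = 0.01,
                           pooled = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly in (0, 1)")
  a <- if (inherits(summary_a, "repeated_run_summary")) summary_a$accuracy
       else as.numeric(summary_a)
  b <- if (inherits(summary_b, "repeated_run_summary")) summary_b$accuracy
       else as.numeric(summary_b)
  if (length(a) != length(b))
    stop("summaries must have the same repetition count")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
    return(list(statistic = 0, p_value = p, reject = p < alpha,
                alpha = alpha, mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = pooled)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       reject = tt$p.value < alpha, alpha = alpha,
       mean_a = mean(a), mean_b = mean(b))
}

#' Render metric panels as a compact summary table
#'
#' @param reports Named list of `metrics_report` objects (one per model).
#' @param digits Display rounding (default 2, matching conventional
#'   reporting); raw values are kept in the reports themselves.
#' @return A data.frame, one row per model.
#' @export
metrics_table <- function(reports, digits = 2) {
  keys <- c("ACC", "TPR", "TNR", "PPV", "NPV", "FPR", "FNR", "FDR", "AUC")
  out <- do.call(rbind, lapply(reports, function(r)
    as.data.frame(lapply(r[keys], function(v) round(v, digits)))))
  cbind(model = names(reports), out)
}
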
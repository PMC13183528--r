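# Confusion-matrix performance metrics, rank-based ROC AUC, and the
# imbalance-robust suite (balanced accuracy, G-mean, MCC, Cohen's kappa).
# "malignant" is the positive class throughout. Metrics whose denominator
# is zero are reported as NA (an explicit undefined marker), never silently
# substituted with 0 or 1.

#' Confusion counts for a two-class problem
#'
#' @param pred_labels,true_labels Equal-length label vectors.
#' @param positive The positive class (default `"malignant"`).
#' @param negative The negative class; inferred when the label set has at
#'   most two levels.
#' @return An object of class `confusion_counts`: list with `TP`, `TN`,
#'   `FP`, `FN`, `positive`, `negative`.
#' @examples
#' confusion(c("malignant", "benign"), c("malignant", "malignant"))
#' @export
confusion <- function(pred_labels, true_labels, positive = "malignant",
                      negative = NULL) {
  pred_labels <- as.character(pred_labels)
  true_labels <- as.character(true_labels)
  if (length(pred_labels) != length(true_labels) || !length(true_labels)) {
    stop("`pred_labels` and `true_labels` must be equal non-zero length")
  }
  lev <- unique(c(true_labels, pred_labels))
  if (is.null(negative)) {
    neg <- setdiff(lev, positive)
    if (length(neg) > 1L) {
      stop("labels other than the positive class: ",
           paste(neg, collapse = ", "), "; give `negative` explicitly")
    }
    negative <- if (length(neg)) neg else
      if (positive == "malignant") "benign" else "negative"
  }
  bad <- setdiff(lev, c(positive, negative))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  p <- pred_labels == positive
  t_ <- true_labels == positive
  structure(list(TP = sum(p & t_), TN = sum(!p & !t_), FP = sum(p & !t_),
                 FN = sum(!p & t_), positive = positive, negative = negative),
            class = "confusion_counts")
}

as_counts <- function(c_) {
  if (inherits(c_, "confusion_counts")) return(c_)
  if (is.numeric(c_) && all(c("TP", "TN", "FP", "FN") %in% names(c_))) {
    return(structure(as.list(c_[c("TP", "TN", "FP", "FN")]),
                     class = "confusion_counts"))
  }
  stop("expected a confusion_counts object or named TP/TN/FP/FN vector")
}

safe_div <- function(num, den) if (den > 0) num / den else NA_real_

#' Core confusion-matrix metrics
#'
#' Precision `TP/(TP+FP)`, sensitivity (recall) `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, their harmonic-mean F1, and accuracy. Zero-denominator
#' entries are `NA`.
#'
#' @param c_ A [confusion()] result (or named `TP`/`TN`/`FP`/`FN` vector).
#' @return Named list with `precision`, `sensitivity`, `specificity`,
#'   `f1`, `accuracy`.
#' @export
basic_metrics <- function(c_) {
  c_ <- as_counts(c_)
  tot <- c_$TP + c_$TN + c_$FP + c_$FN
  if (tot < 1) stop("empty confusion counts")
  prec <- safe_div(c_$TP, c_$TP + c_$FP)
  sens <- safe_div(c_$TP, c_$TP + c_$FN)
  spec <- safe_div(c_$TN, c_$TN + c_$FP)
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
    2 * prec * sens / (prec + sens)
  list(precision = prec, sensitivity = sens, specificity = spec, f1 = f1,
       accuracy = (c_$TP + c_$TN) / tot)
}

#' Imbalance-robust metrics
#'
#' Balanced accuracy (mean of sensitivity and specificity), G-mean (their
#' geometric mean), Matthews correlation coefficient, and Cohen's kappa
#' (agreement above the chance level implied by the marginals). MCC is
#' `NA` when any marginal is empty; kappa is `NA` when chance agreement
#' is 1.
#'
#' @inheritParams basic_metrics
#' @return Named list with `balanced_accuracy`, `g_mean`, `mcc`, `kappa`.
#' @export
imbalance_metrics <- function(c_) {
  c_ <- as_counts(c_)
  tp <- as.numeric(c_$TP); tn <- as.numeric(c_$TN)
  fp <- as.numeric(c_$FP); fn <- as.numeric(c_$FN)
  tot <- tp + tn + fp + fn
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  ba <- if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2
  gm <- if (is.na(sens) || is.na(spec)) NA_real_ else sqrt(sens * spec)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else NA_real_
  po <- (tp + tn) / tot
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / tot^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else NA_real_
  list(balanced_accuracy = ba, g_mean = gm, mcc = mcc, kappa = kappa)
}

#' ROC AUC by the rank (Mann-Whitney) statistic
#'
#' The probability that a random positive scores above a random negative;
#' ties contribute 1/2 (midranks). Exactly equals the trapezoidal area
#' under the empirical ROC curve.
#'
#' @param scores Positive-class probabilities or scores.
#' @param true_labels Label vector.
#' @param positive Positive class name.
#' @return AUC in [0, 1]; `NA` when only one class is present.
#' @examples
#' auc_rank(c(0.9, 0.4, 0.6, 0.1), c("malignant", "malignant", "benign", "benign"))
#' @export
auc_rank <- function(scores, true_labels, positive = "malignant") {
  stopifnot(length(scores) == length(true_labels))
  pos <- as.character(true_labels) == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full performance report
#'
#' Bundles [basic_metrics()], [imbalance_metrics()] and (when scores are
#' given) [auc_rank()] into one report.
#'
#' @param pred_labels,true_labels Label vectors.
#' @param scores Optional positive-class scores for AUC.
#' @param positive Positive class (default `"malignant"`).
#' @return A list of class `metrics_report` with the confusion counts and
#'   all metric fields (proportions in [0, 1]; `NA` marks undefined).
#' @export
metrics_report <- function(pred_labels, true_labels, scores = NULL,
                           positive = "malignant") {
  cc <- confusion(pred_labels, true_labels, positive = positive)
  out <- c(list(counts = cc), basic_metrics(cc), imbalance_metrics(cc))
  out$auc <- if (is.null(scores)) NA_real_ else
    auc_rank(scores, true_labels, positive)
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cc <- x$counts
  cat(sprintf("confusion (positive = %s): TP=%d FP=%d FN=%d TN=%d\n",
              cc$positive, cc$TP, cc$FP, cc$FN, cc$TN))
  nm <- setdiff(names(x), "counts")
  for (n in nm) {
    v <- x[[n]]
    if (is.na(v)) {
      cat(sprintf("  %-18s undefined\n", n))
    } else {
      cat(sprintf("  %-18s %.*f (%.1f%%)\n", n, digits, v, 100 * v))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.metrics_report <- function(x, ...) {
  nm <- setdiff(names(x), "counts")
  data.frame(metric = nm,
             value = vapply(nm, function(n) x[[n]], numeric(1)),
             row.names = NULL)
}
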
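#' Build a confusion matrix from truth and predicted labels
#'
#' @param truth,predicted Vectors of labels (`"DNA_BP"` / `"NON_DNA_BP"`).
#' @param positive The positive class (default `"DNA_BP"`).
#' @return A named integer vector `c(TP, FN, FP, TN)`.
#' @export
confusion_matrix <- function(truth, predicted, positive = "DNA_BP") {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  c(TP = sum(truth == positive & predicted == positive),
    FN = sum(truth == positive & predicted != positive),
    FP = sum(truth != positive & predicted == positive),
    TN = sum(truth != positive & predicted != positive))
}

#' Confusion-matrix performance metrics
#'
#' Computes the four standard binary-classification statistics:
#' \deqn{Accuracy = (TP + TN) / (TP + TN + FP + FN)}
#' \deqn{Sensitivity = TP / (TP + FN)}
#' \deqn{Specificity = TN / (TN + FP)}
#' \deqn{MCC = (TP \times TN - FN \times FP) /
#'   \sqrt{(TP+FN)(TP+FP)(TN+FN)(TN+FP)}}
#' Metrics with a zero denominator are reported as `NA` (undefined).
#' Values are returned at full precision; round to 2 decimal places for
#' report tables.
#'
#' @param cm A named vector or list with elements `TP`, `TN`, `FP`, `FN`
#'   (as from [confusion_matrix()]).
#' @return A list with `accuracy`, `sensitivity`, `specificity`, `mcc`.
#' @examples
#' confusion_metrics(c(TP = 77, FN = 23, FP = 15, TN = 85))
#' @export
confusion_metrics <- function(cm) {
  cm <- as.list(cm)
  tp <- as.numeric(cm$TP); tn <- as.numeric(cm$TN)
  fp <- as.numeric(cm$FP); fn <- as.numeric(cm$FN)
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative confusion-matrix count")
  total <- tp + tn + fp + fn
  if (total == 0) stop("confusion matrix is all zero")
  denom_mcc <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fn) * sqrt(tn + fp)
  list(accuracy = (tp + tn) / total,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       mcc = if (denom_mcc > 0) (tp * tn - fn * fp) / denom_mcc
             else NA_real_)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Splits the dataset into `k` stratified folds under `seed`; each fold is
#' held out once while a model is trained on the remainder (with its own
#' internal grid search). The summary metrics are computed from the pooled
#' confusion matrix over all folds, which is stable for small folds;
#' per-fold metrics are also returned.
#'
#' @param data A [labeled_dataset()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold assignment (training seeds derive from
#'   it).
#' @param ... Passed to [dbp_train()] (e.g. `cost_grid`, `gamma_grid`,
#'   `inner_folds`).
#' @return A list with `summary` (pooled [confusion_metrics()]), `pooled_cm`,
#'   `folds` (per-fold confusion matrices and metrics), and `assignments`
#'   (fold label per entry, in dataset order).
#' @export
cross_validate <- function(data, k = 5, seed = 1, ...) {
  xy <- as_xy(data)
  folds <- local_seed(seed, stratified_folds(xy$y, k))
  per_fold <- vector("list", k)
  pooled <- c(TP = 0L, FN = 0L, FP = 0L, TN = 0L)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- dbp_train(list(x = xy$x[tr, , drop = FALSE], y = xy$y[tr]),
                     seed = seed + f, ...)
    pred <- predict(fit, xy$x[!tr, , drop = FALSE])
    cm <- confusion_matrix(xy$y[!tr], pred$predicted_label)
    pooled <- pooled + cm
    per_fold[[f]] <- list(cm = cm, metrics = confusion_metrics(cm),
                          cost = fit$cost, gamma = fit$gamma)
  }
  list(summary = confusion_metrics(pooled), pooled_cm = pooled,
       folds = per_fold, assignments = folds)
}

#' Evaluate a trained model on a held-out test set
#'
#' @param model A `dbp_model`.
#' @param test A [labeled_dataset()].
#' @return A list with `cm`, `metrics` and the prediction table.
#' @export
evaluate_model <- function(model, test) {
  pred <- predict(model, test)
  cm <- confusion_matrix(test$label, pred$predicted_label)
  list(cm = cm, metrics = confusion_metrics(cm), predictions = pred)
}

#' Probability-threshold sweep over a prediction table
#'
#' For each threshold, counts the predicted DNA-binding proteins whose
#' probability score is at least the threshold (inclusive), in total and per
#' annotation class when one is supplied. Totals are non-increasing in the
#' threshold; per-class counts sum to the total.
#'
#' @param predictions A prediction data frame (see [predict.dbp_model()]).
#' @param goa_classes Optional character vector of annotation classes
#'   (`"GOA_DB"`, `"GOA_OTHER"`, `"GOA_UNKNOWN"`), either named by
#'   protein id or parallel to `predictions`.
#' @param thresholds Ascending numeric vector of probability thresholds in
#'   \[0.5, 1\].
#' @return A data frame with one row per threshold: `threshold`, `n_total`
#'   and, with classes, `n_goa_db`, `n_goa_other`, `n_goa_unknown`.
#' @export
threshold_sweep <- function(predictions, goa_classes = NULL,
                            thresholds = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(!is.unsorted(thresholds))
  is_db <- predictions$predicted_label == "DNA_BP"
  score <- predictions$probability_score
  if (!is.null(goa_classes)) {
    if (!is.null(names(goa_classes)))
      goa_classes <- unname(goa_classes[predictions$protein_id])
    stopifnot(length(goa_classes) == nrow(predictions))
  }
  rows <- lapply(thresholds, function(th) {
    sel <- is_db & score >= th
    row <- data.frame(threshold = th, n_total = sum(sel))
    if (!is.null(goa_classes)) {
      row$n_goa_db <- sum(sel & goa_classes == "GOA_DB")
      row$n_goa_other <- sum(sel & goa_classes == "GOA_OTHER")
      row$n_goa_unknown <- sum(sel & goa_classes == "GOA_UNKNOWN")
    }
    row
  })
  out <- do.call(rbind, rows)
  if (is.unsorted(rev(out$n_total)))
    stop("internal error: sweep totals increased with threshold")
  out
}

#' Select a probability threshold from an expected DNA-BP fraction
#'
#' DNA-binding proteins are expected to make up roughly 6-7\% of a
#' eukaryotic proteome. Given a threshold sweep, the expected count is
#' `round(expected_fraction * proteome_size)` (half-up rounding), and the
#' selected threshold is the smallest one whose predicted-set size is at or
#' below that expectation — i.e. the largest predicted set that does not
#' exceed it. If every sweep row exceeds the expectation, the largest
#' threshold is returned with a warning.
#'
#' @param sweep A [threshold_sweep()] data frame.
#' @param proteome_size Number of proteins in the proteome.
#' @param expected_fraction Expected DNA-BP fraction (default 0.06).
#' @return The selected threshold, with attribute `expected_count`.
#' @examples
#' sw <- data.frame(threshold = c(0.80, 0.85, 0.90),
#'                  n_total = c(2438, 1459, 659))
#' select_threshold(sw, proteome_size = 34725)  # 0.85, expecting 2084
#' @export
select_threshold <- function(sweep, proteome_size,
                             expected_fraction = 0.06) {
  stopifnot(nrow(sweep) >= 1)
  expected <- floor(expected_fraction * proteome_size + 0.5)
  ord <- order(sweep$threshold)
  ok <- which(sweep$n_total[ord] <= expected)
  if (length(ok)) {
    th <- sweep$threshold[ord][ok[1]]
  } else {
    th <- sweep$threshold[ord][nrow(sweep)]
    warning("no threshold keeps the predicted set within the expected ",
            expected, " proteins; returning the largest threshold ", th)
  }
  structure(th, expected_count = expected)
}
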
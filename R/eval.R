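#' Confusion matrix
#'
#' Rows are true labels, columns predicted, in the order of `labels`.
#'
#' @param truth,predicted Label vectors (character or factor, same length).
#' @param labels Class ordering; defaults to the sorted union.
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(truth, predicted,
                      labels = sort(unique(c(as.character(truth),
                                             as.character(predicted))))) {
  stopifnot(length(truth) == length(predicted))
  t_f <- factor(as.character(truth), levels = labels)
  p_f <- factor(as.character(predicted), levels = labels)
  cm <- table(truth = t_f, predicted = p_f)
  structure(matrix(as.integer(cm), nrow(cm), ncol(cm),
                   dimnames = dimnames(cm)),
            class = c("confusion_matrix", "matrix"))
}

#' Classification metrics from a confusion matrix
#'
#' One-vs-rest reduction per class with the standard definitions:
#' `accuracy = trace / total`, `precision_c = TP / (TP + FP)`,
#' `recall_c = TP / (TP + FN)`, and the F-score as the harmonic mean
#' `2 * precision * recall / (precision + recall)`. A class absent from both
#' truth and predictions has undefined precision/recall; such classes are
#' reported as `NA` and excluded from the macro averages with a warning. A
#' class where precision and recall are both 0 gets F-score 0 by convention.
#'
#' @param cm A square counts matrix (rows truth, columns predicted).
#' @return A `metric_report` list: `accuracy`, per-class `precision`,
#'   `recall`, `f_score`, and `macro_precision`, `macro_recall`,
#'   `macro_f_score`.
#' @export
metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  stopifnot(nrow(cm) == ncol(cm))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f <- ifelse(!is.na(precision) & !is.na(recall),
              ifelse(precision + recall > 0,
                     2 * precision * recall / (precision + recall), 0),
              NA_real_)
  if (anyNA(c(precision, recall)))
    warning("some classes have no observations or predictions; excluded from macro averages")
  structure(list(
    accuracy = sum(tp) / total,
    precision = precision, recall = recall, f_score = f,
    macro_precision = mean(precision, na.rm = TRUE),
    macro_recall = mean(recall, na.rm = TRUE),
    macro_f_score = mean(f, na.rm = TRUE)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro P %.4f R %.4f F %.4f\n", x$accuracy,
              x$macro_precision, x$macro_recall, x$macro_f_score))
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' `n` folds, each holding out one sample. The fold score is recorded both
#' as the mean squared error of the predicted probability vector against the
#' one-hot target and as 0/1 correctness; the aggregates are the means of
#' the per-fold values.
#'
#' @param samples List of labeled samples.
#' @param fit_fn `function(train_samples)` returning a fitted object.
#' @param predict_fn `function(fit, sample)` returning a probability vector
#'   over `labels`.
#' @param labels Class ordering for the one-hot target.
#' @return A `cv_result`: `fold_mse`, `fold_correct`, `cv_mse`,
#'   `cv_accuracy`, `n_folds`.
#' @export
loocv <- function(samples, fit_fn, predict_fn,
                  labels = c("relaxed", "happy", "sad", "angry")) {
  n <- length(samples)
  stopifnot(n >= 2)
  mse <- numeric(n)
  correct <- logical(n)
  for (i in seq_len(n)) {
    fit <- fit_fn(samples[-i])
    p <- predict_fn(fit, samples[[i]])
    stopifnot(length(p) == length(labels))
    y <- as.integer(labels == samples[[i]]$label)
    if (sum(y) != 1) stop("sample label not among `labels`")
    mse[i] <- mean((p - y)^2)
    correct[i] <- labels[which.max(p)] == samples[[i]]$label
  }
  structure(list(fold_mse = mse, fold_correct = correct,
                 cv_mse = mean(mse), cv_accuracy = mean(correct),
                 n_folds = n),
            class = "cv_result")
}

#' One-vs-rest ROC AUC per class
#'
#' AUC by the rank-sum (Mann-Whitney) identity with midranks for ties —
#' identical to the trapezoid area under the empirical ROC curve. Also
#' returns the macro average over classes present in the truth.
#'
#' @param scores `[n x k]` matrix of class scores (columns named or ordered
#'   as `labels`).
#' @param truth Label vector of length `n`.
#' @param labels Class ordering.
#' @return List with `auc` (per class, NA when a class is absent) and
#'   `macro_auc`.
#' @export
roc_auc <- function(scores, truth,
                    labels = c("relaxed", "happy", "sad", "angry")) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(truth), ncol(scores) == length(labels))
  auc <- vapply(seq_along(labels), function(j) {
    pos <- truth == labels[j]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(scores[, j])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  names(auc) <- labels
  list(auc = auc, macro_auc = mean(auc, na.rm = TRUE))
}

#' ROC curve points for one class
#'
#' Threshold sweep over the unique scores; returns the false/true positive
#' rates for CSV export or plotting.
#'
#' @param score Numeric score vector (higher = more positive).
#' @param positive Logical vector marking positives.
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  th <- c(Inf, sort(unique(score), decreasing = TRUE), -Inf)
  n1 <- sum(positive); n0 <- sum(!positive)
  do.call(rbind, lapply(th, function(t) {
    pred <- score >= t
    data.frame(threshold = t,
               fpr = if (n0) sum(pred & !positive) / n0 else 0,
               tpr = if (n1) sum(pred & positive) / n1 else 0)
  }))
}

#' Train/validation/test splits for the two evaluation protocols
#'
#' `person_dependent` draws a stratified split within subjects: every
#' subject contributes to all three sets, stratified by class. The default
#' fractions follow the published protocol's proportions (86 validation and
#' 86 test out of 864, the rest training). `person_independent` holds out
#' whole subjects: no test subject is ever seen in training.
#'
#' @param manifest data.frame with at least `sample_id`, `label`, `subject`.
#' @param mode `"person_dependent"` or `"person_independent"`.
#' @param val_frac,test_frac Sample fractions (person-dependent mode).
#' @param test_subjects,val_subjects Subject ids to hold out
#'   (person-independent mode); by default the last 20% / 20% of subjects
#'   under the split seed.
#' @param seed Split seed.
#' @return List of integer index vectors `train`, `val`, `test` (positions
#'   in `manifest`); disjoint, covering all rows.
#' @export
split_protocols <- function(manifest,
                            mode = c("person_dependent",
                                     "person_independent"),
                            val_frac = 86 / 864, test_frac = 86 / 864,
                            test_subjects = NULL, val_subjects = NULL,
                            seed = 1) {
  mode <- match.arg(mode)
  n <- nrow(manifest)
  if (mode == "person_dependent") {
    n_val <- round(n * val_frac)
    n_test <- round(n * test_frac)
    ## shuffle within each subject-by-class stratum, then deal round-robin
    ## across strata so every subject and class joins each set as evenly as
    ## the counts allow while the totals stay exact
    ord <- with_seed(seed, {
      strata <- split(seq_len(n),
                      interaction(manifest$subject, manifest$label,
                                  drop = TRUE))
      strata <- lapply(strata, function(s) s[sample.int(length(s))])
      strata <- strata[sample.int(length(strata))]
      maxlen <- max(lengths(strata))
      unlist(lapply(seq_len(maxlen), function(i) {
        unlist(lapply(strata, function(s) if (i <= length(s)) s[i]),
               use.names = FALSE)
      }), use.names = FALSE)
    })
    val <- ord[seq_len(n_val)]
    test <- ord[n_val + seq_len(n_test)]
    train <- setdiff(seq_len(n), c(val, test))
  } else {
    subjects <- sort(unique(manifest$subject))
    ns <- length(subjects)
    shuf <- with_seed(seed, sample(subjects))
    if (is.null(test_subjects))
      test_subjects <- shuf[seq_len(max(1, round(0.2 * ns)))]
    if (is.null(val_subjects))
      val_subjects <- setdiff(shuf, test_subjects)[
        seq_len(max(1, round(0.2 * ns)))]
    test <- which(manifest$subject %in% test_subjects)
    val <- which(manifest$subject %in% val_subjects)
    train <- setdiff(seq_len(n), c(test, val))
  }
  list(train = sort(train), val = sort(val), test = sort(test))
}
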
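#' Confusion matrix from counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts (positive class =
#'   smile event, defined by the reference labels).
#' @return An object of class `confusion_matrix`: a list with `tp`, `fp`,
#'   `fn`, `tn` and `n = tp + fp + fn + tn`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) < 1) stop("confusion matrix is empty", call. = FALSE)
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
         tn = as.integer(tn), n = as.integer(sum(counts))),
    class = "confusion_matrix"
  )
}

#' Confusion matrix by cross-tabulating predictions against reference labels
#'
#' @param predictions A tibble `segment_id`, `label` of machine labels.
#' @param truth A tibble `segment_id`, `label` of reference labels
#'   (the human consensus); its positive class defines `tp`.
#' @return A [confusion_matrix()].
#' @export
confusion_counts <- function(predictions, truth) {
  predictions <- validate_labels(predictions)
  truth <- validate_labels(truth)
  only_pred <- setdiff(predictions$segment_id, truth$segment_id)
  only_truth <- setdiff(truth$segment_id, predictions$segment_id)
  if (length(only_pred) > 0 || length(only_truth) > 0) {
    stop("segment ids differ between predictions and truth; ",
         "only in predictions: {",
         paste(utils::head(only_pred, 5), collapse = ", "),
         "}; only in truth: {",
         paste(utils::head(only_truth, 5), collapse = ", "), "}",
         call. = FALSE)
  }
  d <- dplyr::inner_join(predictions, truth, by = "segment_id",
                         suffix = c("_pred", "_true"))
  confusion_matrix(
    tp = sum(d$label_pred == 1L & d$label_true == 1L),
    fp = sum(d$label_pred == 1L & d$label_true == 0L),
    fn = sum(d$label_pred == 0L & d$label_true == 1L),
    tn = sum(d$label_pred == 0L & d$label_true == 0L)
  )
}

#' Sensitivity and specificity
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`.
#'
#' @param cm A [confusion_matrix()].
#' @return Named numeric vector `sensitivity`, `specificity`.
#' @export
sens_spec <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0) {
    stop("sensitivity undefined: no positive reference segments", call. = FALSE)
  }
  if (cm$tn + cm$fp == 0) {
    stop("specificity undefined: no negative reference segments", call. = FALSE)
  }
  c(sensitivity = cm$tp / (cm$tp + cm$fn),
    specificity = cm$tn / (cm$tn + cm$fp))
}

#' Cohen's kappa for a 2x2 confusion matrix
#'
#' Chance-corrected agreement between the machine classification and the
#' reference labels. With observed agreement `p_o = (TP + TN) / n` and
#' chance agreement
#' `p_e = ((TP+FP)(TP+FN) + (FN+TN)(FP+TN)) / n^2`,
#' `kappa = (p_o - p_e) / (1 - p_e)`. The 95% confidence interval is the
#' Wald interval `kappa +/- 1.96 SE` with
#' `SE = sqrt(p_o (1 - p_o) / (n (1 - p_e)^2))`, deliberately not
#' truncated at 1. The p-value is a one-sided z-test of kappa = 0 against
#' kappa > 0 with null standard error `sqrt(p_e / (n (1 - p_e)))`.
#'
#' @param cm A [confusion_matrix()].
#' @return An object of class `agreement` (see [fleiss_kappa()]).
#' @export
cohen_kappa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$n
  if (n < 2) stop("Cohen's kappa needs at least 2 items", call. = FALSE)
  p_o <- (cm$tp + cm$tn) / n
  p_e <- ((cm$tp + cm$fp) * (cm$tp + cm$fn) +
            (cm$fn + cm$tn) * (cm$fp + cm$tn)) / n^2
  if (p_e >= 1) {
    stop("Cohen's kappa undefined: both classifications are constant",
         call. = FALSE)
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
  se0 <- sqrt(p_e / (n * (1 - p_e)))
  z <- kappa / se0
  structure(
    list(
      method = "Cohen's kappa",
      kappa = kappa, se = se,
      ci = kappa + c(-1, 1) * qnorm(0.975) * se,
      p_value = pnorm(z, lower.tail = FALSE), z = z,
      n_items = n, n_raters = 2L, p_bar = p_o, p_e = p_e
    ),
    class = "agreement"
  )
}

#' Evaluate a fitted classifier on the held-out test half
#'
#' Applies the classifier to the test segments only and reports the
#' confusion matrix against the human consensus, sensitivity, specificity
#' and Cohen's kappa with confidence interval and p-value. Refuses to run
#' if the split's training and test ids overlap (label leakage).
#'
#' @param frames A frames tibble (see [read_segments()]).
#' @param classifier A fitted [bilateral_classifier()].
#' @param labels Consensus labels for all segments.
#' @param split A [stratified_split()] result; evaluation uses
#'   `split$test`.
#' @return An object of class `eval_report`: a list with `classifier`,
#'   `confusion`, `sensitivity`, `specificity`, `kappa` (an `agreement`)
#'   and `n_test`.
#' @export
evaluate_classifier <- function(frames, classifier, labels, split) {
  stopifnot(inherits(classifier, "bilateral_classifier"),
            inherits(split, "split_result"))
  labels <- validate_labels(labels)
  leak <- intersect(split$train, split$test)
  if (length(leak) > 0) {
    stop("train/test leakage: ", paste(utils::head(leak, 5), collapse = ", "),
         call. = FALSE)
  }
  features <- aggregate_segments(frames,
                                 c(classifier$left, classifier$right))
  features <- features[features$segment_id %in% split$test, ]
  truth <- labels[labels$segment_id %in% split$test, ]
  predictions <- stats::predict(classifier, features)
  cm <- confusion_counts(predictions, truth)
  ss <- sens_spec(cm)
  structure(
    list(
      classifier = classifier,
      confusion = cm,
      sensitivity = unname(ss["sensitivity"]),
      specificity = unname(ss["specificity"]),
      kappa = cohen_kappa(cm),
      n_test = cm$n
    ),
    class = "eval_report"
  )
}

#' Write an evaluation report to JSON
#'
#' The report carries all intermediate quantities (confusion counts,
#' observed and chance agreement, standard error) for auditability.
#'
#' @param report An [evaluate_classifier()] report.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  k <- report$kappa
  out <- list(
    classifier = unclass(report$classifier),
    confusion = unclass(report$confusion),
    sensitivity = report$sensitivity,
    specificity = report$specificity,
    cohen_kappa = list(
      estimate = k$kappa, se = k$se,
      ci_lower = k$ci[1], ci_upper = k$ci[2],
      p_value = k$p_value, z = k$z,
      observed_agreement = k$p_bar, chance_agreement = k$p_e
    ),
    n_test = report$n_test
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (reference in columns):\n")
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("pred smile", "pred non-smile"),
                              c("smile", "non-smile")))
  print(m)
  invisible(x)
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$classifier)
  print(x$confusion)
  cat(sprintf("sensitivity %.4f, specificity %.4f (n = %d test segments)\n",
              x$sensitivity, x$specificity, x$n_test))
  print(x$kappa)
  invisible(x)
}
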
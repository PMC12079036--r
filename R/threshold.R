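#' Participant- and class-stratified 50/50 split
#'
#' Allocates half of the smile and half of the non-smile segments of every
#' participant to the training set and half to the test set, so that both
#' participants and classes are distributed as evenly as possible across
#' the halves. Within each (participant, class) stratum the segments are
#' shuffled by the seeded generator and paired off alternately; the single
#' leftover segment of each odd-sized stratum is pooled, the pool is
#' shuffled, and its members alternate between the halves. Per stratum the
#' imbalance is therefore at most one segment, and for an even total the
#' two halves have exactly equal size.
#'
#' @param labels A tibble `segment_id`, `label`.
#' @param participants A tibble `segment_id`, `participant_id`
#'   (e.g. from [segment_participants()]).
#' @param seed Integer seed; the split is deterministic per seed.
#' @return An object of class `split_result`: a list with character vectors
#'   `train` and `test` of segment ids (disjoint, union = all ids).
#' @export
stratified_split <- function(labels, participants, seed = 1L) {
  labels <- validate_labels(labels)
  participants <- tibble::as_tibble(participants)
  stopifnot(all(c("segment_id", "participant_id") %in% names(participants)))
  d <- dplyr::inner_join(labels, participants, by = "segment_id")
  if (nrow(d) < nrow(labels)) {
    stop("every labelled segment needs a participant", call. = FALSE)
  }
  d <- dplyr::arrange(d, .data$participant_id, .data$label, .data$segment_id)
  strata <- split(d$segment_id, paste(d$participant_id, d$label))
  withr::with_seed(as.integer(seed), {
    train <- character(0)
    test <- character(0)
    leftover <- character(0)
    for (ids in strata) {
      ids <- sample(ids)
      k <- length(ids) %/% 2
      if (k > 0) {
        train <- c(train, ids[seq_len(k)])
        test <- c(test, ids[k + seq_len(k)])
      }
      if (length(ids) %% 2 == 1) leftover <- c(leftover, ids[length(ids)])
    }
    if (length(leftover) > 0) {
      leftover <- sample(leftover)
      odd <- seq_along(leftover) %% 2 == 1
      train <- c(train, leftover[odd])
      test <- c(test, leftover[!odd])
    }
  })
  structure(list(train = sort(train), test = sort(test)),
            class = "split_result")
}

#' ROC curve on the fixed threshold grid
#'
#' Sweeps thresholds from 0 to 1 in steps of 0.001 (1001 grid points).
#' At each threshold `t`, `TPR` is the share of positives whose score
#' strictly exceeds `t` and `FPR` the same share among negatives, matching
#' the classifier's strict-exceed rule; `J = TPR - FPR` is Youden's index.
#' The AUC is computed by trapezoidal integration over the unique
#' (FPR, TPR) points sorted by FPR then TPR, anchored at (0, 0) and (1, 1).
#'
#' @param scores A tibble `segment_id`, `score` (see [score_segments()]) or
#'   a numeric vector of scores named by segment id.
#' @param truth A tibble `segment_id`, `label`; both classes must occur.
#' @return A tibble of class `roc_curve` with columns `threshold`, `tpr`,
#'   `fpr`, `j` and the scalar AUC as attribute `"auc"`
#'   (see [roc_auc()]).
#' @export
roc_curve <- function(scores, truth) {
  truth <- validate_labels(truth)
  if (is.numeric(scores)) {
    scores <- tibble::tibble(segment_id = names(scores), score = unname(scores))
  }
  stopifnot(all(c("segment_id", "score") %in% names(scores)))
  d <- dplyr::inner_join(scores, truth, by = "segment_id")
  if (nrow(d) != nrow(truth) || nrow(d) != nrow(scores)) {
    stop("scores and truth must cover the same segments", call. = FALSE)
  }
  pos <- d$score[d$label == 1L]
  neg <- d$score[d$label == 0L]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("ROC undefined: truth contains a single class", call. = FALSE)
  }
  grid <- (0:1000) / 1000
  tpr <- vapply(grid, function(t) mean(pos > t), numeric(1))
  fpr <- vapply(grid, function(t) mean(neg > t), numeric(1))
  curve <- tibble::tibble(threshold = grid, tpr = tpr, fpr = fpr,
                          j = tpr - fpr)
  attr(curve, "auc") <- trapezoid_auc(fpr, tpr)
  class(curve) <- c("roc_curve", class(curve))
  curve
}

trapezoid_auc <- function(fpr, tpr) {
  pts <- unique(rbind(c(0, 0), cbind(fpr, tpr), c(1, 1)))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  x <- pts[, 1]
  y <- pts[, 2]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' AUC of a ROC curve
#'
#' @param curve A [roc_curve()].
#' @return The trapezoidal area under the curve, in \[0, 1\].
#' @export
roc_auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  attr(curve, "auc")
}

#' Youden-optimal threshold
#'
#' Returns the grid threshold maximizing Youden's `J = TPR - FPR`. Ties are
#' broken towards the smallest such threshold, which maximizes sensitivity
#' among the equally optimal operating points.
#'
#' @param curve A [roc_curve()].
#' @return A single threshold from the grid.
#' @export
youden_threshold <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  curve$threshold[which.max(curve$j)]
}

#' Fit a bilateral classifier by fixed-grid ROC analysis
#'
#' Scores each segment as the maximum of the left/right features, builds
#' the ROC over the 0.001-step threshold grid against the reference labels,
#' and sets the classifier threshold at the Youden optimum.
#'
#' @param features A features tibble from [aggregate_segments()].
#' @param labels Reference labels (tibble `segment_id`, `label`) for the
#'   same segments, typically the training half of the rater consensus.
#' @param left,right The blendshape pair (default the AU12 mouthSmile pair).
#' @return A list with elements `classifier` (the fitted
#'   [bilateral_classifier()]) and `roc` (the training [roc_curve()]).
#' @export
fit_threshold <- function(features, labels,
                          left = "mouthSmile_L", right = "mouthSmile_R") {
  clf <- bilateral_classifier(left, right, threshold = 0)
  scores <- score_segments(features, clf)
  roc <- roc_curve(scores, labels)
  clf$threshold <- youden_threshold(roc)
  list(classifier = clf, roc = roc)
}

#' Write a ROC curve to CSV
#'
#' Columns `threshold`, `tpr`, `fpr`, `j`, one row per grid point.
#'
#' @param curve A [roc_curve()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(curve, path) {
  stopifnot(inherits(curve, "roc_curve"))
  readr::write_csv(tibble::as_tibble(curve), path, progress = FALSE)
  invisible(path)
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("stratified split: %d training / %d test segments\n",
              length(x$train), length(x$test)))
  invisible(x)
}
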
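#' Bilateral OR-threshold classifier
#'
#' The classifier for a facial action unit links the left and right
#' blendshapes of the face by a logical OR: a segment is positive if either
#' side strictly exceeds the shared threshold. This makes the decision
#' robust to head rotation, where one side of the face may be partly
#' hidden. Because the per-segment feature is the maximum over frames,
#' `(left > t) OR (right > t)` is equivalent to `max(left, right) > t`,
#' which is the scalar score used for ROC analysis.
#'
#' @param left,right Names of the paired blendshape columns
#'   (e.g. `"mouthSmile_L"` and `"mouthSmile_R"`); must differ.
#' @param threshold Decision threshold in \[0, 1\]. Comparison is strict:
#'   a score exactly equal to the threshold classifies negative.
#' @return An object of class `bilateral_classifier`.
#' @export
bilateral_classifier <- function(left, right, threshold) {
  stopifnot(is.character(left), is.character(right), length(left) == 1,
            length(right) == 1)
  if (left == right) stop("left and right blendshapes must differ", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must be a single number in [0, 1]", call. = FALSE)
  }
  structure(
    list(left = left, right = right, threshold = threshold),
    class = "bilateral_classifier"
  )
}

#' Score segments under a bilateral classifier
#'
#' @param features A features tibble from [aggregate_segments()] containing
#'   the classifier's left and right blendshape columns.
#' @param classifier A [bilateral_classifier()].
#' @return A tibble `segment_id`, `score` with
#'   `score = max(left, right)` per segment.
#' @export
score_segments <- function(features, classifier) {
  stopifnot(inherits(classifier, "bilateral_classifier"))
  needed <- c(classifier$left, classifier$right)
  missing <- setdiff(needed, names(features))
  if (length(missing) > 0) {
    stop("features are missing blendshape(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    segment_id = features$segment_id,
    score = pmax(features[[classifier$left]], features[[classifier$right]])
  )
}

#' Predict smile/non-smile labels
#'
#' @param object A [bilateral_classifier()].
#' @param features A features tibble from [aggregate_segments()].
#' @param ... Unused.
#' @return A tibble `segment_id`, `label` with `label = 1` where the score
#'   strictly exceeds the threshold.
#' @export
predict.bilateral_classifier <- function(object, features, ...) {
  scores <- score_segments(features, object)
  tibble::tibble(
    segment_id = scores$segment_id,
    label = as.integer(scores$score > object$threshold)
  )
}

#' Write a classifier to JSON
#'
#' Serialized as `{"left": ..., "right": ..., "threshold": ...}` for
#' hand-off between pipeline stages.
#'
#' @param classifier A [bilateral_classifier()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(classifier, path) {
  stopifnot(inherits(classifier, "bilateral_classifier"))
  jsonlite::write_json(unclass(classifier), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a classifier from JSON
#'
#' @param path Path to a classifier JSON file.
#' @return A [bilateral_classifier()].
#' @export
read_classifier <- function(path) {
  if (!file.exists(path)) {
    stop("classifier file not found: ", path, call. = FALSE)
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bilateral_classifier(x$left, x$right, x$threshold)
}

#' @export
print.bilateral_classifier <- function(x, ...) {
  cat(sprintf("bilateral OR classifier: %s | %s > %.3f\n",
              x$left, x$right, x$threshold))
  invisible(x)
}
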
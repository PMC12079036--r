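#' Read per-frame blendshape segments from CSV
#'
#' The frames CSV is the package's on-disk format for blendshape recordings:
#' one row per frame, with columns `segment_id`, `participant_id`,
#' `frame_index` (0-based) and one numeric column per blendshape
#' (e.g. `mouthSmile_L`, `mouthSmile_R`, `cheekSquint_L`, `cheekSquint_R`;
#' further blendshape columns are carried through untouched). Frame time in
#' seconds is `frame_index / fps` and is never stored.
#'
#' @param path Path to a frames CSV file.
#' @param fps Frames per second of the recording (positive; default 10).
#' @return A tibble of frames sorted by `segment_id` then `frame_index`,
#'   with the sampling rate attached as attribute `"fps"`.
#' @seealso [write_segments()], [aggregate_segments()]
#' @export
read_segments <- function(path, fps = 10) {
  if (!file.exists(path)) {
    stop("frames file not found: ", path, call. = FALSE)
  }
  frames <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  frames <- validate_frames(frames)
  frames <- dplyr::arrange(frames, .data$segment_id, .data$frame_index)
  attr(frames, "fps") <- check_fps(fps)
  frames
}

#' Write blendshape segments to CSV
#'
#' Inverse of [read_segments()]: a file written here reads back with
#' identical values, and re-writing what was read reproduces the file
#' byte for byte.
#'
#' @param frames A validated frames tibble (see [read_segments()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(frames, path) {
  frames <- validate_frames(frames)
  readr::write_csv(frames, path, progress = FALSE)
  invisible(path)
}

#' Validate a frames table
#'
#' Checks the structural contract of per-frame blendshape data: required
#' identifier columns, at least one blendshape column, all blendshape values
#' inside \[0, 1\], and no duplicated (segment, frame) pair.
#'
#' @param frames A data frame of per-frame blendshape values.
#' @return The frames as a tibble (invisible coercion only; no reordering).
#' @export
validate_frames <- function(frames) {
  frames <- tibble::as_tibble(frames)
  required <- c("segment_id", "participant_id", "frame_index")
  missing <- setdiff(required, names(frames))
  if (length(missing) > 0) {
    stop("frames data is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  shapes <- blendshape_names(frames)
  if (length(shapes) == 0) {
    stop("frames data has no blendshape columns", call. = FALSE)
  }
  frames$segment_id <- as.character(frames$segment_id)
  frames$participant_id <- as.character(frames$participant_id)
  key <- paste(frames$segment_id, frames$frame_index)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (segment_id, frame_index): ", dup, call. = FALSE)
  }
  for (nm in shapes) {
    v <- frames[[nm]]
    if (!is.numeric(v)) {
      stop("blendshape column '", nm, "' is not numeric", call. = FALSE)
    }
    bad <- which(is.na(v) | v < 0 | v > 1)
    if (length(bad) > 0) {
      i <- bad[1]
      stop(sprintf(
        "blendshape value out of [0, 1]: %s = %s in segment '%s', frame %s",
        nm, format(v[i]), frames$segment_id[i], frames$frame_index[i]),
        call. = FALSE)
    }
  }
  frames
}

#' Blendshape column names of a frames table
#'
#' @param frames A frames tibble.
#' @return Character vector of blendshape column names.
#' @export
blendshape_names <- function(frames) {
  setdiff(names(frames), c("segment_id", "participant_id", "frame_index"))
}

#' Aggregate each segment's frame series to one feature per blendshape
#'
#' A smile event is present in a segment if the expression appears at any
#' moment, so the per-segment feature is the maximum of the frame series:
#' thresholding the aggregate is then exactly equivalent to asking whether
#' any frame exceeded the threshold.
#'
#' @param frames A frames tibble (see [read_segments()]).
#' @param blendshapes Character vector of blendshape names to aggregate;
#'   default all blendshape columns present.
#' @return A tibble with one row per segment: `segment_id` plus one column
#'   per requested blendshape holding the per-segment maximum.
#' @export
aggregate_segments <- function(frames, blendshapes = NULL) {
  frames <- validate_frames(frames)
  available <- blendshape_names(frames)
  if (is.null(blendshapes)) blendshapes <- available
  unknown <- setdiff(blendshapes, available)
  if (length(unknown) > 0) {
    stop("unknown blendshape name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  frames |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(blendshapes), max),
      .groups = "drop"
    )
}

#' Participant of each segment
#'
#' @param frames A frames tibble.
#' @return A tibble `segment_id`, `participant_id`, one row per segment.
#' @export
segment_participants <- function(frames) {
  frames <- validate_frames(frames)
  dplyr::distinct(frames, .data$segment_id, .data$participant_id)
}

#' Read segment labels from CSV
#'
#' Labels CSV format: columns `segment_id`, `label` with binary labels
#' (0 = non-smile event, 1 = smile event).
#'
#' @param path Path to a labels CSV file.
#' @return A tibble `segment_id`, `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("labels file not found: ", path, call. = FALSE)
  labels <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_labels(labels)
}

#' Write segment labels to CSV
#'
#' @param labels A tibble `segment_id`, `label`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  labels <- validate_labels(labels)
  readr::write_csv(labels, path, progress = FALSE)
  invisible(path)
}

validate_labels <- function(labels) {
  labels <- tibble::as_tibble(labels)
  missing <- setdiff(c("segment_id", "label"), names(labels))
  if (length(missing) > 0) {
    stop("labels data is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(labels) == 0) stop("label set is empty", call. = FALSE)
  labels$segment_id <- as.character(labels$segment_id)
  if (anyDuplicated(labels$segment_id)) {
    stop("duplicate segment_id in labels", call. = FALSE)
  }
  if (!all(labels$label %in% c(0L, 1L))) {
    stop("labels must be 0 (non-smile) or 1 (smile)", call. = FALSE)
  }
  labels$label <- as.integer(labels$label)
  labels[, c("segment_id", "label")]
}

check_fps <- function(fps) {
  if (!is.numeric(fps) || length(fps) != 1 || !is.finite(fps) || fps <= 0) {
    stop("fps must be a single positive number", call. = FALSE)
  }
  fps
}
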
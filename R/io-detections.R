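#' Read and write the detections interchange format
#'
#' Detections travel between tools as a plain CSV with a header row and one
#' row per detection: `video_id, frame_index, x_min, y_min, x_max, y_max,
#' score` plus optional `track_id` (integer, filled by the tracker) and
#' `coasted` (logical, TRUE for boxes emitted from a track's prediction
#' rather than a detector). Readers that do not know the optional columns
#' can ignore them. A write/read round trip preserves integers exactly and
#' floating point fields to full precision.
#'
#' @param path File path of the CSV.
#' @return `read_detections` returns a tibble of detections sorted by
#'   `video_id` then `frame_index`; `write_detections` returns `path`
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' d <- tibble::tibble(video_id = "v", frame_index = 0L,
#'                     x_min = 0, y_min = 0, x_max = 10, y_max = 10,
#'                     score = 0.5)
#' write_detections(d, f)
#' read_detections(f)
#' @export
read_detections <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      video_id = readr::col_character(),
      frame_index = readr::col_integer(),
      x_min = readr::col_double(), y_min = readr::col_double(),
      x_max = readr::col_double(), y_max = readr::col_double(),
      score = readr::col_double(),
      track_id = readr::col_integer(),
      coasted = readr::col_logical(),
      .default = readr::col_guess()),
    progress = FALSE)
  need <- c("video_id", "frame_index", "x_min", "y_min", "x_max", "y_max",
            "score")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing detection column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  if (!"track_id" %in% names(out)) out$track_id <- NA_integer_
  if (!"coasted" %in% names(out)) out$coasted <- FALSE
  validate_detections(out, where = path)
  dplyr::arrange(out, .data$video_id, .data$frame_index)
}

#' @param detections A detections tibble (schema above).
#' @rdname read_detections
#' @export
write_detections <- function(detections, path) {
  detections <- as_tibble(detections)
  if (!"track_id" %in% names(detections)) {
    detections$track_id <- NA_integer_
  }
  if (!"coasted" %in% names(detections)) detections$coasted <- FALSE
  validate_detections(detections, where = path)
  cols <- c("video_id", "frame_index", "x_min", "y_min", "x_max", "y_max",
            "score", "track_id", "coasted")
  out <- detections[cols]
  # 6-decimal fidelity for floats keeps the format diffable and makes
  # write -> read -> write byte-stable
  for (col in c("x_min", "y_min", "x_max", "y_max", "score")) {
    out[[col]] <- round(out[[col]], 6)
  }
  out <- dplyr::arrange(out, .data$video_id, .data$frame_index)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

validate_detections <- function(dets, where = "detections") {
  validate_boxes(dets, where = where)
  bad <- which(!is.finite(dets$score) | dets$score < 0 | dets$score > 1)
  if (length(bad)) {
    abort(sprintf("%s: score outside [0, 1] on row(s) %s", where,
                  paste(head(bad, 5L), collapse = ", ")))
  }
  invisible(dets)
}

empty_detections <- function() {
  tibble(video_id = character(), frame_index = integer(),
         x_min = numeric(), y_min = numeric(),
         x_max = numeric(), y_max = numeric(),
         score = numeric(), track_id = integer(), coasted = logical())
}
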
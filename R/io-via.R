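#' Read a VIA 2.x annotation project as a ground-truth table
#'
#' Parses a VGG Image Annotator (VIA) 2.x project JSON and returns one row
#' per annotated instance. Polygon regions (`shape_attributes$name ==
#' "polygon"`) yield both the polygon and its tight axis-aligned bounding
#' box; rectangle regions (`"rect"`, stored as x/y/width/height) yield a
#' box only. Coordinates are converted to the package's 0-based half-open
#' convention: a VIA rect `(x, y, w, h)` becomes `(x, y, x + w, y + h)`.
#'
#' Region attributes recognised:
#' * `ignore` — values `"1"` or `"true"` (case-insensitive) mark the
#'   instance as non-focal (e.g. an animal in a neighbouring cage); ignored
#'   instances are excluded from both credit and penalty during scoring.
#' * `id` — the individual's identity label; defaults to a sequential
#'   `"instance_<k>"` per region when absent.
#'
#' The frame index of each image is taken from a `frame_index` file
#' attribute when present, otherwise parsed from the last run of digits in
#' the filename, otherwise assigned sequentially in project order.
#'
#' @param path Path to a VIA 2.x project JSON file.
#' @param video_id Video label attached to every row; defaults to the VIA
#'   project name when the file carries one, otherwise the project
#'   filename without extension.
#' @return A tibble with columns `video_id`, `frame_index`, `instance_id`,
#'   `x_min`, `y_min`, `x_max`, `y_max`, `ignore`, and a `polygon`
#'   list-column (NULL for rect regions; otherwise a two-column matrix of
#'   vertices).
#' @export
read_via_project <- function(path, video_id = NULL) {
  proj <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(sprintf("%s: malformed VIA JSON: %s",
                                      path, conditionMessage(e)))
  )
  if (is.null(video_id)) {
    video_id <- proj[["_via_settings"]]$project$name %||%
      sub("\\.[^.]*$", "", basename(path))
  }
  meta <- proj[["_via_img_metadata"]]
  if (is.null(meta)) meta <- proj  # flat export: keys are image entries
  meta <- meta[vapply(meta, function(x) is.list(x) && !is.null(x$filename),
                      logical(1))]
  if (!length(meta)) {
    return(empty_ground_truth())
  }

  rows <- vector("list", length(meta))
  for (i in seq_along(meta)) {
    entry <- meta[[i]]
    fidx <- entry$file_attributes$frame_index
    if (is.null(fidx)) fidx <- parse_trailing_index(entry$filename)
    if (is.null(fidx)) fidx <- i - 1L
    fidx <- as.integer(fidx)

    regions <- entry$regions %||% list()
    if (!length(regions)) next
    reg_rows <- vector("list", length(regions))
    for (j in seq_along(regions)) {
      reg <- regions[[j]]
      sh <- reg$shape_attributes
      if (is.null(sh$name)) {
        abort(sprintf("%s: image %d region %d: missing shape_attributes$name",
                      path, i, j))
      }
      poly <- NULL
      if (identical(sh$name, "polygon")) {
        xs <- as.numeric(unlist(sh$all_points_x))
        ys <- as.numeric(unlist(sh$all_points_y))
        if (length(xs) < 3L || length(xs) != length(ys)) {
          abort(sprintf(
            "%s: image %d region %d: polygon needs >= 3 vertices (found %d)",
            path, i, j, length(xs)))
        }
        poly <- cbind(x = xs, y = ys)
        box <- list(x_min = min(xs), y_min = min(ys),
                    x_max = max(xs), y_max = max(ys))
      } else if (identical(sh$name, "rect")) {
        box <- list(x_min = as.numeric(sh$x), y_min = as.numeric(sh$y),
                    x_max = as.numeric(sh$x) + as.numeric(sh$width),
                    y_max = as.numeric(sh$y) + as.numeric(sh$height))
      } else {
        abort(sprintf("%s: image %d region %d: unsupported shape '%s'",
                      path, i, j, sh$name))
      }
      attrs <- reg$region_attributes %||% list()
      ignore_val <- tolower(as.character(attrs$ignore %||% ""))
      inst <- as.character(attrs$id %||% sprintf("instance_%d", j))
      reg_rows[[j]] <- tibble(
        video_id = video_id, frame_index = fidx, instance_id = inst,
        x_min = box$x_min, y_min = box$y_min,
        x_max = box$x_max, y_max = box$y_max,
        ignore = ignore_val %in% c("1", "true"),
        polygon = list(poly))
    }
    rows[[i]] <- dplyr::bind_rows(reg_rows)
  }
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) return(empty_ground_truth())
  validate_boxes(out, where = path)
  dplyr::arrange(out, .data$frame_index)
}

empty_ground_truth <- function() {
  tibble(video_id = character(), frame_index = integer(),
         instance_id = character(),
         x_min = numeric(), y_min = numeric(),
         x_max = numeric(), y_max = numeric(),
         ignore = logical(), polygon = list())
}

parse_trailing_index <- function(filename) {
  stem <- sub("\\.[^.]*$", "", filename)
  m <- regmatches(stem, regexpr("[0-9]+$", stem))
  if (!length(m)) return(NULL)
  as.integer(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
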
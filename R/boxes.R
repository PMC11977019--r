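#' Validate bounding-box columns
#'
#' Boxes are axis-aligned, 0-based, half-open: a box covers
#' `[x_min, x_max) x [y_min, y_max)` in pixel coordinates, so its area is
#' `(x_max - x_min) * (y_max - y_min)` and must be positive.
#'
#' @param data A data frame with columns `x_min`, `y_min`, `x_max`, `y_max`.
#' @param where Label used in error messages (e.g. a file name).
#' @return `data`, invisibly, if every box is valid; otherwise an error
#'   naming the offending rows.
#' @export
validate_boxes <- function(data, where = "boxes") {
  need <- c("x_min", "y_min", "x_max", "y_max")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(sprintf("%s: missing column(s) %s", where,
                  paste(missing_cols, collapse = ", ")))
  }
  bad <- which(!(data$x_min < data$x_max & data$y_min < data$y_max) |
                 !is.finite(data$x_min) | !is.finite(data$y_min) |
                 !is.finite(data$x_max) | !is.finite(data$y_max))
  if (length(bad)) {
    abort(sprintf("%s: inverted or non-finite box on row(s) %s",
                  where, paste(head(bad, 5L), collapse = ", ")))
  }
  invisible(data)
}

#' Intersection over union of bounding boxes
#'
#' The overlap area of the two boxes divided by the area of their union;
#' 0 for disjoint boxes, 1 for identical boxes. Vectorised over rows:
#' `a` and `b` are recycled to a common length.
#'
#' @param a,b Data frames (or single-row lists) with `x_min`, `y_min`,
#'   `x_max`, `y_max` columns in the half-open pixel convention.
#' @return Numeric vector of IoU values in `[0, 1]`.
#' @examples
#' b1 <- tibble::tibble(x_min = 0, y_min = 0, x_max = 10, y_max = 10)
#' b2 <- tibble::tibble(x_min = 5, y_min = 0, x_max = 15, y_max = 10)
#' box_iou(b1, b2)  # 50 / 150
#' @export
box_iou <- function(a, b) {
  ix <- pmax(0, pmin(a$x_max, b$x_max) - pmax(a$x_min, b$x_min))
  iy <- pmax(0, pmin(a$y_max, b$y_max) - pmax(a$y_min, b$y_min))
  inter <- ix * iy
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  inter / (area_a + area_b - inter)
}

# IoU of one box (length-1 lists) against every row of a box table.
iou_one_vs_many <- function(box, table) {
  if (!nrow(table)) return(numeric(0))
  box_iou(list(x_min = rep(box$x_min, nrow(table)),
               y_min = rep(box$y_min, nrow(table)),
               x_max = rep(box$x_max, nrow(table)),
               y_max = rep(box$y_max, nrow(table))),
          table)
}

# Tight 0-based half-open bounds of a logical mask (matrix [y, x]).
# Returns NULL for an empty mask.
mask_bounds <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  list(x_min = min(idx[, 2L]) - 1, y_min = min(idx[, 1L]) - 1,
       x_max = max(idx[, 2L]), y_max = max(idx[, 1L]))
}
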
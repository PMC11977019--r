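#' In-memory video: a stack of RGB frames
#'
#' A `cw_video` holds decoded frames as numeric arrays `[height, width, 3]`
#' with intensities 0..255, together with the original index of each frame
#' (so a stride-sampled video remembers where its frames came from), the
#' frame rate and a video label.
#'
#' @param frames List of `H x W x 3` numeric arrays, all the same size.
#' @param fps Frames per second of the source recording.
#' @param video_id Text label used in detection/ground-truth tables.
#' @param indices Integer vector of original 0-based frame indices;
#'   defaults to `0:(n-1)`.
#' @return A `cw_video` object.
#' @export
new_video <- function(frames, fps = 15, video_id = "video",
                      indices = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all frames of a video must share the same height and width")
  }
  if (is.null(indices)) indices <- seq_along(frames) - 1L
  structure(
    list(frames = frames, indices = as.integer(indices),
         height = dims[1, 1], width = dims[2, 1],
         fps = fps, video_id = video_id),
    class = "cw_video")
}

#' @export
print.cw_video <- function(x, ...) {
  cat(sprintf("<cw_video '%s': %d frames, %dx%d px, %g fps>\n",
              x$video_id, length(x$frames), x$width, x$height, x$fps))
  invisible(x)
}

#' @export
length.cw_video <- function(x) length(x$frames)

#' Read video frames with stride subsampling
#'
#' Reads a frame-directory video (a directory of `frame_<index>.png` files
#' plus an optional `meta.yaml` with `fps` and `video_id`) or subsamples an
#' in-memory `cw_video`. Every `stride`-th frame is kept, starting at the
#' first, and each kept frame retains its original index: a 30-frame video
#' at stride 10 yields frames with indices 0, 10, 20.
#'
#' @param path Directory path, or a `cw_video`.
#' @param stride Keep every `stride`-th frame (default 1 = all frames).
#' @return A `cw_video` whose `indices` field records original positions.
#' @export
read_video_frames <- function(path, stride = 1L) {
  if (!is.numeric(stride) || length(stride) != 1L || stride < 1) {
    abort("stride must be a single integer >= 1")
  }
  stride <- as.integer(stride)
  if (inherits(path, "cw_video")) {
    keep <- seq(1L, length(path$frames), by = stride)
    return(new_video(path$frames[keep], fps = path$fps,
                     video_id = path$video_id,
                     indices = path$indices[keep]))
  }
  if (!dir.exists(path)) {
    abort(sprintf("cannot read video: '%s' is not a directory", path))
  }
  files <- list.files(path, pattern = "^frame_[0-9]+\\.png$",
                      full.names = TRUE)
  if (!length(files)) {
    abort(sprintf("no frame_<index>.png files found under '%s'", path))
  }
  idx <- as.integer(sub("^frame_([0-9]+)\\.png$", "\\1", basename(files)))
  ord <- order(idx)
  files <- files[ord]; idx <- idx[ord]
  keep <- seq(1L, length(files), by = stride)

  fps <- 15; video_id <- basename(path)
  meta_path <- file.path(path, "meta.yaml")
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    fps <- meta$fps %||% fps
    video_id <- meta$video_id %||% video_id
  }
  frames <- lapply(files[keep], read_frame_png)
  new_video(frames, fps = fps, video_id = video_id, indices = idx[keep])
}

#' Write a video as a PNG frame directory
#'
#' @param video A `cw_video`.
#' @param dir Output directory (created if needed); frames are written as
#'   `frame_<original index>.png` plus a `meta.yaml`.
#' @return `dir`, invisibly.
#' @export
write_video <- function(video, dir) {
  stopifnot(inherits(video, "cw_video"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(video$frames)) {
    png::writePNG(video$frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", video$indices[i])))
  }
  yaml::write_yaml(list(fps = video$fps, video_id = video$video_id,
                        width = video$width, height = video$height),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

read_frame_png <- function(file) {
  img <- png::readPNG(file)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  round(img * 255)
}

# Bilinear resize of an [H, W, 3] frame to width x height (EBImage backend;
# EBImage stores images [x, y, c] in 0..1).
resize_frame <- function(frame, width, height) {
  if (dim(frame)[1] == height && dim(frame)[2] == width) return(frame)
  img <- EBImage::Image(aperm(frame, c(2, 1, 3)) / 255, colormode = "Color")
  out <- EBImage::resize(img, w = width, h = height)
  arr <- aperm(EBImage::imageData(out), c(2, 1, 3))
  pmin(pmax(arr * 255, 0), 255)
}

# Gaussian blur with an OpenCV-style kernel-size parameterisation:
# sigma = 0.3 * ((k - 1)/2 - 1) + 0.8 for an odd kernel width k.
blur_frame <- function(frame, kernel = 5L) {
  if (kernel <= 1L) return(frame)
  sigma <- 0.3 * ((kernel - 1) / 2 - 1) + 0.8
  img <- EBImage::Image(aperm(frame, c(2, 1, 3)) / 255, colormode = "Color")
  out <- EBImage::gblur(img, sigma = sigma)
  arr <- aperm(EBImage::imageData(out), c(2, 1, 3))
  pmin(pmax(arr * 255, 0), 255)
}
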
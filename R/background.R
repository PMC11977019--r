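#' Background-model parameters
#'
#' Settings for training-free background synthesis and foreground
#' extraction. The defaults reproduce the reference pipeline: every 10th
#' frame is sampled, frames are resized to 1280x720 and slightly blurred
#' (5x5 Gaussian), sampled frames are grouped into sets of 120, each
#' group's per-pixel per-channel 70th percentile forms a sub-background,
#' and the final background is the per-pixel median of the sub-backgrounds.
#'
#' Foreground extraction compares each frame against a Gaussian model of
#' the synthesized background that is frozen during inference (learning
#' rate 0): a pixel is foreground when its squared RGB distance from the
#' background exceeds `var_threshold * var_init`. Pixels that pass the
#' foreground test but look like a darkened copy of the background
#' (brightness ratio in `[shadow_tau, 1]`, small colour distortion) are
#' treated as shadow and mapped back to background.
#'
#' @param stride Sample every `stride`-th frame when building the
#'   background (default 10).
#' @param group_size Number of sampled frames per percentile group
#'   (default 120; a final partial group is kept).
#' @param percentile Per-pixel percentile in (0, 100] used within each
#'   group (default 70). Computed with the "lower" rule: the largest data
#'   value at or below the requested rank, so 8-bit values never
#'   interpolate.
#' @param blur_kernel Odd Gaussian kernel width applied to each sampled
#'   frame before percentile accumulation (default 5).
#' @param target_size `c(width, height)` every frame is resized to before
#'   any processing (default `c(1280, 720)`).
#' @param var_threshold Squared-distance multiplier of the foreground test
#'   (default 16).
#' @param var_init Frozen per-pixel variance of the background Gaussian
#'   (default 15, intensity-squared units).
#' @param detect_shadows Run the shadow test and map shadows to background
#'   (default TRUE).
#' @param shadow_tau Lower bound of the shadow brightness ratio
#'   (default 0.5).
#' @return A list of class `cw_bg_params`.
#' @export
bg_params <- function(stride = 10L, group_size = 120L, percentile = 70,
                      blur_kernel = 5L, target_size = c(1280L, 720L),
                      var_threshold = 16, var_init = 15,
                      detect_shadows = TRUE, shadow_tau = 0.5) {
  stopifnot(stride >= 1, group_size >= 1,
            percentile > 0, percentile <= 100,
            blur_kernel >= 1, blur_kernel %% 2 == 1,
            length(target_size) == 2, all(target_size >= 1),
            var_threshold > 0, var_init > 0)
  structure(list(stride = as.integer(stride),
                 group_size = as.integer(group_size),
                 percentile = percentile,
                 blur_kernel = as.integer(blur_kernel),
                 target_size = as.integer(target_size),
                 var_threshold = var_threshold, var_init = var_init,
                 detect_shadows = detect_shadows, shadow_tau = shadow_tau),
            class = "cw_bg_params")
}

#' Synthesize a static background image from sampled frames
#'
#' Frames (already stride-sampled) are resized to the target size and
#' slightly blurred, then partitioned into consecutive groups of
#' `group_size` (a final partial group is kept). Within each group the
#' per-pixel per-channel percentile (default 70th, "lower" rule) gives a
#' sub-background; the final background is the per-pixel per-channel
#' median across sub-backgrounds, rounded to 8-bit. Because a moving
#' animal occupies any given pixel in a minority of frames, the percentile
#' recovers the static scene behind it.
#'
#' @param frames A `cw_video` (or list of `H x W x 3` arrays) of the
#'   sampled frames.
#' @param params A [bg_params()] list.
#' @return A `cw_background`: list with the background `image`
#'   (`height x width x 3`, 0..255) and `params`.
#' @export
build_background <- function(frames, params = bg_params()) {
  if (inherits(frames, "cw_video")) frames <- frames$frames
  if (!length(frames)) abort("build_background: no sampled frames")
  w <- params$target_size[1]; h <- params$target_size[2]
  prep <- lapply(frames, function(f) {
    blur_frame(resize_frame(f, w, h), params$blur_kernel)
  })
  n <- length(prep)
  groups <- split(seq_len(n), (seq_len(n) - 1L) %/% params$group_size)
  sub <- lapply(groups, function(idx) {
    mat <- do.call(rbind, lapply(prep[idx], as.numeric))
    k <- lower_rank(length(idx), params$percentile / 100)
    matrixStats::colOrderStats(mat, which = k)
  })
  bg <- if (length(sub) == 1L) sub[[1]] else {
    matrixStats::colMedians(do.call(rbind, sub))
  }
  image <- array(round(bg), dim = c(h, w, 3L))
  structure(list(image = image, params = params), class = "cw_background")
}

# "lower" percentile rank: 1-based index floor((n - 1) * q) + 1 into the
# sorted sample — the largest value at or below the requested rank.
lower_rank <- function(n, q) {
  min(n, floor((n - 1) * q) + 1L)
}

#' @export
print.cw_background <- function(x, ...) {
  cat(sprintf("<cw_background %dx%d px (stride %d, groups of %d, p%g)>\n",
              dim(x$image)[2], dim(x$image)[1], x$params$stride,
              x$params$group_size, x$params$percentile))
  invisible(x)
}

#' Extract a foreground mask by frozen Gaussian background subtraction
#'
#' Classifies each pixel of a frame against the synthesized background
#' using a per-pixel Gaussian whose mean is the background colour and
#' whose variance is frozen at `var_init` (no model update during
#' inference). Foreground where the squared RGB distance exceeds
#' `var_threshold * var_init`; shadow-like pixels (darkened copies of the
#' background) are mapped back to background when shadow detection is on.
#'
#' @param frame An `H x W x 3` array (resized to the model's target size
#'   if needed).
#' @param model A `cw_background` from [build_background()].
#' @return A logical `height x width` matrix, TRUE = foreground.
#' @export
subtract_background <- function(frame, model) {
  p <- model$params
  w <- p$target_size[1]; h <- p$target_size[2]
  frame <- resize_frame(frame, w, h)
  if (!all(dim(frame)[1:2] == dim(model$image)[1:2])) {
    abort("subtract_background: frame/background size mismatch")  # invariant
  }
  d <- frame - model$image
  dist2 <- d[, , 1]^2 + d[, , 2]^2 + d[, , 3]^2
  thr <- p$var_threshold * p$var_init
  fg <- dist2 > thr
  if (p$detect_shadows && any(fg)) {
    bb <- model$image[, , 1]^2 + model$image[, , 2]^2 + model$image[, , 3]^2
    ib <- frame[, , 1] * model$image[, , 1] +
      frame[, , 2] * model$image[, , 2] +
      frame[, , 3] * model$image[, , 3]
    a <- ib / pmax(bb, 1e-6)
    dd <- (frame[, , 1] - a * model$image[, , 1])^2 +
      (frame[, , 2] - a * model$image[, , 2])^2 +
      (frame[, , 3] - a * model$image[, , 3])^2
    shadow <- fg & a >= p$shadow_tau & a <= 1 & dd <= thr
    fg <- fg & !shadow
  }
  fg
}

#' Refine a foreground mask into merged convex-hull clusters
#'
#' Morphological closing then opening removes noise and bridges gaps;
#' connected components (8-connectivity) are labelled; each component's
#' convex hull is filled to a solid region; overlapping hulls are merged
#' (hulls sharing any pixel collapse into one cluster, iterated to a
#' fixpoint); clusters smaller than `min_area` are dropped.
#'
#' @param mask Logical matrix, TRUE = foreground.
#' @param min_area Minimum filled-hull area in pixels (default 2000,
#'   sized for 1280x720 frames — about 0.2% of the frame; scale it with
#'   the working resolution).
#' @param morph_kernel Odd width of the elliptical structuring element
#'   (default 5).
#' @param close_iterations,open_iterations Iterations of closing and
#'   opening (defaults 2 and 1).
#' @return List of clusters sorted by area descending; each cluster is a
#'   list with `hull` (two-column matrix of 0-based vertex coordinates),
#'   `area` (filled pixels), `box` (tight half-open bounds) and `mask`
#'   (logical matrix of the filled region).
#' @export
refine_mask <- function(mask, min_area = 2000, morph_kernel = 5L,
                        close_iterations = 2L, open_iterations = 1L) {
  if (!any(mask)) return(list())
  kern <- EBImage::makeBrush(morph_kernel, shape = "disc")
  img <- EBImage::Image(t(mask) * 1)  # EBImage is [x, y]
  for (i in seq_len(close_iterations)) img <- EBImage::dilate(img, kern)
  for (i in seq_len(close_iterations)) img <- EBImage::erode(img, kern)
  for (i in seq_len(open_iterations)) img <- EBImage::erode(img, kern)
  for (i in seq_len(open_iterations)) img <- EBImage::dilate(img, kern)
  clean <- t(EBImage::imageData(img)) > 0.5
  if (!any(clean)) return(list())

  # Fill each component's convex hull, then re-label: overlapping hulls
  # fuse into one component. Iterate until the cluster count is stable.
  filled <- clean
  repeat {
    lab <- .label_components(filled, 8L)
    n_comp <- max(lab)
    hull_mask <- matrix(FALSE, nrow(filled), ncol(filled))
    hulls <- vector("list", n_comp)
    for (k in seq_len(n_comp)) {
      px <- which(lab == k, arr.ind = TRUE)
      hulls[[k]] <- fill_convex_hull(px, dim(filled))
      hull_mask <- hull_mask | hulls[[k]]$mask
    }
    if (max(.label_components(hull_mask, 8L)) == n_comp) {
      clusters <- lapply(hulls, function(hl) {
        b <- mask_bounds(hl$mask)
        list(hull = hl$hull, area = sum(hl$mask), box = b, mask = hl$mask)
      })
      break
    }
    filled <- hull_mask
  }
  clusters <- Filter(function(cl) cl$area >= min_area, clusters)
  clusters[order(vapply(clusters, function(cl) cl$area, numeric(1)),
                 decreasing = TRUE)]
}

# Convex hull of a pixel set (row/col indices, 1-based) filled to a solid
# logical mask; hull vertices returned as 0-based (x, y) pixel centres.
fill_convex_hull <- function(px, dims) {
  xs <- px[, 2L] - 1; ys <- px[, 1L] - 1
  pts <- unique(cbind(xs, ys))
  if (nrow(pts) <= 2L) {
    m <- matrix(FALSE, dims[1], dims[2])
    m[cbind(pts[, 2] + 1, pts[, 1] + 1)] <- TRUE
    return(list(hull = pts, mask = m))
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[h, , drop = FALSE]
  # normalise to counter-clockwise
  n <- nrow(hull)
  area2 <- sum(hull[, 1] * hull[c(2:n, 1), 2] - hull[c(2:n, 1), 1] * hull[, 2])
  if (area2 < 0) hull <- hull[n:1, , drop = FALSE]

  b <- list(x0 = min(hull[, 1]), x1 = max(hull[, 1]),
            y0 = min(hull[, 2]), y1 = max(hull[, 2]))
  gx <- b$x0:b$x1; gy <- b$y0:b$y1
  inside <- matrix(TRUE, length(gy), length(gx))
  n <- nrow(hull)
  for (i in seq_len(n)) {
    p1 <- hull[i, ]; p2 <- hull[if (i == n) 1L else i + 1L, ]
    ex <- p2[1] - p1[1]; ey <- p2[2] - p1[2]
    # cross((p2-p1), (grid-p1)) >= 0 for CCW interior (tolerance for
    # pixel centres sitting exactly on an edge)
    cr <- outer(gy - p1[2], gx - p1[1],
                function(dy, dx) ex * dy - ey * dx)
    inside <- inside & (cr >= -1e-9)
  }
  m <- matrix(FALSE, dims[1], dims[2])
  m[(b$y0 + 1):(b$y1 + 1), (b$x0 + 1):(b$x1 + 1)] <- inside
  list(hull = hull, mask = m)
}

#' Detect subjects in one frame by background elimination
#'
#' Runs [subtract_background()] and [refine_mask()] and places a tight
#' bounding box around each refined cluster. Boxes are mapped back to the
#' original frame scale when the frame was resized for the model. The
#' detector carries no confidence, so every detection is scored 1.0.
#'
#' @param frame `H x W x 3` array.
#' @param model `cw_background`.
#' @param frame_index Frame index recorded in the output rows.
#' @param video_id Video label recorded in the output rows.
#' @inheritParams refine_mask
#' @return A detections tibble (see [read_detections()] for the schema).
#' @export
detect_frame <- function(frame, model, frame_index = 0L,
                         video_id = "video", min_area = 2000,
                         morph_kernel = 5L, close_iterations = 2L,
                         open_iterations = 1L) {
  orig_h <- dim(frame)[1]; orig_w <- dim(frame)[2]
  p <- model$params
  sx <- orig_w / p$target_size[1]; sy <- orig_h / p$target_size[2]
  fg <- subtract_background(frame, model)
  clusters <- refine_mask(fg, min_area = min_area,
                          morph_kernel = morph_kernel,
                          close_iterations = close_iterations,
                          open_iterations = open_iterations)
  if (!length(clusters)) return(empty_detections())
  purrr::map_dfr(clusters, function(cl) {
    tibble(video_id = video_id, frame_index = as.integer(frame_index),
           x_min = cl$box$x_min * sx, y_min = cl$box$y_min * sy,
           x_max = cl$box$x_max * sx, y_max = cl$box$y_max * sy,
           score = 1.0, track_id = NA_integer_, coasted = FALSE)
  })
}

#' Run the full background-elimination pipeline on a video
#'
#' Builds the background once from the stride-sampled frames of the video,
#' then processes every frame (stride 1) with foreground extraction, mask
#' refinement and box placement. Deterministic: identical input frames and
#' parameters give identical output.
#'
#' @param video A `cw_video` or a frame-directory path readable by
#'   [read_video_frames()].
#' @param params [bg_params()] settings (its `stride` drives background
#'   sampling).
#' @inheritParams refine_mask
#' @return Detections tibble covering every frame of the video.
#' @export
run_be_pipeline <- function(video, params = bg_params(), min_area = 2000,
                            morph_kernel = 5L, close_iterations = 2L,
                            open_iterations = 1L) {
  if (!inherits(video, "cw_video")) video <- read_video_frames(video)
  sampled <- read_video_frames(video, stride = params$stride)
  model <- build_background(sampled, params)
  out <- purrr::map2_dfr(video$frames, video$indices, function(f, idx) {
    detect_frame(f, model, frame_index = idx, video_id = video$video_id,
                 min_area = min_area, morph_kernel = morph_kernel,
                 close_iterations = close_iterations,
                 open_iterations = open_iterations)
  })
  if (!nrow(out)) empty_detections() else out
}
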
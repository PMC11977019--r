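# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# IoU of two integer-coordinate boxes by enumerating the pixel grid.
iou_enumeration_oracle <- function(a, b) {
  x0 <- min(a$x_min, b$x_min); x1 <- max(a$x_max, b$x_max)
  y0 <- min(a$y_min, b$y_min); y1 <- max(a$y_max, b$y_max)
  if (x1 <= x0 || y1 <= y0) return(0)
  px <- expand.grid(x = x0:(x1 - 1), y = y0:(y1 - 1))
  in_a <- px$x >= a$x_min & px$x < a$x_max & px$y >= a$y_min & px$y < a$y_max
  in_b <- px$x >= b$x_min & px$x < b$x_max & px$y >= b$y_min & px$y < b$y_max
  inter <- sum(in_a & in_b); uni <- sum(in_a | in_b)
  if (uni == 0) 0 else inter / uni
}

random_int_box <- function(max_xy = 60, max_wh = 40) {
  x0 <- sample.int(max_xy, 1) - 1; y0 <- sample.int(max_xy, 1) - 1
  list(x_min = x0, y_min = y0,
       x_max = x0 + sample.int(max_wh, 1), y_max = y0 + sample.int(max_wh, 1))
}

# Minimum assignment cost by enumerating every injective row -> column map.
brute_force_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  flip <- n > m
  if (flip) { cost <- t(cost); tmp <- n; n <- m; m <- tmp }
  best <- Inf
  rec <- function(row, used, acc) {
    if (acc >= best) return()
    if (row > n) { best <<- acc; return() }
    for (col in setdiff(seq_len(m), used)) {
      rec(row + 1L, c(used, col), acc + cost[row, col])
    }
  }
  rec(1L, integer(0), 0)
  best
}

# Exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign
# patterns over the observed (possibly tied) rank multiset.
wilcoxon_enumeration_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  t_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  t_all <- as.numeric(signs %*% r)
  p_le <- mean(t_all <= t_obs + 1e-9)
  p_ge <- mean(t_all >= t_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Fraction of frames on which some detection overlaps the (single) subject
# ground truth at IoU >= 0.5.
frame_hit_rate <- function(dets, gt, n_frames, iou = 0.5) {
  hits <- vapply(0:(n_frames - 1), function(f) {
    d <- dets[dets$frame_index == f, , drop = FALSE]
    g <- gt[gt$frame_index == f & !gt$ignore, , drop = FALSE]
    if (!nrow(d) || !nrow(g)) return(FALSE)
    any(vapply(seq_len(nrow(d)), function(i) {
      max(box_iou(d[i, ], g)) >= iou
    }, logical(1)))
  }, logical(1))
  mean(hits)
}

# Hand-written VIA 2.x project fixture: 2 frames x 2 regions, one region
# flagged ignore, mixing polygon and rect shapes.
write_via_fixture <- function(path) {
  proj <- list(`_via_img_metadata` = list(
    `f0.png-1` = list(
      filename = "frame_000000.png", size = -1,
      regions = list(
        list(shape_attributes = list(name = "rect", x = 10, y = 20,
                                     width = 30, height = 40),
             region_attributes = list(id = "macaque_A")),
        list(shape_attributes = list(name = "polygon",
                                     all_points_x = c(0, 10, 10, 0),
                                     all_points_y = c(0, 0, 10, 10)),
             region_attributes = list(id = "macaque_B"))),
      file_attributes = list(frame_index = 0)),
    `f1.png-1` = list(
      filename = "frame_000001.png", size = -1,
      regions = list(
        list(shape_attributes = list(name = "rect", x = 5, y = 5,
                                     width = 10, height = 10),
             region_attributes = list(id = "macaque_A")),
        list(shape_attributes = list(name = "rect", x = 50, y = 5,
                                     width = 12, height = 9),
             region_attributes = list(id = "neighbour", ignore = "1"))),
      file_attributes = list(frame_index = 1))))
  jsonlite::write_json(proj, path, auto_unbox = TRUE, digits = NA)
  path
}

# Tiny rendered scene shared by fast unit tests.
tiny_scene <- function(seed = 11, n_frames = 60L, n_subjects = 1L, ...) {
  render_scene(scene_config(width = 160L, height = 90L,
                            n_frames = n_frames, n_subjects = n_subjects,
                            seed = seed, video_id = "tiny", ...))
}

tiny_bg_params <- function(...) {
  bg_params(stride = 10, group_size = 120, target_size = c(160L, 90L), ...)
}
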
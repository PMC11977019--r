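#' Configuration for a synthetic home-cage scene
#'
#' Describes a renderable scene with exact ground truth: one or two
#' textured deformable subjects moving between waypoints inside a static
#' textured cage, with optional railing occlusion, enrichment objects,
#' global overexposure episodes, a semi-transparent reflection overlay,
#' and a moving non-focal animal inside a marked neighbour (ignore)
#' region. Identical config and seed give identical frames and ground
#' truth.
#'
#' Subjects are drawn as two overlapping ellipses (body plus head) whose
#' vertical eccentricity varies with a phase term (`deform_amplitude`),
#' filled with a high-contrast filtered-noise texture so that trivial
#' colour thresholding cannot segment them.
#'
#' @param width,height Frame size in pixels (defaults 1280x720; the test
#'   fixtures use 320x180, a scale-preserving quarter).
#' @param fps Frame rate (default 15).
#' @param n_frames Number of frames.
#' @param n_subjects 0, 1 or 2 focal subjects.
#' @param subjects Optional list of per-subject specs (`waypoints`
#'   two-column matrix, `speed` px/frame, `semi_axes` c(a, b),
#'   `deform_amplitude`, `stationary` list of `c(first, last)` frame
#'   spans). Auto-generated from the seed when NULL.
#' @param railing NULL or `list(period =, width =)` — vertical bars drawn
#'   over the subjects.
#' @param enrichment NULL or list of static rectangles
#'   (`list(x_min, y_min, x_max, y_max)`) drawn over the subjects.
#' @param overexposure NULL or `list(delta =, spans = list(c(first,
#'   last)))` — global brightness surges.
#' @param reflection NULL or `list(box =, alpha =)` — static
#'   semi-transparent bright overlay.
#' @param neighbour FALSE or `list(region =, semi_axes =, speed =)` — a
#'   moving subject confined to `region`, annotated `ignore = TRUE`.
#' @param noise_level Per-frame uniform sensor noise amplitude in
#'   intensity levels (default 2).
#' @param seed Integer seed controlling textures, trajectories and noise.
#' @param video_id Label for the rendered video.
#' @return A list of class `cw_scene_config`.
#' @export
scene_config <- function(width = 1280L, height = 720L, fps = 15,
                         n_frames = 300L, n_subjects = 1L, subjects = NULL,
                         railing = NULL, enrichment = NULL,
                         overexposure = NULL, reflection = NULL,
                         neighbour = FALSE, noise_level = 2,
                         seed = 1L, video_id = "scene") {
  stopifnot(width >= 16, height >= 16, n_frames >= 1,
            n_subjects %in% 0:2, noise_level >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 fps = fps, n_frames = as.integer(n_frames),
                 n_subjects = as.integer(n_subjects), subjects = subjects,
                 railing = railing, enrichment = enrichment,
                 overexposure = overexposure, reflection = reflection,
                 neighbour = neighbour, noise_level = noise_level,
                 seed = as.integer(seed), video_id = video_id),
            class = "cw_scene_config")
}

# Run code under a private Mersenne-Twister stream, restoring the caller's
# RNG state afterwards.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

default_subject <- function(cfg, which) {
  a <- max(6L, round(cfg$width / 16))   # body semi-axes
  b <- max(4L, round(cfg$width / 24))
  mx <- a + round(0.8 * a) + round(0.45 * a) + 2L  # head sticks out right
  my <- b + 2L
  if (2 * mx >= cfg$width || 2 * my >= cfg$height) {
    abort("subject larger than frame")
  }
  xr <- c(mx, cfg$width - 1 - mx); yr <- c(my, cfg$height - 1 - my)
  wp <- if (which == 1L) {
    rbind(c(xr[1], yr[1]), c(xr[2], yr[2]), c(xr[2], yr[1]), c(xr[1], yr[2]))
  } else {
    rbind(c(xr[2], yr[1]), c(xr[1], yr[2]), c(xr[1], yr[1]), c(xr[2], yr[2]))
  }
  list(waypoints = wp, speed = 2, semi_axes = c(a, b),
       deform_amplitude = 0.15, stationary = NULL)
}

# Position along a ping-pong waypoint path after `dist` pixels of travel.
path_position <- function(waypoints, dist) {
  seg <- diff(waypoints)
  len <- sqrt(rowSums(seg^2))
  total <- sum(len)
  if (total == 0) return(waypoints[1, ])
  d <- dist %% (2 * total)
  if (d > total) d <- 2 * total - d
  cum <- c(0, cumsum(len))
  i <- max(which(cum <= d + 1e-9)); i <- min(i, length(len))
  t <- if (len[i] > 0) (d - cum[i]) / len[i] else 0
  waypoints[i, ] + t * seg[i, ]
}

# Per-frame integer centre positions honouring stationary episodes.
subject_trajectory <- function(spec, n_frames) {
  moving <- rep(TRUE, n_frames)
  for (sp in spec$stationary %||% list()) {
    lo <- max(0L, sp[1]); hi <- min(n_frames - 1L, sp[2])
    if (hi >= lo) moving[(lo:hi) + 1L] <- FALSE
  }
  eff <- c(0, cumsum(moving[-n_frames]))
  t(vapply(eff, function(e) {
    round(path_position(spec$waypoints, spec$speed * e))
  }, numeric(2)))
}

# Logical subject mask on the full frame; two overlapping ellipses with
# phase-varying vertical eccentricity.
subject_mask <- function(cx, cy, spec, frame_idx, width, height) {
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]
  amp <- spec$deform_amplitude %||% 0
  bt <- max(2, round(b * (1 + amp * sin(2 * pi * frame_idx / 30))))
  hx <- cx + round(0.8 * a); hr <- max(2, round(0.45 * a))
  x0 <- max(0, cx - a - 1); x1 <- min(width - 1, hx + hr + 1)
  y0 <- max(0, cy - max(b, bt) - 1); y1 <- min(height - 1, cy + max(b, bt) + 1)
  gx <- x0:x1; gy <- y0:y1
  dx <- outer(rep(1, length(gy)), gx - cx)
  dy <- outer(gy - cy, rep(1, length(gx)))
  body <- (dx / a)^2 + (dy / bt)^2 <= 1
  dxh <- outer(rep(1, length(gy)), gx - hx)
  hb <- max(2, round(0.45 * bt))
  head <- (dxh / hr)^2 + (dy / hb)^2 <= 1
  m <- matrix(FALSE, height, width)
  m[gy + 1, gx + 1] <- body | head
  m
}

# Filtered-noise texture tile, bright range, per channel.
make_texture <- function(h, w, low = 150, high = 250) {
  tex <- array(0, c(h, w, 3))
  for (c in 1:3) {
    n <- matrix(runif(h * w), h, w)
    img <- EBImage::gblur(EBImage::Image(t(n)), sigma = 1.5)
    sm <- t(EBImage::imageData(img))
    sm <- (sm - min(sm)) / max(1e-9, diff(range(sm)))
    tex[, , c] <- low + sm * (high - low)
  }
  tex
}

draw_rect <- function(frame, box, colour) {
  xs <- max(0, round(box$x_min)):min(dim(frame)[2] - 1, round(box$x_max) - 1)
  ys <- max(0, round(box$y_min)):min(dim(frame)[1] - 1, round(box$y_max) - 1)
  for (c in 1:3) frame[ys + 1, xs + 1, c] <- colour[c]
  frame
}

#' Render a synthetic scene with exact ground truth
#'
#' Produces the video frames and a ground-truth table for a
#' [scene_config()]. Each subject's ground-truth box is the tight bound of
#' its rendered mask *before* occluders are drawn over it (the annotation
#' convention: boxes include all body parts, occluded or not). The
#' neighbour subject, when present, is annotated with `ignore = TRUE`.
#'
#' @param config A [scene_config()].
#' @return List with `video` (a `cw_video`), `gt` (ground-truth tibble as
#'   from [read_via_project()]) and `config`.
#' @export
render_scene <- function(config) {
  stopifnot(inherits(config, "cw_scene_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    w <- cfg$width; h <- cfg$height

    # static cage background: smooth dark texture
    base <- array(0, c(h, w, 3))
    for (c in 1:3) {
      n <- matrix(runif(h * w), h, w)
      img <- EBImage::gblur(EBImage::Image(t(n)), sigma = 4)
      sm <- t(EBImage::imageData(img))
      sm <- (sm - min(sm)) / max(1e-9, diff(range(sm)))
      base[, , c] <- 30 + sm * 60
    }
    for (box in cfg$enrichment %||% list()) {
      base <- draw_rect(base, box, c(90, 70, 50))
    }

    subjects <- cfg$subjects
    if (is.null(subjects) && cfg$n_subjects > 0) {
      subjects <- lapply(seq_len(cfg$n_subjects), default_subject, cfg = cfg)
    }
    subjects <- subjects %||% list()
    trajs <- lapply(subjects, subject_trajectory, n_frames = cfg$n_frames)
    texs <- lapply(subjects, function(s) {
      make_texture(2 * max(s$semi_axes) * 2 + 8, 2 * max(s$semi_axes) * 2 + 8)
    })

    nb <- cfg$neighbour
    nb_traj <- NULL; nb_tex <- NULL
    if (is.list(nb)) {
      reg <- nb$region
      na_ <- nb$semi_axes[1]
      head_reach <- round(1.25 * na_)  # head ellipse tip beyond the centre
      wp <- rbind(c(reg$x_min + na_ + 2, (reg$y_min + reg$y_max) / 2),
                  c(reg$x_max - head_reach - 2, (reg$y_min + reg$y_max) / 2))
      nb_spec <- list(waypoints = wp, speed = nb$speed %||% 1.5,
                      semi_axes = nb$semi_axes, deform_amplitude = 0.1,
                      stationary = NULL)
      nb_traj <- subject_trajectory(nb_spec, cfg$n_frames)
      nb_tex <- make_texture(2 * max(nb$semi_axes) * 2 + 8,
                             2 * max(nb$semi_axes) * 2 + 8)
      nb$spec <- nb_spec
    }

    rail_mask <- NULL
    if (is.list(cfg$railing)) {
      cols <- rep(FALSE, w)
      starts <- seq(0, w - 1, by = cfg$railing$period)
      for (s in starts) {
        cols[(s:min(w - 1, s + cfg$railing$width - 1)) + 1] <- TRUE
      }
      rail_mask <- matrix(rep(cols, each = h), h, w)
    }

    over_frames <- rep(FALSE, cfg$n_frames)
    for (sp in cfg$overexposure$spans %||% list()) {
      lo <- max(0L, sp[1]); hi <- min(cfg$n_frames - 1L, sp[2])
      if (hi >= lo) over_frames[(lo:hi) + 1L] <- TRUE
    }

    noise <- cfg$noise_level
    frames <- vector("list", cfg$n_frames)
    gt_rows <- vector("list", cfg$n_frames)
    for (t in seq_len(cfg$n_frames)) {
      fr <- base
      rows <- list()

      if (!is.null(nb_traj)) {
        m <- subject_mask(nb_traj[t, 1], nb_traj[t, 2], nb$spec, t - 1L, w, h)
        fr <- paint_mask(fr, m, nb_tex)
        b <- mask_bounds(m)
        rows[[length(rows) + 1L]] <- tibble(
          video_id = cfg$video_id, frame_index = t - 1L,
          instance_id = "neighbour", x_min = b$x_min, y_min = b$y_min,
          x_max = b$x_max, y_max = b$y_max, ignore = TRUE,
          polygon = list(NULL))
      }

      for (si in seq_along(subjects)) {
        m <- subject_mask(trajs[[si]][t, 1], trajs[[si]][t, 2],
                          subjects[[si]], t - 1L, w, h)
        fr <- paint_mask(fr, m, texs[[si]])
        b <- mask_bounds(m)
        if (is.null(b)) abort("subject left the frame entirely")
        rows[[length(rows) + 1L]] <- tibble(
          video_id = cfg$video_id, frame_index = t - 1L,
          instance_id = sprintf("subject_%d", si),
          x_min = b$x_min, y_min = b$y_min,
          x_max = b$x_max, y_max = b$y_max, ignore = FALSE,
          polygon = list(NULL))
      }

      # occluders drawn over the subjects; GT already recorded
      if (!is.null(rail_mask)) {
        for (c in 1:3) {
          ch <- fr[, , c]; ch[rail_mask] <- 22; fr[, , c] <- ch
        }
      }
      for (box in cfg$enrichment %||% list()) {
        fr <- draw_rect(fr, box, c(90, 70, 50))
      }
      if (is.list(cfg$reflection)) {
        rb <- cfg$reflection$box; al <- cfg$reflection$alpha %||% 0.25
        xs <- (round(rb$x_min):(round(rb$x_max) - 1)) + 1
        ys <- (round(rb$y_min):(round(rb$y_max) - 1)) + 1
        for (c in 1:3) {
          fr[ys, xs, c] <- (1 - al) * fr[ys, xs, c] + al * 220
        }
      }
      if (over_frames[t]) {
        fr <- fr + (cfg$overexposure$delta %||% 60)
      }
      if (noise > 0) {
        fr <- fr + array(sample.int(2 * noise + 1, h * w * 3, replace = TRUE) -
                           noise - 1L, c(h, w, 3))
      }
      frames[[t]] <- pmin(pmax(round(fr), 0), 255)
      gt_rows[[t]] <- if (length(rows)) dplyr::bind_rows(rows) else NULL
    }

    gt <- dplyr::bind_rows(gt_rows)
    if (!nrow(gt)) gt <- empty_ground_truth()
    list(video = new_video(frames, fps = cfg$fps, video_id = cfg$video_id),
         gt = gt, config = cfg)
  })
}

paint_mask <- function(frame, mask, texture) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(frame)
  th <- dim(texture)[1]; tw <- dim(texture)[2]
  ty <- ((idx[, 1] - min(idx[, 1])) %% th) + 1
  tx <- ((idx[, 2] - min(idx[, 2])) %% tw) + 1
  for (c in 1:3) {
    frame[cbind(idx, c)] <- texture[cbind(ty, tx, c)]
  }
  frame
}

#' Derive a corrupted detection stream from ground truth
#'
#' Simulates an imperfect detector on top of exact ground truth: each
#' ground-truth box (including ignored neighbours — a real detector sees
#' them too) is independently dropped with probability `dropout_rate`;
#' surviving boxes are jittered by a uniform offset in `[-jitter_px,
#' jitter_px]` and given a high confidence score (uniform on
#' `tp_score_range`); spurious false positives are injected per frame with
#' Poisson rate `fp_rate` at random positions with low scores (uniform on
#' `fp_score_range`). The two score ranges are disjoint around 0.70, so a
#' confidence sweep has a known separation point.
#'
#' @param gt Ground-truth tibble.
#' @param dropout_rate,fp_rate Rates in `[0, 1)`.
#' @param jitter_px Maximum absolute positional jitter in pixels.
#' @param seed Integer seed.
#' @param frame_size `c(width, height)` used to place injected false
#'   positives.
#' @param tp_score_range,fp_score_range Score supports for true and false
#'   detections.
#' @return Detections tibble.
#' @export
corrupt_detections <- function(gt, dropout_rate = 0, fp_rate = 0,
                               jitter_px = 0, seed = 1L,
                               frame_size = c(320L, 180L),
                               tp_score_range = c(0.72, 1.0),
                               fp_score_range = c(0.50, 0.68)) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1, fp_rate >= 0, fp_rate < 1)
  with_local_seed(seed, {
    n <- nrow(gt)
    keep <- if (n) runif(n) >= dropout_rate else logical(0)
    kept <- gt[keep, , drop = FALSE]
    out <- if (nrow(kept)) {
      exact <- dropout_rate == 0 && fp_rate == 0 && jitter_px == 0
      dx <- if (jitter_px > 0) runif(nrow(kept), -jitter_px, jitter_px) else 0
      dy <- if (jitter_px > 0) runif(nrow(kept), -jitter_px, jitter_px) else 0
      tibble(video_id = kept$video_id, frame_index = kept$frame_index,
             x_min = kept$x_min + dx, y_min = kept$y_min + dy,
             x_max = kept$x_max + dx, y_max = kept$y_max + dy,
             score = if (exact) 1.0 else
               runif(nrow(kept), tp_score_range[1], tp_score_range[2]),
             track_id = NA_integer_, coasted = FALSE)
    } else empty_detections()

    if (fp_rate > 0 && n) {
      frames <- sort(unique(gt$frame_index))
      vids <- gt$video_id[match(frames, gt$frame_index)]
      fp_rows <- purrr::map_dfr(seq_along(frames), function(i) {
        k <- rpois(1, fp_rate)
        if (!k) return(NULL)
        bw <- runif(k, 0.06, 0.18) * frame_size[1]
        bh <- runif(k, 0.08, 0.22) * frame_size[2]
        x0 <- runif(k, 0, frame_size[1] - bw)
        y0 <- runif(k, 0, frame_size[2] - bh)
        tibble(video_id = vids[i], frame_index = frames[i],
               x_min = x0, y_min = y0, x_max = x0 + bw, y_max = y0 + bh,
               score = runif(k, fp_score_range[1], fp_score_range[2]),
               track_id = NA_integer_, coasted = FALSE)
      })
      out <- dplyr::bind_rows(out, fp_rows)
    }
    dplyr::arrange(out, .data$video_id, .data$frame_index)
  })
}

#' Canonical synthetic fixture suite
#'
#' Regenerates the named scene bundles used throughout the test suite and
#' the acceptance checks, each a list of `video`, `gt`, `detections` and a
#' `description` of the behaviour it probes. All bundles render at
#' 320x180 (a scale-preserving quarter of 1280x720) with seeds derived
#' from `seed`, so regeneration is deterministic.
#'
#' * `single_clean` — 300 frames, one moving textured subject, no
#'   occluders: the background-elimination detector should localise it on
#'   nearly every frame.
#' * `single_static_subject` — the subject never moves, so background
#'   synthesis absorbs it and detection should fail (the known failure
#'   mode of background subtraction on static animals).
#' * `single_overexposed` — brightness surges over two frame spans.
#' * `paired_overlap` — two subjects on crossing paths with an overlap
#'   episode.
#' * `neighbour_ignore` — one focal subject plus a moving animal in a
#'   neighbouring-cage region annotated `ignore = TRUE`.
#' * `dropout_gap5` — clean detections with frames 50..54 deleted: the
#'   tracker should coast across the gap.
#' * `dropout_gap25` — a 25-frame gap (frames 40..64), longer than the
#'   20-frame coast limit: the track must die after exactly 20 coasted
#'   frames.
#'
#' @param seed Base seed (default 20260901).
#' @param names Subset of bundle names to build (default all).
#' @return Named list of fixture bundles.
#' @export
standard_fixture_suite <- function(seed = 20260901L, names = NULL) {
  all_names <- c("single_clean", "single_static_subject",
                 "single_overexposed", "paired_overlap", "neighbour_ignore",
                 "dropout_gap5", "dropout_gap25")
  names <- names %||% all_names
  stopifnot(all(names %in% all_names))
  W <- 320L; H <- 180L
  build <- list(
    single_clean = function(s) {
      sc <- render_scene(scene_config(
        width = W, height = H, n_frames = 300L, n_subjects = 1L,
        seed = s, video_id = "single_clean"))
      list(video = sc$video, gt = sc$gt,
           detections = corrupt_detections(sc$gt, seed = s + 1L,
                                           frame_size = c(W, H)),
           description = "moving subject, no occluders; BE should detect it")
    },
    single_static_subject = function(s) {
      spec <- default_subject(scene_config(width = W, height = H), 1L)
      spec$waypoints <- rbind(c(W / 2, H / 2), c(W / 2, H / 2))
      spec$speed <- 0
      spec$deform_amplitude <- 0  # truly static, e.g. a sleeping animal
      sc <- render_scene(scene_config(
        width = W, height = H, n_frames = 300L, n_subjects = 1L,
        subjects = list(spec), seed = s, video_id = "single_static_subject"))
      list(video = sc$video, gt = sc$gt,
           detections = corrupt_detections(sc$gt, seed = s + 1L,
                                           frame_size = c(W, H)),
           description = "static subject is absorbed into the background")
    },
    single_overexposed = function(s) {
      sc <- render_scene(scene_config(
        width = W, height = H, n_frames = 200L, n_subjects = 1L,
        overexposure = list(delta = 60, spans = list(c(60L, 90L),
                                                     c(140L, 160L))),
        seed = s, video_id = "single_overexposed"))
      list(video = sc$video, gt = sc$gt,
           detections = corrupt_detections(sc$gt, seed = s + 1L,
                                           frame_size = c(W, H)),
           description = "global brightness surges during two episodes")
    },
    paired_overlap = function(s) {
      sc <- render_scene(scene_config(
        width = W, height = H, n_frames = 150L, n_subjects = 2L,
        seed = s, video_id = "paired_overlap"))
      list(video = sc$video, gt = sc$gt,
           detections = corrupt_detections(sc$gt, seed = s + 1L,
                                           frame_size = c(W, H)),
           description = "two subjects on crossing paths with an overlap episode")
    },
    neighbour_ignore = function(s) {
      reg <- list(x_min = 230, y_min = 10, x_max = 315, y_max = 60)
      sc <- render_scene(scene_config(
        width = W, height = H, n_frames = 150L, n_subjects = 1L,
        subjects = list(local({
          sp <- default_subject(scene_config(width = W, height = H), 1L)
          sp$waypoints <- rbind(c(40, 120), c(180, 120), c(180, 60), c(40, 60))
          sp
        })),
        neighbour = list(region = reg, semi_axes = c(12, 8), speed = 1.5),
        seed = s, video_id = "neighbour_ignore"))
      list(video = sc$video, gt = sc$gt,
           detections = corrupt_detections(sc$gt, seed = s + 1L,
                                           frame_size = c(W, H)),
           description = "non-focal animal inside an ignore region")
    },
    dropout_gap5 = function(s) {
      sc <- render_scene(scene_config(
        width = W, height = H, n_frames = 120L, n_subjects = 1L,
        subjects = list(local({
          sp <- default_subject(scene_config(width = W, height = H), 1L)
          sp$waypoints <- rbind(c(40, 90), c(280, 90))
          sp$speed <- 2; sp$deform_amplitude <- 0
          sp
        })),
        seed = s, video_id = "dropout_gap5"))
      dets <- corrupt_detections(sc$gt, seed = s + 1L, frame_size = c(W, H))
      dets <- dets[!(dets$frame_index %in% 50:54), , drop = FALSE]
      list(video = sc$video, gt = sc$gt, detections = dets,
           description = "5-frame detection gap; the tracker should coast across")
    },
    dropout_gap25 = function(s) {
      sc <- render_scene(scene_config(
        width = W, height = H, n_frames = 120L, n_subjects = 1L,
        subjects = list(local({
          sp <- default_subject(scene_config(width = W, height = H), 1L)
          sp$waypoints <- rbind(c(40, 90), c(280, 90))
          sp$speed <- 2; sp$deform_amplitude <- 0
          sp
        })),
        seed = s, video_id = "dropout_gap25"))
      dets <- corrupt_detections(sc$gt, seed = s + 1L, frame_size = c(W, H))
      dets <- dets[!(dets$frame_index %in% 40:64), , drop = FALSE]
      list(video = sc$video, gt = sc$gt, detections = dets,
           description = "25-frame gap exceeds the 20-frame coast limit")
    })
  out <- lapply(seq_along(names), function(i) {
    build[[names[i]]](seed + match(names[i], all_names) * 13L)
  })
  setNames(out, names)
}

#' Export ground truth as a VIA 2.x project
#'
#' Writes a ground-truth table in the VGG Image Annotator project layout
#' (rect regions, `id` and `ignore` region attributes, `frame_index` file
#' attribute) so that generated fixtures exercise the same reader path as
#' real annotations. This is a fixture exporter, not a general VIA writer.
#'
#' @param gt Ground-truth tibble.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
export_via_gt <- function(gt, path) {
  entries <- list()
  for (f in sort(unique(gt$frame_index))) {
    g <- gt[gt$frame_index == f, , drop = FALSE]
    regions <- lapply(seq_len(nrow(g)), function(i) {
      list(shape_attributes = list(
             name = "rect", x = g$x_min[i], y = g$y_min[i],
             width = g$x_max[i] - g$x_min[i],
             height = g$y_max[i] - g$y_min[i]),
           region_attributes = list(
             id = g$instance_id[i],
             ignore = if (g$ignore[i]) "1" else "0"))
    })
    fname <- sprintf("frame_%06d.png", f)
    entries[[paste0(fname, "-1")]] <- list(
      filename = fname, size = -1L, regions = regions,
      file_attributes = list(frame_index = f))
  }
  vid <- if (nrow(gt)) gt$video_id[1] else "video"
  jsonlite::write_json(
    list(`_via_settings` = list(project = list(name = vid)),
         `_via_img_metadata` = entries),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
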
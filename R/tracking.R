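#' Tracker configuration
#'
#' Constant-velocity Kalman tracking with Hungarian association. A track
#' that goes unmatched coasts: its predicted centroid is emitted with the
#' box size of its last matched detection, for at most `coast_limit`
#' consecutive frames, after which the track is dropped.
#'
#' @param coast_limit Maximum consecutive frames a track may survive (and
#'   emit predicted boxes) without a matched detection (default 20).
#' @param gate_distance Association cutoff in pixels: an assigned
#'   prediction/detection pair further apart than this is treated as
#'   unmatched on both sides (default 150, sized for 1280x720).
#' @param process_noise Scale of the white-noise-acceleration process
#'   covariance, px/frame^2 (default 1).
#' @param measurement_noise Standard deviation of the centroid
#'   measurement, px (default 10).
#' @return A list of class `cw_tracker_config`.
#' @export
tracker_config <- function(coast_limit = 20L, gate_distance = 150,
                           process_noise = 1.0, measurement_noise = 10) {
  stopifnot(coast_limit >= 0, gate_distance > 0,
            process_noise > 0, measurement_noise > 0)
  structure(list(coast_limit = as.integer(coast_limit),
                 gate_distance = gate_distance,
                 process_noise = process_noise,
                 measurement_noise = measurement_noise),
            class = "cw_tracker_config")
}

#' Geometric centre of detections
#'
#' The box centre `((x_min + x_max)/2, (y_min + y_max)/2)` for plain
#' boxes; when a `mask` list-column is present (logical matrices), the
#' mean of the mask's 0-based pixel coordinates is used instead.
#'
#' @param dets Detections tibble (optionally with a `mask` list-column).
#' @return Tibble with columns `cx`, `cy`, one row per detection.
#' @export
centroid <- function(dets) {
  cx <- (dets$x_min + dets$x_max) / 2
  cy <- (dets$y_min + dets$y_max) / 2
  if ("mask" %in% names(dets)) {
    for (i in seq_len(nrow(dets))) {
      m <- dets$mask[[i]]
      if (!is.null(m)) {
        px <- which(m, arr.ind = TRUE)
        cx[i] <- mean(px[, 2L] - 1)
        cy[i] <- mean(px[, 1L] - 1)
      }
    }
  }
  tibble(cx = cx, cy = cy)
}

# Constant-velocity transition and measurement matrices (dt = 1 frame).
kf_matrices <- function(config) {
  F_ <- matrix(c(1, 0, 1, 0,
                 0, 1, 0, 1,
                 0, 0, 1, 0,
                 0, 0, 0, 1), 4, 4, byrow = TRUE)
  # discrete white-noise acceleration, dt = 1
  Q <- config$process_noise *
    matrix(c(0.25, 0, 0.5, 0,
             0, 0.25, 0, 0.5,
             0.5, 0, 1, 0,
             0, 0.5, 0, 1), 4, 4, byrow = TRUE)
  H <- matrix(c(1, 0, 0, 0,
                0, 1, 0, 0), 2, 4, byrow = TRUE)
  R <- diag(config$measurement_noise^2, 2)
  list(F_ = F_, Q = Q, H = H, R = R)
}

new_track <- function(id, cx, cy, box_w, box_h, score, config) {
  r2 <- config$measurement_noise^2
  list(track_id = as.integer(id), state = c(cx, cy, 0, 0),
       cov = diag(c(r2, r2, 100 * r2, 100 * r2)),  # velocity unknown at birth
       last_box_size = c(box_w, box_h), last_score = score,
       frames_since_detection = 0L, alive = TRUE)
}

#' One-frame Kalman prediction of a track
#'
#' Advances the constant-velocity state one frame (`cx <- cx + vx`,
#' `cy <- cy + vy`, velocities unchanged) and propagates the covariance as
#' `F P F' + Q`.
#'
#' @param track A track object (as produced inside [tracker_step()]).
#' @param config A [tracker_config()].
#' @return The predicted track.
#' @export
kalman_predict <- function(track, config = tracker_config()) {
  m <- kf_matrices(config)
  track$state <- as.numeric(m$F_ %*% track$state)
  track$cov <- m$F_ %*% track$cov %*% t(m$F_) + m$Q
  track
}

kalman_update <- function(track, z, config) {
  m <- kf_matrices(config)
  S <- m$H %*% track$cov %*% t(m$H) + m$R
  K <- track$cov %*% t(m$H) %*% solve(S)
  track$state <- as.numeric(track$state + K %*% (z - m$H %*% track$state))
  track$cov <- (diag(4) - K %*% m$H) %*% track$cov
  track
}

#' Minimum-cost one-to-one assignment (Hungarian algorithm)
#'
#' Solves the rectangular linear assignment problem for a matrix of
#' pairwise costs, returning `min(n, m)` pairs that minimise the total
#' cost.
#'
#' @param cost `n x m` matrix of finite nonnegative costs (rows = tracks,
#'   columns = detections).
#' @return Tibble with columns `row`, `col`, `cost`, one row per assigned
#'   pair (1-based indices).
#' @examples
#' hungarian_assign(matrix(c(1, 2, 2, 4), 2, byrow = TRUE))
#' @export
hungarian_assign <- function(cost) {
  cost <- as.matrix(cost)
  if (!length(cost) || nrow(cost) == 0L || ncol(cost) == 0L) {
    return(tibble(row = integer(), col = integer(), cost = numeric()))
  }
  if (any(!is.finite(cost)) || any(cost < 0)) {
    abort("hungarian_assign: costs must be finite and nonnegative")
  }
  flipped <- nrow(cost) > ncol(cost)
  m <- if (flipped) t(cost) else cost
  sol <- as.integer(clue::solve_LSAP(m))
  rows <- seq_len(nrow(m))
  out <- tibble(row = rows, col = sol, cost = m[cbind(rows, sol)])
  if (flipped) out <- tibble(row = out$col, col = out$row, cost = out$cost)
  dplyr::arrange(out, .data$row)
}

#' Advance the tracker by one frame
#'
#' Predicts all live tracks, associates predictions to detection centroids
#' with the Hungarian algorithm on Euclidean distance (pairs beyond
#' `gate_distance` are unmatched), updates matched tracks, coasts
#' unmatched tracks up to `coast_limit` frames by emitting their predicted
#' box, kills tracks past the limit, and starts a new track (zero initial
#' velocity) for every unmatched detection.
#'
#' @param tracks List of track objects (empty list to start).
#' @param dets Detections tibble for one frame.
#' @param config A [tracker_config()].
#' @param next_id Next track id to issue.
#' @return List with `tracks` (updated live tracks), `detections` (output
#'   rows: matched detections with `track_id` set, plus coasted synthetic
#'   boxes flagged `coasted = TRUE`), and `next_id`.
#' @export
tracker_step <- function(tracks, dets, config = tracker_config(),
                         next_id = 1L) {
  tracks <- lapply(tracks, kalman_predict, config = config)
  n_tr <- length(tracks); n_de <- nrow(dets)

  matched_tr <- integer(0); matched_de <- integer(0)
  if (n_tr > 0L && n_de > 0L) {
    cen <- centroid(dets)
    pred <- vapply(tracks, function(t) t$state[1:2], numeric(2))
    cost <- outer(seq_len(n_tr), seq_len(n_de), Vectorize(function(i, j) {
      sqrt((pred[1, i] - cen$cx[j])^2 + (pred[2, i] - cen$cy[j])^2)
    }))
    asg <- hungarian_assign(cost)
    asg <- asg[asg$cost <= config$gate_distance, , drop = FALSE]
    matched_tr <- asg$row; matched_de <- asg$col
  }

  out <- vector("list", 0L)
  if (length(matched_de)) {
    cen <- centroid(dets)
    for (k in seq_along(matched_tr)) {
      ti <- matched_tr[k]; di <- matched_de[k]
      tr <- kalman_update(tracks[[ti]], c(cen$cx[di], cen$cy[di]), config)
      tr$last_box_size <- c(dets$x_max[di] - dets$x_min[di],
                            dets$y_max[di] - dets$y_min[di])
      tr$last_score <- dets$score[di]
      tr$frames_since_detection <- 0L
      tracks[[ti]] <- tr
      row <- dets[di, , drop = FALSE]
      row$track_id <- tr$track_id
      row$coasted <- FALSE
      out[[length(out) + 1L]] <- row
    }
  }

  for (ti in setdiff(seq_len(n_tr), matched_tr)) {
    tr <- tracks[[ti]]
    tr$frames_since_detection <- tr$frames_since_detection + 1L
    if (tr$frames_since_detection <= config$coast_limit) {
      w <- tr$last_box_size[1]; h <- tr$last_box_size[2]
      out[[length(out) + 1L]] <- tibble(
        video_id = if (n_de) dets$video_id[1] else NA_character_,
        frame_index = if (n_de) dets$frame_index[1] else NA_integer_,
        x_min = tr$state[1] - w / 2, y_min = tr$state[2] - h / 2,
        x_max = tr$state[1] + w / 2, y_max = tr$state[2] + h / 2,
        score = tr$last_score, track_id = tr$track_id, coasted = TRUE)
    } else {
      tr$alive <- FALSE
    }
    tracks[[ti]] <- tr
  }

  for (di in setdiff(seq_len(n_de), matched_de)) {
    cen <- centroid(dets[di, , drop = FALSE])
    tr <- new_track(next_id, cen$cx, cen$cy,
                    dets$x_max[di] - dets$x_min[di],
                    dets$y_max[di] - dets$y_min[di],
                    dets$score[di], config)
    next_id <- next_id + 1L
    tracks[[length(tracks) + 1L]] <- tr
    row <- dets[di, , drop = FALSE]
    row$track_id <- tr$track_id
    row$coasted <- FALSE
    out[[length(out) + 1L]] <- row
  }

  tracks <- Filter(function(t) t$alive, tracks)
  detections <- if (length(out)) dplyr::bind_rows(out) else empty_detections()
  list(tracks = tracks, detections = detections, next_id = next_id)
}

#' Track a detection stream
#'
#' Runs [tracker_step()] over every frame of every video in a detections
#' table (frames with no detections still advance the tracker, so gaps
#' coast). Each video is tracked independently; output rows gain a
#' `track_id` and coasted fill-in boxes flagged `coasted = TRUE`. For any
#' frame there is at most one output row per track id.
#'
#' @param detections Detections tibble or path to an interchange CSV.
#' @param config A [tracker_config()].
#' @param n_frames Optional total frame count per video (a single number
#'   or named vector by video id); defaults to `max(frame_index) + 1` of
#'   each video, so trailing all-gap frames are only coasted when
#'   `n_frames` says the video extends beyond the last detection.
#' @return Detections tibble with track ids and coast fill-ins.
#' @export
run_tracker <- function(detections, config = tracker_config(),
                        n_frames = NULL) {
  if (is.character(detections)) detections <- read_detections(detections)
  if (!nrow(detections)) return(empty_detections())
  validate_detections(detections)
  out <- detections |>
    dplyr::group_by(.data$video_id) |>
    dplyr::group_map(function(d, key) {
      vid <- key$video_id[1]
      d$video_id <- vid  # group_map strips the grouping column
      nf <- if (is.null(n_frames)) max(d$frame_index) + 1L
        else if (!is.null(names(n_frames))) unname(n_frames[vid])
        else n_frames
      tracks <- list(); next_id <- 1L
      res <- vector("list", nf)
      for (f in 0:(nf - 1L)) {
        fd <- d[d$frame_index == f, , drop = FALSE]
        step <- tracker_step(tracks, fd, config, next_id)
        tracks <- step$tracks; next_id <- step$next_id
        sd <- step$detections
        if (nrow(sd)) {
          sd$video_id <- vid
          sd$frame_index <- f
          res[[f + 1L]] <- sd
        }
      }
      dplyr::bind_rows(res)
    }) |>
    dplyr::bind_rows()
  out <- out[c("video_id", "frame_index", "x_min", "y_min", "x_max",
               "y_max", "score", "track_id", "coasted")]
  dplyr::arrange(out, .data$video_id, .data$frame_index)
}
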
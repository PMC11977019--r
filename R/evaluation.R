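#' Match one frame's detections against ground truth
#'
#' Greedy score-ordered one-to-one matching: detections are visited in
#' decreasing score order and each takes the highest-IoU still-unmatched
#' non-ignored ground-truth box with IoU at or above the threshold (a true
#' positive; IoU ties go to the lower ground-truth index). A detection
#' whose best remaining overlap at the threshold is with an *ignored*
#' instance (e.g. an animal in a neighbouring cage) is discarded from
#' scoring — neither credit nor penalty. Remaining detections are false
#' positives; unmatched non-ignored ground truth are false negatives.
#'
#' @param dets Detections tibble (one frame).
#' @param gts Ground-truth tibble (same frame) with `ignore` column.
#' @param iou_threshold Minimum IoU for a true positive (default 0.50).
#' @return List with `counts` (tibble `tp`, `fp`, `fn`) and `assignments`
#'   (tibble `det_row`, `gt_row`, `iou`, `status` — status is one of
#'   `"tp"`, `"fp"`, `"ignored"`; `gt_row`/`iou` are NA except for tp and
#'   ignored).
#' @export
match_frame <- function(dets, gts, iou_threshold = 0.5) {
  n_de <- if (is.null(dets)) 0L else nrow(dets)
  n_gt <- if (is.null(gts)) 0L else nrow(gts)
  ign <- if (n_gt) gts$ignore else logical(0)

  det_order <- if (n_de) order(-dets$score) else integer(0)
  gt_taken <- rep(FALSE, n_gt)
  status <- character(n_de); gt_row <- rep(NA_integer_, n_de)
  iou_val <- rep(NA_real_, n_de)

  for (di in det_order) {
    ious <- if (n_gt) iou_one_vs_many(dets[di, ], gts) else numeric(0)
    cand <- which(!ign & !gt_taken & ious >= iou_threshold)
    if (length(cand)) {
      best <- cand[which.max(ious[cand])]  # ties: lower index wins
      gt_taken[best] <- TRUE
      status[di] <- "tp"; gt_row[di] <- best; iou_val[di] <- ious[best]
      next
    }
    cand_ign <- which(ign & ious >= iou_threshold)
    if (length(cand_ign)) {
      best <- cand_ign[which.max(ious[cand_ign])]
      status[di] <- "ignored"; gt_row[di] <- best; iou_val[di] <- ious[best]
    } else {
      status[di] <- "fp"
    }
  }
  tp <- sum(status == "tp")
  fp <- sum(status == "fp")
  fn <- sum(!ign & !gt_taken)
  list(counts = tibble(tp = tp, fp = fp, fn = fn),
       assignments = tibble(det_row = seq_len(n_de), gt_row = gt_row,
                            iou = iou_val, status = status))
}

#' Precision, recall and F1 from match counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)` (the harmonic
#' mean). Any 0/0 is undefined and returned as NA; undefined values are
#' excluded from downstream medians rather than coerced to 0 or 1.
#'
#' @param counts Tibble (or list) with `tp`, `fp`, `fn`; vectorised over
#'   rows.
#' @return Tibble with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @examples
#' compute_metrics(tibble::tibble(tp = 90, fp = 10, fn = 10))
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall),
               ifelse(!is.na(precision) & !is.na(recall), NA_real_, NA_real_))
  tibble(tp = tp, fp = fp, fn = fn,
         precision = precision, recall = recall, f1 = f1)
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 * precision * recall / (precision + recall)`:
#' 1 only when both inputs are 1, and 0 when either is 0. Useful for
#' checking reported precision/recall/F1 triples for internal consistency.
#'
#' @param precision,recall Values in `[0, 1]`; vectorised.
#' @return F1 values; NA where `precision + recall` is 0.
#' @examples
#' f1_score(0.89, 0.86)  # 0.8747, rounds to 0.87
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), NA_real_)
}

#' Score detections against ground truth, per video and per individual
#'
#' Counts are accumulated over every frame of a video and metrics computed
#' once per video (micro aggregation). When the ground truth carries
#' individual identities and `per_individual = TRUE`, metrics are
#' additionally computed per instance id: true positives and false
#' negatives are restricted to that individual, while detections matched
#' to *other* individuals are dropped from the individual's false-positive
#' pool (only globally unmatched detections count against it).
#'
#' @param dets Detections tibble (or interchange CSV path).
#' @param gts Ground-truth tibble (or VIA project path).
#' @param iou_threshold Minimum IoU for a true positive (default 0.50).
#' @param score_threshold Detections below this confidence are removed
#'   before matching (default 0).
#' @param per_individual Also emit one row per instance id (default
#'   FALSE).
#' @return Tibble with `video_id`, `instance_id` (`"all"` for the pooled
#'   row), `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
evaluate_video <- function(dets, gts, iou_threshold = 0.5,
                           score_threshold = 0, per_individual = FALSE) {
  if (is.character(dets)) dets <- read_detections(dets)
  if (is.character(gts)) gts <- read_via_project(gts)
  unknown <- setdiff(unique(dets$video_id), unique(gts$video_id))
  if (length(unknown)) {
    abort(sprintf("videos present in detections but absent from ground truth: %s",
                  paste(unknown, collapse = ", ")))
  }
  dets <- dets[dets$score >= score_threshold, , drop = FALSE]

  purrr::map_dfr(unique(gts$video_id), function(vid) {
    d <- dets[dets$video_id == vid, , drop = FALSE]
    g <- gts[gts$video_id == vid, , drop = FALSE]
    frames <- sort(unique(c(d$frame_index, g$frame_index)))
    per_frame <- lapply(frames, function(f) {
      match_frame(d[d$frame_index == f, , drop = FALSE],
                  g[g$frame_index == f, , drop = FALSE],
                  iou_threshold)
    })
    counts <- purrr::map_dfr(per_frame, "counts") |>
      dplyr::summarise(tp = sum(.data$tp), fp = sum(.data$fp),
                       fn = sum(.data$fn))
    pooled <- dplyr::bind_cols(tibble(video_id = vid, instance_id = "all"),
                               compute_metrics(counts))
    if (!per_individual || !nrow(g)) return(pooled)

    ids <- setdiff(unique(g$instance_id[!g$ignore]), NA)
    per_id <- purrr::map_dfr(ids, function(id) {
      tp_i <- 0L; fn_i <- 0L; fp_all <- 0L
      for (k in seq_along(frames)) {
        f <- frames[k]
        gf <- g[g$frame_index == f, , drop = FALSE]
        asg <- per_frame[[k]]$assignments
        matched_gt <- asg$gt_row[asg$status == "tp"]
        is_id <- !gf$ignore & gf$instance_id == id
        tp_i <- tp_i + sum(which(is_id) %in% matched_gt)
        fn_i <- fn_i + sum(is_id & !(seq_len(nrow(gf)) %in% matched_gt))
        fp_all <- fp_all + sum(asg$status == "fp")
      }
      dplyr::bind_cols(
        tibble(video_id = vid, instance_id = id),
        compute_metrics(tibble(tp = tp_i, fp = fp_all, fn = fn_i)))
    })
    dplyr::bind_rows(pooled, per_id)
  })
}

#' Confidence-threshold sweep
#'
#' Evaluates every video at each confidence threshold (0.50 to 0.95 in
#' 0.05 steps by default) and records the median precision, recall and F1
#' across videos (undefined metrics excluded). The selected operating
#' threshold maximises median F1; ties go to the lower threshold.
#' Detectors that carry no confidence (every score 1.0) pass every
#' threshold unchanged.
#'
#' @param dets Detections tibble or CSV path.
#' @param gts Ground-truth tibble or VIA project path.
#' @param thresholds Ascending vector of score thresholds.
#' @param iou_threshold Minimum IoU for a true positive (default 0.50).
#' @return A `cw_sweep` tibble (`threshold`, `median_precision`,
#'   `median_recall`, `median_f1`, `n_videos`) with attribute
#'   `selected_threshold`.
#' @export
threshold_sweep <- function(dets, gts,
                            thresholds = seq(0.50, 0.95, by = 0.05),
                            iou_threshold = 0.5) {
  if (is.character(dets)) dets <- read_detections(dets)
  if (is.character(gts)) gts <- read_via_project(gts)
  stopifnot(!is.unsorted(thresholds))
  sweep <- purrr::map_dfr(thresholds, function(th) {
    ev <- evaluate_video(dets, gts, iou_threshold = iou_threshold,
                         score_threshold = th)
    tibble(threshold = th,
           median_precision = median(ev$precision, na.rm = TRUE),
           median_recall = median(ev$recall, na.rm = TRUE),
           median_f1 = median(ev$f1, na.rm = TRUE),
           n_videos = sum(!is.na(ev$f1)))
  })
  f1 <- ifelse(is.na(sweep$median_f1), -Inf, sweep$median_f1)
  selected <- if (all(!is.finite(f1))) NA_real_ else
    sweep$threshold[which.max(f1)]
  structure(sweep, selected_threshold = selected,
            class = c("cw_sweep", class(sweep)))
}

#' @export
print.cw_sweep <- function(x, ...) {
  NextMethod()
  cat(sprintf("# selected threshold: %s\n",
              format(attr(x, "selected_threshold"))))
  invisible(x)
}

#' Paired per-video comparison of two detection sets
#'
#' Scores two detection streams (e.g. before and after tracking) on the
#' same ground truth and aligns the per-video metrics for paired testing.
#'
#' @param dets_a,dets_b Detections tibbles or CSV paths covering the same
#'   videos.
#' @param gts Ground-truth tibble or VIA project path.
#' @param labels Length-2 condition labels (default
#'   `c("before", "after")`).
#' @inheritParams evaluate_video
#' @return A `cw_comparison` tibble: one row per video with
#'   `precision_<label>`, `recall_<label>`, `f1_<label>` for both
#'   conditions plus `d_precision`, `d_recall`, `d_f1` (second minus
#'   first).
#' @export
compare_before_after <- function(dets_a, dets_b, gts,
                                 labels = c("before", "after"),
                                 iou_threshold = 0.5,
                                 score_threshold = 0) {
  if (is.character(dets_a)) dets_a <- read_detections(dets_a)
  if (is.character(dets_b)) dets_b <- read_detections(dets_b)
  if (!setequal(unique(dets_a$video_id), unique(dets_b$video_id))) {
    abort("compare_before_after: the two detection sets cover different videos")
  }
  ev <- function(d) {
    evaluate_video(d, gts, iou_threshold = iou_threshold,
                   score_threshold = score_threshold)
  }
  a <- ev(dets_a); b <- ev(dets_b)
  metric_cols <- c("precision", "recall", "f1")
  a <- a[c("video_id", metric_cols)]
  b <- b[c("video_id", metric_cols)]
  names(a)[-1] <- paste0(metric_cols, "_", labels[1])
  names(b)[-1] <- paste0(metric_cols, "_", labels[2])
  out <- dplyr::inner_join(a, b, by = "video_id")
  for (mc in metric_cols) {
    out[[paste0("d_", mc)]] <-
      out[[paste0(mc, "_", labels[2])]] - out[[paste0(mc, "_", labels[1])]]
  }
  structure(out, labels = labels,
            class = c("cw_comparison", class(out)))
}

#' Plot a confidence-threshold sweep
#'
#' Median precision against median recall, one point per threshold, the
#' selected threshold highlighted.
#'
#' @param object A `cw_sweep` from [threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cw_sweep <- function(object, ...) {
  sel <- attr(object, "selected_threshold")
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$median_recall,
                                   y = .data$median_precision)) +
    ggplot2::geom_path(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$threshold == sel),
                        size = 2, show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$threshold)),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red",
                                            `FALSE` = "black")) +
    ggplot2::labs(x = "median recall", y = "median precision",
                  title = sprintf("Confidence sweep (selected %.2f)", sel))
}

#' Plot a paired before/after comparison
#'
#' Per-video metric values under both conditions, connected by video.
#'
#' @param object A `cw_comparison` from [compare_before_after()].
#' @param metric One of `"precision"`, `"recall"`, `"f1"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cw_comparison <- function(object, metric = "f1", ...) {
  labels <- attr(object, "labels")
  cols <- paste0(metric, "_", labels)
  df <- tidyr::pivot_longer(as_tibble(object)[c("video_id", cols)],
                            dplyr::all_of(cols),
                            names_to = "condition", values_to = "value")
  df$condition <- factor(sub(paste0("^", metric, "_"), "", df$condition),
                         levels = labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$value,
                                   group = .data$video_id)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(y = metric, x = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
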
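box <- function(x0, y0, x1, y1) {
  tibble::tibble(x_min = x0, y_min = y0, x_max = x1, y_max = y1)
}

gt_row <- function(f, x0, y0, x1, y1, id = "a", ignore = FALSE, vid = "v") {
  tibble::tibble(video_id = vid, frame_index = as.integer(f),
                 instance_id = id, x_min = x0, y_min = y0,
                 x_max = x1, y_max = y1, ignore = ignore)
}

test_that("IoU matches hand geometry and the enumeration oracle", {
  expect_equal(box_iou(box(0, 0, 10, 10), box(0, 0, 10, 10)), 1)
  expect_equal(box_iou(box(0, 0, 10, 10), box(20, 20, 30, 30)), 0)
  expect_equal(box_iou(box(0, 0, 10, 10), box(5, 0, 15, 10)), 50 / 150)

  set.seed(33)
  for (i in 1:60) {
    a <- random_int_box(); b <- random_int_box()
    expect_equal(box_iou(a, b), iou_enumeration_oracle(a, b),
                 tolerance = 1e-12)
    expect_equal(box_iou(a, b), box_iou(b, a))
    expect_gte(box_iou(a, b), 0); expect_lte(box_iou(a, b), 1)
    expect_equal(box_iou(a, a), 1)
  }
})

test_that("frame matching follows the TP/FP/FN and ignore rules", {
  d1 <- cagewatch:::empty_detections()
  g1 <- gt_row(0, 0, 0, 10, 10)
  exact <- tibble::tibble(video_id = "v", frame_index = 0L, x_min = 0,
                          y_min = 0, x_max = 10, y_max = 10, score = 1,
                          track_id = NA_integer_, coasted = FALSE)

  expect_equal(match_frame(exact, g1)$counts,
               tibble::tibble(tp = 1L, fp = 0L, fn = 0L))
  expect_equal(match_frame(exact, g1[0, ])$counts$fp, 1L)
  expect_equal(match_frame(d1, g1)$counts$fn, 1L)

  # two detections on one GT: the higher score takes it, the other is FP
  two <- dplyr::bind_rows(exact, exact)
  two$score <- c(0.8, 0.9)
  two$x_min <- c(0, 1); two$x_max <- c(10, 11)
  m <- match_frame(two, g1)
  expect_equal(m$counts, tibble::tibble(tp = 1L, fp = 1L, fn = 0L))
  expect_equal(m$assignments$status[2], "tp")

  # a detection on an ignored instance is scored as nothing at all
  gi <- gt_row(0, 0, 0, 10, 10, id = "neighbour", ignore = TRUE)
  mi <- match_frame(exact, gi)
  expect_equal(mi$counts, tibble::tibble(tp = 0L, fp = 0L, fn = 0L))
  expect_equal(mi$assignments$status, "ignored")
})

test_that("conservation: tp + fn covers non-ignored GT; dets are partitioned", {
  set.seed(34)
  for (i in 1:25) {
    nd <- sample(0:6, 1); ng <- sample(0:6, 1)
    dets <- if (nd) dplyr::bind_rows(lapply(seq_len(nd), function(j) {
      b <- random_int_box(40, 25)
      tibble::tibble(video_id = "v", frame_index = 0L, x_min = b$x_min,
                     y_min = b$y_min, x_max = b$x_max, y_max = b$y_max,
                     score = runif(1), track_id = NA_integer_,
                     coasted = FALSE)
    })) else cagewatch:::empty_detections()
    gts <- if (ng) dplyr::bind_rows(lapply(seq_len(ng), function(j) {
      b <- random_int_box(40, 25)
      gt_row(0, b$x_min, b$y_min, b$x_max, b$y_max,
             id = letters[j], ignore = runif(1) < 0.3)
    })) else gt_row(0, 0, 0, 1, 1)[0, ]
    m <- match_frame(dets, gts)
    expect_equal(m$counts$tp + m$counts$fn, sum(!gts$ignore))
    expect_equal(m$counts$tp + m$counts$fp +
                   sum(m$assignments$status == "ignored"), nd)
  }
})

test_that("precision/recall/F1 arithmetic and undefined cases", {
  r <- compute_metrics(tibble::tibble(tp = 90, fp = 10, fn = 10))
  expect_equal(c(r$precision, r$recall, r$f1), c(0.9, 0.9, 0.9))
  expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall),
               tolerance = 1e-12)

  z <- compute_metrics(tibble::tibble(tp = 0, fp = 0, fn = 0))
  expect_true(all(is.na(c(z$precision, z$recall, z$f1))))

  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0, 0.5), 0)
})

test_that("video evaluation micro-aggregates and scopes per individual", {
  sc <- tiny_scene(seed = 41, n_frames = 50L)
  perfect <- corrupt_detections(sc$gt, frame_size = c(160L, 90L))
  ev <- evaluate_video(perfect, sc$gt)
  expect_equal(c(ev$precision, ev$recall, ev$f1), c(1, 1, 1))

  # delete exactly 10% of GT boxes: recall 0.9, precision stays 1
  n <- nrow(perfect)
  drop <- seq_len(n) %in% sample(n, round(0.1 * n))
  ev2 <- evaluate_video(perfect[!drop, ], sc$gt)
  expect_equal(ev2$precision, 1)
  expect_equal(ev2$recall, 0.9, tolerance = 0.01)

  # paired subjects: one pooled record plus one per individual
  sc2 <- tiny_scene(seed = 42, n_frames = 40L, n_subjects = 2L)
  d2 <- corrupt_detections(sc2$gt, frame_size = c(160L, 90L))
  d2 <- d2[!(d2$frame_index < 10 &
               d2$x_min %in% sc2$gt$x_min[sc2$gt$instance_id == "subject_2"]), ]
  ev3 <- evaluate_video(d2, sc2$gt, per_individual = TRUE)
  expect_setequal(ev3$instance_id, c("all", "subject_1", "subject_2"))
  expect_equal(ev3$recall[ev3$instance_id == "subject_1"], 1)
  expect_lt(ev3$recall[ev3$instance_id == "subject_2"], 1)

  stray <- perfect
  stray$video_id <- "unannotated_video"
  expect_error(evaluate_video(stray, sc$gt), "absent from ground truth")
})

test_that("video evaluation equals a brute-force per-frame recount", {
  sc <- tiny_scene(seed = 43, n_frames = 30L)
  dets <- corrupt_detections(sc$gt, dropout_rate = 0.15, fp_rate = 0.3,
                             jitter_px = 2, seed = 44,
                             frame_size = c(160L, 90L))
  ev <- evaluate_video(dets, sc$gt)
  counts <- c(tp = 0L, fp = 0L, fn = 0L)
  for (f in 0:29) {
    m <- match_frame(dets[dets$frame_index == f, ],
                     sc$gt[sc$gt$frame_index == f, ])
    counts <- counts + unlist(m$counts)
  }
  expect_equal(ev$tp, counts[["tp"]])
  expect_equal(ev$fp, counts[["fp"]])
  expect_equal(ev$fn, counts[["fn"]])
})

test_that("recall never increases with the score threshold", {
  sc <- tiny_scene(seed = 45, n_frames = 40L)
  dets <- corrupt_detections(sc$gt, dropout_rate = 0.1, fp_rate = 0.4,
                             seed = 46, frame_size = c(160L, 90L))
  rec <- vapply(seq(0.5, 0.95, 0.05), function(th) {
    evaluate_video(dets, sc$gt, score_threshold = th)$recall
  }, numeric(1))
  expect_true(all(diff(rec) <= 1e-12))
})

test_that("the sweep finds the constructed FP/TP separation", {
  sc <- tiny_scene(seed = 47, n_frames = 60L)
  all_one <- corrupt_detections(sc$gt, frame_size = c(160L, 90L))
  sw0 <- threshold_sweep(all_one, sc$gt)
  expect_equal(nrow(sw0), 10L)
  expect_equal(length(unique(sw0$median_f1)), 1L)
  expect_equal(attr(sw0, "selected_threshold"), 0.50)

  # TP scores in [0.72, 1], FP scores in [0.5, 0.68]: as the threshold
  # passes 0.70 all FPs are gone while no TP has been lost
  dets <- corrupt_detections(sc$gt, fp_rate = 0.6, seed = 48,
                             frame_size = c(160L, 90L))
  sw <- threshold_sweep(dets, sc$gt)
  expect_gte(attr(sw, "selected_threshold"), 0.70)
  below <- sw$median_precision[sw$threshold <= 0.7]
  expect_true(all(diff(below) > 0))
  expect_equal(length(unique(sw$median_recall[sw$threshold <= 0.7])), 1L)

  # thresholds above every score give an undefined (empty) sweep point
  sparse <- all_one; sparse$score <- 0.6
  swp <- threshold_sweep(sparse, sc$gt)
  expect_true(is.na(swp$median_precision[swp$threshold == 0.95]))
})

test_that("before/after comparison aligns videos and signs the deltas", {
  sc <- tiny_scene(seed = 49, n_frames = 80L)
  dets <- corrupt_detections(sc$gt, dropout_rate = 0.1, seed = 50,
                             frame_size = c(160L, 90L))
  same <- compare_before_after(dets, dets, sc$gt)
  expect_equal(same$d_f1, 0)

  tracked <- run_tracker(dets, n_frames = 80L)
  cmp <- compare_before_after(dets, tracked, sc$gt)
  expect_gt(cmp$d_recall, 0)

  # a persistent-then-vanishing FP is propagated by the tracker,
  # dragging precision down relative to the untracked stream
  fp <- dets[1, ]
  fp$x_min <- 120; fp$x_max <- 150; fp$y_min <- 10; fp$y_max <- 40
  fps <- dplyr::bind_rows(lapply(0:20, function(f) {
    fp$frame_index <- f; fp
  }))
  with_fp <- dplyr::arrange(dplyr::bind_rows(dets, fps), frame_index)
  tracked_fp <- run_tracker(with_fp, n_frames = 80L)
  cmp2 <- compare_before_after(with_fp, tracked_fp, sc$gt)
  expect_lt(cmp2$d_precision, 0)

  other <- dets; other$video_id <- "other"
  expect_error(compare_before_after(dets, other, sc$gt), "different videos")
})
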
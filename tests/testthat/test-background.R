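const_bg_model <- function(v = 77, h = 90L, w = 160L, ...) {
  frames <- replicate(12, array(v, c(h, w, 3L)), simplify = FALSE)
  build_background(new_video(frames),
                   bg_params(target_size = c(w, h), ...))
}

test_that("background of identical constant frames is that constant", {
  m <- const_bg_model(77)
  expect_true(all(m$image == 77))
})

test_that("group percentile uses the lower-value rule", {
  # one group of 10 frames; channel values 0 (x3) and 200 (x7):
  # the 70th percentile under the lower rule is the 7th order statistic
  frames <- c(replicate(3, array(0, c(4L, 4L, 3L)), simplify = FALSE),
              replicate(7, array(200, c(4L, 4L, 3L)), simplify = FALSE))
  m <- build_background(new_video(frames),
                        bg_params(target_size = c(4L, 4L), blur_kernel = 1L))
  expect_true(all(m$image == 200))
})

test_that("a blob covering a pixel in <30% of frames vanishes from the background", {
  set.seed(31)
  h <- 30L; w <- 40L
  sm <- t(EBImage::imageData(EBImage::gblur(
    EBImage::Image(t(matrix(runif(h * w), h, w))), sigma = 4)))
  sm <- (sm - min(sm)) / diff(range(sm))
  B <- array(rep(30 + sm * 60, 3L), c(h, w, 3L))
  frames <- lapply(seq_len(60L), function(i) {
    f <- B
    if (i <= 15L) f[8:18, 10:22, ] <- 230  # blob in 25% of frames
    f
  })
  m <- build_background(new_video(frames),
                        bg_params(target_size = c(w, h)))
  blurB <- round(cagewatch:::blur_frame(B, 5L))
  expect_lte(max(abs(m$image - blurB)), 2)
})

test_that("shuffling frames within one percentile group changes nothing", {
  set.seed(8)
  frames <- replicate(20, array(sample(0:255, 8 * 8 * 3, TRUE), c(8L, 8L, 3L)),
                      simplify = FALSE)
  p <- bg_params(target_size = c(8L, 8L), blur_kernel = 1L)
  m1 <- build_background(new_video(frames), p)
  m2 <- build_background(new_video(frames[sample(20)]), p)
  expect_identical(m1$image, m2$image)
})

test_that("background synthesis refuses zero frames", {
  expect_error(build_background(list(), bg_params()), "no sampled frames")
})

test_that("foreground extraction separates contrast, tolerates noise", {
  m <- const_bg_model(77)
  B <- array(77, c(90L, 160L, 3L))

  expect_false(any(subtract_background(B, m)))

  patch <- B; patch[30:59, 50:79, ] <- 77 + 120
  fg <- subtract_background(patch, m)
  in_patch <- matrix(FALSE, 90, 160); in_patch[30:59, 50:79] <- TRUE
  expect_gte(mean(fg[in_patch]), 0.95)
  expect_gte(mean(!fg[!in_patch]), 0.99)

  set.seed(9)
  noisy <- B + array(sample(-2:2, length(B), TRUE), dim(B))
  expect_lt(mean(subtract_background(noisy, m)), 0.01)
})

test_that("shadow-like darkening is mapped back to background", {
  m <- const_bg_model(140)
  shadowed <- array(140 * 0.7, c(90L, 160L, 3L))  # uniform 30% darkening
  expect_false(any(subtract_background(shadowed, m)))
  m_off <- const_bg_model(140, detect_shadows = FALSE)
  expect_true(all(subtract_background(shadowed, m_off)))
})

test_that("mask refinement merges bridged blobs and drops specks", {
  expect_equal(refine_mask(matrix(FALSE, 40, 60)), list())

  # two 12x12 squares 6 px apart: closing (disc 5, 2 iterations) bridges
  # the gap, so their hulls overlap and merge into one cluster
  two <- matrix(FALSE, 40, 60)
  two[10:21, 10:21] <- TRUE
  two[10:21, 28:39] <- TRUE
  cl <- refine_mask(two, min_area = 50)
  expect_length(cl, 1L)
  expect_true(cl[[1]]$box$x_min <= 9 + 1 && cl[[1]]$box$x_max >= 39 - 1)
  # the merged hull spans both squares' interiors (morphology may shave
  # up to kernel-radius pixels off the outer corners)
  expect_true(all(cl[[1]]$mask[12:19, 12:19]))
  expect_true(all(cl[[1]]$mask[12:19, 30:37]))
  expect_true(all(cl[[1]]$mask[12:19, 22:27]))  # and bridges the gap

  # a 200 px^2 blob survives min_area = 50; a 3x3 speck does not
  blob_speck <- matrix(FALSE, 40, 60)
  blob_speck[5:18, 5:19] <- TRUE   # 14 x 15
  blob_speck[30:32, 50:52] <- TRUE
  cl2 <- refine_mask(blob_speck, min_area = 50)
  expect_length(cl2, 1L)
  expect_gte(cl2[[1]]$area, 200)
})

test_that("raising min_area never increases the cluster count", {
  set.seed(12)
  for (rep in 1:5) {
    mask <- matrix(runif(50 * 70) < 0.12, 50, 70)
    counts <- vapply(c(0, 20, 50, 100, 200, 500),
                     function(a) length(refine_mask(mask, min_area = a)),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("detect_frame localises inserted rectangles and merges overlaps", {
  m <- const_bg_model(60, h = 720L, w = 1280L)
  B <- array(60, c(720L, 1280L, 3L))

  expect_equal(nrow(detect_frame(B, m)), 0L)

  one <- B; one[101:300, 201:400, ] <- 220
  d1 <- detect_frame(one, m, min_area = 2000)
  expect_equal(nrow(d1), 1L)
  truth <- list(x_min = 200, y_min = 100, x_max = 400, y_max = 300)
  expect_gte(box_iou(d1, truth), 0.8)
  expect_equal(d1$score, 1.0)

  # two rectangles overlapping by half their area fuse into one detection
  two <- B
  two[101:300, 201:400, ] <- 220
  two[101:300, 301:500, ] <- 200
  d2 <- detect_frame(two, m, min_area = 2000)
  expect_equal(nrow(d2), 1L)
})

test_that("output boxes always satisfy box invariants within the frame", {
  sc <- tiny_scene(seed = 13, n_frames = 40L)
  dets <- run_be_pipeline(sc$video, tiny_bg_params(), min_area = 40)
  expect_gt(nrow(dets), 0)
  validate_boxes(dets)
  expect_true(all(dets$x_min >= 0 & dets$y_min >= 0 &
                    dets$x_max <= 160 & dets$y_max <= 90))
})

test_that("the pipeline is deterministic and silent on static scenes", {
  frames <- replicate(50, array(95, c(90L, 160L, 3L)), simplify = FALSE)
  static <- new_video(frames, video_id = "static")
  expect_equal(nrow(run_be_pipeline(static, tiny_bg_params(), min_area = 40)),
               0L)

  sc <- tiny_scene(seed = 14, n_frames = 40L)
  d1 <- run_be_pipeline(sc$video, tiny_bg_params(), min_area = 40)
  d2 <- run_be_pipeline(sc$video, tiny_bg_params(), min_area = 40)
  expect_identical(d1, d2)
})

test_that("a moving subject is tracked frame-by-frame, a frozen one absorbed", {
  sc <- tiny_scene(seed = 15, n_frames = 60L)
  dets <- run_be_pipeline(sc$video, tiny_bg_params(), min_area = 40)
  expect_gte(frame_hit_rate(dets, sc$gt, 60L), 0.9)

  spec <- cagewatch:::default_subject(scene_config(width = 160L, height = 90L),
                                      1L)
  spec$waypoints <- rbind(c(80, 45), c(80, 45))
  spec$speed <- 0; spec$deform_amplitude <- 0
  frozen <- render_scene(scene_config(width = 160L, height = 90L,
                                      n_frames = 60L, subjects = list(spec),
                                      seed = 15, video_id = "frozen"))
  dets_f <- run_be_pipeline(frozen$video, tiny_bg_params(), min_area = 40)
  expect_lte(frame_hit_rate(dets_f, frozen$gt, 60L), 0.05)
})
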
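test_that("rendered videos carry exact per-frame ground truth", {
  segments <- data.frame(zone = "left", start_s = c(0, 10, 20),
                         end_s = c(10, 20, 30),
                         present = c(TRUE, FALSE, TRUE),
                         displacement = c(0, 0, 1))
  script <- video_script(30, 4, 160, 180, segments)
  path <- file.path(tempdir(), "truthy.tif")
  vid <- render_video(script, out_path = path, zones = list(
    cage_zone("left", 0, 0, 160, 180)), anchors = list(left = c(80, 90)),
    seed = 3)

  expect_equal(vid$stream$n_frames, 120)
  expect_equal(nrow(vid$truth), 120)
  expect_true(file.exists(paste0(path, ".truth.csv")))

  absent <- vid$truth[!vid$truth$present, ]
  expect_equal(nrow(absent), 40)
  expect_true(all(is.na(absent$eye_x)))
  expect_true(all(is.na(absent$ear_w)))

  present <- vid$truth[vid$truth$present, ]
  expect_true(all(present$eye_w > 0 & present$ear_w > 0))

  # ground-truth boxes tightly bound shapes darker than the backdrop
  fr <- read_frames(vid$stream, 0L)[[1]]
  tr0 <- vid$truth[vid$truth$frame_index == 0, ]
  eye_px <- fr$pixels[(tr0$eye_y + 1):(tr0$eye_y + tr0$eye_h),
                      (tr0$eye_x + 1):(tr0$eye_x + tr0$eye_w)]
  expect_lt(min(eye_px), 100)           # eye pixels present in the box
  # zero-displacement span: consecutive frames are pixel-identical, so
  # the motion floor over the frozen background is exactly 0
  f0 <- read_frames(vid$stream, 0:1)
  expect_equal(f0[[1]]$pixels, f0[[2]]$pixels)

  # ground-truth boxes have IoU 1 with themselves (harness sanity)
  b <- rect(tr0$eye_x, tr0$eye_y, tr0$eye_w, tr0$eye_h)
  expect_equal(rect_iou(b, b), 1)
})

test_that("renders are pure functions of seed and script", {
  segments <- data.frame(zone = "left", start_s = 0, end_s = 4,
                         present = TRUE, displacement = 0.5)
  script <- video_script(4, 4, 96, 96, segments)
  zones <- list(cage_zone("left", 0, 0, 96, 96))
  anchors <- list(left = c(48, 48))
  p1 <- file.path(tempdir(), "rep1.tif")
  p2 <- file.path(tempdir(), "rep2.tif")
  v1 <- render_video(script, out_path = p1, zones = zones, anchors = anchors,
                     seed = 11)
  v2 <- render_video(script, out_path = p2, zones = zones, anchors = anchors,
                     seed = 11)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  expect_identical(v1$truth, v2$truth)
  v3 <- render_video(script, out_path = p2, zones = zones, anchors = anchors,
                     seed = 12)
  expect_false(identical(unname(tools::md5sum(p1)),
                         unname(tools::md5sum(p2))))
})

test_that("segment schedules must tile the stream without overlap", {
  good <- data.frame(zone = "left", start_s = c(0, 10), end_s = c(10, 30),
                     present = TRUE, displacement = 0)
  expect_s3_class(video_script(30, 4, 96, 96, good), "video_script")
  gap <- data.frame(zone = "left", start_s = c(0, 15), end_s = c(10, 30),
                    present = TRUE, displacement = 0)
  expect_error(video_script(30, 4, 96, 96, gap), "tile")
  short <- data.frame(zone = "left", start_s = 0, end_s = 20,
                      present = TRUE, displacement = 0)
  expect_error(video_script(30, 4, 96, 96, short), "tile")
})

test_that("crop sets are seeded, counted, and written with a faithful index", {
  set1 <- make_crop_set(kind = "eye", n_pos = 30, n_neg = 20, seed = 5)
  set2 <- make_crop_set(kind = "eye", n_pos = 30, n_neg = 20, seed = 5)
  expect_length(set1$positives, 30)
  expect_length(set1$negatives, 20)
  expect_identical(set1$positives, set2$positives)
  expect_identical(set1$negatives, set2$negatives)
  expect_identical(set1$index, set2$index)
  expect_false(identical(
    set1$positives,
    make_crop_set(kind = "eye", n_pos = 30, n_neg = 20, seed = 6)$positives))

  dir <- file.path(tempdir(), "crops")
  unlink(dir, recursive = TRUE)
  on_disk <- make_crop_set(kind = "ear", n_pos = 10, n_neg = 10, seed = 2,
                           dir = dir)
  idx <- utils::read.csv(file.path(dir, "index.csv"))
  expect_equal(nrow(idx), 20)
  expect_true(all(file.exists(idx$path)))
  expect_equal(sum(idx$feature_kind == "ear"), 10)
  # written crops reload to the in-memory matrices
  expect_equal(read_image(idx$path[1]), on_disk$positives[[1]])

  expect_error(make_crop_set(n_pos = 0, n_neg = 5, seed = 1), ">= 1")
})

test_that("crop geometry scales with the scale flag", {
  s1 <- make_crop_set(kind = "eye", n_pos = 25, n_neg = 1, seed = 9, scale = 1)
  s2 <- make_crop_set(kind = "eye", n_pos = 25, n_neg = 1, seed = 9, scale = 2)
  ratio_w <- s2$index$bbox_w[1:25] / s1$index$bbox_w[1:25]
  ratio_h <- s2$index$bbox_h[1:25] / s1$index$bbox_h[1:25]
  expect_true(all(abs(ratio_w - 2) < 0.25))
  expect_true(all(abs(ratio_h - 2) < 0.25))
})

test_that("simulated score sheets reflect the condition split", {
  key <- data.frame(blinded_id = sprintf("IMG%03d", 1:30),
                    condition = rep(c("pain", "no_pain"), 15))
  sim <- simulate_scores(key, n_scorers = 4, seed = 21)
  expect_equal(nrow(sim$scores), 120)
  expect_identical(sim$scores, simulate_scores(key, 4, seed = 21)$scores)
  rec <- parse_scores(sim$scores)
  pain_mean <- mean(rec$mean_score[key$condition[
    match(rec$blinded_id, key$blinded_id)] == "pain"])
  base_mean <- mean(rec$mean_score[key$condition[
    match(rec$blinded_id, key$blinded_id)] == "no_pain"])
  expect_gt(pain_mean, base_mean + 0.5)
  expect_true(all(sim$judgments$call %in% c("pain", "no_pain")))
})
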
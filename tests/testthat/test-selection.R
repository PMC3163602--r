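test_that("motion score is the mean absolute zone difference", {
  z <- cage_zone("z", 0, 0, 2, 2)
  f0 <- frame_ref("s", 0, 0, matrix(0, 2, 2))
  f1 <- frame_ref("s", 1, 0.1, matrix(c(10, 0, 0, 0), 2, 2, byrow = TRUE))
  expect_identical(motion_score(f0, f0, z), 0)
  expect_equal(motion_score(f1, f0, z), 2.5)     # (10+0+0+0)/4

  expect_error(motion_score(frame_ref("s", 1, 0, matrix(0, 3, 3)), f0, z),
               "dimensions")

  # pixels outside the zone cannot move the score
  base <- withr::with_seed(6, round(matrix(runif(40 * 40, 0, 255), 40, 40)))
  cur <- base; cur[1:10, 1:10] <- 255 - cur[1:10, 1:10]
  zl <- cage_zone("left", 0, 0, 20, 40)
  a <- motion_score(frame_ref("s", 1, 0, cur), frame_ref("s", 0, 0, base), zl)
  cur2 <- cur; cur2[, 21:40] <- 0                 # edit only the right half
  b <- motion_score(frame_ref("s", 1, 0, cur2), frame_ref("s", 0, 0, base), zl)
  expect_identical(a, b)
})

test_that("motion score increases with scripted displacement", {
  segments <- data.frame(zone = "left",
                         start_s = c(0, 10, 20, 30),
                         end_s = c(10, 20, 30, 40),
                         present = TRUE,
                         displacement = c(0, 0.5, 1.5, 3))
  script <- video_script(40, 5, 160, 180, segments)
  zone <- cage_zone("left", 0, 0, 160, 180)
  vid <- render_video(script, out_path = file.path(tempdir(), "motion.tif"),
                      zones = list(zone), anchors = list(left = c(80, 90)),
                      seed = 9)
  refs <- read_frames(vid$stream)
  scores <- vapply(2:length(refs), function(i) {
    motion_score(refs[[i]], refs[[i - 1]], zone)
  }, 0)
  seg_of <- floor(vapply(refs[-1], `[[`, 0, "timestamp_s") / 10)
  # skip each segment's first frame (position resets at segment start)
  keep <- seg_of == floor(vapply(refs[-length(refs)], `[[`, 0,
                                 "timestamp_s") / 10)
  means <- tapply(scores[keep], seg_of[keep], mean)
  expect_equal(unname(means[["0"]]), 0)          # frozen zone, exact zero
  expect_true(all(diff(unname(means)) > 0))      # strictly increasing
})

test_that("interval bucketing is half-open, anchored at zero, exhaustive", {
  cands <- list(fake_candidate(0, 0, 1), fake_candidate(179.99, 1, 1),
                fake_candidate(180, 2, 1))
  buckets <- bucket_by_interval(cands, 180)
  expect_length(buckets, 2)
  expect_equal(vapply(buckets[[1]]$candidates, function(cf) cf$frame$frame_index,
                      0L), c(0L, 1L))
  expect_equal(buckets[[2]]$candidates[[1]]$frame$frame_index, 2L)

  expect_length(bucket_by_interval(list(), 180), 0)
  # 30-minute stream tiles into 10 intervals, empties included
  buckets30 <- bucket_by_interval(list(fake_candidate(10, 0, 1)), 180,
                                  duration_s = 1800)
  expect_length(buckets30, 10)
  expect_equal(vapply(buckets30, `[[`, 0L, "interval_index"), 0:9)
  expect_error(bucket_by_interval(cands, 0), "positive")

  # conservation: every candidate in exactly one bucket
  many <- withr::with_seed(8, lapply(1:100, function(i) {
    fake_candidate(runif(1, 0, 900), i, 1)
  }))
  bks <- bucket_by_interval(many, 180, duration_s = 900)
  expect_equal(sum(lengths(lapply(bks, `[[`, "candidates"))), 100)
  idx <- unlist(lapply(bks, function(b) {
    vapply(b$candidates, function(cf) cf$frame$frame_index, 0L)
  }))
  expect_equal(sort(idx), 1:100)
})

test_that("stillest-frame selection equals a brute-force stable sort", {
  b <- bucket_by_interval(list(
    fake_candidate(1, 10, 5.0), fake_candidate(2, 11, 1.0),
    fake_candidate(3, 12, 3.0), fake_candidate(4, 13, 2.0)), 180)[[1]]
  sel <- select_stillest(b)
  expect_equal(vapply(sel$selected, `[[`, 0, "motion_score"), c(1, 2, 3))
  expect_false(sel$sparse)

  # fewer candidates than k: all selected, flagged sparse
  b2 <- bucket_by_interval(list(fake_candidate(1, 0, 2),
                                fake_candidate(2, 1, 1)), 180)[[1]]
  expect_message(sel2 <- select_stillest(b2, k = 3), "sparse")
  expect_length(sel2$selected, 2)
  expect_true(sel2$sparse)

  # seeded random buckets against the brute-force oracle, ties included
  for (seed in 1:50) {
    cands <- withr::with_seed(seed, {
      n <- sample(0:50, 1)
      lapply(seq_len(n), function(i) {
        fake_candidate(runif(1, 0, 179), i, sample(1:10, 1) / 2)
      })
    })
    b <- bucket_by_interval(cands, 180, duration_s = 180)[[1]]
    sel <- suppressMessages(select_stillest(b, k = 3))
    scores <- vapply(cands, `[[`, 0, "motion_score")
    idx <- vapply(cands, function(cf) cf$frame$frame_index, 0L)
    oracle <- order(scores, idx)[seq_len(min(3, length(cands)))]
    expect_equal(vapply(sel$selected, function(cf) cf$frame$frame_index, 0L),
                 idx[oracle])
  }
})

test_that("selection ignores unrankable frames and high-motion additions", {
  # first frame of a stream has no motion score: excluded, logged
  b <- bucket_by_interval(list(fake_candidate(0, 0, NA_real_),
                               fake_candidate(1, 1, 2),
                               fake_candidate(2, 2, 1)), 180)[[1]]
  expect_message(sel <- select_stillest(b, k = 2), "without motion score")
  expect_equal(vapply(sel$selected, function(cf) cf$frame$frame_index, 0L),
               c(2L, 1L))

  # monotonicity: adding a candidate stiller than none changes nothing
  base <- list(fake_candidate(1, 1, 1), fake_candidate(2, 2, 2),
               fake_candidate(3, 3, 3))
  sel_base <- select_stillest(bucket_by_interval(base, 180)[[1]])
  more <- c(base, list(fake_candidate(4, 4, 99)))
  sel_more <- select_stillest(bucket_by_interval(more, 180)[[1]])
  expect_equal(
    vapply(sel_base$selected, function(cf) cf$frame$frame_index, 0L),
    vapply(sel_more$selected, function(cf) cf$frame$frame_index, 0L))
})

test_that("the gap report lists exactly the empty intervals", {
  cands <- lapply(c(10, 200, 250, 1000, 1500), function(t) {
    fake_candidate(t, round(t), 1)
  })
  buckets <- bucket_by_interval(cands, 180, duration_s = 1800)
  gaps <- report_gaps(buckets)
  expect_equal(gaps$interval_index, c(2L, 3L, 4L, 6L, 7L, 9L))

  # no empty intervals -> empty report
  full <- bucket_by_interval(lapply(0:9, function(i) {
    fake_candidate(i * 180 + 1, i, 1)
  }), 180, duration_s = 1800)
  expect_equal(nrow(report_gaps(full)), 0)

  # machine-readable CSV
  path <- file.path(tempdir(), "gaps.csv")
  report_gaps(buckets, path)
  expect_equal(utils::read.csv(path)$interval_index,
               c(2L, 3L, 4L, 6L, 7L, 9L))
})
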
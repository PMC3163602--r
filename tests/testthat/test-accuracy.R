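make_judgments <- function(truth, calls, scorer = "s1") {
  data.frame(blinded_id = truth$blinded_id, scorer_id = scorer, call = calls)
}

test_that("confusion summaries follow the signal-detection definitions", {
  truth <- data.frame(blinded_id = sprintf("i%02d", 1:10),
                      condition = rep(c("pain", "no_pain"), each = 5))
  # perfect scorer
  perfect <- signal_detection(make_judgments(truth, truth$condition), truth)
  expect_equal(perfect$pooled$accuracy, 100)
  expect_equal(perfect$pooled$miss_rate, 0)
  expect_equal(perfect$pooled$false_alarm_rate, 0)

  # 100 photos, 50/50, 6 misses and 4 false alarms
  truth100 <- data.frame(blinded_id = sprintf("i%03d", 1:100),
                         condition = rep(c("pain", "no_pain"), each = 50))
  calls <- truth100$condition
  calls[1:6] <- "no_pain"      # miss 6 pain photos
  calls[51:54] <- "pain"       # false-alarm 4 no-pain photos
  res <- signal_detection(make_judgments(truth100, calls), truth100)
  expect_equal(res$pooled$accuracy, 90)
  expect_equal(res$pooled$miss_rate, 6)
  expect_equal(res$pooled$false_alarm_rate, 4)
  expect_equal(res$pooled$hits, 44)
  expect_equal(res$pooled$correct_rejections, 46)

  expect_error(
    signal_detection(data.frame(blinded_id = "zz", scorer_id = "s",
                                call = "pain"), truth),
    "without a truth label")
  expect_error(
    signal_detection(make_judgments(truth, rep("maybe", 10)), truth),
    "'pain' or 'no_pain'")
})

test_that("counts partition and rates are percentages of all judgments", {
  for (seed in 1:60) {
    dat <- withr::with_seed(seed, {
      n <- sample(10:80, 1)
      truth <- data.frame(blinded_id = sprintf("i%03d", 1:n),
                          condition = sample(c("pain", "no_pain"), n,
                                             replace = TRUE))
      scorers <- sprintf("s%d", 1:sample(2:5, 1))
      j <- do.call(rbind, lapply(scorers, function(s) {
        make_judgments(truth, sample(c("pain", "no_pain"), n, replace = TRUE),
                       s)
      }))
      list(truth = truth, judgments = j)
    })
    res <- signal_detection(dat$judgments, dat$truth)
    p <- res$pooled
    expect_equal(p$hits + p$misses + p$false_alarms + p$correct_rejections,
                 p$n)
    n_pain <- sum(dat$truth$condition == "pain") *
      length(unique(dat$judgments$scorer_id))
    expect_equal(p$hits + p$misses, n_pain)
    expect_equal(p$false_alarms + p$correct_rejections, p$n - n_pain)
    expect_equal(p$hit_rate + p$miss_rate + p$false_alarm_rate +
                   p$correct_rejection_rate, 100)
    expect_equal(p$accuracy, p$hit_rate + p$correct_rejection_rate)
  }
})

test_that("pooled accuracy is the scorer mean when image sets coincide", {
  truth <- data.frame(blinded_id = sprintf("i%03d", 1:40),
                      condition = rep(c("pain", "no_pain"), 20))
  j <- withr::with_seed(99, do.call(rbind, lapply(sprintf("s%d", 1:6),
    function(s) {
      make_judgments(truth, sample(c("pain", "no_pain"), 40, replace = TRUE),
                     s)
    })))
  res <- signal_detection(j, truth)
  expect_equal(res$pooled$accuracy, mean(res$per_scorer$accuracy))
})

ratings_fixture <- function(animal_scores) {
  # animal_scores: list(animal -> c(pain, no_pain)) unit-level means;
  # build a ratings_matrix with one image per animal x condition and
  # two scorers agreeing exactly.
  key <- do.call(rbind, lapply(names(animal_scores), function(a) {
    data.frame(blinded_id = paste0(a, c("_p", "_b")), image_path = "x",
               animal = a, condition = c("pain", "no_pain"))
  }))
  vals <- unlist(lapply(animal_scores, function(v) v))
  scores <- matrix(rep(vals, 2), ncol = 2,
                   dimnames = list(key$blinded_id, c("s1", "s2")))
  units <- lapply(grimace:::rgs_units, function(u) scores)
  names(units) <- grimace:::rgs_units
  structure(list(scores = scores, units = units, key = key,
                 flagged_scorers = character(0)),
            class = "ratings_matrix")
}

test_that("difference scores are pain minus baseline, with SEM over animals", {
  rm <- ratings_fixture(list(r1 = c(1.4, 0.4), r2 = c(1.6, 0.6),
                             r3 = c(1.2, 0.2)))
  d <- difference_scores(rm)
  expect_equal(nrow(d), 5)              # four units + the average
  avg <- d[d$action_unit == "average", ]
  expect_equal(avg$delta, 1.0)
  expect_equal(avg$pain_mean, 1.4)
  expect_equal(avg$no_pain_mean, 0.4)
  expect_equal(avg$sem, 0)              # identical per-animal deltas
  expect_equal(avg$n_animals, 3)
  expect_true(all(d$delta >= -2 & d$delta <= 2))

  # identical pain and baseline: delta 0, SEM 0
  d0 <- difference_scores(ratings_fixture(list(r1 = c(0.7, 0.7),
                                               r2 = c(0.7, 0.7))))
  expect_equal(d0$delta, rep(0, 5))
  expect_equal(d0$sem, rep(0, 5))
})

test_that("animals missing a condition are excluded with a warning", {
  rm <- ratings_fixture(list(r1 = c(1.4, 0.4), r2 = c(1.5, 0.5)))
  rm$key <- rm$key[-4, ]                # drop r2 baseline image
  rm$scores <- rm$scores[-4, ]
  rm$units <- lapply(rm$units, function(u) u[-4, ])
  expect_warning(d <- difference_scores(rm), "r2")
  expect_equal(d$n_animals, rep(1, 5))
  expect_equal(d[d$action_unit == "average", "delta"], 1.0)
})

test_that("simulated cohorts recover the generating effect sizes", {
  effects <- c(orbital_tightening = 1.1, nose_cheek_flattening = 0.8,
               ear_changes = 1.0, whisker_change = 0.9)
  n_animals <- 20
  key <- do.call(rbind, lapply(seq_len(n_animals), function(a) {
    data.frame(blinded_id = sprintf("a%02d%s", a, c("p", "b")),
               image_path = "x", animal = sprintf("a%02d", a),
               condition = c("pain", "no_pain"))
  }))
  units <- withr::with_seed(17, {
    lapply(seq_along(effects), function(u) {
      vals <- ifelse(key$condition == "pain", 0.4 + effects[u], 0.4) +
        rnorm(nrow(key), 0, 0.25)
      matrix(rep(pmin(pmax(vals, 0), 2), 3), ncol = 3,
             dimnames = list(key$blinded_id, c("s1", "s2", "s3")))
    })
  })
  names(units) <- names(effects)
  scores <- Reduce(`+`, units) / 4
  rm <- structure(list(scores = scores, units = units, key = key,
                       flagged_scorers = character(0)),
                  class = "ratings_matrix")
  d <- difference_scores(rm)
  for (u in names(effects)) {
    row <- d[d$action_unit == u, ]
    expect_lt(abs(row$delta - effects[[u]]), 2 * row$sem + 1e-9)
  }
})
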
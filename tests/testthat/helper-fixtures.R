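# Shared fixtures, built once per test run and cached. Everything is
# generated in code with fixed seeds; nothing is read from disk except what
# the pipeline itself writes to tempdir().

fixture_env <- new.env(parent = emptyenv())

# Default-condition cascades (eye + ear), trained once.
get_models <- function() {
  if (is.null(fixture_env$models)) {
    fixture_env$models <- train_default_cascades(seed = 42)
  }
  fixture_env$models
}

# Default 6-minute fixture video + full extraction run, computed once.
get_default_run <- function() {
  if (is.null(fixture_env$run)) {
    dir <- file.path(tempdir(), "grimace-default-run")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    vid <- render_video(default_video_script(),
                        out_path = file.path(dir, "video.tif"), seed = 5)
    ex <- suppressMessages(
      run_extraction(vid$stream, default_zones(), get_models(),
                     out_dir = file.path(dir, "out"))
    )
    fixture_env$run <- list(video = vid, extraction = ex, dir = dir)
  }
  fixture_env$run
}

# A short two-zone script for unit-level pipeline tests: 60 s at 5 fps,
# 30 s intervals, one fully face-free interval per zone.
short_script <- function() {
  segments <- rbind(
    data.frame(zone = "left", start_s = c(0, 30), end_s = c(30, 60),
               present = c(TRUE, FALSE), displacement = c(0, 0)),
    data.frame(zone = "right", start_s = c(0, 30), end_s = c(30, 60),
               present = c(FALSE, TRUE), displacement = c(0, 1))
  )
  video_script(60, 5, 320, 180, segments)
}

# Minimal candidate stub for bucketing/selection tests (only the fields
# those operations read).
fake_candidate <- function(timestamp_s, frame_index, motion_score = NA_real_,
                           zone_label = "left") {
  structure(
    list(frame = list(frame_index = as.integer(frame_index),
                      timestamp_s = timestamp_s),
         zone_label = zone_label, motion_score = motion_score),
    class = "candidate_frame"
  )
}

# Flat background frame with seeded sensor noise.
noise_frame <- function(seed, w = 160, h = 180, mean = 200, sd = 3) {
  withr::with_seed(seed, {
    round(matrix(pmin(pmax(rnorm(w * h, mean, sd), 0), 255), h, w))
  })
}

# Independent direct-summation two-way mean squares (the ICC oracle):
# plain sums over the subjects x raters table, no model fitting.
icc_oracle_ms <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  c(msr = ss_rows / (n - 1), msc = ss_cols / (k - 1),
    mse = ss_err / ((n - 1) * (k - 1)))
}

# Ratios are meaningful only when subjects actually differ: with a zero
# between-subject mean square the coefficients degenerate to -Inf and any
# floating-point jitter dominates, so sweeps skip those matrices (the mean
# squares themselves are still compared).
icc_comparable <- function(m) {
  if (stats::var(as.vector(m)) < 1e-12) return(FALSE)
  ms <- icc_oracle_ms(m)
  n <- nrow(m); k <- ncol(m)
  msr <- ms[["msr"]]; msc <- ms[["msc"]]; mse <- ms[["mse"]]
  dens <- c(msr,
            msr + (msc - mse) / n,
            msr + (k - 1) * mse + k * (msc - mse) / n,
            msr + (k - 1) * mse)
  all(abs(dens) > 1e-6)
}

icc_oracle <- function(m) {
  ms <- icc_oracle_ms(m)
  n <- nrow(m); k <- ncol(m)
  msr <- ms[["msr"]]; msc <- ms[["msc"]]; mse <- ms[["mse"]]
  c(single_absolute = (msr - mse) /
      (msr + (k - 1) * mse + k * (msc - mse) / n),
    average_absolute = (msr - mse) / (msr + (msc - mse) / n),
    single_consistency = (msr - mse) / (msr + (k - 1) * mse),
    average_consistency = (msr - mse) / msr)
}
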
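#' @useDynLib grimace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- Haar-like features -----------------------------------------------------
#
# A Haar-like feature is a small set of axis-aligned rectangles with +/-
# weights inside a square base window; its raw value is the weighted sum of
# pixel sums over the rectangles, computed in O(1) from an integral image.
# Values are contrast-normalized by the window's intensity standard deviation
# (and window area, which makes the value scale-free when the window is
# rescaled during multi-scale scanning).
#
# Feature rectangles are stored as an k x 5 matrix (x, y, w, h, weight) in
# base-window coordinates, 0-based, half-open.

# Enumerate the full pool of two-, three- and four-rectangle features for a
# square window of side `window`. Returns a list of k x 5 matrices.
haar_feature_pool <- function(window) {
  pool <- list()
  add <- function(m) pool[[length(pool) + 1L]] <<- m
  for (w in 1:window) {
    for (h in 1:window) {
      for (x in 0:(window - w)) {
        for (y in 0:(window - h)) {
          if (w %% 2 == 0) {      # two-rect, left/right
            hw <- w / 2
            add(rbind(c(x, y, hw, h, 1), c(x + hw, y, hw, h, -1)))
          }
          if (h %% 2 == 0) {      # two-rect, top/bottom
            hh <- h / 2
            add(rbind(c(x, y, w, hh, 1), c(x, y + hh, w, hh, -1)))
          }
          if (w %% 3 == 0) {      # three-rect, horizontal (dark center)
            tw <- w / 3
            add(rbind(c(x, y, tw, h, 1), c(x + tw, y, tw, h, -2),
                      c(x + 2 * tw, y, tw, h, 1)))
          }
          if (h %% 3 == 0) {      # three-rect, vertical
            th <- h / 3
            add(rbind(c(x, y, w, th, 1), c(x, y + th, w, th, -2),
                      c(x, y + 2 * th, w, th, 1)))
          }
          if (w %% 2 == 0 && h %% 2 == 0) {  # four-rect checkerboard
            hw <- w / 2; hh <- h / 2
            add(rbind(c(x, y, hw, hh, 1), c(x + hw, y, hw, hh, -1),
                      c(x, y + hh, hw, hh, -1), c(x + hw, y + hh, hw, hh, 1)))
          }
        }
      }
    }
  }
  pool
}

# ---- Decision stumps and AdaBoost -------------------------------------------

# Find the best stump over all feature columns for sample weights wts.
# F: n x m value matrix; y: 0/1 labels; ord: n x m order() matrix computed
# once. Predict positive iff pol * value <= pol * thr.
best_stump <- function(F, y, wts, ord) {
  n <- nrow(F); m <- ncol(F)
  total_pos <- sum(wts[y == 1])
  total_neg <- sum(wts[y == 0])
  best <- list(err = Inf)
  for (j in seq_len(m)) {
    o <- ord[, j]
    ws <- wts[o]; ys <- y[o]
    cum_pos <- cumsum(ws * ys)
    cum_neg <- cumsum(ws * (1 - ys))
    # threshold after sorted position i: predict pos for values <= v_i
    err_le <- cum_neg + (total_pos - cum_pos)   # pol = +1
    err_ge <- cum_pos + (total_neg - cum_neg)   # pol = -1
    i1 <- which.min(err_le); i2 <- which.min(err_ge)
    if (err_le[i1] < best$err) {
      best <- list(err = err_le[i1], feature = j, thr = F[o[i1], j], pol = 1)
    }
    if (err_ge[i2] < best$err) {
      best <- list(err = err_ge[i2], feature = j, thr = F[o[i2], j], pol = -1)
    }
  }
  best
}

stump_predict <- function(values, thr, pol) {
  as.numeric(pol * values <= pol * thr)
}

# One boosted stage: AdaBoost with stumps until the stage, thresholded to
# keep hit rate >= stage_hit on positives, has false-alarm rate <=
# stage_max_fa on the stage negatives (or max_rounds reached).
train_stage <- function(F, y, ord, stage_hit, stage_max_fa, max_rounds,
                        min_rounds = 1L, margin_frac = 0) {
  n <- nrow(F)
  wts <- ifelse(y == 1, 0.5 / sum(y == 1), 0.5 / sum(y == 0))
  weaks <- list()
  score <- numeric(n)
  for (round in seq_len(max_rounds)) {
    st <- best_stump(F, y, wts, ord)
    err <- min(max(st$err, 1e-10), 1 - 1e-10)
    beta <- err / (1 - err)
    alpha <- log(1 / beta)
    pred <- stump_predict(F[, st$feature], st$thr, st$pol)
    correct <- as.numeric(pred == y)
    wts <- wts * beta^correct
    wts <- wts / sum(wts)
    weaks[[round]] <- list(feature = st$feature, thr = st$thr, pol = st$pol,
                           alpha = alpha)
    score <- score + alpha * pred
    # stage threshold: keep >= stage_hit of positives, backed off by a
    # margin (fraction of the total vote mass) so windows slightly off the
    # training distribution still pass
    pos_scores <- sort(score[y == 1])
    idx <- max(1L, floor((1 - stage_hit) * length(pos_scores)) + 1L)
    thr_stage <- pos_scores[idx] - margin_frac * sum(vapply(weaks, `[[`, 0,
                                                            "alpha")) - 1e-9
    fa <- mean(score[y == 0] >= thr_stage)
    if (fa <= stage_max_fa && round >= min_rounds) {
      return(list(threshold = thr_stage, weaks = weaks, fa = fa,
                  hit = mean(score[y == 1] >= thr_stage)))
    }
  }
  list(threshold = thr_stage, weaks = weaks, fa = fa,
       hit = mean(score[y == 1] >= thr_stage))
}

# ---- Cascade training -------------------------------------------------------

#' Default Haar-training configuration
#'
#' @param window square base detection window side, px. Feature rectangles
#'   are defined in this coordinate system and rescaled to each crop or scan
#'   window.
#' @param n_features number of Haar features sampled (seeded) from the full
#'   pool as the boosting candidate set.
#' @param max_stages maximum number of cascade stages.
#' @param stage_hit per-stage minimum hit rate on training positives.
#' @param stage_max_fa per-stage maximum false-alarm rate on the negatives
#'   surviving the previous stages.
#' @param max_rounds maximum boosting rounds per stage.
#' @param min_rounds minimum boosting rounds per stage (keeps stages from
#'   stopping at one lucky stump on separable training sets).
#' @param object_frac fraction of a training crop (and hence of a detection
#'   window) that the feature itself occupies; reported detection boxes are
#'   shrunk to this fraction of the window so they bound the feature, not
#'   the window margin.
#' @param margin_frac per-stage threshold back-off, as a fraction of the
#'   stage's total vote mass: a generalization buffer so scan windows a
#'   little off the training distribution (sub-pixel shifts, scale-ladder
#'   mismatch) are not rejected.
#' @param seed seed for the feature-pool subsample.
#' @return A named list of training parameters.
#' @export
haar_params <- function(window = 12L, n_features = 1500L, max_stages = 8L,
                        stage_hit = 0.995, stage_max_fa = 0.4,
                        max_rounds = 30L, min_rounds = 4L,
                        object_frac = 0.8, margin_frac = 0.05, seed = 1L) {
  list(window = as.integer(window), n_features = as.integer(n_features),
       max_stages = as.integer(max_stages), stage_hit = stage_hit,
       stage_max_fa = stage_max_fa, max_rounds = as.integer(max_rounds),
       min_rounds = as.integer(min_rounds), object_frac = object_frac,
       margin_frac = margin_frac, seed = as.integer(seed))
}

# Accept crops as matrices or image paths. Crops are evaluated at native
# size (features rescaled to the crop, exactly as the window scanner does);
# non-square crops are center-cropped to their shorter side.
standardize_crops <- function(crops) {
  lapply(crops, function(cr) {
    if (is.character(cr)) cr <- read_image(cr)
    if (!is.matrix(cr)) stop("crops must be matrices or image paths")
    cr
  })
}

# Native-size feature evaluation via the same compiled kernel the scanner
# uses (identical rect rounding and contrast normalization).
haar_eval_native <- function(features, crops, window) {
  nrects <- vapply(features, nrow, 0L)
  haar_eval_native_cpp(crops, as.integer(window),
                       c(0L, cumsum(nrects)[-length(nrects)]), nrects,
                       do.call(rbind, features))
}

#' Train a boosted Haar cascade
#'
#' Trains a Viola–Jones-style attentional cascade: each stage is an AdaBoost
#' ensemble of decision stumps over contrast-normalized Haar-like features,
#' thresholded to retain at least `stage_hit` of the positives; later stages
#' are trained only on the negatives that earlier stages failed to reject.
#' Deterministic for fixed inputs and `params$seed`.
#'
#' @param positives list of grayscale crop matrices (intensities 0–255) or
#'   image paths, all showing the same feature kind, roughly centered and
#'   filling the crop. Any size: features are evaluated at native crop size
#'   with the same rectangle rescaling the scanner applies.
#' @param negatives list of background crops or image paths.
#' @param feature_kind `"eye"` or `"ear"`; recorded in the model.
#' @param params training configuration from [haar_params()].
#' @return An object of class `haar_cascade`: fields `feature_kind`, `window`,
#'   `features` (rectangle sets), `stages`, and training diagnostics.
#' @seealso [detect_features()], [write_cascade_xml()].
#' @export
train_cascade <- function(positives, negatives, feature_kind = c("eye", "ear"),
                          params = haar_params()) {
  feature_kind <- match.arg(feature_kind)
  if (length(positives) == 0) stop("no positive crops supplied")
  if (length(negatives) == 0) stop("no negative crops supplied")
  window <- params$window
  pos <- standardize_crops(positives)
  neg <- standardize_crops(negatives)

  pool <- haar_feature_pool(window)
  features <- withr::with_seed(params$seed, {
    pool[sort(sample.int(length(pool), min(params$n_features, length(pool))))]
  })

  crops <- c(pos, neg)
  F <- haar_eval_native(features, crops, window)
  y <- c(rep(1, length(pos)), rep(0, length(neg)))

  stages <- list()
  active <- seq_along(crops)          # positives + surviving negatives
  for (s in seq_len(params$max_stages)) {
    ys <- y[active]
    if (sum(ys == 0) == 0) break      # all negatives rejected
    Fs <- F[active, , drop = FALSE]
    ord <- apply(Fs, 2, order)
    stg <- train_stage(Fs, ys, ord, params$stage_hit, params$stage_max_fa,
                       params$max_rounds, params$min_rounds %||% 1L,
                       params$margin_frac %||% 0)
    stages[[s]] <- list(threshold = stg$threshold, weaks = stg$weaks)
    # negatives passing this stage survive to the next
    sc <- stage_scores(Fs, stg)
    pass <- sc >= stg$threshold
    active <- active[y[active] == 1 | pass]
    if (stg$hit < params$stage_hit - 1e-9) {
      stop("Haar training failed to reach the per-stage hit target at stage ",
           s, " (hit = ", signif(stg$hit, 4), ")")
    }
  }
  if (length(stages) == 0) stop("Haar training produced no stages")
  model <- structure(
    list(feature_kind = feature_kind, window = window,
         object_frac = params$object_frac %||% 0.8, features = features,
         stages = stages,
         n_pos = length(pos), n_neg = length(neg),
         train_fa = sum(y[active] == 0) / length(neg)),
    class = "haar_cascade"
  )
  model$.flat <- flatten_cascade(model)
  model
}

stage_scores <- function(F, stage) {
  sc <- numeric(nrow(F))
  for (wk in stage$weaks) {
    sc <- sc + wk$alpha * stump_predict(F[, wk$feature], wk$thr, wk$pol)
  }
  sc
}

#' @export
print.haar_cascade <- function(x, ...) {
  nw <- sum(vapply(x$stages, function(s) length(s$weaks), 0L))
  cat(sprintf("<haar_cascade '%s': %d stages, %d stumps, window %dx%d>\n",
              x$feature_kind, length(x$stages), nw, x$window, x$window))
  invisible(x)
}

#' Classify crops with a trained cascade
#'
#' Runs the full cascade on each crop (resized to the base window); a crop is
#' accepted only if every stage's boosted score reaches its threshold. This is
#' the crop-level view of the same classifier the multi-scale scanner applies
#' to windows, and is used for held-out recall evaluation.
#'
#' @param model a `haar_cascade`.
#' @param crops list of crop matrices or image paths.
#' @return Logical vector, `TRUE` for accepted crops.
#' @export
classify_crops <- function(model, crops) {
  crops <- standardize_crops(crops)
  F <- haar_eval_native(model$features, crops, model$window)
  ok <- rep(TRUE, length(crops))
  for (stage in model$stages) {
    if (!any(ok)) break
    sc <- stage_scores(F, stage)
    ok <- ok & (sc >= stage$threshold)
  }
  ok
}
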
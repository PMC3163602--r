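#' Signal-detection summary of pain/no-pain judgments
#'
#' Scores each dichotomous judgment against the true condition of the image:
#' a *hit* is a pain photograph judged pain, a *correct rejection* a no-pain
#' photograph judged no pain, a *miss* a pain photograph judged no pain, and
#' a *false alarm* a no-pain photograph judged pain. Rates are percentages of
#' all judgments (so with a 50/50 design accuracy + miss rate + false-alarm
#' rate is 100%), and accuracy is the hit rate plus the correct-rejection
#' rate. Summaries are returned pooled and per scorer.
#'
#' @param judgments data frame with columns `blinded_id` (or `image`),
#'   `scorer_id`, `call` — the judgment, `"pain"`/`"no_pain"` (logical
#'   `TRUE` = pain also accepted).
#' @param truth data frame with columns `blinded_id` (or `image`) and
#'   `condition` (`"pain"`/`"no_pain"`); every judged image must appear.
#' @return A `confusion_summary`: `pooled` (one-row data frame of counts and
#'   percent rates) and `per_scorer`.
#' @export
signal_detection <- function(judgments, truth) {
  id_col <- function(df) {
    if ("blinded_id" %in% names(df)) "blinded_id"
    else if ("image" %in% names(df)) "image"
    else stop("need a 'blinded_id' or 'image' column")
  }
  jid <- id_col(judgments); tid <- id_col(truth)
  as_pain <- function(x) {
    if (is.logical(x)) return(x)
    x <- tolower(as.character(x))
    if (!all(x %in% c("pain", "no_pain"))) {
      stop("calls/conditions must be 'pain' or 'no_pain'")
    }
    x == "pain"
  }
  truth_pain <- as_pain(truth$condition)
  idx <- match(judgments[[jid]], truth[[tid]])
  if (anyNA(idx)) {
    stop("judged image(s) without a truth label: ",
         paste(unique(judgments[[jid]][is.na(idx)]), collapse = ", "))
  }
  is_pain <- truth_pain[idx]
  call_pain <- as_pain(judgments$call)

  summarize <- function(sel) {
    n <- sum(sel)
    hits <- sum(sel & is_pain & call_pain)
    misses <- sum(sel & is_pain & !call_pain)
    fa <- sum(sel & !is_pain & call_pain)
    cr <- sum(sel & !is_pain & !call_pain)
    data.frame(
      n = n, hits = hits, misses = misses, false_alarms = fa,
      correct_rejections = cr,
      hit_rate = 100 * hits / n, miss_rate = 100 * misses / n,
      false_alarm_rate = 100 * fa / n,
      correct_rejection_rate = 100 * cr / n,
      accuracy = 100 * (hits + cr) / n
    )
  }
  pooled <- summarize(rep(TRUE, nrow(judgments)))
  scorers <- sort(unique(judgments$scorer_id))
  per <- do.call(rbind, lapply(scorers, function(s) {
    cbind(scorer_id = s, summarize(judgments$scorer_id == s))
  }))
  structure(list(pooled = pooled, per_scorer = per),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, digits = 3, ...) {
  p <- x$pooled
  cat(sprintf(paste0("Pain/no-pain judgments: n = %d, accuracy %.1f%% ",
                     "(hits %.1f%%, CR %.1f%%, misses %.1f%%, FA %.1f%%)\n"),
              p$n, p$accuracy, p$hit_rate, p$correct_rejection_rate,
              p$miss_rate, p$false_alarm_rate))
  acc <- x$per_scorer$accuracy
  if (length(acc) > 1) {
    cat(sprintf("Per-scorer accuracy: %.1f-%.1f%% (%d scorers)\n",
                min(acc), max(acc), length(acc)))
  }
  invisible(x)
}

#' Per-action-unit pain minus no-pain difference scores
#'
#' For each animal with both a pain and a no-pain (baseline) score, the
#' difference score of an action unit is the animal's mean unit score in the
#' pain condition minus its mean in the no-pain condition (means across
#' scorers and images). Reported per unit plus the four-unit average, with
#' the SEM of the difference across animals. Animals missing either condition
#' are excluded with a warning.
#'
#' @param ratings a `ratings_matrix` from [assemble_matrix()] whose key has
#'   `animal` and `condition` (`"pain"`/`"no_pain"`) columns.
#' @return Data frame with one row per action unit plus `"average"`:
#'   `action_unit`, `pain_mean`, `no_pain_mean`, `delta`, `sem`, `n_animals`.
#' @export
difference_scores <- function(ratings) {
  stopifnot(inherits(ratings, "ratings_matrix"))
  key <- ratings$key
  if (!all(c("animal", "condition") %in% names(key))) {
    stop("ratings key needs 'animal' and 'condition' columns")
  }
  cond <- tolower(as.character(key$condition))
  if (!all(cond %in% c("pain", "no_pain"))) {
    stop("conditions must be 'pain' or 'no_pain'")
  }
  animals <- unique(key$animal)
  complete <- vapply(animals, function(a) {
    all(c("pain", "no_pain") %in% cond[key$animal == a])
  }, TRUE)
  if (any(!complete)) {
    warning("excluding animal(s) missing a condition: ",
            paste(animals[!complete], collapse = ", "))
    animals <- animals[complete]
  }
  if (length(animals) == 0) stop("no animal has both conditions")
  per_unit <- function(mat, unit_name) {
    deltas <- vapply(animals, function(a) {
      p <- mean(mat[key$animal == a & cond == "pain", , drop = FALSE],
                na.rm = TRUE)
      b <- mean(mat[key$animal == a & cond == "no_pain", , drop = FALSE],
                na.rm = TRUE)
      c(p, b)
    }, numeric(2))
    d <- deltas[1, ] - deltas[2, ]
    data.frame(
      action_unit = unit_name,
      pain_mean = mean(deltas[1, ]), no_pain_mean = mean(deltas[2, ]),
      delta = mean(d),
      sem = if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else 0,
      n_animals = length(animals)
    )
  }
  rows <- lapply(names(ratings$units), function(u) per_unit(ratings$units[[u]], u))
  rows[[length(rows) + 1]] <- per_unit(ratings$scores, "average")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
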
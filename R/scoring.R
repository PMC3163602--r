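rgs_units <- c("orbital_tightening", "nose_cheek_flattening",
               "ear_changes", "whisker_change")

#' Build a blinded, seed-randomized scoring manifest
#'
#' Assigns every exported image an opaque blinded identifier (a zero-padded
#' random token, deliberately not derived from the filename, which could leak
#' the condition), shuffles the presentation order, and separates the output
#' in two: a scorer-facing manifest (blinded id + image path only) and a key
#' file that re-attaches the hidden source metadata (animal, condition, time
#' point, ...). Both the permutation and the tokens are deterministic
#' functions of `seed`.
#'
#' @param images character vector of exported image paths (must exist, no
#'   duplicates).
#' @param metadata data frame with one row per image: the hidden source
#'   fields, e.g. `animal`, `condition`, `time_point` (any columns are
#'   carried into the key).
#' @param seed integer randomization seed.
#' @return A `scoring_manifest`: `seed`, `entries` (blinded order:
#'   `blinded_id`, `image_path`) and `key` (`blinded_id` + metadata).
#' @seealso [write_manifest()], [assemble_matrix()].
#' @export
build_manifest <- function(images, metadata, seed) {
  if (anyDuplicated(images)) {
    stop("duplicate image paths: ",
         paste(unique(images[duplicated(images)]), collapse = ", "))
  }
  missing <- images[!file.exists(images)]
  if (length(missing) > 0) {
    stop("image files not found: ", paste(missing, collapse = ", "))
  }
  n <- length(images)
  if (!is.data.frame(metadata) || nrow(metadata) != n) {
    stop("metadata must be a data frame with one row per image")
  }
  ids_perm <- withr::with_seed(as.integer(seed), {
    list(ids = sprintf("IMG%05d", sample(0:99999, n)), perm = sample.int(n))
  })
  entries <- data.frame(blinded_id = ids_perm$ids[ids_perm$perm],
                        image_path = images[ids_perm$perm],
                        stringsAsFactors = FALSE)
  key <- cbind(data.frame(blinded_id = ids_perm$ids,
                          image_path = images, stringsAsFactors = FALSE),
               metadata)
  structure(list(seed = as.integer(seed), entries = entries, key = key),
            class = "scoring_manifest")
}

#' Write the scorer-facing manifest and the unblinding key
#'
#' @param manifest a `scoring_manifest` from [build_manifest()].
#' @param prefix output prefix; writes `<prefix>.csv` (scorer-facing, no
#'   source metadata) and `<prefix>.key.csv` (unblinding key).
#' @return Named character vector of the two paths, invisibly.
#' @export
write_manifest <- function(manifest, prefix) {
  stopifnot(inherits(manifest, "scoring_manifest"))
  blind_path <- paste0(prefix, ".csv")
  key_path <- paste0(prefix, ".key.csv")
  utils::write.csv(manifest$entries, blind_path, row.names = FALSE)
  utils::write.csv(manifest$key, key_path, row.names = FALSE)
  invisible(c(manifest = blind_path, key = key_path))
}

#' Parse and validate a grimace-score table
#'
#' Reads one row per scorer x image with the four action-unit columns
#' (`orbital_tightening`, `nose_cheek_flattening`, `ear_changes`,
#' `whisker_change`), each 0 (confidently absent), 1 (moderate or equivocal),
#' 2 (obvious, confident) or NA (not scorable, e.g. whiskers invisible). The
#' image mean score is the mean of the scored units; at least one unit must
#' be scored.
#'
#' @param score_file CSV path or data frame with columns `blinded_id`,
#'   `scorer_id` and the four unit columns.
#' @param manifest optional `scoring_manifest`; if given, every `blinded_id`
#'   must appear in it.
#' @return Data frame of validated records with a `mean_score` column in
#'   `[0, 2]`.
#' @export
parse_scores <- function(score_file, manifest = NULL) {
  df <- if (is.character(score_file)) {
    utils::read.csv(score_file, stringsAsFactors = FALSE)
  } else {
    score_file
  }
  needed <- c("blinded_id", "scorer_id", rgs_units)
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0) {
    stop("score table lacks columns: ", paste(miss, collapse = ", "))
  }
  unit_vals <- as.matrix(df[, rgs_units])
  bad <- which(!(is.na(unit_vals) | unit_vals %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("illegal score values (allowed: 0, 1, 2, NA) in rows: ",
         paste(sort(unique(bad[, 1])), collapse = ", "))
  }
  n_scored <- rowSums(!is.na(unit_vals))
  if (any(n_scored == 0)) {
    stop("rows with no scored action unit: ",
         paste(which(n_scored == 0), collapse = ", "))
  }
  if (!is.null(manifest)) {
    unknown <- setdiff(df$blinded_id, manifest$key$blinded_id)
    if (length(unknown) > 0) {
      stop("unknown blinded ids: ", paste(unknown, collapse = ", "))
    }
  }
  df$mean_score <- rowMeans(unit_vals, na.rm = TRUE)
  df
}

#' Assemble the subjects x raters matrix and unblind conditions
#'
#' Pivots validated records into an images x scorers matrix of per-image
#' mean scores (plus one such matrix per action unit) and re-attaches each
#' image's hidden condition labels from the key. Row order follows the key,
#' so input row order is irrelevant. Scorers covering less than half of the
#' images are flagged with a warning.
#'
#' @param records data frame from [parse_scores()].
#' @param key unblinding key: the `key` element of a `scoring_manifest`, or a
#'   data frame read from `<prefix>.key.csv`.
#' @return A `ratings_matrix`: `scores` (subjects x raters matrix of mean
#'   scores), `units` (list of four per-unit matrices), `key` (row-aligned
#'   metadata), `flagged_scorers`.
#' @export
assemble_matrix <- function(records, key) {
  if (inherits(key, "scoring_manifest")) key <- key$key
  unknown <- setdiff(records$blinded_id, key$blinded_id)
  if (length(unknown) > 0) {
    stop("records reference blinded ids absent from the key: ",
         paste(unknown, collapse = ", "))
  }
  subjects <- key$blinded_id
  raters <- sort(unique(records$scorer_id))
  pivot <- function(col) {
    m <- matrix(NA_real_, nrow = length(subjects), ncol = length(raters),
                dimnames = list(subjects, raters))
    m[cbind(match(records$blinded_id, subjects),
            match(records$scorer_id, raters))] <- records[[col]]
    m
  }
  scores <- pivot("mean_score")
  units <- lapply(rgs_units, pivot)
  names(units) <- rgs_units
  coverage <- colMeans(!is.na(scores))
  flagged <- names(coverage)[coverage < 0.5]
  if (length(flagged) > 0) {
    warning("scorer(s) covering <50% of images: ",
            paste(flagged, collapse = ", "))
  }
  structure(list(scores = scores, units = units, key = key,
                 flagged_scorers = flagged),
            class = "ratings_matrix")
}

#' @export
print.ratings_matrix <- function(x, ...) {
  cat(sprintf("<ratings_matrix: %d images x %d scorers, %d missing cells>\n",
              nrow(x$scores), ncol(x$scores), sum(is.na(x$scores))))
  invisible(x)
}
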
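# Write n neutral-named dummy images and matching hidden metadata.
stage_images <- function(n, conditions = rep(c("pain", "no_pain"),
                                             length.out = n)) {
  dir <- file.path(tempdir(), paste0("imgs-", n, "-",
                                     as.integer(stats::runif(1, 1, 1e9))))
  dir.create(dir, showWarnings = FALSE)
  px <- matrix(128, 4, 4)
  paths <- vapply(seq_len(n), function(i) {
    p <- file.path(dir, sprintf("img_%03d.png", i))
    png::writePNG(px / 255, p)
    p
  }, "")
  list(images = paths,
       metadata = data.frame(animal = sprintf("rat%02d", (seq_len(n) + 1) %/% 2),
                             condition = conditions,
                             time_point = ifelse(conditions == "pain", "6h",
                                                 "baseline")))
}

test_that("manifests are seed-deterministic bijections that hide the source", {
  st <- stage_images(104)
  m1 <- build_manifest(st$images, st$metadata, seed = 7)
  m2 <- build_manifest(st$images, st$metadata, seed = 7)
  expect_identical(m1$entries, m2$entries)
  expect_identical(m1$key, m2$key)
  # a different seed permutes differently
  m3 <- build_manifest(st$images, st$metadata, seed = 8)
  expect_false(identical(m1$entries$blinded_id, m3$entries$blinded_id))

  expect_equal(nrow(m1$entries), 104)
  expect_equal(anyDuplicated(m1$entries$blinded_id), 0)
  # permutation: same images, shuffled
  expect_setequal(m1$entries$image_path, st$images)

  # the scorer-facing file carries no hidden tokens
  paths <- write_manifest(m1, file.path(tempdir(), "manifest"))
  blind_text <- readLines(paths[["manifest"]])
  for (token in c(unique(st$metadata$animal), "pain", "no_pain", "6h",
                  "baseline")) {
    expect_false(any(grepl(token, blind_text, fixed = TRUE)),
                 label = paste("token", token, "leaked"))
  }
  # while the key recovers everything
  key <- utils::read.csv(paths[["key"]])
  expect_setequal(names(key), c("blinded_id", "image_path", "animal",
                                "condition", "time_point"))

  expect_error(build_manifest(rep(st$images[1], 2), st$metadata[1:2, ], 1),
               "duplicate")
  expect_error(build_manifest(file.path(tempdir(), "ghost.png"),
                              st$metadata[1, , drop = FALSE], 1), "not found")
})

test_that("unblinding recovers every image's condition exactly", {
  st <- stage_images(20)
  man <- build_manifest(st$images, st$metadata, seed = 3)
  # join scorer-facing entries back through the key
  j <- merge(man$entries, man$key, by = "blinded_id")
  expect_equal(nrow(j), 20)
  expect_true(all(j$image_path.x == j$image_path.y))
  orig <- st$metadata$condition[match(j$image_path.x, st$images)]
  expect_equal(j$condition, orig)
})

test_that("score tables are validated and averaged over scored units", {
  rows <- data.frame(
    blinded_id = c("a", "b", "c"), scorer_id = "s1",
    orbital_tightening = c(2, 0, 0), nose_cheek_flattening = c(2, 1, 1),
    ear_changes = c(2, 2, 2), whisker_change = c(2, 1, NA))
  rec <- parse_scores(rows)
  expect_equal(rec$mean_score, c(2, 1, 1))

  bad <- rows; bad$ear_changes[2] <- 3
  expect_error(parse_scores(bad), "rows: 2")
  none <- rows; none[3, grimace:::rgs_units] <- NA
  expect_error(parse_scores(none), "no scored action unit")
  expect_error(parse_scores(rows[, -1]), "lacks columns")

  # CSV path and manifest check
  st <- stage_images(3)
  man <- build_manifest(st$images, st$metadata, seed = 1)
  rows$blinded_id <- man$key$blinded_id
  csv <- file.path(tempdir(), "scores.csv")
  utils::write.csv(rows, csv, row.names = FALSE)
  expect_equal(parse_scores(csv, man)$mean_score, c(2, 1, 1))
  rows$blinded_id[1] <- "IMG99999x"
  expect_error(parse_scores(rows, man), "unknown blinded ids")
})

test_that("the ratings matrix pivots records order-invariantly", {
  st <- stage_images(4)
  man <- build_manifest(st$images, st$metadata, seed = 2)
  ids <- man$key$blinded_id
  recs <- expand.grid(blinded_id = ids, scorer_id = c("s1", "s2", "s3"),
                      stringsAsFactors = FALSE)
  units <- withr::with_seed(5, {
    matrix(sample(0:2, nrow(recs) * 4, replace = TRUE), ncol = 4)
  })
  colnames(units) <- grimace:::rgs_units
  recs <- cbind(recs, units)
  recs <- parse_scores(recs)

  rm1 <- assemble_matrix(recs, man)
  expect_equal(dim(rm1$scores), c(4, 3))
  expect_equal(sum(is.na(rm1$scores)), 0)
  expect_length(rm1$units, 4)

  shuffled <- recs[withr::with_seed(6, sample(nrow(recs))), ]
  rm2 <- assemble_matrix(shuffled, man)
  expect_identical(rm1$scores, rm2$scores)
  expect_identical(rm1$units, rm2$units)

  # one missing record leaves one missing cell
  rm3 <- assemble_matrix(recs[-1, ], man)
  expect_equal(sum(is.na(rm3$scores)), 1)

  # a scorer covering under half the images is flagged
  sparse <- recs[!(recs$scorer_id == "s3" & recs$blinded_id %in% ids[1:3]), ]
  expect_warning(rm4 <- assemble_matrix(sparse, man), "s3")
  expect_equal(rm4$flagged_scorers, "s3")

  expect_error(assemble_matrix(transform(recs, blinded_id = "nope"), man),
               "absent from the key")
})

test_that("mean scores span the full 0-2 range at the endpoints", {
  rows <- data.frame(blinded_id = c("a", "b"), scorer_id = "s1",
                     orbital_tightening = c(0, 2),
                     nose_cheek_flattening = c(0, 2),
                     ear_changes = c(0, 2), whisker_change = c(0, 2))
  expect_equal(parse_scores(rows)$mean_score, c(0, 2))
})
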
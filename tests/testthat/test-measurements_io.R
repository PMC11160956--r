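# Reading, validating and writing per-image measurement tables.

build_table <- function(n_eyes = 39, images = rep(c(10, 9), c(26, 13)),
                        scramble = FALSE) {
  stopifnot(length(images) == n_eyes)
  rows <- lapply(seq_len(n_eyes), function(e) {
    n <- images[e]
    data.frame(subject_id = sprintf("S%02d", ceiling(e / 2)),
               eye = if (e %% 2 == 0) "right" else "left",
               image_id = sprintf("e%02d_i%02d", e, seq_len(n)),
               acquired_at = format(
                 as.POSIXct("2022-03-01 10:00:00", tz = "UTC") + 3600 * seq_len(n),
                 "%Y-%m-%dT%H:%M:%S"),
               quality_pbad = round(seq(0.05, 0.6, length.out = n), 4),
               DART = round(1.5 + 0.01 * e + 0.001 * seq_len(n), 6),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (scramble) df <- df[rev(seq_len(nrow(df))), ]
  df
}

test_that("a 377-row table groups into 39 time-sorted eye series and survives a round-trip", {
  df <- build_table(scramble = TRUE)
  expect_equal(nrow(df), 377)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)

  co <- read_cohort(path, methods = "DART")
  expect_s3_class(co, "cohort")
  expect_equal(nrow(co), 377)
  expect_equal(length(unique(paste(co$subject_id, co$eye))), 39)
  # time-sorted within each eye despite scrambled rows on disk
  by_eye <- split(seq_len(nrow(co)), paste(co$subject_id, co$eye))
  for (idx in by_eye) {
    expect_false(is.unsorted(co$acquired_at[idx]))
  }
  # grouping is stable: a second read yields the identical table
  co2 <- read_cohort(path, methods = "DART")
  expect_identical(as.data.frame(co), as.data.frame(co2))
  # serialization round-trip conserves records and values
  out <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, out)
  co3 <- read_cohort(out, methods = "DART")
  expect_equal(nrow(co3), nrow(co))
  expect_equal(co3$DART, co$DART, tolerance = 1e-12)
  expect_identical(co3$acquired_at, co$acquired_at)
})

test_that("an empty table with a valid header yields a cohort with no eyes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("subject_id,eye,image_id,acquired_at,quality_pbad,DART", path)
  co <- read_cohort(path, methods = "DART")
  expect_equal(nrow(co), 0)
  expect_equal(cohort_methods(co), "DART")
})

test_that("schema and validation errors name the offending column or row", {
  df <- build_table(n_eyes = 2, images = c(3, 3))

  bad <- df[, setdiff(names(df), "quality_pbad")]
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_cohort(path, methods = "DART"), "quality_pbad")

  df2 <- df
  df2$quality_pbad[4] <- 1.7
  expect_error(as_cohort(df2, methods = "DART"), "quality_pbad.*4")

  df3 <- df
  df3$acquired_at[2] <- "not-a-date"
  expect_error(as_cohort(df3, methods = "DART"), "timestamp")

  df4 <- df
  df4$image_id[2] <- df4$image_id[1]
  expect_error(as_cohort(df4, methods = "DART"), "duplicated image_id")

  df5 <- df
  df5$DART[3] <- -1
  expect_error(as_cohort(df5, methods = "DART"), "non-positive")
})

test_that("rows with a missing trait value are retained and excluded per-method", {
  df <- build_table(n_eyes = 3, images = c(4, 4, 4))
  df$AutoMorph <- df$DART + 0.1
  df$DART[1:3] <- NA  # first eye keeps only 1 usable DART image
  co <- as_cohort(df, methods = c("DART", "AutoMorph"))
  expect_equal(nrow(co), 12)
  pairs <- first_last_pairing(co, "DART")
  expect_equal(nrow(pairs), 2)
  expect_equal(attr(pairs, "n_skipped"), 1)
  # the other method still sees all three eyes
  expect_equal(nrow(first_last_pairing(co, "AutoMorph")), 3)
})

test_that("filter_min_images keeps exactly the eyes meeting the floor", {
  co <- make_cohort(list(a = 1:3 + 1.0, b = 1:5 + 1.0, c = 1:7 + 1.0))
  expect_equal(nrow(suppressMessages(filter_min_images(co, 5))), 12)
  expect_equal(length(unique(suppressMessages(
    filter_min_images(co, 5))$subject_id)), 2)
  expect_message(filter_min_images(co, 5), "dropped 1 eye")
  # min_n = 1 is the identity
  expect_identical(as.data.frame(filter_min_images(co, 1)),
                   as.data.frame(co))
})

test_that("the shipped example table reads into four eyes with two methods", {
  path <- system.file("extdata", "example_cohort.csv", package = "retrep")
  co <- read_cohort(path)
  expect_equal(nrow(co), 16)
  expect_equal(length(unique(paste(co$subject_id, co$eye))), 4)
  expect_setequal(cohort_methods(co), c("DART", "AutoMorph"))
  # the contaminated image drives its eye's lambda; dropping bad images
  # deflates it
  ref <- 0.02
  lam <- lambda_table(co, "DART", ref)
  worst <- lam$lambda_pct[lam$subject_id == "S02"]
  lam_gated <- lambda_table(apply_quality_threshold(co, 0.8), "DART", ref)
  expect_gt(worst / lam_gated$lambda_pct[lam_gated$subject_id == "S02"], 5)
})

test_that("write_results writes CSVs that round-trip to 1e-9 and a manifest with hashes", {
  co <- make_cohort(list(c(1.5, 1.51, 1.52), c(1.6, 1.62, 1.64),
                         c(1.7, 1.71, 1.73)))
  lam <- lambda_table(co, "FD", reference_sd = 0.05)
  dir <- withr::local_tempdir()
  manifest <- write_results(list(lambdas = lam), dir)
  back <- utils::read.csv(file.path(dir, "lambdas.csv"))
  expect_equal(back$lambda_pct, lam$lambda_pct, tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "summary.json")))
  expect_true(all(c("lambdas.csv", "summary.json") %in% manifest$file))
  expect_true(all(nchar(manifest$md5) == 32))
})
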
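#' Cohort tables of repeated per-image measurements
#'
#' A cohort is a data frame with one row per fundus image, holding the
#' identifiers (`subject_id`, `eye`, `image_id`), the acquisition time
#' (`acquired_at`), a continuous image-quality score `quality_pbad`
#' (probability that the image is of bad quality, in \[0, 1\]) and one
#' numeric column per measurement method (e.g. two fractal-dimension
#' tools). Rows are kept sorted by subject, eye, acquisition time and
#' image id, so that "first" and "last" image of an eye are well
#' defined; the eye (subject and laterality), not the subject, is the
#' unit over which within-series statistics are computed.
#'
#' A missing trait value for some method is stored as `NA` and the row
#' is retained: the image still counts for the other methods, and is
#' excluded per-method downstream.
#'
#' @param x a data frame with the columns described above.
#' @param methods character vector naming the measurement columns. When
#'   `NULL`, every column other than the identifier/quality columns is
#'   treated as a method.
#' @param name cohort label used in printing and result tables.
#' @return An object of class `cohort` (a sorted, validated data frame).
#' @seealso [read_cohort()], [generate_cohort()]
#' @export
as_cohort <- function(x, methods = NULL, name = "cohort") {
  stopifnot(is.data.frame(x))
  required <- c("subject_id", "eye", "image_id", "acquired_at", "quality_pbad")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(methods)) {
    methods <- setdiff(names(x), required)
  }
  if (length(methods) == 0) {
    stop("no measurement method columns found or declared", call. = FALSE)
  }
  missing_methods <- setdiff(methods, names(x))
  if (length(missing_methods) > 0) {
    stop("missing required column(s): ",
         paste(missing_methods, collapse = ", "), call. = FALSE)
  }

  df <- as.data.frame(x[, c(required, methods)], stringsAsFactors = FALSE)
  df$subject_id <- as.character(df$subject_id)
  df$eye <- as.character(df$eye)
  df$image_id <- as.character(df$image_id)
  df$acquired_at <- parse_timestamp(df$acquired_at)
  df$quality_pbad <- as.numeric(df$quality_pbad)

  bad_q <- which(is.na(df$quality_pbad) | df$quality_pbad < 0 |
                   df$quality_pbad > 1)
  if (length(bad_q) > 0) {
    stop("quality_pbad outside [0, 1] (or missing) in row(s): ",
         paste(utils::head(bad_q, 5), collapse = ", "), call. = FALSE)
  }
  for (m in methods) {
    v <- as.numeric(df[[m]])
    bad_v <- which(!is.na(v) & (!is.finite(v) | v <= 0))
    if (length(bad_v) > 0) {
      stop("non-finite or non-positive values for method '", m,
           "' in row(s): ", paste(utils::head(bad_v, 5), collapse = ", "),
           call. = FALSE)
    }
    df[[m]] <- v
  }
  if (anyDuplicated(df$image_id)) {
    dup <- df$image_id[duplicated(df$image_id)]
    stop("duplicated image_id within cohort: ",
         paste(utils::head(unique(dup), 5), collapse = ", "), call. = FALSE)
  }

  ord <- order(df$subject_id, df$eye, df$acquired_at, df$image_id)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            methods = methods,
            cohort_name = as.character(name),
            class = c("cohort", "data.frame"))
}

# Accept ISO-8601 dates or datetimes (UTC); anything unparsable errors.
parse_timestamp <- function(ts) {
  if (inherits(ts, "POSIXct")) {
    return(ts)
  }
  if (inherits(ts, "Date")) {
    return(as.POSIXct(ts, tz = "UTC"))
  }
  ts <- as.character(ts)
  out <- as.POSIXct(ts, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"),
                    optional = TRUE)
  bad <- which(is.na(out) & !is.na(ts))
  if (length(bad) > 0) {
    stop("unparsable timestamp in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (expected ISO-8601 date or datetime)", call. = FALSE)
  }
  if (anyNA(out)) {
    stop("missing acquisition timestamp in row(s): ",
         paste(utils::head(which(is.na(out)), 5), collapse = ", "),
         call. = FALSE)
  }
  out
}

# Rebuild a cohort from a row subset, preserving metadata. Order is
# already canonical, so subsetting with increasing indices keeps it.
cohort_subset <- function(cohort, idx) {
  df <- as.data.frame(cohort)[idx, , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            methods = attr(cohort, "methods"),
            cohort_name = attr(cohort, "cohort_name"),
            class = c("cohort", "data.frame"))
}

# One key per eye (subject + laterality), the analysis unit.
eye_key <- function(cohort) {
  paste(cohort$subject_id, cohort$eye, sep = "\r")
}

#' Measurement methods available in a cohort
#' @param cohort a `cohort` object.
#' @return character vector of method column names.
#' @export
cohort_methods <- function(cohort) {
  attr(cohort, "methods")
}

#' Cohort label
#' @param cohort a `cohort` object.
#' @return the cohort's name string.
#' @export
cohort_name <- function(cohort) {
  attr(cohort, "cohort_name")
}

#' @export
print.cohort <- function(x, ...) {
  keys <- eye_key(x)
  cat(sprintf("<cohort '%s': %d subjects, %d eyes, %d images; methods: %s>\n",
              cohort_name(x), length(unique(x$subject_id)),
              length(unique(keys)), nrow(x),
              paste(cohort_methods(x), collapse = ", ")))
  invisible(x)
}

#' Read a per-image measurement table
#'
#' Reads a delimited text file (comma-separated by default; tab-separated
#' for `.tsv`/`.txt` extensions) with one row per image and returns a
#' validated [as_cohort()] table grouped by eye and sorted by
#' acquisition time (ties broken by `image_id`).
#'
#' @param path path to the CSV/TSV file.
#' @param methods character vector of measurement columns; `NULL` takes
#'   every non-identifier column.
#' @param name cohort label; defaults to the file name without extension.
#' @param col_names optional named list remapping the expected column
#'   names, e.g. `list(subject_id = "patient")`.
#' @return a `cohort` object.
#' @export
read_cohort <- function(path, methods = NULL, name = NULL, col_names = list()) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA, comment.char = "")
  defaults <- list(subject_id = "subject_id", eye = "eye",
                   image_id = "image_id", acquired_at = "acquired_at",
                   quality_pbad = "quality_pbad")
  mapping <- utils::modifyList(defaults, col_names)
  for (canon in names(defaults)) {
    src <- mapping[[canon]]
    if (!src %in% names(df)) {
      stop("missing required column(s): ", src, call. = FALSE)
    }
    names(df)[names(df) == src] <- canon
  }
  if (is.null(name)) {
    name <- sub("\\.[^.]*$", "", basename(path))
  }
  as_cohort(df, methods = methods, name = name)
}

#' Write a cohort back to delimited text
#'
#' Timestamps are serialized as ISO-8601 datetimes so a written cohort
#' reads back identically.
#'
#' @param cohort a `cohort` object.
#' @param path output path; `.tsv`/`.txt` writes tab-separated.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$acquired_at <- format(df$acquired_at, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only eyes with a minimum number of images
#'
#' Mirrors the common design rule of analysing only eyes with at least
#' `min_n` available images (the repeated-imaging cohort used at least
#' five per eye).
#'
#' @param cohort a `cohort` object.
#' @param min_n minimum number of images an eye must have to be kept.
#' @param quiet suppress the message reporting how many eyes were dropped.
#' @return the filtered `cohort`.
#' @export
filter_min_images <- function(cohort, min_n, quiet = FALSE) {
  stopifnot(is.numeric(min_n), length(min_n) == 1L, min_n >= 1)
  keys <- eye_key(cohort)
  counts <- table(keys)
  keep_keys <- names(counts)[counts >= min_n]
  keep <- keys %in% keep_keys
  dropped_eyes <- length(counts) - length(keep_keys)
  if (!quiet && dropped_eyes > 0) {
    message(sprintf("filter_min_images: dropped %d eye(s) / %d image(s) with < %d images",
                    dropped_eyes, sum(!keep), min_n))
  }
  cohort_subset(cohort, which(keep))
}

# Split one method's usable (non-missing) values by eye, each series
# time-sorted; used by every downstream estimator.
eye_values <- function(cohort, method) {
  if (!method %in% cohort_methods(cohort)) {
    stop("method '", method, "' not present in cohort '",
         cohort_name(cohort), "'", call. = FALSE)
  }
  ok <- !is.na(cohort[[method]])
  df <- as.data.frame(cohort)[ok, , drop = FALSE]
  keys <- paste(df$subject_id, df$eye, sep = "\r")
  idx <- split(seq_len(nrow(df)), keys)
  # split() orders groups lexicographically by key; rows within each
  # group keep the cohort's time order.
  lapply(idx, function(i) {
    list(subject_id = df$subject_id[i[1]],
         eye = df$eye[i[1]],
         values = df[[method]][i],
         pbad = df$quality_pbad[i],
         image_id = df$image_id[i])
  })
}
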
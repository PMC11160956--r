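#' Pair the first and last image of each eye
#'
#' For every eye with at least two images carrying a value for `method`,
#' takes the earliest and the latest such image (acquisition-time order,
#' ties broken by `image_id`) as a measurement pair — an objective if
#' arbitrary choice of one pair per eye. Eyes with fewer than two usable
#' images are skipped and counted.
#'
#' @param cohort a `cohort` object.
#' @param method measurement column to pair.
#' @return a `pairing_table`: a data frame with `subject_id`, `eye`,
#'   `value_a` (first), `value_b` (last), and attributes `rule`,
#'   `method` and `n_skipped`.
#' @export
first_last_pairing <- function(cohort, method) {
  series <- eye_values(cohort, method)
  usable <- vapply(series, function(s) length(s$values) >= 2L, logical(1))
  if (length(series) == 0) {
    stop("cohort holds no values for method '", method, "'", call. = FALSE)
  }
  kept <- series[usable]
  df <- data.frame(
    subject_id = vapply(kept, `[[`, character(1), "subject_id"),
    eye = vapply(kept, `[[`, character(1), "eye"),
    value_a = vapply(kept, function(s) s$values[1], numeric(1)),
    value_b = vapply(kept, function(s) s$values[length(s$values)], numeric(1)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, rule = "first_last", method = method,
            n_skipped = sum(!usable),
            class = c("pairing_table", "data.frame"))
}

#' Correlation between paired measurements
#'
#' Pearson (linear, outlier-sensitive) or Spearman (Pearson applied to
#' average ranks, hence robust and monotone-invariant) correlation of
#' the two pair columns, with a two-sided p-value: the t approximation
#' for Pearson, the large-sample approximation for Spearman.
#'
#' @param pairs a `pairing_table` (or any data frame with `value_a`,
#'   `value_b`).
#' @param statistic `"pearson"` or `"spearman"`.
#' @return a one-row data frame: `statistic`, `estimate`, `p_value`,
#'   `n_pairs`, `ci_low`, `ci_high` (the interval columns are `NA` here;
#'   they are filled by [random_pair_resampling()]).
#' @export
pair_correlation <- function(pairs, statistic = c("pearson", "spearman")) {
  statistic <- match.arg(statistic)
  x <- pairs$value_a
  y <- pairs$value_b
  if (length(x) < 3) {
    stop("need at least 3 pairs, got ", length(x), call. = FALSE)
  }
  for (col in c("value_a", "value_b")) {
    if (stats::sd(pairs[[col]]) == 0) {
      stop("correlation undefined: column '", col, "' has zero variance",
           call. = FALSE)
    }
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = statistic, exact = FALSE))
  corr_row(statistic, unname(ct$estimate), ct$p.value, length(x))
}

corr_row <- function(statistic, estimate, p_value, n_pairs,
                     ci_low = NA_real_, ci_high = NA_real_) {
  data.frame(statistic = statistic, estimate = estimate,
             p_value = p_value, n_pairs = n_pairs,
             ci_low = ci_low, ci_high = ci_high,
             stringsAsFactors = FALSE)
}

#' Random-pair resampling of within-eye correlations
#'
#' When eyes have more than two images there is no canonical pair, so
#' the correlation is resampled: each replicate draws, for every eye,
#' one pair of two distinct images uniformly at random (the pair is put
#' in acquisition-time order), computes Pearson and Spearman across
#' eyes, and the procedure is repeated `n_reps` times. Reported are the
#' median correlation and the empirical 2.5th/97.5th percentiles as a
#' 95% interval. Note that such resampling intervals can have inaccurate
#' coverage for Pearson correlation.
#'
#' Eyes with fewer than two usable images are excluded (and counted in
#' the `n_excluded` attribute). When every eye has exactly two images
#' all replicates coincide with the first/last pairing and the interval
#' has zero width.
#'
#' @param cohort a `cohort` object.
#' @param method measurement column.
#' @param n_reps number of resampling replicates (default 20000).
#' @param seed integer seed; the caller's RNG stream is preserved.
#' @return a two-row data frame (Pearson and Spearman rows) in the
#'   [pair_correlation()] layout with `estimate` = median and
#'   `ci_low`/`ci_high` the percentile bounds; `p_value` is `NA` (the
#'   resampling estimates a distribution, not a test).
#' @export
random_pair_resampling <- function(cohort, method, n_reps = 20000,
                                   seed = NULL) {
  stopifnot(is.numeric(n_reps), n_reps >= 1)
  n_reps <- as.integer(n_reps)
  series <- eye_values(cohort, method)
  usable <- vapply(series, function(s) length(s$values) >= 2L, logical(1))
  n_excluded <- sum(!usable)
  series <- series[usable]
  n_eyes <- length(series)
  if (n_eyes == 0) {
    stop("no eye has >= 2 usable images for method '", method, "'",
         call. = FALSE)
  }
  if (n_eyes < 3) {
    stop("need at least 3 eyes with >= 2 usable images, got ", n_eyes,
         call. = FALSE)
  }

  A <- matrix(0, n_reps, n_eyes)
  B <- matrix(0, n_reps, n_eyes)
  with_seed(seed, {
    for (e in seq_len(n_eyes)) {
      v <- series[[e]]$values     # time-sorted
      n <- length(v)
      i <- sample.int(n, n_reps, replace = TRUE)
      d <- sample.int(n - 1L, n_reps, replace = TRUE)
      j <- d + (d >= i)           # second index distinct from the first
      A[, e] <- v[pmin(i, j)]     # earlier image first
      B[, e] <- v[pmax(i, j)]
    }
  })

  pearson <- row_pearson(A, B)
  spearman <- row_pearson(row_ranks(A), row_ranks(B))

  summarize <- function(r, name) {
    q <- stats::quantile(r, probs = c(0.025, 0.5, 0.975), type = 7,
                         names = FALSE, na.rm = TRUE)
    corr_row(name, q[2], NA_real_, n_eyes, q[1], q[3])
  }
  out <- rbind(summarize(pearson, "pearson"), summarize(spearman, "spearman"))
  attr(out, "n_reps") <- n_reps
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Between-/within-eye variance decomposition and ICC
#'
#' Estimates each eye's true trait value by the mean of its available
#' images; `sd_between` is the sample SD of these per-eye means across
#' eyes, and `sd_within` — the measurement-error SD — is the pooled
#' within-eye sample SD (square root of the df-weighted average of
#' per-eye variances). The intraclass correlation coefficient is then
#'
#' \deqn{ICC = \sigma_b^2 / (\sigma_b^2 + \sigma_w^2),}
#'
#' the fraction of total variation attributable to between-eye
#' differences: 1 means no measurement noise, and the ICC falls towards
#' 0 as error grows relative to the between-eye spread. Because the
#' choice of reference population for the between-eye spread is a design
#' decision, an adjusted ICC replacing `sd_between` by a supplied
#' `reference_sd_between` (typically from a broader combined cohort, see
#' [combined_reference_sd()]) is returned when that argument is given.
#'
#' Eyes with a single usable image still contribute their value to
#' `sd_between` but carry no within-eye information.
#'
#' @param cohort a `cohort` object.
#' @param method measurement column.
#' @param reference_sd_between optional between-eye SD from a reference
#'   population, in trait units.
#' @return a `variance_decomposition` list: `method`, `sd_between`,
#'   `sd_within`, `icc`, `icc_adjusted` (`NA` unless a reference SD was
#'   supplied), `n_eyes`, `n_images`.
#' @export
variance_decomposition <- function(cohort, method,
                                   reference_sd_between = NULL) {
  series <- eye_values(cohort, method)
  values <- lapply(series, `[[`, "values")
  n_multi <- sum(lengths(values) >= 2L)
  if (length(values) < 2 || n_multi < 2) {
    stop("variance decomposition needs >= 2 eyes with >= 2 usable images",
         call. = FALSE)
  }
  means <- vapply(values, mean, numeric(1))
  sd_between <- stats::sd(means)
  sd_within <- pooled_within_sd(values)
  icc <- sd_between^2 / (sd_between^2 + sd_within^2)
  icc_adjusted <- NA_real_
  if (!is.null(reference_sd_between)) {
    stopifnot(is.numeric(reference_sd_between), reference_sd_between > 0)
    icc_adjusted <- reference_sd_between^2 /
      (reference_sd_between^2 + sd_within^2)
  }
  structure(list(method = method,
                 sd_between = sd_between,
                 sd_within = sd_within,
                 icc = icc,
                 icc_adjusted = icc_adjusted,
                 n_eyes = length(values),
                 n_images = sum(lengths(values))),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("<variance decomposition [%s]: sd_between=%.5g sd_within=%.5g icc=%.4f%s; %d eyes, %d images>\n",
              x$method, x$sd_between, x$sd_within, x$icc,
              if (is.na(x$icc_adjusted)) ""
              else sprintf(" adj_icc=%.4f", x$icc_adjusted),
              x$n_eyes, x$n_images))
  invisible(x)
}

#' Between-eye SD pooled over several cohorts
#'
#' Computes each eye's mean trait value and returns the sample SD of
#' these means over all eyes of all supplied cohorts. This is the
#' reference between-eye spread used for the adjusted ICC and as the
#' default denominator of the individual-level noise statistic
#' [lambda_table()]: a narrow single-study population (e.g. young
#' healthy adults) understates the trait variation of the population of
#' interest, so the combined spread is the more meaningful yardstick.
#'
#' @param cohorts a `cohort` or a list of cohorts.
#' @param method measurement column.
#' @return the pooled between-eye sample SD (trait units).
#' @export
combined_reference_sd <- function(cohorts, method) {
  if (inherits(cohorts, "cohort")) {
    cohorts <- list(cohorts)
  }
  stopifnot(is.list(cohorts), length(cohorts) >= 1)
  means <- unlist(lapply(cohorts, function(co) {
    if (!method %in% cohort_methods(co)) {
      return(numeric(0))
    }
    vapply(eye_values(co, method), function(s) mean(s$values), numeric(1))
  }), use.names = FALSE)
  if (length(means) == 0) {
    stop("method '", method, "' absent from every supplied cohort",
         call. = FALSE)
  }
  if (length(means) < 2) {
    stop("need >= 2 eyes to estimate a between-eye SD", call. = FALSE)
  }
  stats::sd(means)
}

#' Interchangeability of two measurement methods
#'
#' Quantifies whether two tools measuring the same trait agree: images
#' with `quality_pbad >= pbad_max` are excluded, each method is averaged
#' per eye over the surviving images (averaging reduces measurement
#' noise), and the two per-eye mean vectors are compared by Pearson and
#' Spearman correlation plus a Bland-Altman summary of the differences
#' `a - b` (mean difference, SD of differences, and 95% limits of
#' agreement `mean +/- 1.96 * SD`).
#'
#' @param cohort a `cohort` object holding both methods.
#' @param method_a,method_b measurement columns to compare.
#' @param pbad_max quality gate; images at or above it are excluded
#'   (default 0.8).
#' @return a list with `correlations` (two-row data frame) and
#'   `bland_altman` (one-row data frame: `mean_diff`, `sd_diff`,
#'   `loa_low`, `loa_high`, `n_eyes`).
#' @export
interchangeability <- function(cohort, method_a, method_b, pbad_max = 0.8) {
  stopifnot(is.numeric(pbad_max), pbad_max >= 0, pbad_max <= 1)
  for (m in c(method_a, method_b)) {
    if (!m %in% cohort_methods(cohort)) {
      stop("method '", m, "' not present in cohort '",
           cohort_name(cohort), "'", call. = FALSE)
    }
  }
  gated <- cohort_subset(cohort, which(cohort$quality_pbad < pbad_max))
  if (nrow(gated) == 0) {
    stop("no images survive the quality gate pbad < ", pbad_max,
         call. = FALSE)
  }
  keys <- eye_key(gated)
  mean_by_eye <- function(m) {
    vapply(split(gated[[m]], keys),
           function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
           numeric(1))
  }
  a <- mean_by_eye(method_a)
  b <- mean_by_eye(method_b)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) {
    stop("fewer than 3 eyes with both methods survive the quality gate",
         call. = FALSE)
  }
  a <- a[ok]
  b <- b[ok]
  pairs <- data.frame(value_a = a, value_b = b)
  correlations <- rbind(pair_correlation(pairs, "pearson"),
                        pair_correlation(pairs, "spearman"))
  d <- a - b
  sd_diff <- stats::sd(d)
  bland_altman <- data.frame(mean_diff = mean(d), sd_diff = sd_diff,
                             loa_low = mean(d) - 1.96 * sd_diff,
                             loa_high = mean(d) + 1.96 * sd_diff,
                             n_eyes = length(d))
  list(correlations = correlations, bland_altman = bland_altman)
}
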
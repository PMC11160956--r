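#' Individual-level measurement noise lambda, per eye
#'
#' The relative SD `lambda` expresses how large the measurement
#' variation within one eye is compared to the trait variation between
#' eyes:
#'
#' \deqn{\lambda = 100\% \cdot \mathrm{SD}_{within\ eye} / \mathrm{SD}_{between\ eyes}.}
#'
#' A lambda of 0 means no measurement noise; because the SD squares
#' deviations, a single gross error weighs heavily — deliberate, since a
#' single bad image can move an individual across the population
#' distribution. The denominator `reference_sd` is a fixed between-eye
#' SD, by default taken from a combined reference population
#' ([combined_reference_sd()]) so that lambdas are comparable across
#' cohorts. Alongside each lambda the worst (maximum) `quality_pbad`
#' among the eye's used images is recorded, because a single
#' poor-quality image is the typical cause of a large lambda.
#'
#' Eyes with fewer than `min_images` usable values are ineligible — a
#' within-eye SD cannot be estimated from one value, and reporting 0
#' would understate their noise; their count is kept in the
#' `n_ineligible` attribute.
#'
#' @param cohort a `cohort` object.
#' @param method measurement column.
#' @param reference_sd positive between-eye SD (trait units) used as the
#'   denominator for every eye.
#' @param min_images minimum usable images for an eye to be eligible
#'   (default 2).
#' @return a data frame with one row per eligible eye: `subject_id`,
#'   `eye`, `method`, `lambda_pct`, `n_images`, `worst_pbad`.
#' @export
lambda_table <- function(cohort, method, reference_sd, min_images = 2) {
  stopifnot(is.numeric(reference_sd), length(reference_sd) == 1L)
  if (!is.finite(reference_sd) || reference_sd <= 0) {
    stop("`reference_sd` must be a positive number", call. = FALSE)
  }
  stopifnot(is.numeric(min_images), min_images >= 2)
  series <- eye_values(cohort, method)
  eligible <- vapply(series, function(s) length(s$values) >= min_images,
                     logical(1))
  if (!any(eligible)) {
    stop("no eye has >= ", min_images, " usable images for method '",
         method, "'", call. = FALSE)
  }
  kept <- series[eligible]
  out <- data.frame(
    subject_id = vapply(kept, `[[`, character(1), "subject_id"),
    eye = vapply(kept, `[[`, character(1), "eye"),
    method = method,
    lambda_pct = vapply(kept, function(s)
      100 * stats::sd(s$values) / reference_sd, numeric(1)),
    n_images = vapply(kept, function(s) length(s$values), integer(1)),
    worst_pbad = vapply(kept, function(s) max(s$pbad), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "reference_sd") <- reference_sd
  attr(out, "n_ineligible") <- sum(!eligible)
  out
}

#' Five-number summary of a lambda distribution
#'
#' @param lambdas a [lambda_table()] data frame.
#' @return a one-row data frame: `method`, `n_eyes`, `min`, `q1`,
#'   `median`, `q3`, `max` of `lambda_pct` (percent; type-7 quantiles).
#' @export
lambda_summary <- function(lambdas) {
  stopifnot(is.data.frame(lambdas), nrow(lambdas) >= 1,
            "lambda_pct" %in% names(lambdas))
  q <- five_num(lambdas$lambda_pct)
  data.frame(method = lambdas$method[1], n_eyes = nrow(lambdas),
             min = q$min, q1 = q$q1, median = q$median, q3 = q$q3,
             max = q$max, stringsAsFactors = FALSE)
}

#' Per-eye lambdas plus their cohort summary
#'
#' Convenience wrapper returning both the per-eye [lambda_table()] and
#' its [lambda_summary()].
#'
#' @inheritParams lambda_table
#' @return a list with elements `lambdas` and `summary`.
#' @export
lambda_distribution <- function(cohort, method, reference_sd,
                                min_images = 2) {
  lambdas <- lambda_table(cohort, method, reference_sd, min_images)
  list(lambdas = lambdas, summary = lambda_summary(lambdas))
}
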
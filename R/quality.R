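#' Exclude the worst-quality fraction of a cohort's images
#'
#' Ranks all images in the cohort by `quality_pbad`, descending (ties
#' broken by `image_id` for determinism), and removes the worst
#' `ceiling(fraction * N)` images, so any nonzero fraction removes at
#' least one image. The exclusion is cohort-global, not a per-eye quota,
#' and may leave some eyes with few or no images.
#'
#' @param cohort a `cohort` object.
#' @param fraction fraction of images to exclude, in `[0, 1]`.
#' @return the reduced `cohort`.
#' @export
exclude_worst_fraction <- function(cohort, fraction) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction >= 0, fraction <= 1)
  n <- nrow(cohort)
  k <- ceiling(fraction * n)
  if (k == 0) {
    return(cohort)
  }
  ord <- order(-cohort$quality_pbad, cohort$image_id)
  drop <- ord[seq_len(k)]
  cohort_subset(cohort, sort(setdiff(seq_len(n), drop)))
}

#' Drop images above a quality threshold
#'
#' Removes images with `quality_pbad > pbad_max`, the recommended way of
#' discarding only very bad images (e.g. `pbad_max = 0.8`) rather than a
#' fixed share of the data.
#'
#' @param cohort a `cohort` object.
#' @param pbad_max maximum tolerated quality score, in `[0, 1]`.
#' @return the filtered `cohort`.
#' @export
apply_quality_threshold <- function(cohort, pbad_max) {
  stopifnot(is.numeric(pbad_max), length(pbad_max) == 1L,
            pbad_max >= 0, pbad_max <= 1)
  cohort_subset(cohort, which(cohort$quality_pbad <= pbad_max))
}

#' Quality-exclusion sweep of the lambda distribution
#'
#' Recomputes the per-eye noise statistic lambda after excluding the
#' worst-quality 0%, 5%, ..., 50% of images (the range covering, and
#' slightly exceeding, exclusion levels typical of the oculomics
#' literature), showing how much of the measurement noise is carried by
#' poor-quality images. The `reference_sd` denominator is held fixed
#' across the sweep so the lambdas of different rows are comparable;
#' eyes falling below `min_images` surviving images at some exclusion
#' level are dropped from that row and reflected in `n_eyes_eligible`.
#'
#' @param cohort a `cohort` object.
#' @param method measurement column.
#' @param fractions increasing exclusion fractions in `[0, 0.5]`.
#' @param reference_sd fixed between-eye SD for [lambda_table()].
#' @param min_images eligibility floor per row (default 2).
#' @return a data frame with one row per fraction: `exclusion_fraction`,
#'   `pbad_cutoff` (the smallest excluded quality score; `NA` when
#'   nothing is excluded), `n_images_retained`, `n_eyes_eligible`,
#'   `lambda_min`, `lambda_median`, `lambda_max` (all `NA` when no eye
#'   remains eligible).
#' @export
exclusion_sweep <- function(cohort, method,
                            fractions = seq(0, 0.5, by = 0.05),
                            reference_sd, min_images = 2) {
  stopifnot(is.numeric(fractions), length(fractions) >= 1,
            all(fractions >= 0), all(fractions <= 0.5),
            all(diff(fractions) > 0))
  n <- nrow(cohort)
  rows <- lapply(fractions, function(f) {
    reduced <- exclude_worst_fraction(cohort, f)
    k <- n - nrow(reduced)
    cutoff <- if (k == 0) NA_real_ else {
      excluded <- setdiff(cohort$image_id, reduced$image_id)
      min(cohort$quality_pbad[cohort$image_id %in% excluded])
    }
    lam <- tryCatch(
      lambda_table(reduced, method, reference_sd, min_images),
      error = function(e) NULL)
    if (is.null(lam)) {
      data.frame(exclusion_fraction = f, pbad_cutoff = cutoff,
                 n_images_retained = nrow(reduced), n_eyes_eligible = 0L,
                 lambda_min = NA_real_, lambda_median = NA_real_,
                 lambda_max = NA_real_)
    } else {
      q <- five_num(lam$lambda_pct)
      data.frame(exclusion_fraction = f, pbad_cutoff = cutoff,
                 n_images_retained = nrow(reduced),
                 n_eyes_eligible = nrow(lam),
                 lambda_min = q$min, lambda_median = q$median,
                 lambda_max = q$max)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between lambda and the worst image quality per eye
#'
#' Relates each eye's noise statistic to the worst (maximum)
#' `quality_pbad` among its images — the worst rather than the mean,
#' because the squared deviations in the SD let a single bad image
#' dominate lambda. On the `"probability"` scale the quality score
#' itself is used; on the `"logit"` scale its log-odds
#' `logit(pbad)` are used instead, since a bounded probability can be a
#' poor linear predictor while the underlying raw quality logit is not.
#' The logit is a strictly monotone transform, so the Spearman
#' correlation must agree between the two scales; this identity is
#' verified at run time.
#'
#' @param lambdas a [lambda_table()] data frame.
#' @param scale `"probability"` or `"logit"`.
#' @return a two-row data frame (Pearson, Spearman) in the
#'   [pair_correlation()] layout, with attribute `scale`.
#' @export
lambda_quality_correlation <- function(lambdas,
                                       scale = c("probability", "logit")) {
  scale <- match.arg(scale)
  stopifnot(is.data.frame(lambdas),
            all(c("lambda_pct", "worst_pbad") %in% names(lambdas)))
  if (nrow(lambdas) < 3) {
    stop("need >= 3 eyes, got ", nrow(lambdas), call. = FALSE)
  }
  x <- if (scale == "logit") logit(lambdas$worst_pbad) else lambdas$worst_pbad
  y <- lambdas$lambda_pct
  if (stats::sd(x) == 0) {
    stop("correlation undefined: worst_pbad has zero variance",
         call. = FALSE)
  }
  if (stats::sd(y) == 0) {
    stop("correlation undefined: lambda_pct has zero variance",
         call. = FALSE)
  }
  pairs <- data.frame(value_a = y, value_b = x)
  out <- rbind(pair_correlation(pairs, "pearson"),
               pair_correlation(pairs, "spearman"))
  if (scale == "logit") {
    # rank invariance under the monotone logit link, checked at run time
    sp_prob <- suppressWarnings(stats::cor(y, lambdas$worst_pbad,
                                           method = "spearman"))
    if (abs(out$estimate[2] - sp_prob) > 1e-9) {
      stop("internal error: Spearman correlation differs between ",
           "probability and logit scales", call. = FALSE)
    }
  }
  attr(out, "scale") <- scale
  out
}
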
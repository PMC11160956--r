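#' Configuration for the synthetic cohort generator
#'
#' Describes a data-generating process with the structure the
#' repeatability analysis assumes: each eye has a true trait value drawn
#' around a method-specific mean, each image carries a quality score
#' `quality_pbad ~ Beta(quality_alpha, quality_beta)`, and the
#' measurement noise SD of an image grows with its quality score on the
#' log-odds scale:
#' `sd_image = sigma_within_base * (1 + noise_logit_slope * max(0, logit(pbad)))`,
#' so all images with `pbad < 0.5` share a common noise floor. Images
#' with `pbad > outlier_pbad_threshold` are additionally contaminated,
#' with probability `outlier_prob`, by a gross additive error with SD
#' `outlier_scale * sigma_between` — emulating single badly illuminated
#' images that dominate an eye's within-series SD. Visits (distinct
#' acquisition dates) can carry a cumulative random drift of the true
#' trait, for longitudinal designs; same-day repeats share the drifted
#' truth.
#'
#' Several measurement methods can be simulated on the same eyes: they
#' share each eye's standardized true value, drift path, image quality
#' and outlier flags, but have independent noise and their own scale
#' parameters (`mu`, `sigma_between`, `sigma_within_base`, `drift_sd`).
#'
#' @param name label for generated cohorts.
#' @param n_subjects number of subjects.
#' @param n_eyes total number of eyes; must lie in
#'   `[n_subjects, 2 * n_subjects]`. The first `n_eyes - n_subjects`
#'   subjects contribute both eyes.
#' @param images_per_eye single count or `c(min, max)` range (uniform).
#' @param n_visits single count or `c(min, max)` range of distinct
#'   acquisition dates per eye; capped at the eye's image count.
#' @param visit_interval_days `c(min, max)` days between consecutive
#'   visits (uniform).
#' @param methods named list; each element a list with `mu` (mean trait
#'   value), `sigma_between` (between-eye SD of the true trait),
#'   `sigma_within_base` (noise SD at perfect quality) and optionally
#'   `drift_sd` (SD of the per-visit true-trait step, default 0). All in
#'   trait units.
#' @param quality_alpha,quality_beta Beta shape parameters of the
#'   per-image `quality_pbad` distribution.
#' @param noise_logit_slope slope of the quality-to-noise link (see
#'   above); 0 gives quality-independent noise.
#' @param outlier_pbad_threshold quality level above which contamination
#'   can occur.
#' @param outlier_prob probability that a high-`pbad` image is an outlier.
#' @param outlier_scale outlier error SD as a multiple of each method's
#'   `sigma_between`.
#' @param seed integer seed making generation fully reproducible.
#' @return a `generator_config` list.
#' @seealso [cohort_preset()], [generate_cohort()]
#' @export
generator_config <- function(name = "synthetic",
                             n_subjects,
                             n_eyes = n_subjects,
                             images_per_eye,
                             n_visits = 1L,
                             visit_interval_days = c(1, 60),
                             methods,
                             quality_alpha = 1,
                             quality_beta = 2.5,
                             noise_logit_slope = 0,
                             outlier_pbad_threshold = 0.8,
                             outlier_prob = 0,
                             outlier_scale = 3,
                             seed = NULL) {
  stopifnot(is.numeric(n_subjects), n_subjects >= 1,
            is.numeric(n_eyes), n_eyes >= n_subjects,
            n_eyes <= 2 * n_subjects)
  images_per_eye <- as_range(images_per_eye, "images_per_eye", lower = 1)
  n_visits <- as_range(n_visits, "n_visits", lower = 1)
  visit_interval_days <- as_range(visit_interval_days, "visit_interval_days",
                                  lower = 0)
  if (!is.list(methods) || length(methods) == 0 || is.null(names(methods)) ||
      any(names(methods) == "")) {
    stop("`methods` must be a non-empty named list", call. = FALSE)
  }
  methods <- lapply(methods, function(m) {
    stopifnot(is.list(m), is.numeric(m$mu), m$mu > 0,
              is.numeric(m$sigma_between), m$sigma_between >= 0,
              is.numeric(m$sigma_within_base), m$sigma_within_base >= 0)
    if (is.null(m$drift_sd)) m$drift_sd <- 0
    stopifnot(is.numeric(m$drift_sd), m$drift_sd >= 0)
    m[c("mu", "sigma_between", "sigma_within_base", "drift_sd")]
  })
  stopifnot(quality_alpha > 0, quality_beta > 0,
            noise_logit_slope >= 0,
            outlier_pbad_threshold >= 0, outlier_pbad_threshold <= 1,
            outlier_prob >= 0, outlier_prob <= 1,
            outlier_scale >= 0)
  structure(list(name = name,
                 n_subjects = as.integer(n_subjects),
                 n_eyes = as.integer(n_eyes),
                 images_per_eye = images_per_eye,
                 n_visits = n_visits,
                 visit_interval_days = visit_interval_days,
                 methods = methods,
                 quality_alpha = quality_alpha,
                 quality_beta = quality_beta,
                 noise_logit_slope = noise_logit_slope,
                 outlier_pbad_threshold = outlier_pbad_threshold,
                 outlier_prob = outlier_prob,
                 outlier_scale = outlier_scale,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "generator_config")
}

as_range <- function(x, what, lower) {
  if (length(x) == 1L) x <- c(x, x)
  if (length(x) != 2L || !is.numeric(x) || any(x < lower) || x[1] > x[2]) {
    stop("`", what, "` must be a count or an increasing (min, max) range >= ",
         lower, call. = FALSE)
  }
  as.numeric(x)
}

#' Preset generator configurations for the two emulated study designs
#'
#' `"caledonia-like"` emulates a same-period repeated-imaging design:
#' 26 subjects, 39 eyes, 5-15 images per eye over 1-2 visits, no
#' longitudinal drift, mostly good image quality, and sparse gross
#' outliers confined to very poor-quality images. `"grape-like"`
#' emulates a longitudinal clinical design: 106 subjects, 196 eyes,
#' exactly one baseline and one follow-up image per eye (392 images),
#' between-visit drift of the true trait, and a quality distribution
#' with a heavier bad tail.
#'
#' Both presets carry two measurement methods, `"DART"` and
#' `"AutoMorph"`, whose between-eye SDs default to the eye-level trait
#' SDs observed in the corresponding real designs (DART 0.00733 /
#' 0.03653; AutoMorph 0.02421 / 0.08926).
#'
#' @param name `"caledonia-like"` or `"grape-like"`.
#' @param method_sds optional named numeric vector overriding the
#'   between-eye SD (`sigma_between`) per method.
#' @param seed integer seed stored in the config.
#' @return a [generator_config()].
#' @export
cohort_preset <- function(name = c("caledonia-like", "grape-like"),
                          method_sds = NULL, seed = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    "caledonia-like" = generator_config(
      name = "caledonia-like",
      n_subjects = 26, n_eyes = 39,
      images_per_eye = c(5, 15), n_visits = c(1, 2),
      visit_interval_days = c(1, 90),
      methods = list(
        DART = list(mu = 1.50, sigma_between = 0.00733,
                    sigma_within_base = 0.00125, drift_sd = 0),
        AutoMorph = list(mu = 1.45, sigma_between = 0.02421,
                         sigma_within_base = 0.0105, drift_sd = 0)),
      quality_alpha = 1, quality_beta = 2.5,
      noise_logit_slope = 3,
      outlier_pbad_threshold = 0.8, outlier_prob = 0.5, outlier_scale = 10,
      seed = seed),
    "grape-like" = generator_config(
      name = "grape-like",
      n_subjects = 106, n_eyes = 196,
      images_per_eye = 2, n_visits = 2,
      visit_interval_days = c(160, 1600),
      methods = list(
        DART = list(mu = 1.50, sigma_between = 0.03653,
                    sigma_within_base = 0.008, drift_sd = 0.012),
        AutoMorph = list(mu = 1.45, sigma_between = 0.08926,
                         sigma_within_base = 0.020, drift_sd = 0.030)),
      quality_alpha = 1, quality_beta = 1.6,
      noise_logit_slope = 3,
      outlier_pbad_threshold = 0.8, outlier_prob = 0.3, outlier_scale = 3,
      seed = seed))
  if (!is.null(method_sds)) {
    stopifnot(is.numeric(method_sds), !is.null(names(method_sds)))
    unknown <- setdiff(names(method_sds), names(cfg$methods))
    if (length(unknown) > 0) {
      stop("method_sds names not in preset: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (m in names(method_sds)) {
      cfg$methods[[m]]$sigma_between <- unname(method_sds[[m]])
    }
  }
  cfg
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a cohort from the process described in [generator_config()].
#' Generation is fully reproducible from `config$seed` (the caller's RNG
#' stream is left untouched).
#'
#' @param config a [generator_config()].
#' @return a list with elements
#'   \describe{
#'     \item{cohort}{the generated [as_cohort()] table;}
#'     \item{eye_truth}{one row per eye with the true (undrifted) trait
#'       value per method (`true_<method>` columns);}
#'     \item{image_truth}{one row per image with its visit index, the
#'       per-method noise SD actually applied (`noise_sd_<method>`), and
#'       the outlier flag.}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n_sub <- config$n_subjects
    n_eyes <- config$n_eyes
    n_bilateral <- n_eyes - n_sub
    subject_of_eye <- c(rep(seq_len(n_sub), 2)[seq_len(2 * n_bilateral)],
                        if (n_bilateral < n_sub) seq(n_bilateral + 1, n_sub))
    subject_of_eye <- sort(subject_of_eye)
    side <- unlist(lapply(rle(subject_of_eye)$lengths,
                          function(k) if (k == 2L) c("left", "right")
                                      else "left"),
                   use.names = FALSE)

    methods <- config$methods
    m_names <- names(methods)

    rows <- vector("list", n_eyes)
    eye_truth <- vector("list", n_eyes)
    image_truth <- vector("list", n_eyes)
    img_counter <- 0L

    for (e in seq_len(n_eyes)) {
      sid <- sprintf("S%03d", subject_of_eye[e])
      z_eye <- stats::rnorm(1)

      n_img <- sample_range_int(config$images_per_eye)
      n_vis <- min(sample_range_int(config$n_visits), n_img)
      # allocate images to visits: one each, remainder at random
      visit_of_img <- sort(c(seq_len(n_vis),
                             if (n_img > n_vis)
                               sample.int(n_vis, n_img - n_vis, replace = TRUE)))
      # visit dates: subject-specific start plus cumulative intervals
      start <- as.POSIXct("2022-01-01 09:00:00", tz = "UTC") +
        (subject_of_eye[e] - 1) * 86400
      gaps <- stats::runif(n_vis - 1, config$visit_interval_days[1],
                           config$visit_interval_days[2])
      visit_dates <- start + c(0, cumsum(gaps)) * 86400
      acquired_at <- visit_dates[visit_of_img] + 300 * seq_len(n_img)

      # shared standardized drift path across methods (0 at visit 1)
      drift_z <- c(0, cumsum(stats::rnorm(max(n_vis - 1, 0))))

      pbad <- stats::rbeta(n_img, config$quality_alpha, config$quality_beta)
      noise_factor <- 1 + config$noise_logit_slope * pmax(0, logit(pbad))
      is_outlier <- pbad > config$outlier_pbad_threshold &
        stats::runif(n_img) < config$outlier_prob

      img_ids <- sprintf("img%05d", img_counter + seq_len(n_img))
      img_counter <- img_counter + n_img

      row <- data.frame(subject_id = sid, eye = side[e],
                        image_id = img_ids,
                        acquired_at = acquired_at,
                        quality_pbad = pbad,
                        stringsAsFactors = FALSE)
      truth_i <- data.frame(image_id = img_ids, subject_id = sid,
                            eye = side[e], visit = visit_of_img,
                            quality_pbad = pbad, is_outlier = is_outlier,
                            stringsAsFactors = FALSE)
      truth_e <- data.frame(subject_id = sid, eye = side[e],
                            n_images = n_img, n_visits = n_vis,
                            stringsAsFactors = FALSE)

      for (m in m_names) {
        p <- methods[[m]]
        true_val <- p$mu + p$sigma_between * z_eye
        sd_img <- p$sigma_within_base * noise_factor
        obs <- true_val + p$drift_sd * drift_z[visit_of_img] +
          stats::rnorm(n_img, 0, sd_img)
        if (any(is_outlier)) {
          obs[is_outlier] <- obs[is_outlier] +
            stats::rnorm(sum(is_outlier), 0,
                         config$outlier_scale * p$sigma_between)
        }
        row[[m]] <- obs
        truth_i[[paste0("noise_sd_", m)]] <- sd_img
        truth_e[[paste0("true_", m)]] <- true_val
      }
      rows[[e]] <- row
      eye_truth[[e]] <- truth_e
      image_truth[[e]] <- truth_i
    }

    cohort <- as_cohort(do.call(rbind, rows), methods = m_names,
                        name = config$name)
    list(cohort = cohort,
         eye_truth = do.call(rbind, eye_truth),
         image_truth = do.call(rbind, image_truth))
  })
}

sample_range_int <- function(range) {
  lo <- as.integer(round(range[1]))
  hi <- as.integer(round(range[2]))
  if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
}
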
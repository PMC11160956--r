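#' Run the full repeatability and robustness analysis
#'
#' Orchestrates every analysis this package implements over one or more
#' cohorts and one or more measurement methods: per-method reference
#' between-eye SD pooled over all cohorts (the `"auto"` policy), a
#' population block per cohort and method (first/last-pair Pearson and
#' Spearman, random-pair resampling with empirical 95% interval where
#' eyes have more than two images, and the between-/within-eye variance
#' decomposition with ICC and adjusted ICC where eyes carry repeats),
#' the per-eye lambda tables and summaries, the quality-exclusion
#' sweeps, the lambda-versus-worst-quality correlations on both scales,
#' and — when at least two methods are present — the interchangeability
#' analysis of the first two. Progress and exclusion counts are logged
#' per stage via `message()`.
#'
#' The run is deterministic given `seed`; with an `out_dir` the result
#' tables are written as CSV, a machine-readable JSON summary is
#' emitted, simple plots are drawn, and a manifest with an MD5 content
#' hash per output file is written.
#'
#' @param cohorts a `cohort` or (optionally named) list of cohorts.
#' @param methods measurement columns to analyse; default: the methods
#'   common to all cohorts.
#' @param n_reps resampling replicates for [random_pair_resampling()].
#' @param seed integer seed governing all randomness of the run.
#' @param reference_sd `"auto"` (pool all supplied cohorts per method
#'   via [combined_reference_sd()]) or a fixed positive number.
#' @param fractions exclusion fractions for [exclusion_sweep()].
#' @param min_images eligibility floor for lambda computations.
#' @param pbad_max quality gate for [interchangeability()].
#' @param out_dir optional output directory (created if needed).
#' @param plots draw PDF plots when writing outputs (default `TRUE`).
#' @return a `repeatability_report` list with elements `reference_sd`,
#'   `population`, `lambda`, `lambda_summary`, `sweep`,
#'   `quality_correlation`, `interchangeability`, `config` and (when
#'   written) `manifest`.
#' @export
run_full_analysis <- function(cohorts, methods = NULL, n_reps = 20000,
                              seed = NULL, reference_sd = "auto",
                              fractions = seq(0, 0.5, by = 0.05),
                              min_images = 2, pbad_max = 0.8,
                              out_dir = NULL, plots = TRUE) {
  if (inherits(cohorts, "cohort")) {
    cohorts <- list(cohorts)
  }
  stopifnot(is.list(cohorts), length(cohorts) >= 1)
  if (is.null(names(cohorts)) || any(names(cohorts) == "")) {
    names(cohorts) <- vapply(cohorts, cohort_name, character(1))
  }
  shared <- Reduce(intersect, lapply(cohorts, cohort_methods))
  if (is.null(methods)) {
    methods <- shared
  }
  unknown <- setdiff(methods, shared)
  if (length(unknown) > 0) {
    stop("[methods] method(s) not present in every cohort: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  stage <- function(label, fmt, ...) {
    message(sprintf(paste0("[", label, "] ", fmt), ...))
  }

  ref_sd <- vapply(methods, function(m) {
    if (identical(reference_sd, "auto")) {
      combined_reference_sd(cohorts, m)
    } else {
      stopifnot(is.numeric(reference_sd), reference_sd > 0)
      as.numeric(reference_sd)
    }
  }, numeric(1))
  names(ref_sd) <- methods
  for (m in methods) {
    stage("reference_sd", "method %s: between-eye SD %.6g", m, ref_sd[m])
  }

  population <- list()
  lambda_tabs <- list()
  lambda_sums <- list()
  sweeps <- list()
  qual_corr <- list()
  interchange <- list()

  run_stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", label, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  seed_i <- 0L
  next_seed <- function() {
    if (is.null(seed)) return(NULL)
    seed_i <<- seed_i + 1L
    (as.integer(seed) * 1000L + seed_i) %% .Machine$integer.max
  }

  for (cn in names(cohorts)) {
    co <- cohorts[[cn]]
    for (m in methods) {
      key <- paste(cn, m, sep = ".")
      max_imgs <- max(lengths(lapply(eye_values(co, m), `[[`, "values")))

      pop <- run_stage(paste0("population:", key), {
        fl <- first_last_pairing(co, m)
        if (attr(fl, "n_skipped") > 0) {
          stage("population", "%s: %d eye(s) skipped (<2 usable images)",
                key, attr(fl, "n_skipped"))
        }
        block <- rbind(
          cbind(analysis = "first_last", pair_correlation(fl, "pearson")),
          cbind(analysis = "first_last", pair_correlation(fl, "spearman")))
        if (max_imgs > 2) {
          rs <- random_pair_resampling(co, m, n_reps = n_reps,
                                       seed = next_seed())
          block <- rbind(block, cbind(analysis = "random_pairs", rs))
        }
        vd <- tryCatch(variance_decomposition(co, m, ref_sd[m]),
                       error = function(e) NULL)
        list(correlations = block, variance = vd)
      })
      population[[key]] <- pop

      ld <- run_stage(paste0("lambda:", key),
                      lambda_distribution(co, m, ref_sd[m], min_images))
      lambda_tabs[[key]] <- ld$lambdas
      lambda_sums[[key]] <- cbind(cohort = cn, ld$summary)
      if (attr(ld$lambdas, "n_ineligible") > 0) {
        stage("lambda", "%s: %d ineligible eye(s)", key,
              attr(ld$lambdas, "n_ineligible"))
      }

      sweeps[[key]] <- run_stage(paste0("sweep:", key),
        cbind(cohort = cn, method = m,
              exclusion_sweep(co, m, fractions, ref_sd[m], min_images)))

      qual_corr[[key]] <- run_stage(paste0("quality_corr:", key), {
        rbind(cbind(cohort = cn, method = m, scale = "probability",
                    lambda_quality_correlation(ld$lambdas, "probability")),
              cbind(cohort = cn, method = m, scale = "logit",
                    lambda_quality_correlation(ld$lambdas, "logit")))
      })
    }
    if (length(methods) >= 2) {
      interchange[[cn]] <- run_stage(paste0("interchangeability:", cn),
        interchangeability(co, methods[1], methods[2], pbad_max))
    }
  }

  report <- structure(list(
    reference_sd = ref_sd,
    population = population,
    lambda = lambda_tabs,
    lambda_summary = do.call(rbind, c(lambda_sums, make.row.names = FALSE)),
    sweep = do.call(rbind, c(sweeps, make.row.names = FALSE)),
    quality_correlation = do.call(rbind, c(qual_corr,
                                           make.row.names = FALSE)),
    interchangeability = interchange,
    config = list(methods = methods, n_reps = n_reps, seed = seed,
                  reference_sd_policy = reference_sd,
                  fractions = fractions, min_images = min_images,
                  pbad_max = pbad_max)),
    class = "repeatability_report")

  if (!is.null(out_dir)) {
    report$manifest <- write_results(report, out_dir, plots = plots)
  }
  report
}

#' Serialize a report (or any list of result tables) to disk
#'
#' Data frames become CSV files (full double precision, so values
#' round-trip well beyond 12 significant digits); the whole result is
#' additionally flattened into one machine-readable `summary.json`. A
#' manifest CSV listing every written file with its MD5 content hash is
#' written last and returned.
#'
#' @param results a `repeatability_report` or a named list whose
#'   elements are data frames (written as CSV) or other objects
#'   (serialized into the JSON summary only).
#' @param out_dir output directory, created if missing.
#' @param plots also draw the standard plots (lambda boxplots, sweep
#'   curves, lambda-versus-quality scatter) when the input is a report.
#' @return invisibly, the manifest data frame (`file`, `md5`).
#' @export
write_results <- function(results, out_dir, plots = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  write_df <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }

  is_report <- inherits(results, "repeatability_report")
  if (is_report) {
    for (key in names(results$population)) {
      blk <- results$population[[key]]
      write_df(blk$correlations, paste0("population_", sanitize(key)))
    }
    vd_rows <- lapply(names(results$population), function(key) {
      vd <- results$population[[key]]$variance
      if (is.null(vd)) return(NULL)
      cbind(block = key, as.data.frame(unclass(vd)))
    })
    vd_rows <- Filter(Negate(is.null), vd_rows)
    if (length(vd_rows) > 0) {
      write_df(do.call(rbind, vd_rows), "variance_decomposition")
    }
    for (key in names(results$lambda)) {
      write_df(results$lambda[[key]], paste0("lambda_", sanitize(key)))
    }
    if (!is.null(results$lambda_summary)) {
      write_df(results$lambda_summary, "lambda_summary")
    }
    if (!is.null(results$sweep)) write_df(results$sweep, "sweep")
    if (!is.null(results$quality_correlation)) {
      write_df(results$quality_correlation, "quality_correlation")
    }
    for (cn in names(results$interchangeability)) {
      ic <- results$interchangeability[[cn]]
      write_df(ic$correlations, paste0("interchange_corr_", sanitize(cn)))
      write_df(ic$bland_altman, paste0("interchange_ba_", sanitize(cn)))
    }
    if (plots) {
      files <- c(files, report_plots(results, out_dir))
    }
  } else {
    stopifnot(is.list(results), !is.null(names(results)))
    for (nm in names(results)) {
      if (is.data.frame(results[[nm]])) {
        write_df(results[[nm]], sanitize(nm))
      }
    }
  }

  json_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(strip_report(results), json_path, digits = NA,
                       auto_unbox = TRUE, na = "null", force = TRUE)
  files <- c(files, json_path)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest,
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

sanitize <- function(x) gsub("[^A-Za-z0-9_.-]+", "_", x)

# drop the manifest (self-referential) before JSON serialization
strip_report <- function(results) {
  if (inherits(results, "repeatability_report")) {
    results <- unclass(results)
    results$manifest <- NULL
  }
  results
}

# Standard convenience plots; never inputs to any computation.
report_plots <- function(report, out_dir) {
  path <- file.path(out_dir, "plots.pdf")
  lam <- do.call(rbind, c(unname(Map(function(key, df) {
    cbind(block = key, df)
  }, names(report$lambda), report$lambda)), make.row.names = FALSE))
  grDevices::pdf(path, width = 8, height = 5)
  on.exit(grDevices::dev.off())
  print(ggplot2::ggplot(lam,
                        ggplot2::aes(x = block, y = lambda_pct)) +
          ggplot2::geom_boxplot() +
          ggplot2::labs(x = NULL, y = "lambda (%)",
                        title = "Individual-level measurement noise") +
          ggplot2::theme_minimal())
  print(ggplot2::ggplot(report$sweep,
                        ggplot2::aes(x = exclusion_fraction,
                                     y = lambda_median,
                                     colour = paste(cohort, method))) +
          ggplot2::geom_line() +
          ggplot2::geom_point() +
          ggplot2::labs(x = "fraction of images excluded",
                        y = "median lambda (%)", colour = NULL,
                        title = "Quality-exclusion sweep") +
          ggplot2::theme_minimal())
  print(ggplot2::ggplot(lam, ggplot2::aes(x = worst_pbad,
                                          y = lambda_pct)) +
          ggplot2::geom_point(alpha = 0.6) +
          ggplot2::facet_wrap(~block, scales = "free_y") +
          ggplot2::labs(x = "worst P(bad) per eye", y = "lambda (%)",
                        title = "Noise versus worst image quality") +
          ggplot2::theme_minimal())
  path
}

#' End-to-end demonstration on the two preset designs
#'
#' Generates a `caledonia-like` and a `grape-like` synthetic cohort and
#' runs [run_full_analysis()] on both with the default settings.
#'
#' @param seed integer seed for generation and analysis.
#' @param out_dir optional output directory passed through.
#' @param n_reps resampling replicates (default 20000).
#' @return the `repeatability_report`, with the generated data attached
#'   as attribute `"generated"`.
#' @export
demo_analysis <- function(seed = 1, out_dir = NULL, n_reps = 20000) {
  cal <- generate_cohort(cohort_preset("caledonia-like", seed = seed))
  gra <- generate_cohort(cohort_preset("grape-like", seed = seed + 1))
  report <- run_full_analysis(list(cal$cohort, gra$cohort),
                              n_reps = n_reps, seed = seed,
                              out_dir = out_dir)
  attr(report, "generated") <- list(`caledonia-like` = cal,
                                    `grape-like` = gra)
  report
}
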
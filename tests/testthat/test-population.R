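# Population-level repeatability: pairings, correlations, resampling,
# and the between-/within-eye variance decomposition.

test_that("first/last pairing takes the earliest and latest usable image per eye", {
  co <- make_cohort(list(c(1.50, 1.51, 1.52, 1.53, 1.54),
                         c(1.60, 1.65),
                         c(1.70)))
  pairs <- first_last_pairing(co, "FD")
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$value_a, c(1.50, 1.60))
  expect_equal(pairs$value_b, c(1.54, 1.65))
  expect_equal(attr(pairs, "n_skipped"), 1)
  expect_error(first_last_pairing(co, "nope"), "nope")
})

test_that("pair correlations behave on canonical cases and reject degenerate input", {
  lin <- data.frame(value_a = c(1, 2, 3), value_b = c(2, 4, 6))
  expect_equal(pair_correlation(lin, "pearson")$estimate, 1)

  cub <- data.frame(value_a = 1:4, value_b = (1:4)^3)
  expect_equal(pair_correlation(cub, "spearman")$estimate, 1)
  expect_lt(pair_correlation(cub, "pearson")$estimate, 1)

  flat <- data.frame(value_a = c(1, 1, 1), value_b = c(1, 2, 3))
  expect_error(pair_correlation(flat, "pearson"), "value_a")
  expect_error(pair_correlation(lin[1:2, ], "pearson"), "at least 3")
})

test_that("correlations match independent textbook-formula oracles to 1e-12", {
  set.seed(70)
  n <- 50
  x <- rnorm(n)
  y <- 0.7 * x + sqrt(1 - 0.7^2) * rnorm(n)
  pairs <- data.frame(value_a = 1.5 + 0.05 * x, value_b = 1.5 + 0.05 * y)
  expect_equal(pair_correlation(pairs, "pearson")$estimate,
               oracle_pearson(pairs$value_a, pairs$value_b),
               tolerance = 1e-12)
  expect_equal(pair_correlation(pairs, "spearman")$estimate,
               oracle_spearman(pairs$value_a, pairs$value_b),
               tolerance = 1e-12)
})

test_that("spearman is invariant under strictly increasing transforms", {
  set.seed(71)
  for (i in 1:5) {
    pairs <- data.frame(value_a = exp(rnorm(20)), value_b = exp(rnorm(20)))
    base <- pair_correlation(pairs, "spearman")$estimate
    warped <- data.frame(value_a = log(pairs$value_a),
                         value_b = pairs$value_b^3)
    expect_equal(pair_correlation(warped, "spearman")$estimate, base,
                 tolerance = 1e-12)
  }
})

test_that("variance decomposition matches a brute-force two-pass oracle", {
  vals <- list(c(0.9, 1.1), c(1.9, 2.1))
  co <- make_cohort(vals)
  vd <- variance_decomposition(co, "FD")
  oracle <- oracle_variance_decomposition(vals)
  expect_equal(vd$sd_between, oracle$sd_between, tolerance = 1e-12)
  expect_equal(vd$sd_within, oracle$sd_within, tolerance = 1e-12)
  expect_equal(vd$icc, oracle$icc, tolerance = 1e-12)
  # unbalanced series with a single-image eye: that eye enters
  # sd_between only
  vals2 <- list(c(1.0, 1.2, 1.4), c(2.0, 2.1), c(3.0))
  vd2 <- variance_decomposition(make_cohort(vals2), "FD")
  oracle2 <- oracle_variance_decomposition(vals2)
  expect_equal(vd2$sd_between, oracle2$sd_between, tolerance = 1e-12)
  expect_equal(vd2$sd_within, oracle2$sd_within, tolerance = 1e-12)
  expect_equal(vd2$n_eyes, 3)
})

test_that("a noiseless cohort has ICC 1 and the ICC identity holds exactly", {
  noiseless <- make_cohort(list(c(1.5, 1.5), c(1.6, 1.6), c(1.7, 1.7)))
  expect_equal(variance_decomposition(noiseless, "FD")$icc, 1.0)

  set.seed(72)
  for (i in 1:5) {
    vals <- replicate(6, 1.5 + 0.1 * rnorm(1) + 0.02 * rnorm(4),
                      simplify = FALSE)
    vd <- variance_decomposition(make_cohort(vals), "FD")
    expect_equal(vd$icc, 1 / (1 + (vd$sd_within / vd$sd_between)^2),
                 tolerance = 1e-12)
    expect_true(vd$icc >= 0 && vd$icc <= 1)
  }

  expect_error(variance_decomposition(make_cohort(list(c(1, 2))), "FD"),
               ">= 2 eyes")
})

test_that("the adjusted ICC replaces the between-eye SD by the reference value", {
  vals <- list(c(1.0, 1.2, 1.4), c(2.0, 2.1, 2.3), c(3.0, 3.3, 3.1))
  vd <- variance_decomposition(make_cohort(vals), "FD",
                               reference_sd_between = 2)
  expect_equal(vd$icc_adjusted, 4 / (4 + vd$sd_within^2), tolerance = 1e-12)
  expect_true(is.na(variance_decomposition(make_cohort(vals),
                                           "FD")$icc_adjusted))
})

test_that("combined reference SD pools eyes across cohorts", {
  co1 <- make_cohort(list(c(0, 0) + 1, c(0, 0) + 1))
  co2 <- make_cohort(list(c(1, 1) + 1, c(1, 1) + 1))
  expect_equal(combined_reference_sd(list(co1, co2), "FD"),
               sd(c(1, 1, 2, 2)), tolerance = 1e-12)
  # pooling a cohort with itself is the SD of the duplicated means
  # (equal to the single-cohort SD up to the n-1 denominator, so the
  # two agree ever closer as the number of eyes grows)
  co <- make_cohort(list(c(1.4, 1.5), c(1.6, 1.7), c(1.8, 1.9)))
  expect_equal(combined_reference_sd(list(co, co), "FD"),
               sd(rep(c(1.45, 1.65, 1.85), 2)), tolerance = 1e-12)
  big <- make_cohort(as.list(seq(1, 2, length.out = 400)))
  expect_equal(combined_reference_sd(list(big, big), "FD"),
               combined_reference_sd(big, "FD"), tolerance = 1e-3)
  expect_error(combined_reference_sd(co, "nope"), "absent")
})

test_that("random-pair resampling is deterministic and degenerates correctly", {
  # identical values within each eye: every pairing is perfect
  noiseless <- make_cohort(list(c(1.5, 1.5, 1.5), c(1.6, 1.6, 1.6),
                                c(1.7, 1.7, 1.7), c(1.8, 1.8, 1.8)))
  rs <- random_pair_resampling(noiseless, "FD", n_reps = 200, seed = 1)
  expect_equal(rs$estimate, c(1, 1))
  expect_equal(rs$ci_high - rs$ci_low, c(0, 0))

  # same seed, same answer; RNG stream untouched
  co <- make_cohort(replicate(8, 1.5 + 0.1 * rnorm(1) + 0.01 * rnorm(5),
                              simplify = FALSE))
  set.seed(42)
  before <- .Random.seed
  r1 <- random_pair_resampling(co, "FD", n_reps = 500, seed = 9)
  expect_identical(before, .Random.seed)
  r2 <- random_pair_resampling(co, "FD", n_reps = 500, seed = 9)
  expect_identical(r1, r2)

  # eyes with < 2 usable images are excluded, all-excluded errors
  thin <- make_cohort(list(c(1.5), c(1.6), c(1.7)))
  expect_error(random_pair_resampling(thin, "FD"), "no eye")
})

test_that("interchangeability: self-agreement, constant offset, and noise averaging", {
  vals <- list(c(1.40, 1.42, 1.44), c(1.55, 1.56, 1.54), c(1.62, 1.66, 1.64),
               c(1.71, 1.70, 1.74))
  df <- as.data.frame(make_cohort(vals, method = "A"))
  df$B <- df$A
  co <- as_cohort(df, methods = c("A", "B"))
  ic <- interchangeability(co, "A", "B")
  expect_equal(ic$correlations$estimate, c(1, 1))
  expect_equal(ic$bland_altman$mean_diff, 0)
  expect_equal(ic$bland_altman$loa_high - ic$bland_altman$loa_low, 0)

  df$B <- df$A + 0.5
  co2 <- as_cohort(df, methods = c("A", "B"))
  ic2 <- interchangeability(co2, "A", "B")
  expect_equal(ic2$correlations$estimate, c(1, 1))
  expect_equal(ic2$bland_altman$mean_diff, -0.5)

  # per-eye averaging beats single images when methods share the truth
  cfg <- generator_config(n_subjects = 150, images_per_eye = 6,
                          methods = list(
                            A = list(mu = 1.5, sigma_between = 0.03,
                                     sigma_within_base = 0.02),
                            B = list(mu = 1.5, sigma_between = 0.03,
                                     sigma_within_base = 0.02)),
                          seed = 77)
  g <- generate_cohort(cfg)
  ic3 <- interchangeability(g$cohort, "A", "B", pbad_max = 1)
  first_img <- !duplicated(paste(g$cohort$subject_id, g$cohort$eye))
  single <- cor(g$cohort$A[first_img], g$cohort$B[first_img])
  expect_gt(ic3$correlations$estimate[1], single)

  # the quality gate can starve the analysis
  df3 <- df
  df3$quality_pbad <- 0.95
  co3 <- as_cohort(df3, methods = c("A", "B"))
  expect_error(interchangeability(co3, "A", "B", pbad_max = 0.8),
               "quality gate")
})
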
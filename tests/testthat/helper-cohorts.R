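# Builders for small in-code fixtures.

# Build a cohort from a list of per-eye value vectors (one method).
# Eyes are named E01, E02, ...; images are minutes apart in list order,
# so the first element of each vector is the "first" image.
make_cohort <- function(values_by_eye, pbad_by_eye = NULL,
                        method = "FD", name = "toy") {
  n_eyes <- length(values_by_eye)
  rows <- lapply(seq_len(n_eyes), function(e) {
    v <- values_by_eye[[e]]
    p <- if (is.null(pbad_by_eye)) rep(0.1, length(v)) else pbad_by_eye[[e]]
    data.frame(subject_id = sprintf("E%02d", e),
               eye = "left",
               image_id = sprintf("e%02d_i%02d", e, seq_along(v)),
               acquired_at = as.POSIXct("2022-01-01 09:00:00", tz = "UTC") +
                 60 * seq_along(v),
               quality_pbad = p,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df[[method]] <- unlist(values_by_eye, use.names = FALSE)
  as_cohort(df, methods = method, name = name)
}

# Independent two-pass / textbook-sum-formula oracles, deliberately
# written without sd()/cor() so they cannot share code paths with the
# package implementation.
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x), rank(y))
}

oracle_variance_decomposition <- function(values_by_eye) {
  means <- vapply(values_by_eye, function(v) sum(v) / length(v), numeric(1))
  sd_b <- oracle_sd(means)
  num <- 0
  den <- 0
  for (v in values_by_eye) {
    if (length(v) >= 2) {
      num <- num + (length(v) - 1) * oracle_sd(v)^2
      den <- den + (length(v) - 1)
    }
  }
  sd_w <- sqrt(num / den)
  list(sd_between = sd_b, sd_within = sd_w,
       icc = sd_b^2 / (sd_b^2 + sd_w^2))
}
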
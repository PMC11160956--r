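# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations do not
#' perturb the caller's random stream. With `seed = NULL` the expression
#' runs against the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Log-odds with clipping
#'
#' `logit(p) = log(p / (1 - p))` with `p` clipped to `[eps, 1 - eps]` so
#' that quality scores of exactly 0 or 1 map to large finite values.
#'
#' @param p numeric vector of probabilities.
#' @param eps clipping bound; defaults to `1e-6`.
#' @return numeric vector of log-odds.
#' @export
#' @examples
#' logit(c(0.5, 0.9))
logit <- function(p, eps = 1e-6) {
  stopifnot(is.numeric(p), eps > 0, eps < 0.5)
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

# Pooled within-group sample SD: sqrt of the df-weighted mean of the
# per-group sample variances (standard one-way layout). Groups with
# fewer than 2 values contribute nothing.
pooled_within_sd <- function(values_by_group) {
  ns <- lengths(values_by_group)
  keep <- ns >= 2L
  if (!any(keep)) {
    return(NA_real_)
  }
  vars <- vapply(values_by_group[keep], stats::var, numeric(1))
  dfs <- ns[keep] - 1L
  sqrt(sum(dfs * vars) / sum(dfs))
}

# Row-wise ranks of a numeric matrix (average ties). Uses a single
# order() pass for the tie-free case, falling back to apply(rank) only
# when some row contains duplicated values.
row_ranks <- function(m) {
  R <- nrow(m)
  C <- ncol(m)
  if (C == 0L || R == 0L) {
    return(m)
  }
  ri <- row(m)
  o <- order(ri, m)
  sorted <- m[o]
  rows_sorted <- ri[o]
  has_ties <- anyNA(sorted) ||
    any(diff(sorted) == 0 & diff(rows_sorted) == 0L)
  if (has_ties) {
    return(t(apply(m, 1L, rank)))
  }
  rr <- m
  rr[o] <- rep.int(seq_len(C), R)
  rr
}

# Row-wise Pearson correlation of two conformable matrices (one value
# per row, computed across columns).
row_pearson <- function(a, b) {
  ac <- a - rowMeans(a)
  bc <- b - rowMeans(b)
  rowSums(ac * bc) / sqrt(rowSums(ac * ac) * rowSums(bc * bc))
}

# Type-7 quantiles named for summary tables.
five_num <- function(x) {
  q <- stats::quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1), type = 7,
                       names = FALSE)
  list(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}
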
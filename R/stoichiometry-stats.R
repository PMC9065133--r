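#' Per-condition box-whisker summary of step counts
#'
#' Aggregates included step counts into the statistics used for
#' box-and-whisker reporting: box between the 25th and 75th percentiles
#' with the median marked, whiskers at the 10th and 90th percentiles, and
#' values outside the whiskers listed individually as outliers.
#' Percentiles use linear interpolation between closest ranks
#' ([stats::quantile()] type 7). The "average" stoichiometry is the
#' arithmetic mean of included counts; the median is reported alongside.
#'
#' @param results A step-count tibble from [count_steps()] (columns
#'   `condition`, `k_steps`, `exclusion_reason`, `included`).
#' @param quantile_type Percentile convention, passed to
#'   [stats::quantile()].
#' @return A tibble of class `condition_summary` with one row per
#'   condition: `condition`, `n_included`, per-reason exclusion counts
#'   (`n_edge_clipped`, `n_bright_cy3`, `n_unstable`, `n_zero_steps`),
#'   `mean`, `median`, `q25`, `q75`, `p10`, `p90`, `max_count`, and a
#'   list-column `outliers`.
#' @export
summarize_conditions <- function(results, quantile_type = 7) {
  stopifnot(is.data.frame(results), all(c("k_steps", "included") %in%
                                          names(results)))
  if (!"condition" %in% names(results)) results$condition <- NA_character_
  split_by <- split(seq_len(nrow(results)), results$condition, drop = FALSE)
  if (length(split_by) == 0L) split_by <- list(seq_len(nrow(results)))
  rows <- purrr::imap(split_by, function(idx, label) {
    sub <- results[idx, , drop = FALSE]
    counts <- sub$k_steps[sub$included]
    if (length(counts) == 0L) {
      abort(sprintf("Condition %s has no included traces.", label),
            class = "bleachsteps_empty_cohort")
    }
    q <- quantile(counts, c(0.10, 0.25, 0.50, 0.75, 0.90),
                  type = quantile_type, names = FALSE)
    n_reason <- table(factor(
      sub$exclusion_reason,
      levels = c("edge_clipped", "bright_cy3", "unstable", "zero_steps")
    ))
    tibble(
      condition = label,
      n_included = length(counts),
      n_edge_clipped = as.integer(n_reason[["edge_clipped"]]),
      n_bright_cy3 = as.integer(n_reason[["bright_cy3"]]),
      n_unstable = as.integer(n_reason[["unstable"]]),
      n_zero_steps = as.integer(n_reason[["zero_steps"]]),
      mean = mean(counts),
      median = q[3], q25 = q[2], q75 = q[4], p10 = q[1], p90 = q[5],
      max_count = max(counts),
      outliers = list(sort(counts[counts < q[1] | counts > q[5]]))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("condition_summary", class(out))
  out
}

#' @export
print.condition_summary <- function(x, ...) {
  cat("<condition_summary> photobleaching steps per intasome\n")
  NextMethod()
}

# Exact two-sided rank-sum p-value by enumeration of all C(n1+n2, n1)
# group assignments of the pooled ranks (midranks for ties).
ranksum_exact <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pooled), n1)
  sums <- colSums(matrix(r[combos], nrow = n1))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

#' Distribution-free comparison of two step-count cohorts
#'
#' Wilcoxon rank-sum comparison of per-intasome step counts between two
#' conditions. For small cohorts (`n1 + n2 <= exact_max`) the two-sided
#' p-value is computed exactly by enumerating all assignments of the
#' pooled (mid)ranks; otherwise the normal approximation with tie
#' correction is used. The standardized statistic is antisymmetric:
#' swapping the cohorts flips its sign and leaves the p-value unchanged.
#'
#' @param a,b Numeric vectors of step counts (each of length >= 3).
#' @param exact_max Largest pooled size for exact enumeration.
#' @return A one-row tibble: `statistic` (standardized rank-sum z),
#'   `p.value`, `method`, `n_a`, `n_b`.
#' @export
compare_conditions <- function(a, b, exact_max = 12L) {
  if (length(a) < 3L || length(b) < 3L) {
    abort("Both cohorts must contain at least 3 values.")
  }
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (sigma2 > 0) (w - mu) / sqrt(sigma2) else 0
  if (n <= exact_max) {
    p <- ranksum_exact(a, b)
    method <- "exact rank-sum permutation"
  } else {
    p <- if (sigma2 > 0) 2 * pnorm(-abs(z)) else 1
    method <- "normal approximation with tie correction"
  }
  tibble(statistic = z, p.value = min(p, 1), method = method,
         n_a = n1, n_b = n2)
}
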
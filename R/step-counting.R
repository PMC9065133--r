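#' Trace filtering parameters
#'
#' Exclusion rules applied to extracted traces, in the fixed order
#' edge-clipped, bright Cy3, unstable, zero steps, so every excluded trace
#' carries exactly one reason. The Cy3 brightness cutoff (200 arb. units,
#' about twice the single-intasome reference intensity) removes spots
#' likely to contain overlapping complexes.
#'
#' @param cy3_max Maximum Cy3 reference intensity for inclusion
#'   (arb. units).
#' @param require_steps_min Minimum number of photobleaching steps for
#'   inclusion.
#' @param instability_jump_factor A trace is unstable when its smoothed
#'   profile rises by more than this multiple of the unit step size.
#' @param incomplete_bleach_frac A trace is unstable when the mean of its
#'   final 10% of frames exceeds this fraction of the mean of its initial
#'   10% (incomplete bleaching).
#' @param smoothing_window_frames Median pre-smoothing window (odd,
#'   >= 1).
#' @param density_prominence Relative height threshold for qualifying
#'   density peaks (fraction of the tallest positive-side peak).
#' @return A `filter_params` list.
#' @export
filter_params <- function(cy3_max = 200,
                          require_steps_min = 1L,
                          instability_jump_factor = 1.0,
                          incomplete_bleach_frac = 0.2,
                          smoothing_window_frames = 5L,
                          density_prominence = 0.1) {
  check_positive(cy3_max, "cy3_max")
  if (smoothing_window_frames < 1L || smoothing_window_frames %% 2L == 0L) {
    abort("`smoothing_window_frames` must be odd and >= 1.")
  }
  structure(
    list(cy3_max = cy3_max,
         require_steps_min = as.integer(require_steps_min),
         instability_jump_factor = instability_jump_factor,
         incomplete_bleach_frac = incomplete_bleach_frac,
         smoothing_window_frames = as.integer(smoothing_window_frames),
         density_prominence = density_prominence),
    class = "filter_params"
  )
}

#' Pairwise intensity differences of a trace
#'
#' For a trace of length `n` this returns all `n (n - 1) / 2` differences
#' between an earlier and a later frame, `I(t_j) - I(t_i)` with
#' `t_i > t_j`, so a photobleaching step of size `s` contributes positive
#' values and equal-size steps accumulate at integer multiples of `s`.
#' (The sign is flipped relative to the later-minus-earlier convention so
#' step structure lies on the positive axis; this is pure relabeling.)
#'
#' @param intensity Numeric trace of length >= 2.
#' @return Numeric vector of length `n (n - 1) / 2`.
#' @examples
#' pairwise_differences(c(3, 2, 1))  # 1 2 1
#' @export
pairwise_differences <- function(intensity) {
  n <- length(intensity)
  if (n < 2L) abort("A trace must contain at least 2 frames.")
  m <- outer(intensity, intensity, `-`)   # m[j, i] = I[j] - I[i]
  m[upper.tri(m)]                         # row j < column i => earlier - later
}

#' Smoothed density and local maxima of pairwise differences
#'
#' Gaussian kernel density over the pairwise-difference values with
#' bandwidth `h = max(noise_sd_hat, 0.05 * drop_scale)` (the floor keeps
#' the density non-degenerate for noiseless traces), followed by local
#' maxima identification on the positive side. Peaks are restricted to
#' `d > d_min = max(3 * noise_sd_hat, 0.5 * h)` (excluding the zero-lag
#' noise mode); a peak qualifies when its height reaches
#' `prominence * the tallest positive-side peak` and at least 1% of the
#' density mode; peaks closer than one bandwidth are merged to the taller.
#'
#' @param values Pairwise differences from [pairwise_differences()].
#' @param noise_sd_hat Robust trace noise estimate (arb. units, >= 0).
#' @param drop_scale Scale of a candidate step used for the bandwidth
#'   floor, typically the largest single-frame drop of the smoothed
#'   trace; defaults to `max(abs(values))`.
#' @param prominence Relative height threshold for qualification.
#' @param n_grid Density grid size.
#' @return A `pdd_density` object: list with `density` (tibble `d`,
#'   `density`), `peaks` (tibble `position`, `height`, `rel_height`,
#'   `qualifying`), `bandwidth`, `d_min`, `n_values`.
#' @export
estimate_density <- function(values, noise_sd_hat, drop_scale = NULL,
                             prominence = 0.1, n_grid = 2048L) {
  if (length(values) < 1L) abort("`values` must be non-empty.")
  check_positive(noise_sd_hat, "noise_sd_hat", strict = FALSE)
  drop_scale <- drop_scale %||% max(abs(values))
  h <- max(noise_sd_hat, 0.05 * drop_scale)
  if (h <= 0) h <- max(sd(values), .Machine$double.eps)  # all-zero trace
  lo <- min(values) - 4 * h
  hi <- max(values) + 4 * h
  den <- density(values, bw = h, from = lo, to = hi, n = n_grid)
  y <- den$y; x <- den$x

  peak_idx <- which(diff(sign(diff(y))) < 0) + 1L
  d_min <- max(3 * noise_sd_hat, 0.5 * h)
  peaks <- tibble(position = x[peak_idx], height = y[peak_idx])
  pos <- peaks[peaks$position > d_min, , drop = FALSE]
  if (nrow(pos) > 0L) {
    # merge peaks closer than one bandwidth, keeping the taller
    ord <- order(-pos$height)
    keep <- rep(FALSE, nrow(pos))
    suppressed <- rep(FALSE, nrow(pos))
    for (i in ord) {
      if (suppressed[i]) next
      keep[i] <- TRUE
      close <- abs(pos$position - pos$position[i]) < h
      suppressed[close & !keep] <- TRUE
    }
    pos <- pos[keep, , drop = FALSE]
    top <- max(pos$height)
    pos$rel_height <- pos$height / top
    pos$qualifying <- pos$rel_height >= prominence &
      pos$height >= 0.01 * max(y)
    pos <- pos[order(pos$position), ]
  } else {
    pos$rel_height <- numeric(0)
    pos$qualifying <- logical(0)
  }
  structure(
    list(density = tibble(d = x, density = y), peaks = pos,
         bandwidth = h, d_min = d_min, n_values = length(values)),
    class = "pdd_density"
  )
}

#' @export
print.pdd_density <- function(x, ...) {
  nq <- sum(x$peaks$qualifying)
  cat(sprintf(
    "<pdd_density> %d pairwise differences, bandwidth %.4g, d_min %.4g\n",
    x$n_values, x$bandwidth, x$d_min
  ))
  cat(sprintf("  %d positive-side peak%s (%d qualifying)\n",
              nrow(x$peaks), if (nrow(x$peaks) == 1L) "" else "s", nq))
  if (nq > 0) {
    cat("  qualifying at d =",
        paste(signif(x$peaks$position[x$peaks$qualifying], 4),
              collapse = ", "), "\n")
  }
  invisible(x)
}

# Robust noise estimate from successive differences of a trace:
# median(|dI|) / (sqrt(2) * 0.6745), insensitive to the steps themselves.
successive_diff_sigma <- function(intensity) {
  d <- abs(diff(intensity))
  median(d) / (sqrt(2) * 0.6745)
}

median_smooth <- function(intensity, window) {
  if (window <= 1L || length(intensity) < window) return(intensity)
  as.numeric(stats::runmed(intensity, window, endrule = "median"))
}

# Group frames falling by more than a quarter unit step into transition
# regions (frames closer than the smoothing window belong to one region:
# the median filter can smear a step edge over 2-3 frames) and measure
# each region's net drop between the plateau medians on either side.
detect_transition_regions <- function(sm, drops, step, window) {
  ev <- which(drops > 0.25 * step)
  if (length(ev) == 0L) {
    return(list(start = integer(), drop = numeric()))
  }
  n_sm <- length(sm)
  grp <- cumsum(c(1L, diff(ev) > window))
  starts <- as.integer(tapply(ev, grp, min))
  ends <- as.integer(tapply(ev, grp, max))
  ord <- order(starts)
  starts <- starts[ord]
  ends <- ends[ord]
  # plateau level on either side of each region, median over the
  # transition-free run up to the neighboring region (capped), so the
  # smeared edge frames do not bias the measured drop
  cap <- 5L * window
  lo_lim <- c(1L, ends + 2L)                    # first usable frame left
  hi_lim <- c(starts - 1L, n_sm)                # last usable frame right
  drop_tot <- vapply(seq_along(starts), function(g) {
    pre_from <- max(lo_lim[g], starts[g] - cap)
    post_to <- min(hi_lim[g + 1L], ends[g] + 1L + cap)
    pre <- sm[pre_from:starts[g]]
    post <- sm[min(ends[g] + 1L, n_sm):post_to]
    median(pre) - median(post)
  }, numeric(1))
  list(start = starts, drop = drop_tot)
}

#' Count photobleaching steps in one trace
#'
#' The estimator follows the pairwise-difference construction: the trace
#' is median-smoothed (window `smoothing_window_frames`), the noise level
#' is estimated robustly from successive differences, all pairwise
#' intensity differences are computed and their smoothed density's local
#' maxima are identified. The first (smallest-d) qualifying positive-side
#' peak calibrates the unit step size; the step count is then the sum of
#' `round(drop / step)` over downward transitions of the smoothed trace
#' larger than half a unit step. Counting transitions against the
#' peak-calibrated unit, rather than counting the density peaks
#' themselves, keeps the count exact when the occupancy is high: the pair
#' mass feeding the peak at `k * s` decays as `(k + 1 - m)`, so the top
#' rungs of the ladder fall below any fixed relative prominence long
#' before the steps become unresolvable. The count is invariant to
#' scaling the trace by any positive constant and to additive offsets.
#'
#' @param intensity Numeric trace (arb. units).
#' @param params A [filter_params()].
#' @return A `step_fit` object: list with `k_steps`,
#'   `step_size_estimate` (position of the first qualifying peak, `NA`
#'   when no step is found), `sigma_hat`, `pdd` (the [estimate_density()]
#'   result), `smoothed`, `transitions` (tibble `frame`, `drop`,
#'   `n_steps`), `n_frames`.
#' @export
estimate_step_count <- function(intensity, params = filter_params()) {
  if (length(intensity) < 2L) abort("A trace must contain at least 2 frames.")
  sm <- median_smooth(intensity, params$smoothing_window_frames)
  # noise from the raw trace: successive differences of the median-filtered
  # trace are mostly exact zeros, which would collapse the bandwidth
  sigma_hat <- successive_diff_sigma(intensity)
  drops <- -diff(sm)
  drop_scale <- max(drops, 0)
  values <- pairwise_differences(sm)
  pdd <- estimate_density(values, noise_sd_hat = sigma_hat,
                          drop_scale = drop_scale,
                          prominence = params$density_prominence)
  qual <- pdd$peaks[pdd$peaks$qualifying, , drop = FALSE]
  if (nrow(qual) == 0L) {
    fit <- list(k_steps = 0L, step_size_estimate = NA_real_,
                sigma_hat = sigma_hat, pdd = pdd, smoothed = sm,
                transitions = tibble(frame = integer(), drop = numeric(),
                                     n_steps = integer()),
                n_frames = length(intensity))
    return(structure(fit, class = "step_fit"))
  }
  # unit step: the first qualifying peak, cross-checked against the ladder
  # spacing — when fast early bleaching leaves the first rung with little
  # pair mass, the smallest qualifying peak sits at a multiple of the unit
  # step but consecutive rungs remain one unit apart
  step <- qual$position[1L]
  w <- params$smoothing_window_frames
  regions <- detect_transition_regions(sm, drops, step, w)
  # the first ladder rung of the difference density is pulled low by pair
  # values from smeared step edges, and with fast early bleaching it can
  # sit at twice the unit step; the measured plateau-to-plateau drops are
  # unbiased, so recalibrate the unit on the drops classified as singles
  if (length(regions$drop) > 0L) {
    halves <- sum(regions$drop > 0.35 * step & regions$drop < 0.65 * step)
    singles <- sum(regions$drop > 0.7 * step & regions$drop < 1.3 * step)
    if (halves >= 2L && halves > singles) step <- step / 2
    single_drops <- regions$drop[regions$drop > 0.6 * step &
                                   regions$drop < 1.45 * step]
    if (length(single_drops) >= 2L) step <- median(single_drops)
    regions <- detect_transition_regions(sm, drops, step, w)
  }
  n_steps <- as.integer(round(regions$drop / step))
  keep <- regions$drop > 0.5 * step & n_steps >= 1L
  transitions <- tibble(frame = regions$start[keep] - 1L,
                        drop = regions$drop[keep],
                        n_steps = n_steps[keep])
  # a fluorophore emitting for a single frame at either end leaves no
  # plateau the median filter can keep; compare the raw end frames against
  # the first/last smoothed plateau unless a transition sits there already
  n_sm <- length(sm)
  if (!any(transitions$frame < w)) {
    lead_drop <- intensity[1L] - median(sm[seq_len(min(n_sm, w))])
    lead_n <- as.integer(round(lead_drop / step))
    if (lead_drop > 0.5 * step && lead_n >= 1L) {
      transitions <- dplyr::bind_rows(
        tibble(frame = 0L, drop = lead_drop, n_steps = lead_n), transitions)
    }
  }
  if (!any(transitions$frame > n_sm - 1L - w)) {
    tail_drop <- median(sm[max(1L, n_sm - w + 1L):n_sm]) - intensity[n_sm]
    tail_n <- as.integer(round(tail_drop / step))
    if (tail_drop > 0.5 * step && tail_n >= 1L) {
      transitions <- dplyr::bind_rows(
        transitions,
        tibble(frame = n_sm - 2L, drop = tail_drop, n_steps = tail_n))
    }
  }
  structure(
    list(k_steps = as.integer(sum(transitions$n_steps)),
         step_size_estimate = step,
         sigma_hat = sigma_hat, pdd = pdd, smoothed = sm,
         transitions = transitions, n_frames = length(intensity)),
    class = "step_fit"
  )
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("<step_fit> %d photobleaching step%s",
              x$k_steps, if (x$k_steps == 1L) "" else "s"))
  if (!is.na(x$step_size_estimate)) {
    cat(sprintf(" (unit step %.4g arb. units)", x$step_size_estimate))
  }
  cat(sprintf("; noise sd %.3g over %d frames\n", x$sigma_hat, x$n_frames))
  invisible(x)
}

#' Flag unstable bleaching profiles
#'
#' A trace is unstable when its median-smoothed profile contains an
#' upward transition larger than `instability_jump_factor` times the unit
#' step size (re-brightening / binding events) or when the mean of its
#' final 10% of frames exceeds `incomplete_bleach_frac` of the mean of
#' its initial 10% (incomplete bleaching).
#'
#' @param intensity Numeric trace.
#' @param step_size_estimate Unit step size from [estimate_step_count()]
#'   (must be positive).
#' @param params A [filter_params()].
#' @return Logical.
#' @export
classify_unstable <- function(intensity, step_size_estimate,
                              params = filter_params()) {
  if (is.na(step_size_estimate) || step_size_estimate <= 0) {
    abort("`step_size_estimate` must be positive (or the trace constant).")
  }
  sm <- median_smooth(intensity, params$smoothing_window_frames)
  rises <- diff(sm)
  if (any(rises > params$instability_jump_factor * step_size_estimate)) {
    return(TRUE)
  }
  n <- length(sm)
  w <- max(1L, floor(n / 10))
  head_mean <- mean(sm[seq_len(w)])
  tail_mean <- mean(sm[(n - w + 1L):n])
  head_mean > 0 && tail_mean > params$incomplete_bleach_frac * head_mean
}

#' Filter and count steps for a cohort of traces
#'
#' Applies the exclusion chain in its fixed order — edge-clipped traces,
#' bright Cy3 spots (likely overlapping complexes), unstable bleaching
#' profiles, traces without photobleaching steps — and reports the step
#' count for every trace that survives. Each excluded trace carries
#' exactly one reason.
#'
#' @param traces A traces tibble from [simulate_traces()] or
#'   [extract_traces()] (columns `spot_id`, `condition`, `cy3_intensity`,
#'   `edge_clipped`, list-column `intensity`).
#' @param params A [filter_params()].
#' @return A tibble with one row per trace: `spot_id`, `condition`,
#'   `k_steps` (`NA` where not computed), `step_size_estimate`,
#'   `sigma_hat`, `exclusion_reason` (factor: `none`, `edge_clipped`,
#'   `bright_cy3`, `unstable`, `zero_steps`), `included`.
#' @export
count_steps <- function(traces, params = filter_params()) {
  stopifnot(is.data.frame(traces), "intensity" %in% names(traces))
  reasons <- c("none", "edge_clipped", "bright_cy3", "unstable", "zero_steps")
  rows <- purrr::map(seq_len(nrow(traces)), function(i) {
    out <- tibble(
      spot_id = traces$spot_id[i],
      condition = if ("condition" %in% names(traces)) {
        traces$condition[i]
      } else NA_character_,
      k_steps = NA_integer_, step_size_estimate = NA_real_,
      sigma_hat = NA_real_, exclusion_reason = "none"
    )
    if (isTRUE(traces$edge_clipped[i])) {
      out$exclusion_reason <- "edge_clipped"
      return(out)
    }
    if (traces$cy3_intensity[i] > params$cy3_max) {
      out$exclusion_reason <- "bright_cy3"
      return(out)
    }
    fit <- estimate_step_count(traces$intensity[[i]], params)
    out$k_steps <- fit$k_steps
    out$step_size_estimate <- fit$step_size_estimate
    out$sigma_hat <- fit$sigma_hat
    if (fit$k_steps > 0L &&
        classify_unstable(traces$intensity[[i]], fit$step_size_estimate,
                          params)) {
      out$exclusion_reason <- "unstable"
      return(out)
    }
    if (fit$k_steps < params$require_steps_min) {
      out$exclusion_reason <- "zero_steps"
    }
    out
  })
  res <- dplyr::bind_rows(rows)
  res$exclusion_reason <- factor(res$exclusion_reason, levels = reasons)
  res$included <- res$exclusion_reason == "none"
  res
}
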
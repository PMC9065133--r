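# Shared fixtures: everything is generated in code at test time.

reason_levels <- c("none", "edge_clipped", "bright_cy3", "unstable",
                   "zero_steps")

# Noiseless descending staircase: k equal steps of `step`, equal dwells.
make_staircase <- function(k, step = 10, dwell = 40, noise_sd = 0,
                           seed = 1) {
  levels <- rev(seq_len(k + 1)) - 1
  tr <- rep(levels * step, each = dwell)
  if (noise_sd > 0) {
    set.seed(seed)
    tr <- tr + rnorm(length(tr), 0, noise_sd)
  }
  tr
}

# Counts tibble in the shape count_steps() emits.
make_counts <- function(k_steps, condition = "x",
                        reason = rep("none", length(k_steps))) {
  tibble::tibble(
    spot_id = seq_along(k_steps),
    condition = condition,
    k_steps = as.integer(k_steps),
    step_size_estimate = NA_real_,
    sigma_hat = NA_real_,
    exclusion_reason = factor(reason, levels = reason_levels),
    included = reason == "none"
  )
}

# Small field setup used by the image-processing tests.
small_field <- function(n_spots_mean = 20, width = 128L) {
  field_config(width_px = width, height_px = width,
               n_spots_mean = n_spots_mean)
}
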
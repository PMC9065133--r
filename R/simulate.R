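#' Draw per-intasome occupancy counts
#'
#' Site occupancy is modeled as independent Bernoulli trials over the
#' intasome's binding sites, so the number of labeled subunits is
#' `Binomial(n_sites, occupancy_p * labeling_efficiency)`. The model
#' carries no cooperativity; only the mean occupancy is constrained by the
#' measured per-condition averages.
#'
#' @param n_complexes Number of intasomes to draw (>= 1).
#' @param config A [sim_config()].
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return Integer vector of length `n_complexes` with values in
#'   `[0, n_sites]`.
#' @export
simulate_occupancy <- function(n_complexes, config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(n_complexes) || n_complexes < 1) {
    abort("`n_complexes` must be at least 1.")
  }
  p <- config$occupancy_p * config$labeling_efficiency
  with_seed(seed, rbinom(n_complexes, size = config$n_sites, prob = p))
}

# Truncated-positive normal draw (simple rejection; resamples are rare for
# the calibrations used here).
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

# Core trace generator; assumes RNG state is already set by the caller.
simulate_trace_impl <- function(k_true, config, complete_bleach = FALSE,
                                inject_jump = FALSE, jump_units = 2) {
  n <- config$n_frames
  noise <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else numeric(n)
  units <- numeric(0)
  bleach <- integer(0)
  if (k_true > 0) {
    units <- rnorm_pos(k_true, config$unit_step_mean,
                       config$unit_step_cv * config$unit_step_mean)
    # bleach frame = last frame at which the fluorophore still emits;
    # geometric with mean 1/q - 1, so every fluorophore emits at frame 0
    bleach <- rgeom(k_true, config$bleach_rate)
    if (complete_bleach) {
      # condition on the step occurring within the movie (dark by the
      # final frame): resample survivors from the truncated geometric
      late <- which(bleach > n - 2L)
      while (length(late) > 0L) {
        bleach[late] <- rgeom(length(late), config$bleach_rate)
        late <- late[bleach[late] > n - 2L]
      }
    }
    frames <- 0:(n - 1L)
    active <- outer(frames, bleach, `<=`)      # n x k logical
    signal <- as.numeric(active %*% units)
  } else {
    signal <- numeric(n)
  }
  if (inject_jump && k_true > 0) {
    # re-brightening artifact: an upward jump of `jump_units` unit steps in
    # the middle third of the movie, persisting to the end of the movie
    f0 <- floor(n / 3) + sample.int(max(1L, floor(n / 3)), 1L) - 1L
    jump <- numeric(n)
    jump[(f0 + 1L):n] <- jump_units * config$unit_step_mean
    signal <- signal + jump
  }
  list(
    intensity = signal + noise,
    bleach_frames = sort(bleach),
    unit_intensities = units
  )
}

#' Simulate one Surf649 photobleaching trace
#'
#' Each of the `k_true` fluorophores receives a unit intensity drawn once
#' (Normal with mean `unit_step_mean` and CV `unit_step_cv`, truncated
#' positive) and held until it bleaches; bleaching is geometric with
#' per-frame probability `bleach_rate`, with the bleach frame recorded as
#' the last frame at which the fluorophore emits. Frame 0 therefore always
#' carries the full occupancy. Gaussian read noise of sd `noise_sd` is
#' added to every frame.
#'
#' @param k_true Number of labeled subunits, in `[0, n_sites]`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param complete_bleach If `TRUE`, survivor fluorophores (those whose
#'   geometric bleach frame falls beyond the movie) are resampled from the
#'   movie-truncated geometric so that every step occurs on camera. Use for
#'   constructing traces with a guaranteed number of observable steps; the
#'   default `FALSE` keeps the unconditional kinetics.
#' @param inject_jump If `TRUE`, inject an upward re-brightening artifact
#'   of `jump_units` unit steps at a random frame in the middle third of
#'   the movie (ground truth for the unstable-trace filter).
#' @param jump_units Size of the injected artifact in unit steps.
#'
#' @return A list with `intensity` (length `n_frames`), `time_s`,
#'   `bleach_frames` (sorted, one per fluorophore; values `>= n_frames - 1`
#'   mean the fluorophore outlived the movie), `unit_intensities`, and
#'   `cy3_intensity` drawn from the Cy3 reference distribution.
#' @export
simulate_trace <- function(k_true, config = sim_config(), seed = 1L,
                           complete_bleach = FALSE,
                           inject_jump = FALSE, jump_units = 2) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(k_true) || length(k_true) != 1L || k_true < 0 ||
      k_true > config$n_sites) {
    abort(sprintf("`k_true` must lie in [0, %d].", config$n_sites))
  }
  with_seed(seed, {
    tr <- simulate_trace_impl(as.integer(k_true), config,
                              complete_bleach = complete_bleach,
                              inject_jump = inject_jump,
                              jump_units = jump_units)
    tr$cy3_intensity <- rnorm_pos(1L, config$cy3_mean, config$cy3_sd)
    tr
  })
}

#' Simulate a cohort of photobleaching traces
#'
#' Draws `n_traces` intasomes with binomial occupancy and simulates each
#' trace on its own RNG substream (derived from `seed` and the trace
#' index), so trace `i` is bit-identical regardless of cohort size.
#'
#' @param n_traces Number of intasomes.
#' @inheritParams simulate_trace
#' @return A tibble with one row per trace: `spot_id`, `condition`,
#'   `k_true`, `n_labeled`, `cy3_intensity`, `edge_clipped` (always
#'   `FALSE` for trace-level simulation), and list-columns `intensity`,
#'   `time_s`, `bleach_frames`.
#' @export
simulate_traces <- function(n_traces, config = sim_config(), seed = 1L,
                            complete_bleach = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  k <- simulate_occupancy(n_traces, config, seed = substream_seed(seed, 0L))
  time_s <- frames_to_seconds(seq_len(config$n_frames) - 1, config$frame_rate_hz)
  rows <- purrr::map(seq_len(n_traces), function(i) {
    tr <- simulate_trace(k[i], config, seed = substream_seed(seed, i),
                         complete_bleach = complete_bleach)
    tibble(
      spot_id = i,
      condition = config$condition,
      k_true = k[i],
      n_labeled = k[i],
      cy3_intensity = tr$cy3_intensity,
      edge_clipped = FALSE,
      intensity = list(tr$intensity),
      time_s = list(time_s),
      bleach_frames = list(tr$bleach_frames)
    )
  })
  dplyr::bind_rows(rows)
}

# Render Gaussian spots (integrated intensity `amp[i]`) onto `img` in place.
render_spots <- function(img, x, y, amp, sigma_px) {
  if (length(x) == 0L) return(img)
  w <- ncol(img)  # x = column
  h <- nrow(img)  # y = row
  r <- ceiling(4 * sigma_px)
  for (i in seq_along(x)) {
    cx <- x[i]; cy <- y[i]
    c0 <- max(1L, floor(cx + 1 - r)); c1 <- min(w, ceiling(cx + 1 + r))
    r0 <- max(1L, floor(cy + 1 - r)); r1 <- min(h, ceiling(cy + 1 + r))
    if (c0 > c1 || r0 > r1) next
    gx <- exp(-((c0:c1 - 1 - cx)^2) / (2 * sigma_px^2))
    gy <- exp(-((r0:r1 - 1 - cy)^2) / (2 * sigma_px^2))
    stamp <- (amp[i] / (2 * pi * sigma_px^2)) * outer(gy, gx)
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + stamp
  }
  img
}

field_background <- function(field) {
  ramp <- matrix(
    rep(seq(0, 1, length.out = field$width_px), each = field$height_px),
    nrow = field$height_px
  )
  field$camera_offset + field$background_level +
    field$background_gradient * ramp
}

#' Simulate a two-channel imaging field
#'
#' Renders the acquisition sequence for one field of view: a 5-frame Cy3
#' snapshot stack (one Gaussian spot per intasome, constant over frames)
#' and an `n_frames` Surf649 movie in which each intasome's integrated
#' spot intensity follows its simulated photobleaching time course. Both
#' channels carry the field background, gradient, camera offset and
#' per-pixel read noise. The number of intasomes is Poisson with mean
#' `field$n_spots_mean`; positions are uniform with subpixel coordinates
#' (pixel-centered, origin at the corner pixel center, x = column,
#' y = row).
#'
#' @param config A [sim_config()].
#' @param field A [field_config()].
#' @param seed Integer seed.
#' @param channels Channels to render: subset of `c("cy3", "surf649")`.
#'   Rendering only the Cy3 snapshots is much cheaper when the movie is
#'   not needed (e.g. detection-density studies).
#' @param n_cy3_frames Number of Cy3 snapshot frames.
#'
#' @return A list with `cy3` (an [image_stack()] or `NULL`), `surf649`
#'   (an [image_stack()] or `NULL`), and `truth`, a tibble with one row
#'   per intasome: `complex_id`, `x_px`, `y_px`, `k_true`, `n_labeled`,
#'   `cy3_true`, list-column `bleach_frames`, and `overlap_flag`
#'   (`TRUE` when another intasome lies within one detection aperture,
#'   0.78 um).
#' @export
simulate_field <- function(config = sim_config(), field = field_config(),
                           seed = 1L, channels = c("cy3", "surf649"),
                           n_cy3_frames = 5L) {
  stopifnot(inherits(config, "sim_config"), inherits(field, "field_config"))
  channels <- match.arg(channels, c("cy3", "surf649"), several.ok = TRUE)
  sigma_px <- um_to_px(field$psf_sigma_um, field$pixel_size_um)
  aperture_px <- um_to_px(0.78, field$pixel_size_um)

  with_seed(substream_seed(seed, 0L), {
    n_spots <- rpois(1L, field$n_spots_mean)
    x <- runif(n_spots, 0, field$width_px - 1)
    y <- runif(n_spots, 0, field$height_px - 1)
    k <- rbinom(n_spots, config$n_sites,
                config$occupancy_p * config$labeling_efficiency)
    cy3 <- rnorm_pos(n_spots, config$cy3_mean, config$cy3_sd)
  })

  overlap <- rep(FALSE, n_spots)
  if (n_spots > 1L) {
    d <- as.matrix(stats::dist(cbind(x, y)))
    diag(d) <- Inf
    overlap <- apply(d < aperture_px, 1L, any)
  }

  traces <- vector("list", n_spots)
  bleach_frames <- vector("list", n_spots)
  for (i in seq_len(n_spots)) {
    tr <- with_seed(substream_seed(seed, i), {
      cfg <- config
      cfg$noise_sd <- 0  # camera noise is added per pixel, not per trace
      simulate_trace_impl(k[i], cfg)
    })
    traces[[i]] <- tr$intensity
    bleach_frames[[i]] <- tr$bleach_frames
  }

  bg <- field_background(field)
  make_noise <- function(seed_off) {
    if (field$read_noise_sd <= 0) return(0)
    with_seed(substream_seed(seed, seed_off),
              matrix(rnorm(field$height_px * field$width_px, 0,
                           field$read_noise_sd),
                     nrow = field$height_px))
  }

  cy3_stack <- NULL
  if ("cy3" %in% channels) {
    base <- render_spots(bg, x, y, cy3, sigma_px)
    frames <- array(0, dim = c(field$height_px, field$width_px, n_cy3_frames))
    for (f in seq_len(n_cy3_frames)) {
      frames[, , f] <- base + make_noise(1000000L + f)
    }
    cy3_stack <- image_stack(frames, pixel_size_um = field$pixel_size_um,
                             channel = "Cy3",
                             frame_rate_hz = config$frame_rate_hz)
  }

  surf_stack <- NULL
  if ("surf649" %in% channels) {
    n <- config$n_frames
    frames <- array(0, dim = c(field$height_px, field$width_px, n))
    amp <- do.call(rbind, traces)  # n_spots x n_frames (may be 0-row)
    for (f in seq_len(n)) {
      img <- render_spots(bg, x, y,
                          if (n_spots > 0) amp[, f] else numeric(0),
                          sigma_px)
      frames[, , f] <- img + make_noise(2000000L + f)
    }
    surf_stack <- image_stack(frames, pixel_size_um = field$pixel_size_um,
                              channel = "Surf649",
                              frame_rate_hz = config$frame_rate_hz)
  }

  truth <- tibble(
    complex_id = seq_len(n_spots),
    x_px = x, y_px = y,
    k_true = k, n_labeled = k,
    cy3_true = cy3,
    bleach_frames = bleach_frames,
    overlap_flag = overlap
  )
  list(cy3 = cy3_stack, surf649 = surf_stack, truth = truth)
}
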
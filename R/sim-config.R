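#' Trace-level simulation parameters
#'
#' Describes the generative model for a single intasome's Surf649
#' photobleaching trace: binomial occupancy of the 16 LEDGF/p75 binding
#' sites, one fluorescence unit per labeled subunit (drawn once per
#' fluorophore), geometric per-frame photobleaching, and additive Gaussian
#' read noise. Defaults reproduce the acquisition: 900 frames at 5 Hz
#' (a 3-minute movie) with a per-frame bleaching probability of 0.005 so
#' that 1 - 0.995^900 (about 98.9%) of fluorophores bleach within the
#' movie, comfortably beyond the 95% completeness the experiment relies on.
#'
#' The arbitrary-unit calibration places a single intasome's Cy3 reference
#' intensity at Normal(100, 25) truncated positive, so that coincident
#' double complexes typically exceed the 200 arb. unit exclusion cutoff.
#' `noise_sd` defaults to `0.15 * unit_step_mean`.
#'
#' @param n_sites Number of LEDGF/p75 binding sites per intasome.
#' @param occupancy_p Per-site occupancy probability in `[0, 1]`.
#' @param labeling_efficiency Probability a bound subunit carries an active
#'   fluorophore.
#' @param unit_step_mean Mean single-fluorophore Surf649 intensity
#'   (arb. units).
#' @param unit_step_cv Coefficient of variation of the single-fluorophore
#'   intensity.
#' @param bleach_rate Per-frame bleaching probability, in `(0, 1]`.
#' @param noise_sd Additive Gaussian read-noise standard deviation on the
#'   aperture-integrated trace (arb. units); default
#'   `0.15 * unit_step_mean`.
#' @param n_frames Movie length in frames (>= 2).
#' @param frame_rate_hz Frame rate in Hz.
#' @param cy3_mean,cy3_sd Single-intasome Cy3 reference intensity
#'   distribution (Normal truncated positive, arb. units).
#' @param condition Free-text condition label attached to simulated traces.
#'
#' @return A `sim_config` list.
#' @seealso [condition_preset()] for the salt-series presets,
#'   [simulate_trace()], [simulate_traces()], [simulate_field()].
#' @export
sim_config <- function(n_sites = 16L,
                       occupancy_p = 0.375,
                       labeling_efficiency = 1.0,
                       unit_step_mean = 20,
                       unit_step_cv = 0.15,
                       bleach_rate = 0.005,
                       noise_sd = NULL,
                       n_frames = 900L,
                       frame_rate_hz = 5,
                       cy3_mean = 100,
                       cy3_sd = 25,
                       condition = NA_character_) {
  check_probability(occupancy_p, "occupancy_p")
  check_probability(labeling_efficiency, "labeling_efficiency")
  check_positive(unit_step_mean, "unit_step_mean")
  check_positive(unit_step_cv, "unit_step_cv", strict = FALSE)
  if (!is.numeric(bleach_rate) || bleach_rate <= 0 || bleach_rate > 1) {
    abort("`bleach_rate` must lie in (0, 1].")
  }
  if (!is.numeric(n_frames) || n_frames < 2) {
    abort("`n_frames` must be at least 2.")
  }
  check_positive(frame_rate_hz, "frame_rate_hz")
  check_positive(cy3_mean, "cy3_mean")
  check_positive(cy3_sd, "cy3_sd", strict = FALSE)
  noise_sd <- noise_sd %||% (0.15 * unit_step_mean)
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  structure(
    list(
      n_sites = as.integer(n_sites),
      occupancy_p = occupancy_p,
      labeling_efficiency = labeling_efficiency,
      unit_step_mean = unit_step_mean,
      unit_step_cv = unit_step_cv,
      bleach_rate = bleach_rate,
      noise_sd = noise_sd,
      n_frames = as.integer(n_frames),
      frame_rate_hz = frame_rate_hz,
      cy3_mean = cy3_mean,
      cy3_sd = cy3_sd,
      condition = condition
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d sites, per-site occupancy %.4g, labeling eff. %.3g\n",
              x$n_sites, x$occupancy_p, x$labeling_efficiency))
  cat(sprintf("  unit step %.3g (cv %.3g), noise sd %.3g arb. units\n",
              x$unit_step_mean, x$unit_step_cv, x$noise_sd))
  cat(sprintf("  %d frames @ %g Hz, bleach rate %.4g/frame\n",
              x$n_frames, x$frame_rate_hz, x$bleach_rate))
  if (!is.na(x$condition)) cat(sprintf("  condition: %s\n", x$condition))
  invisible(x)
}

#' Field-level simulation parameters
#'
#' Geometry and background model for rendering synthetic two-channel
#' fields: a 512 x 512 EMCCD frame at 160 nm pixels spans 81.92 um, and on
#' average 400 intasomes are scattered uniformly per field (Poisson count,
#' subpixel positions). Each intasome is rendered as a 2-D Gaussian whose
#' integrated intensity equals its trace value, on top of a constant
#' background, an optional linear gradient, a camera offset, and per-pixel
#' Gaussian read noise.
#'
#' @param width_px,height_px Field dimensions in pixels.
#' @param pixel_size_um Physical pixel edge (um).
#' @param n_spots_mean Expected number of intasomes per field (Poisson).
#' @param psf_sigma_um Gaussian point-spread standard deviation (um).
#' @param background_level Constant additive background (arb. units).
#' @param background_gradient Peak-to-peak amplitude of a linear background
#'   ramp across the field width (arb. units).
#' @param camera_offset Constant camera offset (arb. units).
#' @param read_noise_sd Per-pixel additive Gaussian read noise (arb.
#'   units).
#'
#' @return A `field_config` list.
#' @export
field_config <- function(width_px = 512L,
                         height_px = 512L,
                         pixel_size_um = 0.16,
                         n_spots_mean = 400,
                         psf_sigma_um = 0.15,
                         background_level = 5,
                         background_gradient = 2,
                         camera_offset = 100,
                         read_noise_sd = 0.1) {
  if (width_px < 1 || height_px < 1) {
    abort("Field dimensions must be positive.")
  }
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(n_spots_mean, "n_spots_mean", strict = FALSE)
  check_positive(psf_sigma_um, "psf_sigma_um")
  structure(
    list(
      width_px = as.integer(width_px),
      height_px = as.integer(height_px),
      pixel_size_um = pixel_size_um,
      n_spots_mean = n_spots_mean,
      psf_sigma_um = psf_sigma_um,
      background_level = background_level,
      background_gradient = background_gradient,
      camera_offset = camera_offset,
      read_noise_sd = read_noise_sd
    ),
    class = "field_config"
  )
}

#' Salt-condition simulation presets
#'
#' Returns a [sim_config()] whose per-site occupancy probability is
#' calibrated so the expected occupancy of the 16-site intasome matches the
#' measured mean stoichiometry at that ionic strength: 6, 4 and 2 LEDGF/p75
#' subunits per intasome at 0.2, 0.5 and 1 M NaCl respectively (occupancy
#' probabilities 6/16, 4/16, 2/16). All other parameters keep their
#' defaults unless overridden through `...`.
#'
#' @param name One of `"salt_0.2M"`, `"salt_0.5M"`, `"salt_1.0M"`.
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @examples
#' condition_preset("salt_0.2M")$occupancy_p  # 0.375
#' @export
condition_preset <- function(name, ...) {
  means <- c("salt_0.2M" = 6, "salt_0.5M" = 4, "salt_1.0M" = 2)
  labels <- c("salt_0.2M" = "0.2 M NaCl", "salt_0.5M" = "0.5 M NaCl",
              "salt_1.0M" = "1 M NaCl")
  if (!is.character(name) || length(name) != 1L || !name %in% names(means)) {
    abort(sprintf(
      "Unknown condition preset %s; available: %s.",
      deparse(name), paste(names(means), collapse = ", ")
    ))
  }
  defaults <- list(occupancy_p = means[[name]] / 16, condition = labels[[name]])
  args <- modifyList(defaults, list(...))
  do.call(sim_config, args)
}

#' Names of the built-in salt-series presets
#' @return Character vector of preset names, lowest to highest NaCl.
#' @export
salt_series <- function() c("salt_0.2M", "salt_0.5M", "salt_1.0M")
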
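#' Physical-unit conversions
#'
#' All micrometre/pixel and frame/second conversions in the package go
#' through these two helpers, so the acquisition geometry (160 nm pixels,
#' 5 Hz sampling) is applied in exactly one place.
#'
#' @param um Length in micrometres.
#' @param pixel_size_um Physical pixel edge in micrometres (default 0.16).
#' @param frames Zero-based frame indices.
#' @param frame_rate_hz Acquisition rate in frames per second (default 5).
#'
#' @return `um_to_px()` returns the length in pixels (fractional, never
#'   rounded); `frames_to_seconds()` returns times in seconds with frame 0
#'   at t = 0.
#'
#' @examples
#' um_to_px(0.78)           # detection aperture: 4.875 px
#' um_to_px(0.48)           # rolling-ball radius: 3 px
#' frames_to_seconds(899)   # last frame of a 3-min movie: 179.8 s
#' @export
um_to_px <- function(um, pixel_size_um = 0.16) {
  stopifnot(is.numeric(um), is.numeric(pixel_size_um), pixel_size_um > 0)
  um / pixel_size_um
}

#' @rdname um_to_px
#' @export
frames_to_seconds <- function(frames, frame_rate_hz = 5) {
  stopifnot(is.numeric(frames), frame_rate_hz > 0)
  frames / frame_rate_hz
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Stable per-item substream seed: trace i of a batch is reproducible
# regardless of batch size. Arithmetic stays exact in doubles
# (seed < 2^31, index < 2^20) and the result is a valid 32-bit seed.
substream_seed <- function(seed, index) {
  stopifnot(seed == trunc(seed), abs(seed) < 2^31)
  as.integer((abs(seed) + 1664525 * index + 1013904223) %% 2147483647)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be a single %s number.",
                  name, if (strict) "positive" else "non-negative"))
  }
  invisible(x)
}
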
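#' Time-ordered image stack
#'
#' Lightweight container for a single-channel fluorescence stack: a
#' `height x width x n_frames` numeric array plus the physical pixel size,
#' channel label and frame rate. Coordinates are pixel-centered with the
#' origin at the corner pixel center; x indexes columns and y rows, both
#' stored as subpixel floats elsewhere in the package.
#'
#' @param frames A 2-D matrix (promoted to one frame) or 3-D array with
#'   frames along the third dimension, in time order.
#' @param pixel_size_um Physical pixel edge (um).
#' @param channel Channel label, e.g. `"Cy3"` or `"Surf649"`.
#' @param frame_rate_hz Acquisition rate (Hz).
#' @return An `image_stack` object.
#' @export
image_stack <- function(frames, pixel_size_um = 0.16, channel = "Cy3",
                        frame_rate_hz = 5) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be a matrix or a 3-D array (height x width x time).")
  }
  check_positive(pixel_size_um, "pixel_size_um")
  check_positive(frame_rate_hz, "frame_rate_hz")
  structure(
    list(frames = frames, pixel_size_um = pixel_size_um,
         channel = channel, frame_rate_hz = frame_rate_hz),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<image_stack> %s: %d x %d px (%.3g um/px), %d frame%s @ %g Hz\n",
    x$channel, d[2], d[1], x$pixel_size_um, d[3],
    if (d[3] == 1L) "" else "s", x$frame_rate_hz
  ))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

#' Number of frames in a stack
#' @param stack An [image_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Temporal mean of a stack
#' @param stack An [image_stack()].
#' @return A matrix: the pixelwise mean over frames.
#' @export
stack_mean <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  rowMeans(stack$frames, dims = 2L)
}

#' Write / read image stacks as multi-page TIFF
#'
#' Stacks are written as 16-bit unsigned multi-page TIFF (frame order =
#' time order; values are clamped to `[0, 65535]` and rounded) together
#' with a YAML sidecar (`<path>.yaml`) carrying the pixel size, channel
#' and frame rate so that a stack round-trips through disk.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `write_stack()` returns `path` invisibly; `read_stack()`
#'   returns an [image_stack()].
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[3]), function(f) {
    pmin(pmax(round(stack$frames[, , f]), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(
    list(pixel_size_um = stack$pixel_size_um, channel = stack$channel,
         frame_rate_hz = stack$frame_rate_hz),
    paste0(path, ".yaml")
  )
  invisible(path)
}

#' @rdname write_stack
#' @param pixel_size_um,channel,frame_rate_hz Metadata used when no YAML
#'   sidecar is found next to `path`.
#' @export
read_stack <- function(path, pixel_size_um = 0.16, channel = "Cy3",
                       frame_rate_hz = 5) {
  if (!file.exists(path)) {
    abort(sprintf("No such TIFF file: %s", path))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort(sprintf("Frames in %s have inconsistent dimensions.", path))
  }
  frames <- array(0, dim = c(dims[1, 1], dims[2, 1], length(pages)))
  for (f in seq_along(pages)) {
    p <- pages[[f]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    frames[, , f] <- round(p * 65535)
  }
  side <- paste0(path, ".yaml")
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    pixel_size_um <- meta$pixel_size_um %||% pixel_size_um
    channel <- meta$channel %||% channel
    frame_rate_hz <- meta$frame_rate_hz %||% frame_rate_hz
  }
  image_stack(frames, pixel_size_um = pixel_size_um, channel = channel,
              frame_rate_hz = frame_rate_hz)
}
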
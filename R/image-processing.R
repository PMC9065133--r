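#' Spot-detection parameters
#'
#' Carries the four printed processing constants of the acquisition
#' pipeline — detection aperture radius 0.78 um, contrast threshold 14.5,
#' denoise strength 5, rolling-ball radius 0.48 um — plus the point-spread
#' scale at which the blob response is computed. At 160 nm pixels the
#' aperture radius is 4.875 px (kept fractional; all masks are built on
#' subpixel distances) and the rolling ball is 3 px.
#'
#' @param spot_radius_um Detection/photometry aperture radius (um).
#' @param contrast_min Minimum contrast score for an emitted detection:
#'   (aperture mean - local annulus median) / annulus robust noise.
#' @param denoise_strength Denoise setting; Gaussian sigma is
#'   `strength / 5` px, so the printed setting 5 means a 1 px blur.
#' @param rolling_ball_radius_um Rolling-ball radius (um).
#' @param psf_sigma_um Gaussian point-spread sigma (um) used for the
#'   Laplacian-of-Gaussian blob response; must match the optics, not the
#'   aperture, for spots at the imaged density to stay resolvable.
#' @param annulus_gap_px,annulus_width_px Local-background annulus: inner
#'   radius `aperture + gap`, width `width` (px).
#' @return A `detection_params` list.
#' @export
detection_params <- function(spot_radius_um = 0.78,
                             contrast_min = 14.5,
                             denoise_strength = 5,
                             rolling_ball_radius_um = 0.48,
                             psf_sigma_um = 0.15,
                             annulus_gap_px = 2,
                             annulus_width_px = 3) {
  check_positive(spot_radius_um, "spot_radius_um")
  check_positive(contrast_min, "contrast_min", strict = FALSE)
  check_positive(denoise_strength, "denoise_strength", strict = FALSE)
  check_positive(rolling_ball_radius_um, "rolling_ball_radius_um")
  check_positive(psf_sigma_um, "psf_sigma_um")
  structure(
    list(spot_radius_um = spot_radius_um, contrast_min = contrast_min,
         denoise_strength = denoise_strength,
         rolling_ball_radius_um = rolling_ball_radius_um,
         psf_sigma_um = psf_sigma_um,
         annulus_gap_px = annulus_gap_px,
         annulus_width_px = annulus_width_px),
    class = "detection_params"
  )
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

convolve2_replicate <- function(img, kernel) {
  EBImage::filter2(img, kernel, boundary = "replicate")
}

#' Gaussian denoising
#'
#' Mild Gaussian smoothing standing in for the acquisition software's
#' proprietary denoise filter: the printed setting maps to a Gaussian of
#' sigma `strength / 5` px, so the value 5 used for both channels means a
#' 1 px blur. Strength 0 is the identity.
#'
#' @param x An [image_stack()] or a 2-D matrix.
#' @param strength Non-negative denoise setting.
#' @return Same type as `x`.
#' @export
denoise <- function(x, strength = 5) {
  if (!is.numeric(strength) || length(strength) != 1L || is.na(strength) ||
      strength < 0) {
    abort("`strength` must be a single non-negative number.")
  }
  if (strength == 0) return(x)
  sigma <- strength / 5
  k1 <- gaussian_kernel_1d(sigma)
  kern <- outer(k1, k1)
  if (is.matrix(x)) return(convolve2_replicate(x, kern))
  stopifnot(inherits(x, "image_stack"))
  out <- x
  for (f in seq_len(n_frames(x))) {
    out$frames[, , f] <- convolve2_replicate(x$frames[, , f], kern)
  }
  out
}

ball_offsets <- function(radius_px) {
  r <- floor(radius_px)
  dd <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- dd$dx^2 + dd$dy^2
  keep <- d2 <= radius_px^2
  dd <- dd[keep, , drop = FALSE]
  # hemisphere height profile in intensity units, scaled so the ball is
  # `radius_px` intensity units tall
  dd$z <- sqrt(pmax(radius_px^2 - d2[keep], 0))
  dd
}

shift_pad <- function(img, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  ys <- pmin(pmax(seq_len(h) + dy, 1L), h)
  xs <- pmin(pmax(seq_len(w) + dx, 1L), w)
  img[ys, xs, drop = FALSE]
}

gray_erode_ball <- function(img, off) {
  out <- matrix(Inf, nrow(img), ncol(img))
  for (i in seq_len(nrow(off))) {
    out <- pmin(out, shift_pad(img, off$dy[i], off$dx[i]) - off$z[i])
  }
  out
}

gray_dilate_ball <- function(img, off) {
  out <- matrix(-Inf, nrow(img), ncol(img))
  for (i in seq_len(nrow(off))) {
    out <- pmax(out, shift_pad(img, -off$dy[i], -off$dx[i]) + off$z[i])
  }
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the slowly varying background of a fluorescence image as the
#' envelope traced by a ball rolled under the intensity surface —
#' implemented as a grayscale morphological opening with a hemisphere
#' structuring element — and subtracts it. Structures narrower than the
#' ball (diffraction-limited spots) survive; flat or smoothly varying
#' background maps to approximately zero, and the output is never negative
#' beyond numerical tolerance because the opening is anti-extensive.
#'
#' @param image 2-D numeric matrix.
#' @param ball_radius_um Ball radius (um); must be at least 1 px after
#'   conversion.
#' @param pixel_size_um Physical pixel edge (um).
#' @return Matrix of the same dimensions: `image - background`.
#' @export
subtract_background <- function(image, ball_radius_um = 0.48,
                                pixel_size_um = 0.16) {
  stopifnot(is.matrix(image))
  r_px <- um_to_px(ball_radius_um, pixel_size_um)
  if (r_px < 1) {
    abort("Rolling-ball radius is below 1 px after unit conversion.")
  }
  off <- ball_offsets(r_px)
  background <- gray_dilate_ball(gray_erode_ball(image, off), off)
  image - background
}

disc_offsets <- function(r_lo, r_hi) {
  r <- ceiling(r_hi)
  dd <- expand.grid(dy = -r:r, dx = -r:r)
  d <- sqrt(dd$dx^2 + dd$dy^2)
  dd[d >= r_lo & d <= r_hi, c("dy", "dx")]
}

# Gather pixel values at integer offsets around a subpixel center; offsets
# outside the field are dropped (attribute `clipped` reports whether any
# were).
gather_offsets <- function(img, cx, cy, off) {
  rows <- round(cy) + 1L + off$dy
  cols <- round(cx) + 1L + off$dx
  ok <- rows >= 1L & rows <= nrow(img) & cols >= 1L & cols <= ncol(img)
  vals <- img[cbind(rows[ok], cols[ok])]
  attr(vals, "clipped") <- any(!ok)
  vals
}

log_kernel <- function(sigma) {
  r <- max(2L, ceiling(4 * sigma))
  g <- expand.grid(dy = -r:r, dx = -r:r)
  d2 <- g$dx^2 + g$dy^2
  k <- (d2 - 2 * sigma^2) / sigma^4 * exp(-d2 / (2 * sigma^2))
  k <- k - mean(k)  # zero response to constant background
  matrix(k, nrow = 2L * r + 1L)
}

#' Detect diffraction-limited bright spots
#'
#' Blob detection on a (already denoised, background-subtracted) image:
#' local maxima of a negated Laplacian-of-Gaussian response at the
#' point-spread scale are candidate spots; candidates closer than one
#' aperture radius to a stronger candidate are suppressed; each survivor
#' is scored by a robust signal-to-noise contrast,
#' `(aperture mean - annulus median) / annulus MAD`, and emitted iff the
#' score reaches `contrast_min`. Centroids are refined to subpixel
#' precision by the intensity-weighted center of mass over the aperture.
#'
#' @param image 2-D numeric matrix (one channel, typically the temporal
#'   mean of the 5-frame Cy3 snapshot stack).
#' @param params A [detection_params()].
#' @param pixel_size_um Physical pixel edge (um).
#' @return A tibble with one row per detection: `spot_id`, `x_px`, `y_px`
#'   (subpixel), `aperture_radius_px`, `contrast`, `log_response`.
#' @export
detect_spots <- function(image, params = detection_params(),
                         pixel_size_um = 0.16) {
  stopifnot(is.matrix(image), inherits(params, "detection_params"))
  empty <- tibble(spot_id = integer(), x_px = numeric(), y_px = numeric(),
                  aperture_radius_px = numeric(), contrast = numeric(),
                  log_response = numeric())
  if (length(image) == 0L) return(empty)
  if (anyNA(image)) abort("`image` contains NA pixels.")

  ap_px <- um_to_px(params$spot_radius_um, pixel_size_um)
  sigma <- um_to_px(params$psf_sigma_um, pixel_size_um)
  resp <- -convolve2_replicate(image, log_kernel(sigma))

  h <- nrow(resp); w <- ncol(resp)
  if (h < 3L || w < 3L) return(empty)
  core <- resp[2:(h - 1), 2:(w - 1)]
  is_max <- core > 0
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    nb <- resp[2:(h - 1) + dy, 2:(w - 1) + dx]
    is_max <- is_max & (core >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  cand <- tibble(
    row = idx[, 1] + 1L, col = idx[, 2] + 1L,
    response = resp[cbind(idx[, 1] + 1L, idx[, 2] + 1L)]
  )
  # drop noise-floor maxima before the quadratic suppression pass; real
  # spots sit far above the robust response scale and are never touched
  rthr <- median(resp) + 6 * mad(resp)
  cand <- cand[cand$response > rthr, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(-cand$response), ]

  # non-maximum suppression at one aperture radius
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1L):nrow(cand)
      too_close <- (cand$row[j] - cand$row[i])^2 +
        (cand$col[j] - cand$col[i])^2 < ap_px^2
      keep[j[too_close]] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]

  ap_off <- disc_offsets(0, ap_px)
  an_off <- disc_offsets(ap_px + params$annulus_gap_px,
                         ap_px + params$annulus_gap_px + params$annulus_width_px)

  out <- vector("list", nrow(cand))
  n_emit <- 0L
  for (i in seq_len(nrow(cand))) {
    cx <- cand$col[i] - 1L; cy <- cand$row[i] - 1L
    ap_vals <- gather_offsets(image, cx, cy, ap_off)
    an_vals <- gather_offsets(image, cx, cy, an_off)
    if (length(an_vals) < 8L) next
    bg <- median(an_vals)
    noise <- max(mad(an_vals), .Machine$double.eps)
    contrast <- (mean(ap_vals) - bg) / noise
    if (contrast < params$contrast_min) next
    # subpixel centroid: center of mass of background-subtracted aperture
    rows <- round(cy) + 1L + ap_off$dy
    cols <- round(cx) + 1L + ap_off$dx
    ok <- rows >= 1L & rows <= h & cols >= 1L & cols <= w
    wgt <- pmax(image[cbind(rows[ok], cols[ok])] - bg, 0)
    if (sum(wgt) > 0) {
      cx <- sum((cols[ok] - 1L) * wgt) / sum(wgt)
      cy <- sum((rows[ok] - 1L) * wgt) / sum(wgt)
    }
    if (cx < 0 || cx > w - 1L || cy < 0 || cy > h - 1L) next
    n_emit <- n_emit + 1L
    out[[n_emit]] <- tibble(
      spot_id = n_emit, x_px = cx, y_px = cy,
      aperture_radius_px = ap_px, contrast = contrast,
      log_response = cand$response[i]
    )
  }
  if (n_emit == 0L) return(empty)
  dplyr::bind_rows(out[seq_len(n_emit)])
}

#' Extract aperture-photometry traces at detected spots
#'
#' For each detected intasome position, the Surf649 intensity per frame is
#' the sum over a circular aperture (radius = detection radius) minus the
#' local annulus median scaled by the aperture area; the Cy3 reference
#' intensity is the same measure averaged over the Cy3 snapshot frames.
#' Feed this the denoised (not rolling-ball-flattened) stacks: the annulus
#' median is the photometric background estimate, and flattening first
#' would subtract part of the spot itself, attenuating the flux scale
#' nonlinearly. Spots whose aperture or annulus is clipped by the field
#' edge are flagged `edge_clipped` (excluded downstream rather than
#' erroring).
#'
#' @param surf_stack Surf649 movie, an [image_stack()].
#' @param cy3_stack Cy3 snapshot stack sharing the field geometry.
#' @param spots Detections from [detect_spots()].
#' @param params A [detection_params()].
#' @return A tibble shaped like [simulate_traces()] output: one row per
#'   spot with `spot_id`, `condition`, `cy3_intensity`, `edge_clipped`,
#'   and list-columns `intensity`, `time_s`.
#' @export
extract_traces <- function(surf_stack, cy3_stack, spots,
                           params = detection_params()) {
  stopifnot(inherits(surf_stack, "image_stack"),
            inherits(cy3_stack, "image_stack"))
  d_s <- dim(surf_stack$frames); d_c <- dim(cy3_stack$frames)
  if (!all(d_s[1:2] == d_c[1:2])) {
    abort("Surf649 and Cy3 stacks do not share field geometry.")
  }
  ap_px <- um_to_px(params$spot_radius_um, surf_stack$pixel_size_um)
  ap_off <- disc_offsets(0, ap_px)
  an_off <- disc_offsets(ap_px + params$annulus_gap_px,
                         ap_px + params$annulus_gap_px + params$annulus_width_px)
  n_fr <- d_s[3]
  time_s <- frames_to_seconds(seq_len(n_fr) - 1, surf_stack$frame_rate_hz)

  h <- d_s[1]; w <- d_s[2]
  # flatten once: pixels x frames views of both stacks
  flat_surf <- matrix(surf_stack$frames, nrow = h * w)
  flat_cy3 <- matrix(cy3_stack$frames, nrow = h * w)

  photometry <- function(flat, cx, cy) {
    ap_r <- round(cy) + 1L + ap_off$dy; ap_c <- round(cx) + 1L + ap_off$dx
    an_r <- round(cy) + 1L + an_off$dy; an_c <- round(cx) + 1L + an_off$dx
    ok_ap <- ap_r >= 1L & ap_r <= h & ap_c >= 1L & ap_c <= w
    ok_an <- an_r >= 1L & an_r <= h & an_c >= 1L & an_c <= w
    clipped <- any(!ok_ap) || any(!ok_an)
    ap_idx <- (ap_c[ok_ap] - 1L) * h + ap_r[ok_ap]
    an_idx <- (an_c[ok_an] - 1L) * h + an_r[ok_an]
    ap_mat <- flat[ap_idx, , drop = FALSE]
    an_mat <- flat[an_idx, , drop = FALSE]
    bg <- apply(an_mat, 2L, median)
    list(trace = colSums(ap_mat) - bg * sum(ok_ap), clipped = clipped)
  }

  rows <- purrr::map(seq_len(nrow(spots)), function(i) {
    cx <- spots$x_px[i]; cy <- spots$y_px[i]
    surf <- photometry(flat_surf, cx, cy)
    cy3 <- photometry(flat_cy3, cx, cy)
    tibble(
      spot_id = spots$spot_id[i],
      condition = NA_character_,
      cy3_intensity = mean(cy3$trace),
      edge_clipped = surf$clipped || cy3$clipped,
      intensity = list(as.numeric(surf$trace)),
      time_s = list(time_s)
    )
  })
  dplyr::bind_rows(rows)
}

#' Run the Cy3 processing chain on a snapshot stack
#'
#' Convenience wrapper applying the printed processing order — denoise,
#' rolling-ball background subtraction, temporal mean over the snapshot
#' frames, bright-spot detection.
#'
#' @param cy3_stack Cy3 snapshot [image_stack()].
#' @param params A [detection_params()].
#' @return Detections tibble from [detect_spots()].
#' @export
process_cy3 <- function(cy3_stack, params = detection_params()) {
  stopifnot(inherits(cy3_stack, "image_stack"))
  dn <- denoise(cy3_stack, params$denoise_strength)
  for (f in seq_len(n_frames(dn))) {
    dn$frames[, , f] <- subtract_background(
      dn$frames[, , f], params$rolling_ball_radius_um, dn$pixel_size_um
    )
  }
  detect_spots(stack_mean(dn), params, pixel_size_um = dn$pixel_size_um)
}
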
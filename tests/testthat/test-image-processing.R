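test_that("denoise is a normalized Gaussian blur with identity at zero", {
  img <- matrix(rnorm(64 * 64), 64)
  expect_identical(denoise(img, 0), img)

  const <- matrix(3.7, 32, 32)
  expect_equal(denoise(const, 5), const, tolerance = 1e-8)

  # impulse response: discrete Gaussian kernel, total intensity preserved
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  out <- denoise(imp, 5)
  expect_lt(abs(sum(out) - 1), 1e-6)
  expect_equal(which.max(out), which.max(imp))
  # sigma = strength/5 = 1 px: value one pixel away relative to center
  expect_equal(out[17, 18] / out[17, 17], exp(-0.5), tolerance = 1e-6)

  expect_error(denoise(img, -1), "non-negative")
})

test_that("rolling-ball background subtraction removes smooth structure", {
  const <- matrix(7, 40, 40)
  expect_lt(max(abs(subtract_background(const))), 1e-8)

  # isolated spike narrower than the ball is foreground (the hemisphere
  # element leaves a sub-percent residue under an ideal 1-px impulse)
  spike <- matrix(0, 41, 41); spike[21, 21] <- 50
  out <- subtract_background(spike)
  expect_equal(out[21, 21], 50, tolerance = 0.01)

  # anti-extensive: never negative for input minus its own background
  img <- matrix(runif(40 * 40, 0, 10), 40)
  expect_gt(min(subtract_background(img)), -1e-8)

  expect_error(subtract_background(const, ball_radius_um = 0.1),
               "below 1 px")
})

test_that("rolling ball flattens a ramp while keeping a narrow spot", {
  w <- 64
  ramp <- matrix(rep(seq(0, 20, length.out = w), each = w), w)
  x <- matrix(rep(1:w, each = w), w); y <- t(x)
  spot <- 30 * exp(-((x - 32)^2 + (y - 32)^2) / 2)
  out <- subtract_background(ramp + spot)
  # ramp removed to < 5% of its range away from the spot
  away <- out[abs(x - 32) > 8 | abs(y - 32) > 8]
  expect_lt(max(abs(away)), 0.05 * 20)
  # spot amplitude preserved within 10%
  expect_gt(out[32, 32], 0.9 * 30)

  # oracle: direct brute-force grayscale opening with the same ball
  small <- ramp[1:24, 1:24] + spot[9:32, 9:32]
  off <- expand.grid(dy = -3:3, dx = -3:3)
  off <- off[off$dx^2 + off$dy^2 <= 9, ]
  off$z <- sqrt(9 - off$dx^2 - off$dy^2)
  brute_get <- function(m, r, c) {
    r <- pmin(pmax(r, 1), nrow(m)); c <- pmin(pmax(c, 1), ncol(m))
    m[cbind(r, c)]
  }
  er <- matrix(0, 24, 24)
  for (r in 1:24) for (c in 1:24) {
    er[r, c] <- min(brute_get(small, r + off$dy, c + off$dx) - off$z)
  }
  op <- matrix(0, 24, 24)
  for (r in 1:24) for (c in 1:24) {
    op[r, c] <- max(brute_get(er, r - off$dy, c - off$dx) + off$z)
  }
  expect_equal(subtract_background(small), small - op, tolerance = 1e-10)
})

test_that("detect_spots finds planted spots and rejects blank noise", {
  # dominant planted spot: exactly one detection within 1 px of truth
  set.seed(11)
  img <- matrix(rnorm(96 * 96, 0, 1), 96)
  x <- matrix(rep(1:96, each = 96), 96) - 1; y <- t(x)
  img <- img + 1500 / (2 * pi) * exp(-((x - 47.3)^2 + (y - 52.6)^2) / 2)
  det <- detect_spots(denoise(img, 5))
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x_px - 47.3), 1)
  expect_lt(abs(det$y_px - 52.6), 1)
  expect_gt(det$contrast, 14.5)

  # blank Gaussian noise at the printed threshold: virtually never a hit
  fp <- vapply(1:60, function(i) {
    set.seed(900 + i)
    blank <- denoise(matrix(rnorm(64 * 64), 64), 5)
    nrow(detect_spots(blank))
  }, numeric(1))
  expect_gte(mean(fp == 0), 0.99)

  expect_error(detect_spots(matrix(c(NA, 1, 2, 3), 2)), "NA")
  expect_equal(nrow(detect_spots(matrix(numeric(0), 0, 0))), 0L)
})

test_that("field-level detection reaches 95% recall and precision", {
  cfg <- sim_config(n_frames = 10L)
  recall <- precision <- c()
  for (s in 1:3) {
    f <- simulate_field(cfg, small_field(25, 160L), seed = 60 + s,
                        channels = "cy3")
    spots <- process_cy3(f$cy3)
    tr <- f$truth
    d2 <- outer(tr$x_px, spots$x_px, "-")^2 +
      outer(tr$y_px, spots$y_px, "-")^2
    ap2 <- (0.78 / 0.16)^2
    recall <- c(recall, mean(apply(d2[!tr$overlap_flag, , drop = FALSE],
                                   1, min) < ap2))
    precision <- c(precision, mean(apply(d2, 2, min) < ap2))
  }
  expect_gte(mean(recall), 0.95)
  expect_gte(mean(precision), 0.95)
})

test_that("photometric linearity: scaling the movie scales the traces", {
  cfg <- condition_preset("salt_0.2M", n_frames = 40L)
  f <- simulate_field(cfg, small_field(6, 64L), seed = 5)
  spots <- detect_spots(subtract_background(stack_mean(denoise(f$cy3, 5))))
  expect_gt(nrow(spots), 0L)
  tr1 <- extract_traces(f$surf649, f$cy3, spots)
  f2 <- f
  f2$surf649$frames <- 3 * f$surf649$frames
  tr2 <- extract_traces(f2$surf649, f$cy3, spots)
  expect_equal(tr2$intensity[[1]], 3 * tr1$intensity[[1]], tolerance = 1e-8)
})

test_that("extract_traces recovers amplitude, time axis and edge flags", {
  # zero movie -> all-zero traces
  zero <- image_stack(array(0, c(48, 48, 6)), frame_rate_hz = 5)
  spots <- tibble::tibble(spot_id = 1L, x_px = 24, y_px = 24)
  tr <- extract_traces(zero, zero, spots)
  expect_equal(tr$intensity[[1]], rep(0, 6))
  expect_equal(tr$time_s[[1]], (0:5) / 5)
  expect_false(tr$edge_clipped[1])

  # constant-amplitude noiseless spot: every frame ~ its integrated flux
  frames <- array(0, c(48, 48, 4))
  for (f in 1:4) {
    frames[, , f] <- bleachsteps:::render_spots(
      matrix(0, 48, 48), 23.4, 25.7, 80, 1.2)
  }
  st <- image_stack(frames)
  tr2 <- extract_traces(st, st,
                        tibble::tibble(spot_id = 1L, x_px = 23.4,
                                       y_px = 25.7))
  expect_equal(tr2$intensity[[1]], rep(80, 4), tolerance = 0.02 * 80)

  # spot close to the field edge is flagged
  tr3 <- extract_traces(st, st,
                        tibble::tibble(spot_id = 1L, x_px = 2, y_px = 24))
  expect_true(tr3$edge_clipped[1])

  bad <- image_stack(array(0, c(32, 32, 2)))
  expect_error(extract_traces(st, bad, spots), "geometry")
})

test_that("physical unit conversions match the acquisition geometry", {
  expect_equal(um_to_px(0.78), 4.875)
  expect_equal(um_to_px(0.48), 3)
  expect_equal(frames_to_seconds(899), 179.8)
  expect_equal(512 * 0.16, 81.92)
})
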
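test_that("occupancy draws follow the binomial site model", {
  cfg_full <- sim_config(occupancy_p = 1)
  expect_true(all(simulate_occupancy(50, cfg_full, seed = 1) == 16L))
  cfg_empty <- sim_config(occupancy_p = 0)
  expect_true(all(simulate_occupancy(50, cfg_empty, seed = 1) == 0L))

  # binomial mean n * p: 16 * 0.375 = 6, analytic oracle
  cfg <- sim_config(occupancy_p = 0.375)
  k <- simulate_occupancy(1e5, cfg, seed = 42)
  expect_true(all(k >= 0 & k <= 16))
  expect_lt(abs(mean(k) - 6), 0.05)

  # labeling efficiency thins the binomial
  cfg_thin <- sim_config(occupancy_p = 0.5, labeling_efficiency = 0.5)
  k2 <- simulate_occupancy(2e4, cfg_thin, seed = 3)
  se <- sqrt(16 * 0.25 * 0.75 / 2e4)
  expect_lt(abs(mean(k2) - 4), 3 * se + 0.05)

  expect_error(sim_config(occupancy_p = 1.2), "probability")
  expect_error(simulate_occupancy(0, cfg), "at least 1")
})

test_that("simulated traces are piecewise constant sums of unit steps", {
  cfg0 <- sim_config(noise_sd = 0)
  tr0 <- simulate_trace(0, cfg0, seed = 1)
  expect_equal(tr0$intensity, rep(0, cfg0$n_frames))
  expect_length(tr0$bleach_frames, 0)

  cfg <- sim_config(noise_sd = 0, unit_step_cv = 0, unit_step_mean = 1)
  tr <- simulate_trace(3, cfg, seed = 7)
  expect_equal(tr$intensity[1], 3)
  expect_equal(tr$intensity[cfg$n_frames], 0)
  expect_true(all(tr$intensity %in% 0:3))
  expect_true(all(diff(tr$intensity) <= 0))

  expect_error(simulate_trace(17, cfg), "k_true")
  expect_error(simulate_trace(-1, cfg), "k_true")
})

test_that("bleach frames are geometric with mean 1/q - 1", {
  q <- 0.01
  cfg <- sim_config(bleach_rate = q, n_frames = 5000L)
  frames <- unlist(lapply(1:400, function(i) {
    simulate_trace(4, cfg, seed = i)$bleach_frames
  }))
  expect_lt(abs(mean(frames) - (1 / q - 1)),
            3 * (sqrt(1 - q) / q) / sqrt(length(frames)))
})

test_that("trace conservation: one bleach frame per labeled fluorophore", {
  cfg <- condition_preset("salt_0.2M")
  tt <- simulate_traces(40, cfg, seed = 9)
  expect_equal(lengths(tt$bleach_frames), tt$n_labeled)
  expect_equal(tt$k_true, tt$n_labeled)  # labeling efficiency 1
})

test_that("simulation is deterministic and batch-size independent", {
  cfg <- condition_preset("salt_0.5M")
  a <- simulate_traces(12, cfg, seed = 5)
  b <- simulate_traces(12, cfg, seed = 5)
  expect_identical(a, b)
  big <- simulate_traces(20, cfg, seed = 5)
  expect_identical(a$intensity[[7]], big$intensity[[7]])

  f1 <- simulate_field(cfg, small_field(8, 64L), seed = 3)
  f2 <- simulate_field(cfg, small_field(8, 64L), seed = 3)
  expect_identical(f1$cy3$frames, f2$cy3$frames)
  expect_identical(f1$truth, f2$truth)
})

test_that("default bleach rate exceeds 95% completeness in a 3-min movie", {
  cfg <- sim_config()
  # geometric closed form, checked against simulation
  expect_gt(1 - (1 - cfg$bleach_rate)^cfg$n_frames, 0.95)
  frames <- unlist(lapply(1:500, function(i) {
    simulate_trace(4, cfg, seed = 100 + i)$bleach_frames
  }))
  expect_gt(mean(frames < cfg$n_frames - 1), 0.95)
})

test_that("condition presets encode the salt-series occupancies", {
  expect_equal(condition_preset("salt_0.2M")$occupancy_p, 6 / 16)
  expect_equal(condition_preset("salt_0.5M")$occupancy_p, 4 / 16)
  expect_equal(condition_preset("salt_1.0M")$occupancy_p, 2 / 16)
  expect_error(condition_preset("salt_0.9M"), "Unknown condition")

  # preset means recovered over many draws within 3 standard errors
  for (nm in salt_series()) {
    cfg <- condition_preset(nm)
    k <- simulate_occupancy(2e4, cfg, seed = 17)
    mu <- 16 * cfg$occupancy_p
    se <- sqrt(16 * cfg$occupancy_p * (1 - cfg$occupancy_p) / 2e4)
    expect_lt(abs(mean(k) - mu), 3 * se)
  }
})

test_that("simulated fields carry spots, background and ground truth", {
  cfg <- sim_config(n_frames = 30L)
  f0 <- simulate_field(cfg, small_field(0, 48L), seed = 1)
  expect_equal(nrow(f0$truth), 0L)
  expect_equal(dim(f0$cy3$frames)[3], 5L)
  # background + offset only, plus noise
  expect_lt(abs(mean(f0$cy3$frames) -
                  (100 + 5 + 1)), 1)  # offset + level + gradient/2

  # one noiseless spot: aperture flux matches the drawn Cy3 intensity
  cfg1 <- sim_config(cy3_sd = 0, n_frames = 10L)
  fld <- field_config(width_px = 64L, height_px = 64L, n_spots_mean = 1,
                      read_noise_sd = 0, background_gradient = 0)
  repeat_seed <- 2
  f1 <- simulate_field(cfg1, fld, seed = repeat_seed)
  if (nrow(f1$truth) == 1L) {
    img <- f1$cy3$frames[, , 1]
    bg <- 100 + 5
    expect_lt(abs(sum(img - bg) - f1$truth$cy3_true), 1)
  }

  # Poisson spot counts: mean over fields within 3 SE of the density
  counts <- vapply(1:60, function(i) {
    nrow(simulate_field(cfg, small_field(25, 64L), seed = 40 + i,
                        channels = "cy3")$truth)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 25), 3 * sqrt(25 / 60))
})

test_that("overlap flags mark intasome pairs within one aperture", {
  cfg <- sim_config(n_frames = 10L)
  f <- simulate_field(cfg, small_field(40, 96L), seed = 8)
  tr <- f$truth
  d <- as.matrix(dist(cbind(tr$x_px, tr$y_px)))
  diag(d) <- Inf
  expect_equal(tr$overlap_flag, apply(d < 0.78 / 0.16, 1, any))
})

test_that("rebrightening artifact injects an upward jump", {
  cfg <- sim_config(noise_sd = 0, unit_step_cv = 0)
  tr <- simulate_trace(3, cfg, seed = 4, inject_jump = TRUE,
                       jump_units = 2)
  expect_gt(max(diff(tr$intensity)), 1.5 * cfg$unit_step_mean)
})
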
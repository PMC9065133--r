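test_that("pairwise differences enumerate all earlier-minus-later pairs", {
  expect_equal(sort(pairwise_differences(c(3, 2, 1))), c(1, 1, 2))
  expect_equal(pairwise_differences(c(5, 5, 5, 5)), rep(0, 6))
  expect_length(pairwise_differences(rnorm(100)), 4950)
  expect_error(pairwise_differences(1), "at least 2")

  # pair-count invariant across lengths
  for (n in c(2, 7, 33)) {
    expect_length(pairwise_differences(seq_len(n)), n * (n - 1) / 2)
  }
})

test_that("difference density locates step-multiple peaks", {
  # noiseless 2-step unit trace with long plateaus: exact multiset has
  # mass at {0, 1, 2}; exactly two positive-side peaks at ~1 and ~2
  vals <- pairwise_differences(rep(c(2, 1, 0), each = 50))
  expect_equal(sort(unique(vals)), c(0, 1, 2))
  d <- estimate_density(vals, noise_sd_hat = 0.05)
  qual <- d$peaks[d$peaks$qualifying, ]
  expect_equal(nrow(qual), 2L)
  expect_equal(qual$position, c(1, 2), tolerance = 0.05)

  # all-zero values: single mode at 0, no positive-side peaks
  d0 <- estimate_density(rep(0, 100), noise_sd_hat = 0)
  expect_equal(nrow(d0$peaks), 0L)
  expect_gt(d0$bandwidth, 0)  # bandwidth floor, no degenerate density

  # density integrates to ~1
  grid <- d$density
  expect_lt(abs(sum(grid$density) * diff(grid$d[1:2]) - 1), 1e-3)

  expect_error(estimate_density(numeric(0), 1), "non-empty")
})

test_that("noiseless staircases are counted exactly for k = 0..16", {
  for (k in 0:16) {
    fit <- estimate_step_count(make_staircase(k))
    expect_identical(fit$k_steps, as.integer(k))
    if (k > 0) {
      expect_equal(fit$step_size_estimate, 10, tolerance = 0.1 * 10)
    }
  }
})

test_that("step counts are invariant to positive scaling and shifts", {
  cfg <- condition_preset("salt_0.2M")
  for (i in 1:8) {
    tr <- simulate_trace((i %% 6) + 1, cfg, seed = 200 + i)$intensity
    k0 <- estimate_step_count(tr)$k_steps
    for (c in c(0.02, 3, 1000)) {
      expect_identical(estimate_step_count(c * tr)$k_steps, k0)
    }
    expect_identical(estimate_step_count(tr + 500)$k_steps, k0)
  }
})

test_that("equal-step traces are recovered exactly at moderate noise", {
  # one step per fluorophore at noise 0.1x step; recovery measured against
  # the steps that occur within the movie (a fluorophore outliving the
  # acquisition leaves no step to count)
  cfg <- sim_config(unit_step_cv = 0, noise_sd = 2)
  for (k in c(1, 3, 5, 8)) {
    hits <- 0; n <- 60
    for (r in seq_len(n)) {
      tr <- simulate_trace(k, cfg, seed = 1000 * k + r)
      k_obs <- sum(tr$bleach_frames < cfg$n_frames - 1)
      hits <- hits + (estimate_step_count(tr$intensity)$k_steps == k_obs)
    }
    expect_gte(hits / n, 0.9)
  }
})

test_that("constant and single-step traces behave at the boundaries", {
  fit0 <- estimate_step_count(rep(5, 200))
  expect_identical(fit0$k_steps, 0L)
  expect_true(is.na(fit0$step_size_estimate))

  cfg <- condition_preset("salt_0.2M")
  tr <- simulate_trace(1, cfg, seed = 31, complete_bleach = TRUE)
  expect_identical(estimate_step_count(tr$intensity)$k_steps, 1L)
})

test_that("unstable profiles are classified by jumps and completeness", {
  # monotone staircase to zero: stable
  expect_false(classify_unstable(make_staircase(4), 10))

  # injected re-brightening jump of 2x step: unstable
  cfg <- sim_config(noise_sd = 1, unit_step_cv = 0)
  tr <- simulate_trace(4, cfg, seed = 12, inject_jump = TRUE,
                       jump_units = 2)
  fit <- estimate_step_count(tr$intensity)
  expect_true(classify_unstable(tr$intensity, fit$step_size_estimate))

  # trace ending at half its initial intensity: incomplete bleaching
  half <- c(rep(20, 100), rep(10, 100))
  expect_true(classify_unstable(half, 10))

  expect_error(classify_unstable(half, NA_real_), "positive")
})

test_that("exclusion chain applies exactly one reason in fixed order", {
  cfg <- condition_preset("salt_0.2M")
  ok <- simulate_trace(3, cfg, seed = 1, complete_bleach = TRUE)
  traces <- tibble::tibble(
    spot_id = 1:4,
    condition = "x",
    cy3_intensity = c(150, 250, 150, 250),
    edge_clipped = c(FALSE, FALSE, FALSE, TRUE),
    intensity = list(ok$intensity, ok$intensity, rep(3, cfg$n_frames),
                     ok$intensity),
    time_s = rep(list(seq_len(cfg$n_frames) / 5), 4)
  )
  res <- count_steps(traces)
  expect_equal(as.character(res$exclusion_reason),
               c("none", "bright_cy3", "zero_steps", "edge_clipped"))
  expect_equal(res$included, c(TRUE, FALSE, FALSE, FALSE))
  expect_true(all(res$k_steps[res$included] >= 1))
  # bookkeeping: total = included + per-reason exclusions
  expect_equal(nrow(res),
               sum(res$included) + sum(!res$included))
})

test_that("rebrightening traces are excluded as unstable by count_steps", {
  cfg <- condition_preset("salt_0.2M")
  tr <- simulate_trace(4, cfg, seed = 2, inject_jump = TRUE, jump_units = 2)
  traces <- tibble::tibble(
    spot_id = 1L, condition = "x", cy3_intensity = 150,
    edge_clipped = FALSE, intensity = list(tr$intensity),
    time_s = list(seq_len(cfg$n_frames) / 5)
  )
  expect_equal(as.character(count_steps(traces)$exclusion_reason),
               "unstable")
})

test_that("change-point oracle is exact on clean segmentations", {
  expect_identical(oracle_step_count(make_staircase(4, dwell = 30)), 4L)
  expect_identical(oracle_step_count(rep(5, 120)), 0L)
  # upward events are not counted as bleaching steps
  upd <- c(rep(2, 50), rep(5, 50), rep(1, 50))
  expect_identical(oracle_step_count(upd), 1L)
  # budget reduction warns on short traces
  expect_warning(oracle_step_count(rnorm(20), max_steps = 15), "reduced")
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- estimate_step_count(make_staircase(3, noise_sd = 0.3))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("position", "height", "qualifying") %in% names(td)))
  g <- glance(fit)
  expect_equal(nrow(g), 1L)
  expect_identical(g$k_steps, 3L)
  expect_equal(g$n_pairs, choose(fit$n_frames, 2))
})
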
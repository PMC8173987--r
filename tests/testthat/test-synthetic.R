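test_that("stride waveform has the contracted length, borders and margin", {
  cfg <- gait_config(noise_sd_dps = 0)
  sw <- generate_stride_waveform(1.0, cfg)
  expect_length(sw$gyr_ml, 103L)           # round(1.0 * 102.4) + 1
  expect_identical(sw$border_indices, c(1L, 103L))
  g <- sw$gyr_ml
  expect_true(which.min(g) %in% c(1L, length(g)))
  # each border lower than every interior sample by >= 0.25 * border amp
  margin <- min(g[-c(1L, length(g))]) - max(g[1L], g[length(g)])
  expect_gte(margin, 0.25 * cfg$border_peak_amp_dps)
  expect_equal(g[1L], -cfg$border_peak_amp_dps, tolerance = 1e-3)
  expect_error(generate_stride_waveform(0, cfg), "duration")
})

test_that("identical seeds reproduce waveforms, bouts and datasets bitwise", {
  cfg <- gait_config(noise_sd_dps = 5, seed = 42)
  w1 <- generate_stride_waveform(1.1, cfg, rng_stream(9))
  w2 <- generate_stride_waveform(1.1, cfg, rng_stream(9))
  expect_identical(w1, w2)
  b1 <- generate_bout(5, cfg, rng_stream(4))
  b2 <- generate_bout(5, cfg, rng_stream(4))
  expect_identical(b1, b2)
  d1 <- generate_dataset(2, bout_lengths = c(4, 6), config = cfg)
  d2 <- generate_dataset(2, bout_lengths = c(4, 6), config = cfg)
  expect_identical(d1, d2)
})

test_that("bout strides chain contiguously and borders sit on local minima", {
  cfg <- gait_config(noise_sd_dps = 5, seed = 11)
  bout <- generate_bout(20, cfg, rng_stream(2))
  expect_identical(nrow(bout$strides), 20L)
  expect_equal(bout$strides[-20L, 2], bout$strides[-1L, 1])
  g <- bout$data$gyr_ml
  minima <- which(diff(sign(diff(g))) > 0) + 1L
  for (b in unique(as.vector(bout$strides)))
    expect_lte(min(abs(minima - b)), 3)
  expect_error(generate_bout(0, cfg), "n_strides")
})

test_that("a four-stride block yields exactly one bout under the definition", {
  cfg <- gait_config(seed = 5)
  bout <- generate_bout(4, cfg, rng_stream(1))
  wb <- define_walking_bouts(list(left = bout$strides, right = NULL), cfg$sampling_rate_hz)
  expect_identical(nrow(wb), 1L)
  expect_identical(attr(wb, "n_strides"), 4L)
})

test_that("datasets are bookkept exactly and bouts round-trip", {
  cfg <- gait_config(seed = 13)
  lens <- c(4, 7, 12)
  ds <- generate_dataset(3, bout_lengths = lens, config = cfg)
  expect_length(ds, 3L)
  for (rec in ds) {
    expect_identical(nrow(rec$strides$left) + nrow(rec$strides$right),
                     as.integer(sum(lens)))
    wb <- define_walking_bouts(rec$strides, rec$fs)
    expect_equal(as.vector(unname(wb)), as.vector(unname(rec$bouts)))
    expect_identical(attr(wb, "n_strides"), as.integer(lens))
  }
  expect_error(generate_dataset(2, bout_lengths = c(0, 4), config = cfg),
               "count")
})

test_that("snapping ground-truth borders moves them at most one sample", {
  # noise at a tenth of the border amplitude, 100 seeded bouts
  cfg <- gait_config(noise_sd_dps = 40, seed = 1)
  moved <- 0L
  for (s in 1:100) {
    bout <- generate_bout(4, cfg, rng_stream(s))
    g <- bout$data$gyr_ml
    for (b in unique(as.vector(bout$strides))) {
      snapped <- snap_to_minimum(g, b, 200, cfg$sampling_rate_hz)
      expect_lte(abs(snapped - b), 1)
    }
  }
})

test_that("every generated recording satisfies the label invariants", {
  for (s in 1:50) {
    rng <- rng_stream(1000 + s)
    cfg <- with_rng(rng, gait_config(
      border_peak_amp_dps = runif(1, 250, 500),
      swing_peak_amp_dps = runif(1, 180, 350),
      noise_sd_dps = runif(1, 0, 10),
      transition_amp_dps = runif(1, 50, 130),
      short_bout_heterogeneity = sample(c(TRUE, FALSE), 1),
      seed = s))
    rec <- generate_dataset(1, bout_lengths = c(4, 9), config = cfg)[[1]]
    n <- nrow(rec$left$data)
    expect_identical(n, nrow(rec$right$data))
    for (foot in c("left", "right")) {
      s_m <- rec$strides[[foot]]
      expect_true(all(s_m[, 1] >= 1 & s_m[, 2] <= n))
      expect_true(all(s_m[, 1] < s_m[, 2]))
      expect_false(is.unsorted(s_m[, 1]))
      if (nrow(s_m) > 1L)
        expect_true(all(s_m[-1L, 1] >= s_m[-nrow(s_m), 2]))
      # every stride inside some bout
      for (r in seq_len(nrow(s_m)))
        expect_true(any(s_m[r, 1] >= rec$bouts[, 1] &
                          s_m[r, 2] <= rec$bouts[, 2]))
    }
  }
})

test_that("generator configuration invariants are enforced", {
  expect_error(gait_config(sampling_rate_hz = 0), "sampling_rate_hz")
  expect_error(gait_config(noise_sd_dps = -1), "noise_sd")
  expect_error(gait_config(transition_amp_dps = 500), "must exceed")
  expect_error(gait_config(rest_gap_s = c(5, 2)), "rest_gap")
})
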
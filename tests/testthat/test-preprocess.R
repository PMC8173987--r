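test_that("body-frame transform honours rotation and right-foot mirroring", {
  rec <- make_recording(100)
  left <- to_body_frame(rec, diag(3), "left")
  expect_equal(left$data, rec$data)
  right <- to_body_frame(rec, diag(3), "right")
  expect_equal(right$data$gyr_ml, -rec$data$gyr_ml)
  expect_equal(right$data$gyr_pa, rec$data$gyr_pa)
  expect_equal(right$data$gyr_si, rec$data$gyr_si)
  expect_error(to_body_frame(rec, diag(3) * 0.5), "orthonormal")
})

test_that("gravity alignment recovers a synthetic tilt about the pa axis", {
  n <- 400
  theta <- 10 * pi / 180
  R <- matrix(c(cos(theta), 0, sin(theta), 0, 1, 0,
                -sin(theta), 0, cos(theta)), 3, 3, byrow = TRUE)
  g_tilt <- as.numeric(solve(R) %*% c(0, 0, 9.81))
  rec <- flat_recording(n, acc = g_tilt)
  aligned <- align_gravity(rec)
  # recovered gravity direction within 0.5 degrees of +si
  v <- colMeans(aligned$data[1:50, c("acc_ml", "acc_pa", "acc_si")])
  ang <- acos(sum(v * c(0, 0, 1)) / sqrt(sum(v^2))) * 180 / pi
  expect_lt(ang, 0.5)
  # already aligned input is a fixed point
  rec0 <- flat_recording(n)
  expect_equal(align_gravity(rec0)$data, rec0$data, tolerance = 1e-9)
  # all-moving recording: no static frame
  moving <- flat_recording(n, gyr = 300)
  expect_error(align_gravity(moving), "static")
})

test_that("zero-phase filter has unit DC gain and textbook band behaviour", {
  fs <- 102.4
  expect_equal(lowpass_zero_phase(rep(3.7, 500), fs), rep(3.7, 500),
               tolerance = 1e-9)
  t <- seq(0, 10, by = 1 / fs)
  mid <- 200:(length(t) - 200)
  y1 <- lowpass_zero_phase(sin(2 * pi * 1 * t), fs)
  expect_lt(abs(max(abs(y1[mid])) - 1), 0.01)          # 1 Hz preserved
  y25 <- lowpass_zero_phase(sin(2 * pi * 25 * t), fs)
  expect_lt(max(abs(y25[mid])), 0.01)                  # 25 Hz crushed
  # symmetric pulse keeps its peak location (zero phase)
  pulse <- exp(-0.5 * ((seq_len(501) - 251) / 5)^2)
  expect_identical(which.max(lowpass_zero_phase(pulse, fs)), 251L)
  expect_error(lowpass_zero_phase(rnorm(5), fs), "short")
})

test_that("filtering commutes with time reversal", {
  rng <- rng_stream(8)
  x <- with_rng(rng, cumsum(rnorm(600)))
  fwd <- rev(lowpass_zero_phase(x, 102.4))
  bwd <- lowpass_zero_phase(rev(x), 102.4)
  # transients differ only in the first/last filter warm-up region
  interior <- 100:501
  expect_equal(bwd[interior], fwd[interior], tolerance = 1e-9)
})

test_that("decimation keeps every second sample and halves the rate", {
  d <- decimate_by_two(seq_len(1001), fs = 102.4)
  expect_length(d$series, 501L)
  expect_equal(d$fs, 51.2)
  expect_equal(d$series, seq(1, 1001, by = 2))
  rec <- make_recording(100)
  rec2 <- decimate_by_two(rec)
  expect_equal(rec2$fs, rec$fs / 2)
  expect_equal(rec2$data$gyr_ml, rec$data$gyr_ml[seq(1, 100, 2)])
})

test_that("annotation re-indexing preserves event times within half a coarse sample", {
  doc <- gait_annotations(list(left = rbind(c(101, 205), c(205, 312))),
                          bouts = rbind(c(101, 312)), fs = 102.4)
  half <- reindex_annotations_by_two(doc)
  expect_equal(half$sampling_rate_hz, 51.2)
  orig_t <- (doc$strides$left - 1) / 102.4
  new_t <- (half$strides$left - 1) / 51.2
  expect_true(all(abs(orig_t - new_t) <= 0.5 / 51.2 + 1e-12))
})

test_that("activity windows isolate movement bursts", {
  fs <- 102.4
  n <- round(60 * fs)
  g <- rep(0, n)
  burst <- round(20 * fs):round(25 * fs)
  g[burst] <- 200
  rec <- flat_recording(n)
  rec$data$gyr_ml <- g
  w <- detect_activity_windows(rec, threshold_dps = 50)
  expect_identical(nrow(w), 1L)
  expect_lt(abs(w[1, 1] - burst[1]), fs)
  expect_lt(abs(w[1, 2] - burst[length(burst)]), fs)
  expect_identical(nrow(detect_activity_windows(flat_recording(n), 50)), 0L)
  full <- detect_activity_windows(flat_recording(1000), 0)
  expect_equal(unname(full), cbind(1, 1000))
})

test_that("snapping finds windowed minima, truncates and is idempotent", {
  fs <- 102.4
  x <- (seq_len(200) - 120)^2               # parabola, vertex at 120
  expect_identical(snap_to_minimum(x, 117, 200, fs), 120L)
  expect_identical(snap_to_minimum(x, 120, 200, fs), 120L)
  y <- c(-5, 1, 2, 3, 4, 5, 6, 7)           # minimum at the boundary
  expect_identical(snap_to_minimum(y, 3, 200, fs), 1L)
  expect_error(snap_to_minimum(x, 0, 200, fs), "range")
  rng <- rng_stream(5)
  for (i in 1:50) {
    sig <- with_rng(rng, rnorm(100))
    idx <- with_rng(rng, sample(100, 1))
    once <- snap_to_minimum(sig, idx, 200, fs)
    expect_identical(snap_to_minimum(sig, once, 200, fs), once)
  }
})
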
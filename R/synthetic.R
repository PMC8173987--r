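## Synthetic labelled gait recordings.
##
## The generator emulates the signal structure the segmenter relies on: on
## gyr_ml each stride carries sharp negative peaks at both borders, a broad
## positive mid-swing peak and a near-zero stance plateau; bouts are
## contiguous per-foot stride trains flanked by low-amplitude irregular
## "transition" movement, separated by quiet rest gaps; the accelerometer
## si-axis sits at gravity. Both feet are generated with an alternating
## phase offset of half a stride so the merged-timeline bout definition
## applies. All ground-truth borders are exact by construction.

#' Configuration for the synthetic gait generator
#'
#' Defaults describe a plausible foot-worn IMU gait recording: 102.4 Hz
#' sampling, ~1.1 s strides, border peaks of 400 deg/s, mid-swing peaks of
#' 300 deg/s, 5 deg/s additive sensor noise and 100 deg/s non-gait
#' transition movement.
#'
#' @param sampling_rate_hz Sampling rate (Hz).
#' @param stride_duration_s Length-2 vector `c(mean, sd)` of per-stride
#'   duration in seconds.
#' @param border_peak_amp_dps Magnitude of the negative gyr_ml peak at each
#'   stride border (deg/s).
#' @param swing_peak_amp_dps Magnitude of the positive mid-swing peak (deg/s).
#' @param noise_sd_dps Standard deviation of additive Gaussian noise (deg/s).
#' @param transition_amp_dps Amplitude scale of the irregular movement at
#'   bout edges (deg/s); must stay below `border_peak_amp_dps` so borders
#'   remain distinguishable.
#' @param rest_gap_s Length-2 vector `c(min, max)` of rest-gap duration
#'   between bouts (seconds).
#' @param subject_variability Fractional (log-normal) standard deviation of
#'   per-subject amplitude and duration multipliers.
#' @param short_bout_heterogeneity If `TRUE`, strides in bouts shorter than
#'   30 strides (both feet combined) receive stronger duration/amplitude
#'   jitter and attenuated, variable border peaks, emulating the more
#'   heterogeneous, less clearly bordered strides observed in short
#'   free-living walking bouts.
#' @param seed Integer seed; all randomness flows through one stream derived
#'   from it.
#' @return An object of class `"gait_config"`.
#' @export
gait_config <- function(sampling_rate_hz = 102.4,
                        stride_duration_s = c(mean = 1.1, sd = 0.06),
                        border_peak_amp_dps = 400,
                        swing_peak_amp_dps = 300,
                        noise_sd_dps = 5,
                        transition_amp_dps = 100,
                        rest_gap_s = c(min = 4, max = 8),
                        subject_variability = 0.1,
                        short_bout_heterogeneity = FALSE,
                        seed = 1L) {
  stopifnot_scalar(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  if (length(stride_duration_s) != 2L || any(stride_duration_s[1] <= 0))
    stop("stride_duration_s must be c(mean, sd) with mean > 0", call. = FALSE)
  stopifnot_scalar(border_peak_amp_dps, "border_peak_amp_dps", positive = TRUE)
  stopifnot_scalar(swing_peak_amp_dps, "swing_peak_amp_dps", positive = TRUE)
  if (noise_sd_dps < 0) stop("noise_sd_dps must be >= 0", call. = FALSE)
  if (length(rest_gap_s) != 2L || any(rest_gap_s <= 0) ||
      rest_gap_s[2] < rest_gap_s[1])
    stop("rest_gap_s must be c(min, max) with 0 < min <= max", call. = FALSE)
  if (transition_amp_dps >= border_peak_amp_dps)
    stop("border_peak_amp_dps must exceed transition_amp_dps", call. = FALSE)
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 stride_duration_s = unname(stride_duration_s),
                 border_peak_amp_dps = border_peak_amp_dps,
                 swing_peak_amp_dps = swing_peak_amp_dps,
                 noise_sd_dps = noise_sd_dps,
                 transition_amp_dps = transition_amp_dps,
                 rest_gap_s = unname(rest_gap_s),
                 subject_variability = subject_variability,
                 short_bout_heterogeneity = short_bout_heterogeneity,
                 seed = seed),
            class = "gait_config")
}

## sharp two-sample border notch profile: depth `amp` at offset 0,
## ~0.71*amp at offset 1, zero beyond offset 2
border_notch <- function(offsets, amp) {
  v <- numeric(length(offsets))
  k <- abs(offsets)
  inside <- k < 2
  v[inside] <- -amp * cos(pi * k[inside] / 4)
  v
}

#' Generate one synthetic stride waveform (gyr_ml)
#'
#' The noiseless waveform has strict negative peaks of depth
#' `border_peak_amp_dps` at the first and last sample (the two stride
#' borders), a positive mid-swing peak around 35% of the stride, and a
#' near-zero stance plateau. Each border sample is lower than every interior
#' sample by at least a quarter of the border-peak amplitude.
#'
#' @param duration_s Stride duration in seconds (> 0).
#' @param config A [gait_config()].
#' @param rng An [rng_stream()] for the additive noise.
#' @return `list(gyr_ml, border_indices = c(1, L))` with
#'   `L = round(duration_s * fs) + 1` samples.
#' @export
generate_stride_waveform <- function(duration_s, config, rng = rng_stream(config$seed)) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("duration_s must be > 0", call. = FALSE)
  w <- stride_waveform_shape(duration_s, config$sampling_rate_hz,
                             config$border_peak_amp_dps,
                             config$swing_peak_amp_dps,
                             STRIDE_TYPES$steady)
  if (config$noise_sd_dps > 0)
    w <- w + with_rng(rng, stats::rnorm(length(w), 0, config$noise_sd_dps))
  list(gyr_ml = w, border_indices = c(1L, length(w)))
}

## noiseless stride shape for one stride type
stride_waveform_shape <- function(duration_s, fs, border_amp, swing_amp,
                                  type) {
  L <- round(duration_s * fs) + 1L
  k <- seq_len(L) - 1L
  phase <- k / (L - 1L)
  w <- swing_amp * type$swing *
    exp(-0.5 * ((phase - type$swing_pos) / type$swing_width)^2)
  for (ex in type$extra)
    w <- w + swing_amp * ex["amp"] *
      exp(-0.5 * ((phase - ex["pos"]) / ex["width"])^2)
  # small stance-phase dip for realism, well above the border depth
  w <- w - 0.08 * border_amp * exp(-0.5 * ((phase - 0.82) / 0.06)^2)
  w <- w + border_notch(k, border_amp * type$border)
  w <- w + border_notch(k - (L - 1L), border_amp * type$border)
  w
}

## irregular movement for transition flourishes: random low-frequency
## sinusoids with a heterogeneous per-flourish amplitude (free-living
## transitions range from gentle weight shifts to vigorous turns), tapered
## to zero at the edges. Amplitudes stay below the stride border peaks.
transition_movement <- function(n, fs, amp, rng) {
  if (n <= 0L) return(numeric(0))
  t <- (seq_len(n) - 1L) / fs
  with_rng(rng, {
    scale <- exp(stats::rnorm(1, 0, 0.5))
    scale <- min(max(scale, 0.3), 2.2)
    f <- stats::runif(4, 0.5, 5)
    ph <- stats::runif(4, 0, 2 * pi)
    a <- stats::runif(4, 0.3, 1)
  })
  s <- amp * scale * colSums(a * sin(outer(f, t) * 2 * pi + ph)) / sum(a)
  # aborted partial steps: a swing-like bump next to a single shallow dip,
  # common when starting/stopping gait; never as deep as a stride border
  n_steps <- with_rng(rng, stats::rbinom(1, 2, 0.3))
  if (n_steps > 0L && n > round(0.6 * fs)) {
    for (i in seq_len(n_steps)) {
      with_rng(rng, {
        ctr <- stats::runif(1, 0.2, 0.8) * max(t)
        bump_a <- stats::runif(1, 1.2, 2.0) * amp
        dip_a <- stats::runif(1, 0.8, 1.6) * amp
        side <- sample(c(-1, 1), 1)
      })
      s <- s + bump_a * exp(-0.5 * ((t - ctr) / 0.06)^2) -
        dip_a * exp(-0.5 * ((t - ctr - side * 0.14) / 0.025)^2)
    }
  }
  taper <- 0.5 - 0.5 * cos(pi * pmin(1, pmin(t, rev(t)) / max(t[2], 0.25)))
  s * taper
}

## stride-type library: shape variants seen in short free-living bouts.
## Each type scales the swing peak, moves it, attenuates the borders and may
## add extra lobes; a single averaged template cannot cover this diversity,
## while mixture-emission HMM states can.
STRIDE_TYPES <- list(
  steady = list(swing = 1, swing_pos = 0.35, swing_width = 0.08,
                border = 1, dur = 1, extra = NULL),
  turning = list(swing = 0.35, swing_pos = 0.45, swing_width = 0.11,
                 border = 0.8, dur = 1.25, extra = NULL),
  shuffle = list(swing = 0.3, swing_pos = 0.33, swing_width = 0.07,
                 border = 0.55, dur = 0.9,
                 extra = list(c(pos = 0.68, amp = 0.3, width = 0.08))),
  irregular = list(swing = 0.8, swing_pos = 0.26, swing_width = 0.07,
                   border = 0.75, dur = 1.1,
                   extra = list(c(pos = 0.52, amp = 0.55, width = 0.08)))
)

## per-stride shape/jitter parameters; short-bout mode draws from the full
## stride-type library, steady gait keeps mild log-normal jitter only
stride_jitter <- function(n_strides, combined_count, config, rng) {
  short_mode <- isTRUE(config$short_bout_heterogeneity) && combined_count < 30
  with_rng(rng, {
    if (short_mode) {
      types <- sample(names(STRIDE_TYPES), n_strides, replace = TRUE,
                      prob = c(0.5, 0.2, 0.15, 0.15))
      dur <- exp(stats::rnorm(n_strides, 0, 0.12))
      amp <- exp(stats::rnorm(n_strides, 0, 0.15))
    } else {
      types <- rep("steady", n_strides)
      dur <- exp(stats::rnorm(n_strides, 0, 0.05))
      amp <- exp(stats::rnorm(n_strides, 0, 0.08))
    }
    list(dur = dur, amp = amp, types = types)
  })
}

## build the gyr_ml stride train of one foot: contiguous strides sharing
## border samples; returns signal plus 1-based stride intervals
stride_train <- function(n_strides, combined_count, config, rng,
                         subject_dur = 1, subject_amp = 1) {
  jit <- stride_jitter(n_strides, combined_count, config, rng)
  sig <- numeric(0)
  strides <- matrix(0, n_strides, 2L)
  pos <- 1L
  for (i in seq_len(n_strides)) {
    type <- STRIDE_TYPES[[jit$types[i]]]
    dur <- config$stride_duration_s[1] * subject_dur * jit$dur[i] * type$dur +
      with_rng(rng, stats::rnorm(1, 0, config$stride_duration_s[2]))
    dur <- min(max(dur, 0.55 * config$stride_duration_s[1]),
               1.8 * config$stride_duration_s[1])
    w <- stride_waveform_shape(dur, config$sampling_rate_hz,
                               config$border_peak_amp_dps * subject_amp *
                                 jit$amp[i],
                               config$swing_peak_amp_dps * subject_amp *
                                 jit$amp[i],
                               type)                 # noise added per bout
    L <- length(w)
    if (i == 1L) {
      sig <- w
      strides[i, ] <- c(1L, L)
    } else {
      # share the border sample; keep the deeper of the two border notches
      sig[pos] <- min(sig[pos], w[1L])
      sig <- c(sig, w[-1L])
      strides[i, ] <- c(pos, pos + L - 1L)
    }
    pos <- pos + L - 1L
  }
  list(gyr_ml = sig, strides = strides)
}

## fill the remaining six channels around a gyr_ml series
fill_channels <- function(gyr_ml, fs, config, rng, active = NULL) {
  n <- length(gyr_ml)
  nz <- function(sd) if (sd > 0) with_rng(rng, stats::rnorm(n, 0, sd)) else numeric(n)
  sd_g <- max(config$noise_sd_dps, 1)
  data.frame(
    time_s = (seq_len(n) - 1L) / fs,
    acc_ml = nz(0.3),
    acc_pa = nz(0.3) + 0.002 * gyr_ml,
    acc_si = GRAVITY_MS2 + nz(0.3) + 0.004 * abs(gyr_ml),
    gyr_ml = gyr_ml,
    gyr_pa = 0.25 * gyr_ml + nz(sd_g),
    gyr_si = 0.15 * gyr_ml + nz(sd_g)
  )
}

#' Generate one synthetic single-foot walking bout
#'
#' `n_strides` strides are concatenated so stride i's end sample equals
#' stride i+1's start sample; low-amplitude irregular transition movement is
#' prepended and appended; the accompanying channels are filled (acc_si near
#' gravity plus noise, other axes low-amplitude noise).
#'
#' @param n_strides Number of strides (>= 1).
#' @param config A [gait_config()].
#' @param rng An [rng_stream()].
#' @return `list(data = 7-column data frame, strides = 2-column matrix of
#'   1-based stride intervals within the block)`.
#' @export
generate_bout <- function(n_strides, config, rng = rng_stream(config$seed)) {
  if (!is.numeric(n_strides) || n_strides < 1)
    stop("n_strides must be >= 1", call. = FALSE)
  fs <- config$sampling_rate_hz
  train <- stride_train(n_strides, n_strides, config, rng)
  pre_n <- round(with_rng(rng, stats::runif(1, 0.9, 1.6)) * fs)
  post_n <- round(with_rng(rng, stats::runif(1, 0.9, 1.6)) * fs)
  pre <- transition_movement(pre_n, fs, config$transition_amp_dps, rng)
  post <- transition_movement(post_n, fs, config$transition_amp_dps, rng)
  gyr_ml <- c(pre, train$gyr_ml, post)
  if (config$noise_sd_dps > 0)
    gyr_ml <- gyr_ml + with_rng(rng, stats::rnorm(length(gyr_ml), 0,
                                                  config$noise_sd_dps))
  strides <- train$strides + pre_n
  list(data = fill_channels(gyr_ml, fs, config, rng), strides = strides)
}

#' Generate a synthetic labelled gait dataset
#'
#' One labelled recording per subject: per-subject amplitude and duration
#' multipliers are drawn from `subject_variability`; each bout places both
#' feet on a shared timeline with the right foot offset by half a stride;
#' bouts are separated by rest gaps drawn from `rest_gap_s`. Ground-truth
#' stride intervals and walking bouts are exact by construction, and
#' [define_walking_bouts()] applied to the stride annotations recovers the
#' generated bouts.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param bouts_per_subject Number of bouts per subject (>= 1), used when
#'   `bout_lengths` is a sampler function.
#' @param bout_lengths Either an integer vector of combined (both-feet)
#'   stride counts used for every subject, or a `function(n)` drawing `n`
#'   counts.
#' @param config A [gait_config()]; `config$seed` makes the dataset
#'   reproducible.
#' @return List of `"labeled_recording"` objects, each with elements
#'   `left`/`right` ([imu_recording()]s on a shared time axis), `strides`
#'   (per-foot interval matrices), `bouts`, `fs` and `subject_id`.
#' @export
generate_dataset <- function(n_subjects, bouts_per_subject = NULL,
                             bout_lengths, config = gait_config()) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  rng <- rng_stream(config$seed)
  fs <- config$sampling_rate_hz
  out <- vector("list", n_subjects)
  for (subj in seq_len(n_subjects)) {
    if (is.function(bout_lengths)) {
      nb <- bouts_per_subject
      if (is.null(nb) || nb < 1) stop("bouts_per_subject must be >= 1", call. = FALSE)
      counts <- with_rng(rng, bout_lengths(nb))
    } else {
      counts <- as.integer(bout_lengths)
    }
    if (!length(counts) || any(counts < 1))
      stop("bout length sampler produced a count < 1", call. = FALSE)
    sv <- config$subject_variability
    subject_amp <- with_rng(rng, exp(stats::rnorm(1, 0, sv)))
    subject_dur <- with_rng(rng, exp(stats::rnorm(1, 0, sv / 2)))
    gl <- numeric(0); gr <- numeric(0)       # per-foot gyr_ml timelines
    sl <- NULL; sr <- NULL                   # per-foot stride intervals
    bouts <- NULL
    pad <- function(n) rep(0, max(0L, n))
    lead_n <- round(2 * fs)
    gl <- pad(lead_n); gr <- pad(lead_n)
    for (b in seq_along(counts)) {
      Ncomb <- counts[b]
      n_left <- ceiling(Ncomb / 2)
      n_right <- Ncomb - n_left
      tl <- stride_train(n_left, Ncomb, config, rng, subject_dur, subject_amp)
      offset <- round(0.5 * config$stride_duration_s[1] * subject_dur * fs)
      pre_n <- round(with_rng(rng, stats::runif(1, 0.9, 1.6)) * fs)
      post_n <- round(with_rng(rng, stats::runif(1, 0.9, 1.6)) * fs)
      base <- length(gl)                      # bout block starts after this
      lstart <- base + pre_n                  # left train offset within block
      l_sig <- c(transition_movement(pre_n, fs, config$transition_amp_dps, rng),
                 tl$gyr_ml,
                 transition_movement(post_n, fs, config$transition_amp_dps, rng))
      if (n_right > 0L) {
        tr <- stride_train(n_right, Ncomb, config, rng, subject_dur, subject_amp)
        # right foot starts half a stride later: longer leading transition
        r_sig <- c(transition_movement(pre_n + offset, fs,
                                       config$transition_amp_dps, rng),
                   tr$gyr_ml,
                   transition_movement(post_n, fs, config$transition_amp_dps, rng))
        rstart <- base + pre_n + offset
      } else {
        tr <- NULL
        r_sig <- transition_movement(pre_n + post_n, fs,
                                     config$transition_amp_dps, rng)
        rstart <- base + pre_n
      }
      block_len <- max(length(l_sig), length(r_sig))
      l_block <- c(l_sig, pad(block_len - length(l_sig)))
      r_block <- c(r_sig, pad(block_len - length(r_sig)))
      gl <- c(gl, l_block)
      gr <- c(gr, r_block)
      s_l <- tl$strides + lstart
      sl <- rbind(sl, s_l)
      if (!is.null(tr)) {
        s_r <- tr$strides + rstart
        sr <- rbind(sr, s_r)
      } else {
        s_r <- NULL
      }
      all_s <- rbind(s_l, s_r)
      bouts <- rbind(bouts, c(min(all_s[, 1]), max(all_s[, 2])))
      if (b < length(counts)) {
        gap_n <- round(with_rng(rng, stats::runif(1, config$rest_gap_s[1],
                                                  config$rest_gap_s[2])) * fs)
        gl <- c(gl, pad(gap_n)); gr <- c(gr, pad(gap_n))
      }
    }
    tail_n <- round(2 * fs)
    gl <- c(gl, pad(tail_n)); gr <- c(gr, pad(tail_n))
    stopifnot(length(gl) == length(gr))
    if (config$noise_sd_dps > 0) {
      gl <- gl + with_rng(rng, stats::rnorm(length(gl), 0, config$noise_sd_dps))
      gr <- gr + with_rng(rng, stats::rnorm(length(gr), 0, config$noise_sd_dps))
    }
    left <- imu_recording(fill_channels(gl, fs, config, rng), fs, "left")
    right <- imu_recording(fill_channels(gr, fs, config, rng), fs, "right")
    out[[subj]] <- structure(
      list(left = left, right = right,
           strides = list(left = as_interval_matrix(sl),
                          right = as_interval_matrix(sr)),
           bouts = as_interval_matrix(bouts),
           fs = fs, subject_id = sprintf("S%02d", subj)),
      class = "labeled_recording")
  }
  out
}

#' @export
print.labeled_recording <- function(x, ...) {
  cat(sprintf("<labeled_recording> %s: %d + %d strides in %d bouts, %.1f s @ %.4g Hz\n",
              x$subject_id, nrow(x$strides$left), nrow(x$strides$right),
              nrow(x$bouts), nrow(x$left$data) / x$fs, x$fs))
  invisible(x)
}

#' Convert a labelled recording's ground truth to an annotation document
#'
#' @param x A `"labeled_recording"`.
#' @return A [gait_annotations()] object at the recording's sampling rate.
#' @export
as_annotations <- function(x) {
  stopifnot(inherits(x, "labeled_recording"))
  gait_annotations(strides = x$strides, bouts = x$bouts, fs = x$fs,
                   n_samples = nrow(x$left$data),
                   provenance = paste0("synthetic ground truth, subject ",
                                       x$subject_id))
}
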
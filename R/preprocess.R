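## Signal front end: body-frame transform, gravity alignment, zero-phase
## low-pass, decimation, activity windows and border snapping.

GRAVITY_MS2 <- 9.81

acc_cols <- c("acc_ml", "acc_pa", "acc_si")
gyr_cols <- c("gyr_ml", "gyr_pa", "gyr_si")

#' Rotate a sensor-frame recording into the shared body frame
#'
#' Applies one fixed mounting rotation to both the accelerometer and the
#' gyroscope triplets. For the right foot the medial-lateral axes are
#' sign-flipped after rotation so that both feet share the same gyr_ml
#' polarity and a single segmentation pipeline can serve both sides.
#'
#' @param recording An [imu_recording()] in sensor coordinates.
#' @param rotation 3x3 orthonormal rotation matrix (sensor -> body).
#' @param foot `"left"` or `"right"`.
#' @return The rotated [imu_recording()].
#' @export
to_body_frame <- function(recording, rotation = diag(3), foot = recording$foot) {
  stopifnot(inherits(recording, "imu_recording"))
  foot <- match.arg(foot, c("left", "right"))
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      abs(abs(det(rotation)) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("'rotation' must be a 3x3 orthonormal matrix", call. = FALSE)
  df <- recording$data
  df[acc_cols] <- as.matrix(df[acc_cols]) %*% t(rotation)
  df[gyr_cols] <- as.matrix(df[gyr_cols]) %*% t(rotation)
  if (foot == "right") {
    df$gyr_ml <- -df$gyr_ml
    df$acc_ml <- -df$acc_ml
  }
  out <- recording
  out$data <- df
  out$foot <- foot
  out
}

## shortest-arc rotation mapping unit vector u onto unit vector v
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s2 <- sum(w^2)
  if (s2 < 1e-18) {
    if (c_ > 0) return(diag(3))
    # antipodal: rotate pi about any axis orthogonal to u
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- a - sum(a * u) * u; w <- w / sqrt(sum(w^2))
    return(2 * tcrossprod(w) - diag(3))
  }
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s2)
}

#' Align the accelerometer si-axis to gravity using a static frame
#'
#' Searches for a static frame (a sliding window in which the mean gyroscope
#' norm stays below `static_thresh_dps`), takes the mean accelerometer vector
#' over it, and rotates the whole recording by the shortest-arc rotation
#' mapping that vector onto (0, 0, +9.81) on (ml, pa, si).
#'
#' @param recording Body-frame [imu_recording()].
#' @param static_window_s Length of the static-frame window in seconds.
#' @param static_thresh_dps Gyro-norm threshold (deg/s) below which a window
#'   counts as static.
#' @return The gravity-aligned [imu_recording()].
#' @export
align_gravity <- function(recording, static_window_s = 0.5,
                          static_thresh_dps = 5) {
  stopifnot(inherits(recording, "imu_recording"))
  df <- recording$data
  n <- nrow(df)
  w <- max(1L, round(static_window_s * recording$fs))
  if (n < w) stop("no static frame found", call. = FALSE)
  gnorm <- sqrt(df$gyr_ml^2 + df$gyr_pa^2 + df$gyr_si^2)
  mov <- moving_sum(gnorm, w) / w
  idx <- which(mov < static_thresh_dps)
  if (!length(idx)) stop("no static frame found", call. = FALSE)
  i0 <- idx[1]                      # window [i0, i0+w-1]
  span <- i0:(i0 + w - 1L)
  g <- c(mean(df$acc_ml[span]), mean(df$acc_pa[span]), mean(df$acc_si[span]))
  R <- rotation_between(g, c(0, 0, GRAVITY_MS2))
  df[acc_cols] <- as.matrix(df[acc_cols]) %*% t(R)
  df[gyr_cols] <- as.matrix(df[gyr_cols]) %*% t(R)
  out <- recording
  out$data <- df
  out
}

## windowed running sum over w consecutive samples, value at window start
moving_sum <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1L):length(cs)] - cs[seq_len(length(cs) - w)]
}

## --- zero-phase Butterworth -------------------------------------------------

## steady-state initial conditions for a direct-form-II-transposed IIR filter
lfilter_zi <- function(b, a) {
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  b <- b / a[1]; a <- a / a[1]
  n <- nfilt - 1L
  comp <- matrix(0, n, n)
  comp[1, ] <- -a[2:nfilt]
  if (n > 1L) comp[cbind(2:n, 1:(n - 1L))] <- 1
  solve(diag(n) - t(comp), b[2:nfilt] - a[2:nfilt] * b[1])
}

## causal IIR filter with explicit initial state (direct form II transposed)
iir_filter <- function(b, a, x, zi) {
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b))) / a[1]
  a <- c(a, rep(0, nfilt - length(a))) / a[1]
  n <- length(x)
  y <- numeric(n)
  z <- zi
  nz <- nfilt - 1L
  for (t in seq_len(n)) {
    xt <- x[t]
    yt <- b[1] * xt + z[1]
    if (nz > 1L)
      for (k in seq_len(nz - 1L)) z[k] <- b[k + 1L] * xt + z[k + 1L] - a[k + 1L] * yt
    z[nz] <- b[nfilt] * xt - a[nfilt] * yt
    y[t] <- yt
  }
  y
}

## forward-backward filtering with odd-reflection padding and steady-state
## initial conditions (removes start-up transients; exact unit DC gain)
filtfilt_padded <- function(b, a, x) {
  n <- length(x)
  nfilt <- max(length(a), length(b))
  npad <- 3L * (nfilt - 1L)
  if (n <= npad)
    stop("series too short for zero-phase filtering", call. = FALSE)
  pre <- 2 * x[1] - x[(npad + 1L):2]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xe <- c(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, xe, zi * xe[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(npad + 1L):(npad + n)]
}

#' Zero-phase low-pass Butterworth filter
#'
#' Fourth-order (by default) Butterworth low-pass applied forward and
#' backward, giving zero phase distortion and squared magnitude response.
#' Coefficients come from [signal::butter()]; the forward-backward pass uses
#' odd-reflection padding with steady-state initial conditions so that
#' constant signals are reproduced exactly (unit DC gain).
#'
#' @param series Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param cutoff_hz Cut-off frequency in Hz (default 10).
#' @param order Filter order of one pass (default 4).
#' @return Filtered signal, same length as the input.
#' @export
lowpass_zero_phase <- function(series, fs, cutoff_hz = 10, order = 4) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(cutoff_hz, "cutoff_hz", positive = TRUE)
  if (fs <= 2 * cutoff_hz)
    stop("fs must exceed twice the cut-off frequency", call. = FALSE)
  if (length(series) < 3 * order + 1)
    stop("series too short for the filter warm-up", call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  filtfilt_padded(bf$b, bf$a, as.numeric(series))
}

#' Downsample by a factor of two
#'
#' Keeps every second sample starting at the first one; meant to run after
#' [lowpass_zero_phase()], whose 10 Hz cut-off already provides the
#' anti-aliasing for the halved Nyquist frequency (e.g. 102.4 Hz -> 51.2 Hz).
#'
#' @param x Numeric signal or [imu_recording()].
#' @param fs Sampling rate (ignored for recordings, taken from the object).
#' @return For a signal: `list(series, fs)`. For a recording: the decimated
#'   [imu_recording()].
#' @export
decimate_by_two <- function(x, fs = NULL) {
  if (inherits(x, "imu_recording")) {
    df <- x$data[seq(1L, max(nrow(x$data), 0L), by = 2L), , drop = FALSE]
    rownames(df) <- NULL
    out <- x
    out$data <- df
    out$fs <- x$fs / 2
    return(out)
  }
  series <- as.numeric(x)
  kept <- if (length(series)) series[seq(1L, length(series), by = 2L)] else series
  list(series = kept, fs = if (is.null(fs)) NA_real_ else fs / 2)
}

#' Re-index annotations after decimation by two
#'
#' Maps each 1-based sample index to the nearest retained coarse sample,
#' `floor((i - 1) / 2 + 0.5) + 1`, so event times move by at most half a
#' coarse sample.
#'
#' @param doc A [gait_annotations()] object.
#' @return The re-indexed [gait_annotations()] at half the sampling rate.
#' @export
reindex_annotations_by_two <- function(doc) {
  stopifnot(inherits(doc, "gait_annotations"))
  f <- function(m) {
    m <- as_interval_matrix(m)
    floor((m - 1) / 2 + 0.5) + 1
  }
  gait_annotations(strides = list(left = f(doc$strides$left),
                                  right = f(doc$strides$right)),
                   bouts = f(doc$bouts),
                   fs = doc$sampling_rate_hz / 2,
                   provenance = doc$provenance)
}

#' Detect activity windows from the smoothed gyroscope norm
#'
#' The gyro norm is smoothed with a 1 s centered moving average; maximal runs
#' above `threshold_dps` are kept if at least `min_duration_s` long, and runs
#' separated by less than 1 s are merged first.
#'
#' @param recording Body-frame [imu_recording()].
#' @param threshold_dps Gyro-norm threshold in deg/s.
#' @param min_duration_s Minimum window duration in seconds.
#' @return 2-column matrix of windows (1-based inclusive sample indices).
#' @export
detect_activity_windows <- function(recording, threshold_dps = 50,
                                    min_duration_s = 1) {
  stopifnot(inherits(recording, "imu_recording"))
  if (threshold_dps < 0) stop("threshold_dps must be >= 0", call. = FALSE)
  df <- recording$data
  n <- nrow(df)
  if (n == 0L) return(as_interval_matrix(NULL))
  gnorm <- sqrt(df$gyr_ml^2 + df$gyr_pa^2 + df$gyr_si^2)
  w <- max(1L, round(recording$fs))
  if (w %% 2L == 0L) w <- w + 1L
  if (n >= w) {
    sm <- as.numeric(stats::filter(gnorm, rep(1 / w, w), sides = 2))
    h <- (w - 1L) %/% 2L
    for (i in seq_len(min(h, n))) {
      sm[i] <- mean(gnorm[1:min(n, i + h)])
      j <- n - i + 1L
      sm[j] <- mean(gnorm[max(1L, j - h):n])
    }
  } else {
    sm <- rep(mean(gnorm), n)
  }
  active <- if (threshold_dps == 0) rep(TRUE, n) else sm > threshold_dps
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  if (!nrow(runs)) return(as_interval_matrix(NULL))
  # merge runs separated by < 1 s
  merged <- runs[1, , drop = FALSE]
  gap <- recording$fs * 1
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      if (runs[i, 1] - merged[nrow(merged), 2] - 1L < gap) {
        merged[nrow(merged), 2] <- runs[i, 2]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  keep <- (merged[, 2] - merged[, 1] + 1L) >= min_duration_s * recording$fs
  as_interval_matrix(merged[keep, , drop = FALSE])
}

#' Snap a border index to the local signal minimum
#'
#' Returns the index of the minimum value of `gyr_ml` within a centered
#' window of total length `window_ms` (i.e. half of it per side), truncated
#' at the signal bounds. Ties break toward the smallest index. The window is
#' re-centered and the search repeated until the index no longer moves, which
#' makes the operation idempotent; on signals with clear border minima the
#' first step already lands on the fixed point.
#'
#' @param gyr_ml Numeric signal (deg/s).
#' @param index 1-based sample index to snap.
#' @param window_ms Total window length in milliseconds (default 200).
#' @param fs Sampling rate in Hz.
#' @return The snapped 1-based index.
#' @export
snap_to_minimum <- function(gyr_ml, index, window_ms = 200, fs) {
  n <- length(gyr_ml)
  if (length(index) != 1L || is.na(index) || index < 1 || index > n)
    stop("index out of range", call. = FALSE)
  h <- as.integer(round(window_ms * fs / 1000 / 2))
  i <- as.integer(index)
  repeat {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    j <- lo + which.min(gyr_ml[lo:hi]) - 1L
    if (j == i) return(i)
    i <- j
  }
}
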
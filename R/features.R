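## Sliding-window feature extraction on the gyr_ml signal, and per-bout
## z-score standardization. One feature row per input sample (windows are
## shifted by a single sample for maximum temporal resolution).

FEATURE_CHOICES <- c("raw", "grad", "var", "polyfit")

#' Sliding centered-window features of a signal
#'
#' Computes, for every sample, features over a centered window of
#' `window_ms` milliseconds (forced to an odd number of samples; clipped at
#' the signal bounds, minimum 3 samples):
#' \describe{
#'   \item{raw}{the signal value itself;}
#'   \item{grad}{the least-squares slope of a linear fit over the window, in
#'     signal units per second;}
#'   \item{var}{the population variance over the window;}
#'   \item{polyfit}{the three coefficients (quadratic, linear, constant) of a
#'     second-order least-squares fit on window-centered time in seconds.}
#' }
#'
#' @param signal Numeric gyr_ml series.
#' @param fs Sampling rate in Hz.
#' @param window_ms Window length in milliseconds (100, 220 and 500 are the
#'   values explored in the hyperparameter grid).
#' @param feature_set Character vector drawn from
#'   `c("raw", "grad", "var", "polyfit")`.
#' @return A numeric matrix with one row per input sample; column names
#'   identify the features. Attributes `fs` and `window_samples` record the
#'   geometry.
#' @export
sliding_window_features <- function(signal, fs, window_ms = 220,
                                    feature_set = c("raw", "grad")) {
  signal <- as.numeric(signal)
  n <- length(signal)
  if (n < 3L) stop("signal must have at least 3 samples", call. = FALSE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  feature_set <- match.arg(feature_set, FEATURE_CHOICES, several.ok = TRUE)
  W <- round(window_ms * fs / 1000)
  if (W %% 2L == 0L) W <- W + 1L
  W <- max(3L, min(W, if (n %% 2L == 1L) n else n - 1L))
  h <- (W - 1L) %/% 2L
  dt <- 1 / fs

  need_fit <- any(c("grad", "var", "polyfit") %in% feature_set)
  cols <- list()
  if (need_fit) {
    # interior samples: fixed symmetric window -> convolution kernels
    k <- (-h):h                        # sample offsets
    tk <- k * dt                       # centered time, seconds
    m0 <- W
    m2 <- sum(tk^2)
    m4 <- sum(tk^4)
    den <- m0 * m4 - m2^2
    slope_kern <- tk / m2
    quad_kern <- (m0 * tk^2 - m2) / den
    const_kern <- (m4 - m2 * tk^2) / den
    mean_kern <- rep(1 / W, W)
    conv <- function(kern) as.numeric(stats::filter(signal, rev(kern), sides = 2))
    grad <- conv(slope_kern)
    vr <- NULL
    if ("var" %in% feature_set) {
      mu <- conv(mean_kern)
      mu2 <- as.numeric(stats::filter(signal^2, mean_kern, sides = 2))
      vr <- pmax(mu2 - mu^2, 0)
    }
    c2 <- c0 <- NULL
    if ("polyfit" %in% feature_set) {
      c2 <- conv(quad_kern)
      c0 <- conv(const_kern)
    }
    # edge samples: direct least squares on the clipped window
    edge <- unique(c(seq_len(min(h, n)), seq.int(max(1L, n - h + 1L), n)))
    for (i in edge) {
      lo <- max(1L, i - h); hi <- min(n, i + h)
      if (hi - lo + 1L < 3L) { lo <- max(1L, hi - 2L); hi <- min(n, lo + 2L) }
      y <- signal[lo:hi]
      tt <- ((lo:hi) - i) * dt
      if ("var" %in% feature_set) vr[i] <- mean((y - mean(y))^2)
      X1 <- cbind(1, tt)
      fit1 <- solve(crossprod(X1), crossprod(X1, y))
      grad[i] <- fit1[2]
      if ("polyfit" %in% feature_set) {
        X2 <- cbind(1, tt, tt^2)
        fit2 <- solve(crossprod(X2), crossprod(X2, y))
        c0[i] <- fit2[1]; c2[i] <- fit2[3]
      }
    }
    if ("grad" %in% feature_set) cols$grad <- grad
    if ("var" %in% feature_set) cols$var <- vr
    if ("polyfit" %in% feature_set) {
      # linear coefficient of the order-2 fit equals the linear-fit slope on
      # a symmetric window (odd/even moment orthogonality); edges: recompute
      c1 <- grad
      for (i in edge) {
        lo <- max(1L, i - h); hi <- min(n, i + h)
        if (hi - lo + 1L < 3L) { lo <- max(1L, hi - 2L); hi <- min(n, lo + 2L) }
        tt <- ((lo:hi) - i) * dt
        X2 <- cbind(1, tt, tt^2)
        c1[i] <- solve(crossprod(X2), crossprod(X2, signal[lo:hi]))[2]
      }
      cols$poly_quad <- c2
      cols$poly_lin <- c1
      cols$poly_const <- c0
    }
  }
  out <- cbind(
    if ("raw" %in% feature_set) matrix(signal, ncol = 1, dimnames = list(NULL, "raw")),
    if (length(cols)) do.call(cbind, cols)
  )
  if (!all(is.finite(out)))
    stop("non-finite feature values produced", call. = FALSE)
  attr(out, "fs") <- fs
  attr(out, "window_samples") <- W
  out
}

#' Standardize features per walking bout
#'
#' Within each bout, every feature column is independently z-scored
#' (mean 0, sd 1 computed over the bout's samples). Columns whose standard
#' deviation is below `1e-12` are set to zero. Samples outside every bout are
#' left untouched; they are never decoded.
#'
#' @param features Feature matrix from [sliding_window_features()].
#' @param bouts 2-column matrix of bout intervals (1-based inclusive row
#'   indices into `features`).
#' @return The standardized feature matrix.
#' @export
zscore_per_bout <- function(features, bouts) {
  bouts <- as_interval_matrix(bouts)
  out <- features
  for (b in seq_len(nrow(bouts))) {
    lo <- bouts[b, 1]; hi <- bouts[b, 2]
    if (lo > hi || lo < 1 || hi > nrow(features))
      stop("empty or out-of-range bout", call. = FALSE)
    rows <- lo:hi
    block <- features[rows, , drop = FALSE]
    mu <- colMeans(block)
    sdv <- apply(block, 2L, stats::sd)
    const <- !is.finite(sdv) | sdv < 1e-12
    sdv[const] <- 1
    block <- sweep(sweep(block, 2L, mu, "-"), 2L, sdv, "/")
    block[, const] <- 0
    out[rows, ] <- block
  }
  out
}
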
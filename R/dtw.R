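## Subsequence dynamic-time-warping baseline: template generation by stride
## averaging, subsequence matching with a maximum warping-cost threshold,
## and stride prediction with border snapping.

#' Build a stride template by averaging
#'
#' Each stride is linearly resampled to the rounded mean stride length, the
#' per-sample mean over all strides is taken, and the waveform is divided by
#' `scale_dps` so warping costs live on a normalized amplitude scale.
#'
#' @param strides List of numeric gyr_ml stride segments (each length >= 2).
#' @param scale_dps Amplitude divisor in deg/s (default 500).
#' @return An object of class `"dtw_template"` with elements `waveform`,
#'   `length` and `scale_dps`.
#' @export
build_template <- function(strides, scale_dps = 500) {
  if (!length(strides)) stop("no strides to build a template from", call. = FALSE)
  lens <- lengths(strides)
  if (any(lens < 2L)) stop("stride segments must have length >= 2", call. = FALSE)
  L <- as.integer(round(mean(lens)))
  resampled <- vapply(strides, function(s)
    stats::approx(seq(0, 1, length.out = length(s)), s,
                  xout = seq(0, 1, length.out = L))$y,
    numeric(L))
  waveform <- rowMeans(matrix(resampled, nrow = L)) / scale_dps
  structure(list(waveform = waveform, length = L, scale_dps = scale_dps),
            class = "dtw_template")
}

#' @export
print.dtw_template <- function(x, ...) {
  cat(sprintf("<dtw_template> %d samples, amplitude scale %g deg/s\n",
              x$length, x$scale_dps))
  invisible(x)
}

## subsequence-DTW accumulated-cost matrix: free start in the signal
## (first template row pays only its local cost at every signal position),
## steps {match (1,1), insertion into template (1,0), deletion (0,1)},
## local cost = squared difference on amplitude-scaled signals
dtw_cost_matrix <- function(template, x) {
  n <- length(template)
  m <- length(x)
  D <- matrix(0, n, m)
  D[1L, ] <- (template[1L] - x)^2
  for (i in 2:n) {
    cost <- (template[i] - x)^2
    prev <- D[i - 1L, ]
    cur <- numeric(m)
    cur[1L] <- cost[1L] + prev[1L]
    for (j in 2:m)
      cur[j] <- cost[j] + min(prev[j - 1L], prev[j], cur[j - 1L])
    D[i, ] <- cur
  }
  D
}

## trace a match back from final-row position j to its start column
dtw_traceback_start <- function(D, template, x, j) {
  i <- nrow(D)
  while (i > 1L) {
    if (j == 1L) { i <- i - 1L; next }
    choice <- which.min(c(D[i - 1L, j - 1L], D[i - 1L, j], D[i, j - 1L]))
    if (choice == 1L) { i <- i - 1L; j <- j - 1L }
    else if (choice == 2L) i <- i - 1L
    else j <- j - 1L
  }
  j
}

## candidate matches below max_cost at local minima of the final row,
## overlaps resolved greedily by ascending cost
dtw_matches_from_D <- function(D, template, x, max_cost,
                               max_overlap_frac = 0.25) {
  final <- D[nrow(D), ]
  m <- length(final)
  is_min <- final < max_cost
  if (m > 1L) {
    is_min[1L] <- is_min[1L] & final[1L] <= final[2L]
    is_min[m] <- is_min[m] & final[m] < final[m - 1L]
    if (m > 2L) {
      mid <- 2:(m - 1L)
      is_min[mid] <- is_min[mid] & final[mid] < final[mid + 1L] &
        final[mid] <= final[mid - 1L]
    }
  }
  cand <- which(is_min)
  if (!length(cand))
    return(data.frame(start = integer(0), end = integer(0), cost = numeric(0)))
  starts <- vapply(cand, function(j) dtw_traceback_start(D, template, x, j),
                   integer(1))
  cand_df <- data.frame(start = starts, end = cand, cost = final[cand])
  cand_df <- cand_df[order(cand_df$cost, cand_df$start), , drop = FALSE]
  kept <- NULL
  for (r in seq_len(nrow(cand_df))) {
    s <- cand_df$start[r]; e <- cand_df$end[r]
    conflict <- FALSE
    if (!is.null(kept)) {
      inter <- pmin(kept$end, e) - pmax(kept$start, s) + 1
      lim <- max_overlap_frac * pmin(kept$end - kept$start + 1, e - s + 1)
      conflict <- any(inter > pmax(1, lim))
    }
    if (!conflict) kept <- rbind(kept, cand_df[r, ])
  }
  kept[order(kept$start), , drop = FALSE]
}

#' Subsequence DTW matching of a template in a signal
#'
#' The signal is divided by the template's amplitude scale; an accumulated-
#' cost matrix with a free start in the signal and steps
#' match/insertion/deletion (local cost: squared difference) is filled;
#' candidate matches are the local minima of the final row with cost below
#' `max_cost`; starts are found by path traceback and overlapping candidates
#' are resolved by keeping the lower cost.
#'
#' @param template A [build_template()] result.
#' @param signal Numeric gyr_ml series (unscaled deg/s).
#' @param max_cost Maximum accumulated warping cost.
#' @return Data frame of matches (`start`, `end`, `cost`), sorted by start.
#' @export
subsequence_dtw <- function(template, signal, max_cost) {
  stopifnot(inherits(template, "dtw_template"))
  if (max_cost <= 0) stop("max_cost must be > 0", call. = FALSE)
  if (length(signal) < template$length / 2)
    stop("signal shorter than half the template", call. = FALSE)
  x <- as.numeric(signal) / template$scale_dps
  D <- dtw_cost_matrix(template$waveform, x)
  dtw_matches_from_D(D, template$waveform, x, max_cost)
}

#' Predict strides with the DTW baseline
#'
#' Runs [subsequence_dtw()] on the working-rate gyr_ml signal, converts each
#' match into a stride interval, snaps both borders to the local gyr_ml
#' minimum with the 200 ms rule and drops degenerate strides.
#'
#' @param template A [build_template()] result.
#' @param gyr_ml Preprocessed (filtered, working-rate) gyr_ml signal.
#' @param fs Working sampling rate in Hz.
#' @param max_cost Maximum warping cost.
#' @param snap_window_ms Snapping window (default 200 ms).
#' @return 2-column matrix of stride intervals sorted by start.
#' @export
dtw_predict_strides <- function(template, gyr_ml, fs, max_cost,
                                snap_window_ms = 200) {
  matches <- subsequence_dtw(template, gyr_ml, max_cost)
  out <- NULL
  for (r in seq_len(nrow(matches))) {
    a <- snap_to_minimum(gyr_ml, matches$start[r], snap_window_ms, fs)
    b <- snap_to_minimum(gyr_ml, matches$end[r], snap_window_ms, fs)
    if (b > a) out <- rbind(out, c(a, b))
  }
  out <- as_interval_matrix(out)
  out[order(out[, 1]), , drop = FALSE]
}

#' Candidate max-cost thresholds
#'
#' The grid 2.0 to 5.0 in steps of 0.25 (13 values) explored when tuning the
#' warping-cost threshold.
#'
#' @return Numeric vector of thresholds.
#' @export
dtw_cost_grid <- function() seq(2, 5, by = 0.25)
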
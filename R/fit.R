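## High-level fitting interface: the two-class HMM segmenter and the DTW
## baseline, both as classed model objects with predict methods.

## filter + decimate one foot's gyr_ml; returns working-rate signal and fs
preprocess_gyr_ml <- function(recording, cutoff_hz = 10, order = 4,
                              decimate = TRUE) {
  g <- lowpass_zero_phase(recording$data$gyr_ml, recording$fs, cutoff_hz, order)
  if (decimate) {
    d <- decimate_by_two(g, recording$fs)
    list(gyr_ml = d$series, fs = d$fs)
  } else {
    list(gyr_ml = g, fs = recording$fs)
  }
}

## context windows: each bout expanded by context_s, clipped to the
## recording and to the midpoint of the gap to the neighbouring bout
bout_context_windows <- function(bouts, n, fs, context_s = 1.5) {
  bouts <- as_interval_matrix(bouts)
  k <- nrow(bouts)
  if (!k) return(bouts)
  pad <- round(context_s * fs)
  lo <- pmax(1, bouts[, 1] - pad)
  hi <- pmin(n, bouts[, 2] + pad)
  if (k > 1L) {
    mid <- floor((bouts[-k, 2] + bouts[-1L, 1]) / 2)
    lo[-1L] <- pmax(lo[-1L], mid + 1)
    hi[-k] <- pmin(hi[-k], mid)
  }
  cbind(start = lo, end = hi)
}

## split one bout-context region of one foot into contiguous labeled
## segments; stride intervals are relative to the region
segment_bout_region <- function(region_len, strides_rel) {
  segs <- list()
  pos <- 1L
  for (r in seq_len(nrow(strides_rel))) {
    a <- strides_rel[r, 1]; b <- strides_rel[r, 2]
    if (a > pos) segs[[length(segs) + 1L]] <-
        list(class = "transition", start = pos, end = a - 1L)
    segs[[length(segs) + 1L]] <-
      list(class = "stride", start = max(a, pos), end = b)
    pos <- b + 1L
  }
  if (pos <= region_len) segs[[length(segs) + 1L]] <-
      list(class = "transition", start = pos, end = region_len)
  segs
}

## per recording+foot: working-rate signal, features per context region and
## the labeled segment tiling (used by both training and evaluation)
prepare_foot <- function(recording, strides, bouts, hyper) {
  pp <- preprocess_gyr_ml(recording, hyper$cutoff_hz, hyper$order,
                          hyper$decimate)
  n <- length(pp$gyr_ml)
  regions <- bout_context_windows(bouts, n, pp$fs, hyper$context_s)
  out <- vector("list", nrow(regions))
  for (b in seq_len(nrow(regions))) {
    lo <- regions[b, 1]; hi <- regions[b, 2]
    seg <- pp$gyr_ml[lo:hi]
    feats <- sliding_window_features(seg, pp$fs, hyper$window_ms,
                                     hyper$feature_set)
    if (hyper$standardize)
      feats <- zscore_per_bout(feats, matrix(c(1, length(seg)), 1))
    inb <- strides[, 1] >= bouts[b, 1] & strides[, 2] <= bouts[b, 2]
    srel <- strides[inb, , drop = FALSE] - lo + 1
    out[[b]] <- list(region = c(lo, hi), gyr_ml = seg, features = feats,
                     strides_rel = srel, bout = b)
  }
  list(fs = pp$fs, gyr_ml = pp$gyr_ml, regions = regions, bouts_data = out)
}

#' Fit the two-class HMM stride segmenter
#'
#' The spine of the package: per walking bout, labelled strides become
#' stride training sequences and the unlabelled within-bout remainder
#' becomes transition sequences; a strict left-right stride model and a
#' wrap-around transition model are initialized by equal splitting, trained
#' separately with Baum-Welch (at most ten iterations) and flattened into a
#' single combined segmenter via [combine_models()]. Fully deterministic
#' given `seed`.
#'
#' @param recordings List of `"labeled_recording"` objects (see
#'   [generate_dataset()]), with annotations at the native sampling rate.
#' @param n_stride_states,n_transition_states Hidden-state counts of the two
#'   sub-models (defaults 25 and 5, the selected operating point).
#' @param n_components Gaussian mixture components per state (default 8).
#' @param window_ms Feature window (default 220 ms).
#' @param feature_set Features, see [sliding_window_features()]; default
#'   raw + gradient.
#' @param standardize Per-bout z-scoring of the features (default `TRUE`).
#' @param max_iter,tol Baum-Welch iteration cap and relative stopping
#'   tolerance.
#' @param cutoff_hz,order,decimate Front-end filter settings (10 Hz
#'   fourth-order zero-phase Butterworth, then decimation by two).
#' @param context_s Context margin around each bout (seconds) that supplies
#'   the transition-state support for decoding and z-scoring.
#' @param seed Integer seed controlling the GMM initialization.
#' @return An object of class `"stride_hmm"`.
#' @export
fit_stride_hmm <- function(recordings,
                           n_stride_states = 25L, n_transition_states = 5L,
                           n_components = 8L, window_ms = 220,
                           feature_set = c("raw", "grad"),
                           standardize = TRUE, max_iter = 10L, tol = 1e-4,
                           cutoff_hz = 10, order = 4, decimate = TRUE,
                           context_s = 1.5, seed = 1L) {
  if (!length(recordings)) stop("empty training set", call. = FALSE)
  if (inherits(recordings, "labeled_recording")) recordings <- list(recordings)
  hyper <- list(n_stride_states = n_stride_states,
                n_transition_states = n_transition_states,
                n_components = n_components, window_ms = window_ms,
                feature_set = feature_set, standardize = standardize,
                cutoff_hz = cutoff_hz, order = order, decimate = decimate,
                context_s = context_s)
  stride_seqs <- list()
  transition_seqs <- list()
  labeled_bouts <- list()
  n_bouts <- 0L
  fs_work <- NULL
  for (rec in recordings) {
    ann <- as_annotations(rec)
    if (decimate) ann <- reindex_annotations_by_two(ann)
    for (foot in c("left", "right")) {
      strides <- ann$strides[[foot]]
      if (!nrow(strides)) next
      prep <- prepare_foot(rec[[foot]], strides, ann$bouts, hyper)
      fs_work <- prep$fs
      for (bd in prep$bouts_data) {
        if (!nrow(bd$strides_rel)) next
        if (any(bd$strides_rel[, 2] - bd$strides_rel[, 1] + 1 < n_stride_states))
          next                     # stride shorter than the state chain
        n_bouts <- n_bouts + 1L
        segs <- segment_bout_region(length(bd$gyr_ml), bd$strides_rel)
        bout_segs <- list()
        for (sg in segs) {
          feats <- bd$features[sg$start:sg$end, , drop = FALSE]
          bout_segs[[length(bout_segs) + 1L]] <-
            list(class = sg$class, features = feats)
          if (sg$class == "transition") {
            if (nrow(feats) >= max(3L, n_transition_states))
              transition_seqs[[length(transition_seqs) + 1L]] <- feats
          }
        }
        # full stride intervals (including the shared border sample)
        for (r in seq_len(nrow(bd$strides_rel)))
          stride_seqs[[length(stride_seqs) + 1L]] <-
            bd$features[bd$strides_rel[r, 1]:bd$strides_rel[r, 2], ,
                        drop = FALSE]
        labeled_bouts[[length(labeled_bouts) + 1L]] <- bout_segs
      }
    }
  }
  if (!length(stride_seqs)) stop("no usable training strides", call. = FALSE)
  if (!length(transition_seqs)) stop("no usable transition sequences", call. = FALSE)
  rng <- rng_stream(seed)
  stride0 <- init_left_right_model(stride_seqs, n_stride_states, n_components,
                                   wrap_edge = FALSE, free_ends = FALSE,
                                   seed = spawn_seed(rng))
  trans0 <- init_left_right_model(transition_seqs, n_transition_states,
                                  n_components, wrap_edge = TRUE,
                                  free_ends = TRUE, seed = spawn_seed(rng))
  stride_fit <- baum_welch(stride0, stride_seqs, max_iter = max_iter, tol = tol)
  trans_fit <- baum_welch(trans0, transition_seqs, max_iter = max_iter,
                          tol = tol)
  combined <- combine_models(trans_fit$model, stride_fit$model, labeled_bouts)
  structure(list(combined = combined,
                 stride_model = stride_fit$model,
                 transition_model = trans_fit$model,
                 reports = list(stride = stride_fit$report,
                                transition = trans_fit$report),
                 hyper = hyper, fs_work = fs_work,
                 n_train = list(strides = length(stride_seqs),
                                transitions = length(transition_seqs),
                                bouts = n_bouts),
                 seed = seed, call = match.call()),
            class = "stride_hmm")
}

#' @export
print.stride_hmm <- function(x, ...) {
  cat("Two-class HMM stride segmenter\n")
  cat(sprintf("  states: %d stride + %d transition; %d GMM component(s)/state\n",
              x$hyper$n_stride_states, x$hyper$n_transition_states,
              x$hyper$n_components))
  cat(sprintf("  features: %s, %g ms window%s @ %.4g Hz\n",
              paste(x$hyper$feature_set, collapse = "+"), x$hyper$window_ms,
              if (x$hyper$standardize) ", per-bout z-scored" else "",
              x$fs_work))
  cat(sprintf("  trained on %d strides / %d transitions in %d bouts\n",
              x$n_train$strides, x$n_train$transitions, x$n_train$bouts))
  invisible(x)
}

#' @export
summary.stride_hmm <- function(object, ...) {
  print(object)
  r <- object$reports
  cat(sprintf("  Baum-Welch: stride %d iter (logLik %.1f -> %.1f), transition %d iter (%.1f -> %.1f)\n",
              r$stride$n_iterations,
              r$stride$log_likelihood_per_iteration[1],
              utils::tail(r$stride$log_likelihood_per_iteration, 1),
              r$transition$n_iterations,
              r$transition$log_likelihood_per_iteration[1],
              utils::tail(r$transition$log_likelihood_per_iteration, 1)))
  cat(sprintf("  combined transition matrix: %dx%d, rows sum to 1\n",
              nrow(object$combined$trans), ncol(object$combined$trans)))
  invisible(object)
}

#' @export
coef.stride_hmm <- function(object, ...) {
  list(transitions = object$combined$trans,
       start = object$combined$start,
       end = object$combined$end,
       state_class = object$combined$state_class)
}

#' @export
logLik.stride_hmm <- function(object, features, ...) {
  loglik(object$combined, features)
}

#' Segment strides in a recording with a fitted model
#'
#' Preprocesses the recording like the training data (10 Hz zero-phase
#' low-pass, decimation), extracts features per bout-context region,
#' z-scores them, decodes the combined model with Viterbi and converts the
#' state path into border-snapped stride intervals.
#'
#' @param object A fitted `"stride_hmm"`.
#' @param recording An [imu_recording()] at the native sampling rate.
#' @param bouts 2-column matrix of predefined walking-bout intervals at the
#'   native sampling rate.
#' @param ... Unused.
#' @return Data frame (`start`, `end`, `bout`) of predicted strides at the
#'   working rate (attribute `"fs"`).
#' @export
predict.stride_hmm <- function(object, recording, bouts, ...) {
  stopifnot(inherits(recording, "imu_recording"))
  hyper <- object$hyper
  bouts <- as_interval_matrix(bouts)
  if (hyper$decimate) bouts <- floor((bouts - 1) / 2 + 0.5) + 1
  pp <- preprocess_gyr_ml(recording, hyper$cutoff_hz, hyper$order,
                          hyper$decimate)
  regions <- bout_context_windows(bouts, length(pp$gyr_ml), pp$fs,
                                  hyper$context_s)
  out <- NULL
  for (b in seq_len(nrow(regions))) {
    lo <- regions[b, 1]; hi <- regions[b, 2]
    seg <- pp$gyr_ml[lo:hi]
    feats <- sliding_window_features(seg, pp$fs, hyper$window_ms,
                                     hyper$feature_set)
    if (hyper$standardize)
      feats <- zscore_per_bout(feats, matrix(c(1, length(seg)), 1))
    ps <- predict_strides(object$combined, feats, seg, pp$fs)
    if (nrow(ps$strides))
      out <- rbind(out, data.frame(start = ps$strides[, 1] + lo - 1,
                                   end = ps$strides[, 2] + lo - 1,
                                   bout = b))
  }
  if (is.null(out))
    out <- data.frame(start = numeric(0), end = numeric(0), bout = integer(0))
  attr(out, "fs") <- pp$fs
  out
}

#' Fit the DTW baseline segmenter
#'
#' Builds a stride template by averaging all (preprocessed, working-rate)
#' training strides and tunes the maximum warping-cost threshold on the
#' training recordings by pooled F1 over the candidate grid.
#'
#' @param recordings List of `"labeled_recording"` objects.
#' @param grid Candidate max-cost thresholds (default [dtw_cost_grid()]).
#' @param scale_dps Amplitude divisor applied before matching (default 500).
#' @param cutoff_hz,order,decimate Front end, as in [fit_stride_hmm()].
#' @param tol_samples Matching tolerance used during tuning.
#' @return An object of class `"stride_dtw"` with the template, the tuned
#'   `max_cost` and the per-threshold tuning table.
#' @export
fit_stride_dtw <- function(recordings, grid = dtw_cost_grid(),
                           scale_dps = 500, cutoff_hz = 10, order = 4,
                           decimate = TRUE, tol_samples = 3) {
  if (!length(recordings)) stop("empty training set", call. = FALSE)
  if (inherits(recordings, "labeled_recording")) recordings <- list(recordings)
  segments <- list()
  preps <- list()
  fs_work <- NULL
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    ann <- as_annotations(rec)
    if (decimate) ann <- reindex_annotations_by_two(ann)
    for (foot in c("left", "right")) {
      strides <- ann$strides[[foot]]
      if (!nrow(strides)) next
      pp <- preprocess_gyr_ml(rec[[foot]], cutoff_hz, order, decimate)
      fs_work <- pp$fs
      for (r in seq_len(nrow(strides)))
        segments[[length(segments) + 1L]] <-
          pp$gyr_ml[strides[r, 1]:strides[r, 2]]
      preps[[length(preps) + 1L]] <- list(gyr_ml = pp$gyr_ml,
                                          strides = strides,
                                          bouts = ann$bouts)
    }
  }
  if (!length(segments)) stop("no training strides", call. = FALSE)
  template <- build_template(segments, scale_dps)
  # one cost matrix per training signal serves the whole threshold grid
  tune <- matrix(0, length(grid), 3L,
                 dimnames = list(NULL, c("tp", "fp", "fn")))
  for (pp in preps) {
    D <- dtw_cost_matrix(template$waveform, pp$gyr_ml / scale_dps)
    for (gi in seq_along(grid)) {
      matches <- dtw_matches_from_D(D, template$waveform,
                                    pp$gyr_ml / scale_dps, grid[gi])
      pred <- snap_matches(matches, pp$gyr_ml, fs_work)
      pred <- keep_in_bouts(pred, pp$bouts, tol_samples)
      mm <- match_strides(pred, pp$strides, tol_samples)
      tune[gi, ] <- tune[gi, ] + c(mm$tp, mm$fp, mm$fn)
    }
  }
  f1 <- apply(tune, 1L, function(r) compute_metrics(r[1], r[2], r[3])$f1)
  best <- which.max(f1)
  structure(list(template = template, max_cost = grid[best],
                 grid = grid,
                 tuning = data.frame(max_cost = grid, tune, f1 = f1),
                 scale_dps = scale_dps, fs_work = fs_work,
                 cutoff_hz = cutoff_hz, order = order, decimate = decimate),
            class = "stride_dtw")
}

snap_matches <- function(matches, gyr_ml, fs, snap_window_ms = 200) {
  out <- NULL
  for (r in seq_len(nrow(matches))) {
    a <- snap_to_minimum(gyr_ml, matches$start[r], snap_window_ms, fs)
    b <- snap_to_minimum(gyr_ml, matches$end[r], snap_window_ms, fs)
    if (b > a) out <- rbind(out, c(a, b))
  }
  out <- as_interval_matrix(out)
  out[order(out[, 1]), , drop = FALSE]
}

## keep predictions whose midpoint falls inside a (slightly widened) bout
keep_in_bouts <- function(pred, bouts, tol_samples) {
  bouts <- as_interval_matrix(bouts)
  if (!nrow(bouts) || !nrow(pred)) return(pred)
  mid <- (pred[, 1] + pred[, 2]) / 2
  keep <- vapply(mid, function(x)
    any(x >= bouts[, 1] - tol_samples & x <= bouts[, 2] + tol_samples),
    logical(1))
  pred[keep, , drop = FALSE]
}

#' @export
print.stride_dtw <- function(x, ...) {
  cat(sprintf("DTW stride segmenter: template of %d samples, max cost %.2f (tuned on F1)\n",
              x$template$length, x$max_cost))
  invisible(x)
}

#' Segment strides in a recording with the DTW baseline
#'
#' @param object A fitted `"stride_dtw"`.
#' @param recording An [imu_recording()] at the native rate.
#' @param bouts Optional bout intervals (native rate); when given,
#'   predictions outside every bout are discarded, mirroring an evaluation
#'   restricted to predefined walking bouts.
#' @param ... Unused.
#' @return Data frame (`start`, `end`) at the working rate (attribute `"fs"`).
#' @export
predict.stride_dtw <- function(object, recording, bouts = NULL, ...) {
  stopifnot(inherits(recording, "imu_recording"))
  pp <- preprocess_gyr_ml(recording, object$cutoff_hz, object$order,
                          object$decimate)
  pred <- dtw_predict_strides(object$template, pp$gyr_ml, pp$fs,
                              object$max_cost)
  if (!is.null(bouts)) {
    bouts <- as_interval_matrix(bouts)
    if (object$decimate) bouts <- floor((bouts - 1) / 2 + 0.5) + 1
    pred <- keep_in_bouts(pred, bouts, 3)
  }
  out <- data.frame(start = pred[, 1], end = pred[, 2])
  attr(out, "fs") <- pp$fs
  out
}

#' Evaluate a fitted segmenter on labelled recordings
#'
#' Predicts strides for both feet of every recording (using the ground-truth
#' bouts as the predefined decode regions), matches them per foot and per
#' bout against the reference strides with the tolerance rule, and pools the
#' counts (micro-averaging). Per-bout counts are also returned for
#' bout-length grouping, with `n_strides` the combined (both feet) reference
#' stride count of the bout.
#'
#' @param object A `"stride_hmm"` or `"stride_dtw"` fit.
#' @param recordings List of `"labeled_recording"` objects.
#' @param tol_samples Matching tolerance at the working rate (default 3,
#'   i.e. +/-60 ms at 51.2 Hz).
#' @return `list(metrics, per_bout, per_subject)`.
#' @export
evaluate_on_recordings <- function(object, recordings, tol_samples = 3) {
  if (inherits(recordings, "labeled_recording")) recordings <- list(recordings)
  decimate <- if (inherits(object, "stride_hmm")) object$hyper$decimate
              else object$decimate
  total <- c(tp = 0, fp = 0, fn = 0)
  per_bout <- NULL
  per_subject <- NULL
  for (rec in recordings) {
    ann <- as_annotations(rec)
    if (decimate) ann <- reindex_annotations_by_two(ann)
    bouts <- ann$bouts
    nb <- nrow(bouts)
    counts <- matrix(0, nb, 3L, dimnames = list(NULL, c("tp", "fp", "fn")))
    nstr <- integer(nb)
    subj <- c(tp = 0, fp = 0, fn = 0)
    for (foot in c("left", "right")) {
      ref <- ann$strides[[foot]]
      pred <- if (inherits(object, "stride_hmm")) {
        p <- predict(object, rec[[foot]], rec$bouts)
        as_interval_matrix(p[, c("start", "end")])
      } else {
        as_interval_matrix(predict(object, rec[[foot]], rec$bouts))
      }
      pred <- keep_in_bouts(pred, bouts, tol_samples)
      for (b in seq_len(nb)) {
        inb <- function(m) {
          mid <- (m[, 1] + m[, 2]) / 2
          m[mid >= bouts[b, 1] - tol_samples &
              mid <= bouts[b, 2] + tol_samples, , drop = FALSE]
        }
        ref_b <- ref[ref[, 1] >= bouts[b, 1] & ref[, 2] <= bouts[b, 2], ,
                     drop = FALSE]
        pred_b <- inb(pred)
        mm <- match_strides(pred_b, ref_b, tol_samples)
        counts[b, ] <- counts[b, ] + c(mm$tp, mm$fp, mm$fn)
        nstr[b] <- nstr[b] + nrow(ref_b)
        subj <- subj + c(mm$tp, mm$fp, mm$fn)
      }
    }
    total <- total + subj
    if (nb)
      per_bout <- rbind(per_bout,
                        data.frame(subject = rec$subject_id,
                                   bout = seq_len(nb), n_strides = nstr,
                                   counts))
    sm <- compute_metrics(subj["tp"], subj["fp"], subj["fn"])
    per_subject <- rbind(per_subject,
                         data.frame(subject = rec$subject_id,
                                    tp = subj["tp"], fp = subj["fp"],
                                    fn = subj["fn"],
                                    precision = sm$precision,
                                    recall = sm$recall, f1 = sm$f1,
                                    row.names = NULL))
  }
  list(metrics = compute_metrics(total["tp"], total["fp"], total["fn"]),
       per_bout = per_bout, per_subject = per_subject)
}
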
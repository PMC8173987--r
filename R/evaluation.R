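## Walking-bout definition, tolerance-window stride matching,
## precision/recall/F1, bout-length groups, cross-validation folds and the
## hyperparameter grid search.

#' Define walking bouts from both feet's strides
#'
#' Strides of both feet are merged on one timeline by start sample. A new
#' bout begins whenever the gap between one stride's end and the next
#' stride's start exceeds `max_rest_s` (a gap exactly equal to it stays in
#' the same bout); candidate bouts with fewer than `min_strides` strides
#' (both feet combined) are discarded. A bout interval spans the first
#' stride start to the last stride end.
#'
#' @param strides_both_feet List with per-foot 2-column stride matrices
#'   (`left`, `right`), each sorted by start.
#' @param fs Sampling rate in Hz the indices refer to.
#' @param min_strides Minimum combined stride count per bout (default 4).
#' @param max_rest_s Maximum within-bout resting period in seconds
#'   (default 2.5).
#' @return 2-column matrix of bout intervals with attribute
#'   `"n_strides"` giving the combined stride count per bout.
#' @export
define_walking_bouts <- function(strides_both_feet, fs, min_strides = 4,
                                 max_rest_s = 2.5) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  feet <- lapply(strides_both_feet[c("left", "right")], as_interval_matrix)
  for (f in feet)
    if (nrow(f) > 1L && is.unsorted(f[, 1]))
      stop("stride lists must be sorted by start", call. = FALSE)
  all_s <- rbind(feet$left, feet$right)
  if (!nrow(all_s)) {
    out <- as_interval_matrix(NULL)
    attr(out, "n_strides") <- integer(0)
    return(out)
  }
  ord <- order(all_s[, 1], all_s[, 2])
  all_s <- all_s[ord, , drop = FALSE]
  max_gap <- max_rest_s * fs
  bouts <- NULL
  counts <- integer(0)
  grp_start <- 1L
  run_end <- all_s[1L, 2]
  flush <- function(from, to) {
    n <- to - from + 1L
    if (n >= min_strides) {
      bouts <<- rbind(bouts, c(min(all_s[from:to, 1]), max(all_s[from:to, 2])))
      counts <<- c(counts, n)
    }
  }
  if (nrow(all_s) > 1L) {
    for (i in 2:nrow(all_s)) {
      # rest gap: end of the previous merged-timeline stride to this start
      gap <- all_s[i, 1] - all_s[i - 1L, 2]
      if (gap > max_gap) {
        flush(grp_start, i - 1L)
        grp_start <- i
      }
      run_end <- all_s[i, 2]
    }
  }
  flush(grp_start, nrow(all_s))
  out <- as_interval_matrix(bouts)
  attr(out, "n_strides") <- counts
  out
}

#' Match predicted against reference strides within a tolerance window
#'
#' A predicted/reference pair is compatible iff both start and end differ by
#' at most `tol_samples` samples (the +/-60 ms rule: 3 samples at 51.2 Hz).
#' Matching is one-to-one: references are swept in start order and each is
#' assigned the first unused compatible prediction.
#'
#' @param predicted,reference 2-column stride matrices sorted by start.
#' @param tol_samples Tolerance in samples (default 3).
#' @return `list(tp, fp, fn, pairs)`; `pairs` is a 2-column matrix of matched
#'   (predicted row, reference row) indices.
#' @export
match_strides <- function(predicted, reference, tol_samples = 3) {
  if (tol_samples < 0) stop("tol_samples must be >= 0", call. = FALSE)
  predicted <- as_interval_matrix(predicted)
  reference <- as_interval_matrix(reference)
  used <- logical(nrow(predicted))
  pairs <- NULL
  for (r in seq_len(nrow(reference))) {
    ok <- which(!used &
                  abs(predicted[, 1] - reference[r, 1]) <= tol_samples &
                  abs(predicted[, 2] - reference[r, 2]) <= tol_samples)
    if (length(ok)) {
      used[ok[1L]] <- TRUE
      pairs <- rbind(pairs, c(ok[1L], r))
    }
  }
  tp <- sum(used)
  list(tp = tp, fp = nrow(predicted) - tp, fn = nrow(reference) - tp,
       pairs = if (is.null(pairs)) matrix(integer(0), ncol = 2L) else pairs)
}

#' Precision, recall and F1 from match counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`, `F1` their harmonic
#' mean. If a denominator is zero the affected ratio and F1 are reported as
#' 0 and the `degenerate` flag is set, so pooled tables never propagate
#' non-numbers.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return An object of class `"stride_metrics"`.
#' @export
compute_metrics <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  if (any(c(tp, fp, fn) < 0)) stop("counts must be >= 0", call. = FALSE)
  degenerate <- (tp + fp) == 0 || (tp + fn) == 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, degenerate = degenerate),
            class = "stride_metrics")
}

#' @export
print.stride_metrics <- function(x, ...) {
  cat(sprintf("TP %g  FP %g  FN %g | precision %.3f  recall %.3f  F1 %.3f%s\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Bout-length group edges (combined stride counts)
#'
#' The six groups `4<=N<=15`, `15<N<=30`, `30<N<=50`, `50<N<=100`,
#' `100<N<=200` and `N>200` partition all valid bouts.
#'
#' @return Numeric vector of right-closed bin edges.
#' @export
bout_length_bins <- function() c(15, 30, 50, 100, 200, Inf)

bout_bin_label <- function(n_strides) {
  edges <- bout_length_bins()
  labels <- c("4<=N<=15", "15<N<=30", "30<N<=50", "50<N<=100",
              "100<N<=200", "N>200")
  labels[findInterval(n_strides, c(-Inf, edges[-length(edges)]),
                      left.open = TRUE)]
}

#' Pool match counts per bout-length group
#'
#' Counts are pooled (micro-averaged) within each group before the ratios
#' are computed; empty groups are omitted.
#'
#' @param per_bout_results Data frame with columns `n_strides`, `tp`, `fp`,
#'   `fn` (one row per bout).
#' @return Data frame with one row per non-empty group: `group`, pooled
#'   counts and `precision`, `recall`, `f1`.
#' @export
group_metrics_by_bout_length <- function(per_bout_results) {
  df <- as.data.frame(per_bout_results)
  stopifnot(all(c("n_strides", "tp", "fp", "fn") %in% names(df)))
  df$group <- bout_bin_label(df$n_strides)
  groups <- unique(bout_bin_label(c(4, 16, 31, 51, 101, 201)))
  out <- NULL
  for (g in groups) {
    rows <- df[df$group == g, , drop = FALSE]
    if (!nrow(rows)) next
    mm <- compute_metrics(sum(rows$tp), sum(rows$fp), sum(rows$fn))
    out <- rbind(out, data.frame(group = g, n_bouts = nrow(rows),
                                 tp = mm$tp, fp = mm$fp, fn = mm$fn,
                                 precision = mm$precision, recall = mm$recall,
                                 f1 = mm$f1))
  }
  out
}

#' Subject-wise cross-validation folds
#'
#' Shuffles the subjects with `seed` and splits them into `k` near-equal
#' test groups; no subject ever appears in both the train and the test set
#' of a fold. Optional inner folds are built the same way on each train set.
#'
#' @param subject_ids Character or integer vector of subject identifiers.
#' @param k Number of folds (default 4).
#' @param seed Integer seed.
#' @param inner_k If non-`NULL`, the number of inner folds per outer fold.
#' @return List of folds, each `list(train, test, inner)`.
#' @export
make_subject_folds <- function(subject_ids, k = 4L, seed = 1L, inner_k = NULL) {
  subject_ids <- unique(subject_ids)
  if (k > length(subject_ids))
    stop("k exceeds the number of subjects", call. = FALSE)
  rng <- rng_stream(seed)
  shuffled <- with_rng(rng, sample(subject_ids))
  groups <- split(shuffled, rep(seq_len(k), length.out = length(shuffled)))
  lapply(seq_len(k), function(i) {
    test <- sort(groups[[i]])
    train <- sort(setdiff(subject_ids, test))
    inner <- if (!is.null(inner_k))
      make_subject_folds(train, inner_k, spawn_seed(rng)) else NULL
    list(train = train, test = test, inner = inner)
  })
}

#' Enumerate the hyperparameter grid
#'
#' @param window_ms,feature_sets,gmm_components,stride_states,transition_states
#'   Candidate values; defaults are the full optimization grid (720
#'   configurations).
#' @return Data frame with one row per configuration, in fixed lexicographic
#'   order; `feature_set` is a list column.
#' @export
hyperparameter_grid <- function(window_ms = c(100, 220, 500),
                                feature_sets = list("raw", c("raw", "grad"),
                                                    c("raw", "var", "polyfit")),
                                gmm_components = c(1, 3, 5, 8),
                                stride_states = c(5, 10, 15, 20, 25),
                                transition_states = c(3, 5, 8, 12)) {
  g <- expand.grid(window_ms = window_ms,
                   feature_set = seq_along(feature_sets),
                   gmm_components = gmm_components,
                   stride_states = stride_states,
                   transition_states = transition_states,
                   KEEP.OUT.ATTRS = FALSE)
  g$feature_set <- feature_sets[g$feature_set]
  g
}

#' Cross-validated grid search over segmenter hyperparameters
#'
#' For every configuration, fits the segmenter on each fold's training
#' subjects and scores F1 on the test subjects; configurations are ranked by
#' mean F1 over folds. Configurations that fail to train (e.g. sequences
#' shorter than the state count) are recorded with `NA` and excluded from
#' the ranking rather than aborting the search. Deterministic given `seed`.
#'
#' @param grid Data frame from [hyperparameter_grid()].
#' @param folds Folds from [make_subject_folds()].
#' @param data List of `"labeled_recording"` objects.
#' @param seed Integer seed passed to every fit.
#' @param tol_samples Matching tolerance at the working rate.
#' @return `list(best, table)`: the best configuration (ties resolved by
#'   grid order) and the per-configuration mean-F1 table.
#' @export
grid_search <- function(grid, folds, data, seed = 1L, tol_samples = 3) {
  if (!nrow(grid) || !length(data)) stop("empty grid or data", call. = FALSE)
  ids <- vapply(data, `[[`, character(1), "subject_id")
  mean_f1 <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    f1s <- rep(NA_real_, length(folds))
    for (fi in seq_along(folds)) {
      fold <- folds[[fi]]
      res <- tryCatch({
        fit <- fit_stride_hmm(data[ids %in% fold$train],
                              n_stride_states = grid$stride_states[gi],
                              n_transition_states = grid$transition_states[gi],
                              n_components = grid$gmm_components[gi],
                              window_ms = grid$window_ms[gi],
                              feature_set = grid$feature_set[[gi]],
                              seed = seed)
        ev <- evaluate_on_recordings(fit, data[ids %in% fold$test],
                                     tol_samples = tol_samples)
        ev$metrics$f1
      }, error = function(e) NA_real_)
      f1s[fi] <- res
    }
    mean_f1[gi] <- if (all(is.na(f1s))) NA_real_ else mean(f1s, na.rm = TRUE)
  }
  table <- cbind(grid, mean_f1 = mean_f1)
  ok <- which(!is.na(mean_f1))
  if (!length(ok)) stop("no configuration could be trained", call. = FALSE)
  best <- table[ok[which.max(mean_f1[ok])], , drop = FALSE]
  list(best = best, table = table)
}
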
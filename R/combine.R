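## Flattening the stride and transition sub-models into one segmenter, and
## extracting stride borders from its Viterbi path.

#' Combine the transition and stride sub-models into one segmenter
#'
#' The hidden-state sequence of every training segment is predicted with its
#' own class model (Viterbi), the per-segment paths are merged into one
#' continuous state sequence per walking bout (transition states first:
#' indices `1..m`, stride states `m+1..m+n`), and the full combined
#' transition matrix is re-estimated from the merged transition counts.
#' Additive smoothing `eps` is applied only to structurally plausible edges
#' (sub-model edges plus observed cross edges). Start/end distributions come
#' from the merged sequences' first/last states with add-one smoothing; the
#' already-trained emission distributions are copied unchanged.
#'
#' @param transition_model Trained transition-variant `"left_right_hmm"`.
#' @param stride_model Trained stride-variant `"left_right_hmm"`.
#' @param labeled_bouts List of bouts; each bout is a list of segments in
#'   temporal order, each segment a `list(class = "stride"|"transition",
#'   features = matrix)` tiling the bout contiguously.
#' @param eps Additive smoothing for plausible edges.
#' @return A `"combined_hmm"` object.
#' @export
combine_models <- function(transition_model, stride_model, labeled_bouts,
                           eps = 1e-12) {
  stopifnot(inherits(transition_model, "left_right_hmm"),
            inherits(stride_model, "left_right_hmm"))
  m <- transition_model$n_states
  n <- stride_model$n_states
  Ntot <- m + n
  counts <- matrix(0, Ntot, Ntot)
  first_counts <- numeric(Ntot)
  last_counts <- numeric(Ntot)
  for (bout in labeled_bouts) {
    classes <- vapply(bout, `[[`, character(1), "class")
    if (!any(classes == "stride"))
      stop("a bout contains no stride segment", call. = FALSE)
    merged <- integer(0)
    for (seg in bout) {
      mod <- if (seg$class == "stride") stride_model else transition_model
      off <- if (seg$class == "stride") m else 0L
      merged <- c(merged, viterbi_decode(mod, seg$features) + off)
    }
    Tn <- length(merged)
    first_counts[merged[1L]] <- first_counts[merged[1L]] + 1
    last_counts[merged[Tn]] <- last_counts[merged[Tn]] + 1
    if (Tn > 1L) {
      idx <- cbind(merged[-Tn], merged[-1L])
      for (r in seq_len(nrow(idx)))
        counts[idx[r, 1L], idx[r, 2L]] <- counts[idx[r, 1L], idx[r, 2L]] + 1
    }
  }
  plausible <- matrix(FALSE, Ntot, Ntot)
  plausible[1:m, 1:m] <- lr_allowed_mask(m, transition_model$wrap_edge)
  plausible[(m + 1):Ntot, (m + 1):Ntot] <- lr_allowed_mask(n, stride_model$wrap_edge)
  plausible <- plausible | counts > 0
  trans <- counts
  trans[plausible] <- trans[plausible] + eps
  rs <- rowSums(trans)
  zero_rows <- rs == 0
  if (any(zero_rows)) {            # unreachable state: keep its self-loop
    trans[cbind(which(zero_rows), which(zero_rows))] <- 1
    rs[zero_rows] <- 1
  }
  trans <- trans / rs
  start <- (first_counts + 1) / sum(first_counts + 1)
  end <- (last_counts + 1) / sum(last_counts + 1)
  structure(list(trans = trans, state_class = rep(c("transition", "stride"),
                                                  c(m, n)),
                 m = m, n = n,
                 stride_first_state = m + 1L, stride_last_state = Ntot,
                 emissions = c(transition_model$emissions,
                               stride_model$emissions),
                 start = start, end = end),
            class = "combined_hmm")
}

#' @export
print.combined_hmm <- function(x, ...) {
  cat(sprintf("<combined_hmm> %d transition + %d stride states (%dx%d matrix)\n",
              x$m, x$n, x$m + x$n, x$m + x$n))
  invisible(x)
}

## contiguous same-state runs of a path: matrix (state, start, end)
state_runs <- function(path) {
  r <- rle(as.vector(path))
  ends <- cumsum(r$lengths)
  cbind(state = r$values, start = ends - r$lengths + 1L, end = ends)
}

#' Extract stride intervals from a combined-model decode
#'
#' Decodes the feature sequence with the combined model, marks a border
#' candidate at every change between a transition-class and a stride-class
#' state and at every transition from the last to the first stride state
#' (back-to-back strides), snaps each border to the minimum of `gyr_ml` over
#' the union of the two state-occupancy runs flanking the change, and
#' assembles stride intervals from consecutive borders that bracket
#' stride-class stretches. The end of stride i may equal the start of
#' stride i+1 (shared border sample).
#'
#' @param model A `"combined_hmm"`.
#' @param features Feature matrix for the decoded region.
#' @param gyr_ml The (filtered, working-rate) gyr_ml signal of the same
#'   region, used for border snapping.
#' @param fs Working sampling rate in Hz.
#' @return `list(strides = 2-column matrix (start, end), path = state path)`.
#'   An empty matrix is a valid result.
#' @export
predict_strides <- function(model, features, gyr_ml, fs) {
  stopifnot(inherits(model, "combined_hmm"))
  if (nrow(as.matrix(features)) != length(gyr_ml))
    stop("features and gyr_ml disagree in length", call. = FALSE)
  path <- viterbi_decode(model, features)
  runs <- state_runs(path)
  cls <- model$state_class
  Tn <- length(path)
  borders <- numeric(0)
  stride_after <- logical(0)     # is the stretch after this border stride-class?
  if (nrow(runs) > 1L) {
    for (r in seq_len(nrow(runs) - 1L)) {
      s1 <- runs[r, "state"]; s2 <- runs[r + 1L, "state"]
      class_change <- cls[s1] != cls[s2]
      wrap <- s1 == model$stride_last_state && s2 == model$stride_first_state
      if (!(class_change || wrap)) next
      region <- runs[r, "start"]:runs[r + 1L, "end"]
      b <- region[which.min(gyr_ml[region])]
      borders <- c(borders, b)
      stride_after <- c(stride_after, cls[s2] == "stride")
    }
  }
  strides <- matrix(numeric(0), ncol = 2L)
  if (length(borders) > 1L) {
    for (i in seq_len(length(borders) - 1L)) {
      if (stride_after[i] && borders[i + 1L] > borders[i])
        strides <- rbind(strides, c(borders[i], borders[i + 1L]))
    }
  }
  colnames(strides) <- c("start", "end")
  list(strides = strides, path = path)
}
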
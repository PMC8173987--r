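# Independent oracles: exhaustive path enumeration for HMM likelihood and
# decoding, and exhaustive maximum bipartite matching for stride evaluation.
# These share no code with the package's inference routines.

# mixture log-density of sample row x under one state's GMM
oracle_state_logdens <- function(em, x) {
  dens <- 0
  for (j in seq_along(em$weights)) {
    if (em$weights[j] <= 0) next
    d <- em$weights[j]
    for (dd in seq_along(x))
      d <- d * stats::dnorm(x[dd], em$means[j, dd], sqrt(em$vars[j, dd]))
    dens <- dens + d
  }
  max(log(dens), -700)
}

# all state paths of length Tn over n states, lexicographic order
oracle_all_paths <- function(n, Tn) {
  g <- do.call(expand.grid, rev(rep(list(seq_len(n)), Tn)))
  as.matrix(g[, rev(seq_len(Tn)), drop = FALSE])
}

oracle_path_logprobs <- function(model, X) {
  X <- as.matrix(X)
  Tn <- nrow(X)
  n <- nrow(model$trans)
  logB <- matrix(0, Tn, n)
  for (t in seq_len(Tn))
    for (i in seq_len(n))
      logB[t, i] <- oracle_state_logdens(model$emissions[[i]], X[t, ])
  paths <- oracle_all_paths(n, Tn)
  logA <- log(model$trans)
  lp <- log(model$start[paths[, 1]]) + log(model$end[paths[, Tn]])
  for (t in seq_len(Tn)) lp <- lp + logB[cbind(t, paths[, t])]
  if (Tn > 1) for (t in seq_len(Tn - 1))
    lp <- lp + logA[cbind(paths[, t], paths[, t + 1])]
  list(paths = paths, logprobs = lp)
}

oracle_loglik <- function(model, X) {
  lp <- oracle_path_logprobs(model, X)$logprobs
  m <- max(lp)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lp - m)))
}

oracle_viterbi <- function(model, X) {
  pp <- oracle_path_logprobs(model, X)
  pp$paths[which.max(pp$logprobs), ]
}

# random structured left-right toy model (built directly, not via the
# package initializer) plus random sequences
random_toy_model <- function(n_states, d = 1L, k = 1L, wrap = FALSE,
                             free_ends = FALSE) {
  trans <- matrix(0, n_states, n_states)
  for (i in seq_len(n_states)) {
    edges <- i
    if (i < n_states) edges <- c(edges, i + 1L)
    if (wrap && i == n_states && n_states > 1L) edges <- c(edges, 1L)
    p <- stats::runif(length(edges), 0.2, 1)
    trans[i, edges] <- p / sum(p)
  }
  if (free_ends) {
    start <- stats::runif(n_states, 0.2, 1); start <- start / sum(start)
    end <- stats::runif(n_states, 0.2, 1); end <- end / sum(end)
  } else {
    start <- c(1, rep(0, n_states - 1L))
    end <- c(rep(0, n_states - 1L), 1)
  }
  emissions <- lapply(seq_len(n_states), function(i) {
    w <- stats::runif(k, 0.3, 1)
    list(weights = w / sum(w),
         means = matrix(stats::rnorm(k * d, 0, 2), k, d),
         vars = matrix(stats::runif(k * d, 0.3, 2), k, d))
  })
  structure(list(n_states = n_states, trans = trans, start = start,
                 end = end, emissions = emissions, wrap_edge = wrap,
                 free_ends = free_ends),
            class = "left_right_hmm")
}

# exhaustive maximum bipartite matching size (references x predictions)
oracle_max_matching <- function(compat) {
  nr <- nrow(compat)
  if (nr == 0L) return(0L)
  best <- 0L
  rec <- function(r, used) {
    if (r > nr) return(0L)
    res <- rec(r + 1L, used)             # leave reference r unmatched
    for (p in which(compat[r, ] & !used)) {
      used2 <- used; used2[p] <- TRUE
      res <- max(res, 1L + rec(r + 1L, used2))
    }
    res
  }
  rec(1L, rep(FALSE, ncol(compat)))
}

compat_matrix <- function(predicted, reference, tol) {
  nr <- nrow(reference)
  np <- nrow(predicted)
  m <- matrix(FALSE, nr, np)
  for (r in seq_len(nr))
    m[r, ] <- abs(predicted[, 1] - reference[r, 1]) <= tol &
      abs(predicted[, 2] - reference[r, 2]) <= tol
  m
}

# realistic random matching instance: perturbed references plus spurious
# and dropped predictions
random_matching_instance <- function(max_strides = 8L, tol = 3) {
  n_ref <- sample(0:max_strides, 1L)
  dur <- round(stats::runif(n_ref + 2L, 45, 65))
  starts <- cumsum(c(100, dur[seq_len(max(0L, n_ref - 1L))])) +
    cumsum(sample(c(0, 0, 0, 30), n_ref, replace = TRUE))
  ref <- if (n_ref > 0L) cbind(starts, starts + dur[seq_len(n_ref)])
         else matrix(numeric(0), ncol = 2L)
  pred <- NULL
  for (r in seq_len(n_ref)) {
    if (stats::runif(1) < 0.85) {
      off <- sample(-5:5, 2L, replace = TRUE)
      pred <- rbind(pred, ref[r, ] + off)
    }
  }
  n_spur <- sample(0:2, 1L)
  for (s in seq_len(n_spur)) {
    a <- round(stats::runif(1, 50, 600))
    pred <- rbind(pred, c(a, a + round(stats::runif(1, 45, 65))))
  }
  if (!is.null(pred) && nrow(pred) > 1L)
    pred <- pred[order(pred[, 1], pred[, 2]), , drop = FALSE]
  if (is.null(pred)) pred <- matrix(numeric(0), ncol = 2L)
  list(predicted = pred, reference = ref)
}
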
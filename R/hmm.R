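## Left-right hidden Markov models with diagonal Gaussian-mixture emissions.
##
## Two variants share one representation:
##  * stride model  — strict left-right chain; sequences are forced to start
##    in the first and end in the last state (delta start/end distributions);
##  * transition model — left-right chain plus a wrap edge from the last to
##    the first state; sequences may start and end in any state.
## Structural zeros of the transition matrix are exact zeros and stay zero
## through training.

VAR_FLOOR <- 1e-6
LOGDENS_FLOOR <- -700

new_left_right_hmm <- function(trans, start, end, emissions, wrap_edge,
                               free_ends) {
  structure(list(n_states = nrow(trans), trans = trans, start = start,
                 end = end, emissions = emissions, wrap_edge = wrap_edge,
                 free_ends = free_ends),
            class = "left_right_hmm")
}

#' @export
print.left_right_hmm <- function(x, ...) {
  cat(sprintf("<left_right_hmm> %d states, %d mixture component(s), %s\n",
              x$n_states, length(x$emissions[[1]]$weights),
              if (x$wrap_edge) "wrap edge (transition variant)"
              else "strict left-right (stride variant)"))
  invisible(x)
}

## structural mask of allowed edges
lr_allowed_mask <- function(n, wrap_edge) {
  A <- matrix(FALSE, n, n)
  diag(A) <- TRUE
  if (n > 1L) {
    A[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- TRUE
    if (wrap_edge) A[n, 1L] <- TRUE
  }
  A
}

## k-means++ center picking followed by Lloyd iterations
kmeanspp <- function(X, k, rng) {
  n <- nrow(X)
  with_rng(rng, {
    centers <- matrix(0, k, ncol(X))
    centers[1L, ] <- X[sample.int(n, 1L), ]
    if (k > 1L) {
      d2 <- rowSums((X - rep(centers[1L, ], each = n))^2)
      for (j in 2:k) {
        p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        centers[j, ] <- X[sample(n, 1L, prob = p), ]
        d2 <- pmin(d2, rowSums((X - rep(centers[j, ], each = n))^2))
      }
    }
    km <- tryCatch(
      stats::kmeans(X, centers = centers, iter.max = 20L),
      error = function(e) list(cluster = max.col(-outer(
        rowSums(X^2), rowSums(centers^2), "+") + 2 * X %*% t(centers),
        ties.method = "first"))
    )
    km$cluster
  })
}

## fit a diagonal GMM to pooled rows by k-means assignment
fit_gmm <- function(X, k, rng) {
  X <- as.matrix(X)
  d <- ncol(X)
  n <- nrow(X)
  if (n < k) X <- X[rep(seq_len(n), length.out = k), , drop = FALSE]
  if (k == 1L) {
    cl <- rep(1L, nrow(X))
  } else {
    cl <- kmeanspp(X, k, rng)
  }
  weights <- numeric(k); means <- matrix(0, k, d); vars <- matrix(0, k, d)
  global_var <- pmax(apply(X, 2L, stats::var), VAR_FLOOR)
  if (any(!is.finite(global_var))) global_var <- rep(1, d)
  for (j in seq_len(k)) {
    rows <- which(cl == j)
    if (!length(rows)) { # empty cluster: fall back to global stats
      weights[j] <- 1e-6
      means[j, ] <- colMeans(X)
      vars[j, ] <- global_var
      next
    }
    weights[j] <- length(rows)
    means[j, ] <- colMeans(X[rows, , drop = FALSE])
    v <- apply(X[rows, , drop = FALSE], 2L, function(col) mean((col - mean(col))^2))
    vars[j, ] <- pmax(ifelse(is.finite(v) & v > 0, v, global_var), VAR_FLOOR)
  }
  list(weights = weights / sum(weights), means = means, vars = vars)
}

#' Initialize a left-right HMM from labeled sequences
#'
#' Each training sequence is split into `n_states` contiguous, equal-as-
#' possible segments; state i's Gaussian mixture is fitted (k-means++
#' seeding) to the pooled i-th segments of all sequences. Every structurally
#' allowed transition edge of a row receives equal probability (0.5/0.5 for
#' interior rows; the last row is all self-loop unless `wrap_edge` adds the
#' wrap transition).
#'
#' @param sequences List of feature matrices (rows = samples).
#' @param n_states Number of hidden states.
#' @param n_components Gaussian mixture components per state.
#' @param wrap_edge Add the last-to-first wrap transition (transition-model
#'   variant).
#' @param free_ends Allow sequences to start/end in any state (transition
#'   variant); otherwise start is pinned to the first and end to the last
#'   state (stride variant).
#' @param seed Integer seed for the k-means++ initialization.
#' @return A `"left_right_hmm"` object.
#' @export
init_left_right_model <- function(sequences, n_states, n_components = 1L,
                                  wrap_edge = FALSE, free_ends = FALSE,
                                  seed = 1L) {
  if (!length(sequences)) stop("no training sequences", call. = FALSE)
  sequences <- lapply(sequences, as.matrix)
  if (n_components < 1L) stop("n_components must be >= 1", call. = FALSE)
  lens <- vapply(sequences, nrow, integer(1))
  short <- which(lens < n_states)
  if (length(short))
    stop(sprintf("sequence %d has %d samples, fewer than n_states = %d",
                 short[1], lens[short[1]], n_states), call. = FALSE)
  rng <- rng_stream(seed)
  pooled <- vector("list", n_states)
  for (s in sequences) {
    bnd <- floor(seq(0, nrow(s), length.out = n_states + 1L))
    for (i in seq_len(n_states))
      pooled[[i]] <- c(pooled[[i]], list(s[(bnd[i] + 1L):bnd[i + 1L], , drop = FALSE]))
  }
  emissions <- lapply(seq_len(n_states), function(i)
    fit_gmm(do.call(rbind, pooled[[i]]), n_components, rng))
  allowed <- lr_allowed_mask(n_states, wrap_edge)
  trans <- matrix(0, n_states, n_states)
  for (i in seq_len(n_states)) {
    edges <- which(allowed[i, ])
    trans[i, edges] <- 1 / length(edges)
  }
  if (free_ends) {
    start <- rep(1 / n_states, n_states)
    end <- rep(1 / n_states, n_states)
  } else {
    start <- c(1, rep(0, n_states - 1L))
    end <- c(rep(0, n_states - 1L), 1)
  }
  new_left_right_hmm(trans, start, end, emissions, wrap_edge, free_ends)
}

## per-state GMM log-density for all samples: returns T x n_states matrix
emission_logdens <- function(emissions, X) {
  X <- as.matrix(X)
  Tn <- nrow(X)
  out <- matrix(0, Tn, length(emissions))
  for (i in seq_along(emissions)) {
    em <- emissions[[i]]
    k <- length(em$weights)
    comp <- matrix(-Inf, Tn, k)
    for (j in seq_len(k)) {
      if (em$weights[j] <= 0) next
      ld <- 0
      for (dd in seq_len(ncol(X)))
        ld <- ld + stats::dnorm(X[, dd], em$means[j, dd],
                                sqrt(em$vars[j, dd]), log = TRUE)
      comp[, j] <- log(em$weights[j]) + ld
    }
    if (k == 1L) {
      out[, i] <- comp[, 1L]
    } else {
      m <- apply(comp, 1L, max)
      out[, i] <- m + log(rowSums(exp(comp - m)))
    }
  }
  pmax(out, LOGDENS_FLOOR)
}

model_parts <- function(model) {
  if (inherits(model, "left_right_hmm"))
    list(trans = model$trans, start = model$start, end = model$end,
         emissions = model$emissions)
  else if (inherits(model, "combined_hmm"))
    list(trans = model$trans, start = model$start, end = model$end,
         emissions = model$emissions)
  else stop("not an HMM object", call. = FALSE)
}

## scaled forward pass; returns list(alpha_hat TxN, logc T, loglik)
forward_scaled <- function(trans, start, end, logB) {
  Tn <- nrow(logB); N <- ncol(logB)
  K <- apply(logB, 1L, max)                 # per-sample shift
  Blin <- exp(logB - K)
  alpha <- matrix(0, Tn, N)
  logc <- numeric(Tn)
  a <- start * Blin[1L, ]
  s <- sum(a)
  if (s <= 0) return(NULL)
  alpha[1L, ] <- a / s
  logc[1L] <- log(s) + K[1L]
  if (Tn > 1L) for (t in 2:Tn) {
    a <- as.numeric(alpha[t - 1L, ] %*% trans) * Blin[t, ]
    s <- sum(a)
    if (s <= 0) return(NULL)
    alpha[t, ] <- a / s
    logc[t] <- log(s) + K[t]
  }
  tail_mass <- sum(alpha[Tn, ] * end)
  if (tail_mass <= 0) return(NULL)
  list(alpha = alpha, logc = logc, Blin = Blin,
       loglik = sum(logc) + log(tail_mass))
}

## scaled backward pass matching forward_scaled's normalizers
backward_scaled <- function(trans, end, Blin, logc, K) {
  Tn <- nrow(Blin); N <- ncol(Blin)
  beta <- matrix(0, Tn, N)
  beta[Tn, ] <- end
  if (Tn > 1L) for (t in (Tn - 1L):1L) {
    v <- Blin[t + 1L, ] * beta[t + 1L, ]
    beta[t, ] <- as.numeric(trans %*% v) / exp(logc[t + 1L] - K[t + 1L])
  }
  beta
}

#' Forward-algorithm log-likelihood of a feature sequence
#'
#' @param model A `"left_right_hmm"` or `"combined_hmm"`.
#' @param features Feature matrix (rows = samples); its column count must
#'   match the emission dimension.
#' @return The log-likelihood; `-Inf` if the sequence is structurally
#'   impossible under the model.
#' @export
loglik <- function(model, features) {
  p <- model_parts(model)
  X <- as.matrix(features)
  if (ncol(X) != ncol(p$emissions[[1]]$means))
    stop("feature dimension does not match the model emissions", call. = FALSE)
  logB <- emission_logdens(p$emissions, X)
  fwd <- forward_scaled(p$trans, p$start, p$end, logB)
  if (is.null(fwd)) -Inf else fwd$loglik
}

#' Most likely hidden-state path (Viterbi)
#'
#' Log-space dynamic program honoring the start/end distributions and the
#' structural zeros of the transition matrix. Ties break toward the lowest
#' state index.
#'
#' @inheritParams loglik
#' @return Integer state path (1-based state indices), with attribute
#'   `"logprob"` holding the path log-probability.
#' @export
viterbi_decode <- function(model, features) {
  p <- model_parts(model)
  X <- as.matrix(features)
  if (ncol(X) != ncol(p$emissions[[1]]$means))
    stop("feature dimension does not match the model emissions", call. = FALSE)
  logB <- emission_logdens(p$emissions, X)
  Tn <- nrow(logB); N <- ncol(logB)
  logA <- log(p$trans)
  delta <- log(p$start) + logB[1L, ]
  psi <- matrix(0L, Tn, N)
  if (Tn > 1L) for (t in 2:Tn) {
    M <- logA + delta              # column j: delta_i + log A[i, j]
    arg <- max.col(t(M), ties.method = "first")
    delta <- M[cbind(arg, seq_len(N))] + logB[t, ]
    psi[t, ] <- arg
  }
  fin <- delta + log(p$end)
  if (max(fin) == -Inf)
    stop("sequence is structurally impossible under the model", call. = FALSE)
  path <- integer(Tn)
  path[Tn] <- which.max(fin)
  if (Tn > 1L) for (t in (Tn - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  attr(path, "logprob") <- max(fin)
  path
}
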
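## Baum-Welch (EM) training of a left-right HMM on multiple sequences.
## Expectation uses scaled forward/backward passes; maximization re-estimates
## the transition matrix (structural zeros preserved exactly, since expected
## edge counts inherit the zeros), the start distribution (free-ends variant
## only) and the per-state Gaussian mixtures. End distributions stay fixed.

#' Train a left-right HMM with the Baum-Welch algorithm
#'
#' Expectation-maximization over the transition probabilities, the start
#' distribution (transition-model variant) and the GMM emission parameters.
#' The total log-likelihood over all sequences is non-decreasing across
#' iterations; training stops at `max_iter` iterations (ten, following the
#' training protocol this package implements) or when the relative
#' improvement falls below `tol`.
#'
#' @param model A `"left_right_hmm"` from [init_left_right_model()].
#' @param sequences List of feature matrices.
#' @param max_iter Maximum number of EM iterations (default 10).
#' @param tol Relative log-likelihood improvement below which training stops.
#' @return `list(model, report)` where `report` has elements
#'   `log_likelihood_per_iteration`, `n_iterations` and `converged`.
#' @export
baum_welch <- function(model, sequences, max_iter = 10L, tol = 1e-4) {
  stopifnot(inherits(model, "left_right_hmm"))
  sequences <- lapply(sequences, as.matrix)
  d <- ncol(model$emissions[[1]]$means)
  if (any(vapply(sequences, ncol, integer(1)) != d))
    stop("sequence feature dimension does not match the model", call. = FALSE)
  N <- model$n_states
  lls <- numeric(0)
  converged <- FALSE
  n_done <- 0L
  for (iter in seq_len(max_iter)) {
    acc <- list(xi = matrix(0, N, N), start = numeric(N),
                nk = lapply(model$emissions, function(e) numeric(length(e$weights))),
                sx = lapply(model$emissions, function(e)
                  matrix(0, length(e$weights), d)),
                sxx = lapply(model$emissions, function(e)
                  matrix(0, length(e$weights), d)))
    ll_total <- 0
    for (s in sequences) {
      es <- expectation_step(model, s)
      if (is.null(es))
        stop("a training sequence has -Inf likelihood under the model; ",
             "check features and variance floor", call. = FALSE)
      ll_total <- ll_total + es$loglik
      acc$xi <- acc$xi + es$xi
      acc$start <- acc$start + es$gamma[1L, ]
      for (i in seq_len(N)) {
        acc$nk[[i]] <- acc$nk[[i]] + es$comp_n[[i]]
        acc$sx[[i]] <- acc$sx[[i]] + es$comp_sx[[i]]
        acc$sxx[[i]] <- acc$sxx[[i]] + es$comp_sxx[[i]]
      }
    }
    lls <- c(lls, ll_total)
    if (iter > 1L) {
      rel <- (ll_total - lls[iter - 1L]) / max(abs(lls[iter - 1L]), 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
    model <- maximization_step(model, acc)
    n_done <- iter
  }
  report <- list(log_likelihood_per_iteration = lls,
                 n_iterations = n_done, converged = converged)
  list(model = model, report = report)
}

## E-step for one sequence: gamma, summed xi, and per-state mixture stats
expectation_step <- function(model, X) {
  logB_parts <- state_component_logdens(model$emissions, X)
  logB <- logB_parts$logB
  fwd <- forward_scaled(model$trans, model$start, model$end, logB)
  if (is.null(fwd)) return(NULL)
  Tn <- nrow(logB); N <- ncol(logB)
  K <- apply(logB, 1L, max)
  beta <- backward_scaled(model$trans, model$end, fwd$Blin, fwd$logc, K)
  gamma <- fwd$alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, N, N)
  if (Tn > 1L) for (t in seq_len(Tn - 1L)) {
    M <- outer(fwd$alpha[t, ], fwd$Blin[t + 1L, ] * beta[t + 1L, ]) * model$trans
    sm <- sum(M)
    if (sm > 0) xi <- xi + M / sm
  }
  d <- ncol(X)
  comp_n <- vector("list", N); comp_sx <- vector("list", N)
  comp_sxx <- vector("list", N)
  X <- as.matrix(X)
  for (i in seq_len(N)) {
    lc <- logB_parts$comp[[i]]                 # T x k component log-densities
    k <- ncol(lc)
    if (k == 1L) {
      R <- matrix(gamma[, i], ncol = 1L)
    } else {
      m <- apply(lc, 1L, max)
      w <- exp(lc - m)
      R <- (w / rowSums(w)) * gamma[, i]
    }
    comp_n[[i]] <- colSums(R)
    comp_sx[[i]] <- crossprod(R, X)
    comp_sxx[[i]] <- crossprod(R, X^2)
  }
  list(loglik = fwd$loglik, gamma = gamma, xi = xi,
       comp_n = comp_n, comp_sx = comp_sx, comp_sxx = comp_sxx)
}

## per-state total log-density plus per-component log-densities
state_component_logdens <- function(emissions, X) {
  X <- as.matrix(X)
  Tn <- nrow(X)
  N <- length(emissions)
  logB <- matrix(0, Tn, N)
  comp <- vector("list", N)
  for (i in seq_len(N)) {
    em <- emissions[[i]]
    k <- length(em$weights)
    lc <- matrix(-Inf, Tn, k)
    for (j in seq_len(k)) {
      if (em$weights[j] <= 0) next
      ld <- 0
      for (dd in seq_len(ncol(X)))
        ld <- ld + stats::dnorm(X[, dd], em$means[j, dd],
                                sqrt(em$vars[j, dd]), log = TRUE)
      lc[, j] <- log(em$weights[j]) + ld
    }
    comp[[i]] <- lc
    if (k == 1L) {
      logB[, i] <- lc[, 1L]
    } else {
      m <- apply(lc, 1L, max)
      logB[, i] <- m + log(rowSums(exp(lc - m)))
    }
  }
  list(logB = pmax(logB, LOGDENS_FLOOR), comp = comp)
}

maximization_step <- function(model, acc) {
  N <- model$n_states
  allowed <- lr_allowed_mask(N, model$wrap_edge)
  trans <- model$trans
  for (i in seq_len(N)) {
    rs <- sum(acc$xi[i, ])
    if (rs > 0) {
      row <- acc$xi[i, ] / rs
      row[!allowed[i, ]] <- 0            # exact structural zeros
      trans[i, ] <- row / sum(row)
    }
  }
  if (model$free_ends && sum(acc$start) > 0)
    model$start <- acc$start / sum(acc$start)
  for (i in seq_len(N)) {
    em <- model$emissions[[i]]
    nk <- acc$nk[[i]]
    tot <- sum(nk)
    if (tot <= 1e-10) next               # unoccupied state: keep parameters
    upd <- nk > 1e-10
    em$weights <- nk / tot               # exact EM update; empty -> ~0
    mu <- em$means
    vv <- em$vars
    mu[upd, ] <- acc$sx[[i]][upd, , drop = FALSE] / nk[upd]
    vv[upd, ] <- pmax(acc$sxx[[i]][upd, , drop = FALSE] / nk[upd] -
                        mu[upd, , drop = FALSE]^2, VAR_FLOOR)
    em$means <- mu
    em$vars <- vv
    model$emissions[[i]] <- em
  }
  model$trans <- trans
  model
}
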
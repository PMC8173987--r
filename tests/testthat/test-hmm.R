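seq_list <- function(rng, n_seq, len, d = 1L) {
  lapply(seq_len(n_seq), function(i)
    matrix(with_rng(rng, rnorm(len * d)), len, d))
}

test_that("naive initialization splits sequences equally and edges uniformly", {
  rng <- rng_stream(2)
  s <- matrix(with_rng(rng, rnorm(50)), 50, 1)
  m <- init_left_right_model(list(s), n_states = 5, n_components = 1, seed = 1)
  # state means equal the pooled 10-sample segment means exactly
  for (i in 1:5)
    expect_equal(m$emissions[[i]]$means[1, 1],
                 mean(s[((i - 1) * 10 + 1):(i * 10), 1]), tolerance = 1e-12)
  # interior rows: exactly two nonzeros of 0.5 each
  for (i in 1:4) {
    expect_identical(which(m$trans[i, ] != 0), c(i, i + 1L))
    expect_equal(unname(m$trans[i, c(i, i + 1L)]), c(0.5, 0.5))
  }
  expect_equal(unname(m$trans[5, ]), c(0, 0, 0, 0, 1))   # absorbing last row
  expect_equal(m$start, c(1, 0, 0, 0, 0))
  expect_equal(m$end, c(0, 0, 0, 0, 1))
  # wrap variant: last row splits between self-loop and wrap edge
  w <- init_left_right_model(list(s), 5, 1, wrap_edge = TRUE,
                             free_ends = TRUE, seed = 1)
  expect_equal(unname(w$trans[5, ]), c(0.5, 0, 0, 0, 0.5))
  expect_equal(w$start, rep(0.2, 5))
  expect_error(init_left_right_model(list(s[1:3, , drop = FALSE]), 5, 1),
               "fewer than")
})

test_that("forward log-likelihood matches exhaustive enumeration", {
  rng <- rng_stream(31)
  for (i in 1:25) {
    with_rng(rng, {
      n <- sample(2:4, 1)
      Tn <- sample(2:6, 1)
      d <- sample(1:2, 1)
      model <- random_toy_model(n, d, k = sample(1:2, 1),
                                wrap = runif(1) < 0.5,
                                free_ends = runif(1) < 0.5)
      X <- matrix(rnorm(Tn * d), Tn, d)
    })
    expect_equal(loglik(model, X), oracle_loglik(model, X), tolerance = 1e-9)
  }
  # single-state, single-component model: plain sum of Gaussian log-densities
  m1 <- random_toy_model(1, 1, 1)
  x <- matrix(c(0.3, -1, 2), 3, 1)
  expect_equal(loglik(m1, x),
               sum(dnorm(x, m1$emissions[[1]]$means[1, 1],
                         sqrt(m1$emissions[[1]]$vars[1, 1]), log = TRUE)),
               tolerance = 1e-9)
  # permuting mixture components leaves the likelihood unchanged
  m2 <- random_toy_model(2, 1, k = 2, free_ends = TRUE)
  m2p <- m2
  m2p$emissions <- lapply(m2$emissions, function(e)
    list(weights = rev(e$weights), means = e$means[2:1, , drop = FALSE],
         vars = e$vars[2:1, , drop = FALSE]))
  X <- matrix(c(0.5, -0.2, 1.4, 0.1), 4, 1)
  expect_equal(loglik(m2, X), loglik(m2p, X), tolerance = 1e-10)
})

test_that("Viterbi equals brute-force path maximization and breaks ties low", {
  rng <- rng_stream(77)
  for (i in 1:25) {
    with_rng(rng, {
      n <- sample(2:3, 1)
      Tn <- sample(3:6, 1)
      model <- random_toy_model(n, 1, 1, wrap = runif(1) < 0.5,
                                free_ends = TRUE)
      X <- matrix(rnorm(Tn), Tn, 1)
    })
    expect_identical(as.vector(viterbi_decode(model, X)),
                     as.vector(oracle_viterbi(model, X)))
  }
  # single-state model decodes to a constant path
  m1 <- random_toy_model(1, 1, 1)
  expect_identical(as.vector(viterbi_decode(m1, matrix(0, 4, 1))),
                   rep(1L, 4))
  # exact tie between two states: identical emissions, symmetric
  # transitions; the lowest state index wins everywhere
  tie <- random_toy_model(2, 1, 1, free_ends = TRUE)
  tie$trans <- matrix(0.5, 2, 2)
  tie$start <- c(0.5, 0.5); tie$end <- c(0.5, 0.5)
  tie$emissions[[2]] <- tie$emissions[[1]]
  expect_identical(as.vector(viterbi_decode(tie, matrix(c(0, 1, -1), 3, 1))),
                   rep(1L, 3))
})

test_that("one Baum-Welch iteration matches posterior re-estimation from scratch", {
  rng <- rng_stream(15)
  X <- matrix(with_rng(rng, rnorm(5)), 5, 1)
  model <- with_rng(rng, random_toy_model(2, 1, 1))
  # exact posteriors by path enumeration (end-weighted path measure)
  pp <- oracle_path_logprobs(model, X)
  w <- exp(pp$logprobs - max(pp$logprobs))
  w <- w / sum(w)
  paths <- pp$paths
  n <- 2; Tn <- 5
  gamma <- sapply(1:n, function(i) colSums(w * (paths == i)))  # Tn x n
  xi <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    for (t in 1:(Tn - 1))
      xi[i, j] <- xi[i, j] + sum(w[paths[, t] == i & paths[, t + 1] == j])
  A_exp <- xi / rowSums(xi)
  A_exp[is.nan(A_exp)] <- model$trans[is.nan(A_exp)]
  mu_exp <- colSums(gamma * as.vector(X)) / colSums(gamma)
  var_exp <- pmax(colSums(gamma * as.vector(X)^2) / colSums(gamma) - mu_exp^2,
                  1e-6)
  bw <- baum_welch(model, list(X), max_iter = 1)
  expect_equal(bw$model$trans, A_exp, tolerance = 1e-10)
  for (i in 1:n) {
    expect_equal(bw$model$emissions[[i]]$means[1, 1], mu_exp[i],
                 tolerance = 1e-10)
    expect_equal(bw$model$emissions[[i]]$vars[1, 1], var_exp[i],
                 tolerance = 1e-10)
  }
  expect_equal(bw$report$log_likelihood_per_iteration[1],
               oracle_loglik(model, X), tolerance = 1e-9)
})

test_that("Baum-Welch is monotone, capped at ten iterations and a fixed point stops", {
  rng <- rng_stream(55)
  for (i in 1:20) {
    with_rng(rng, {
      n <- sample(2:4, 1)
      wrap <- runif(1) < 0.5
    })
    seqs <- seq_list(rng, 3, 12)
    model <- init_left_right_model(seqs, n, 1, wrap_edge = wrap,
                                   free_ends = wrap, seed = i)
    bw <- baum_welch(model, seqs, max_iter = 10)
    lls <- bw$report$log_likelihood_per_iteration
    expect_lte(bw$report$n_iterations, 10L)
    expect_true(all(diff(lls) >= -1e-6))
    # structural zeros and start/end constraints survive training
    mask <- strideseg:::lr_allowed_mask(n, wrap)
    expect_true(all(bw$model$trans[!mask] == 0))
    expect_equal(unname(rowSums(bw$model$trans)), rep(1, n), tolerance = 1e-9)
    if (!wrap) {
      expect_identical(bw$model$start, c(1, rep(0, n - 1)))
      expect_identical(bw$model$end, c(rep(0, n - 1), 1))
    }
  }
  # re-running on a converged model changes nothing and stops immediately
  seqs <- seq_list(rng_stream(3), 3, 15)
  m0 <- init_left_right_model(seqs, 3, 1, seed = 1)
  fit1 <- baum_welch(m0, seqs, max_iter = 400, tol = 0)
  fit2 <- baum_welch(fit1$model, seqs, max_iter = 10, tol = 1e-4)
  expect_identical(fit2$report$n_iterations, 1L)
  expect_equal(fit2$model$trans, fit1$model$trans, tolerance = 1e-6)
})

test_that("model combination builds the documented flattened structure", {
  rng <- rng_stream(40)
  stride_seqs <- seq_list(rng, 4, 50)
  trans_seqs <- seq_list(rng, 4, 12)
  sm <- baum_welch(init_left_right_model(stride_seqs, 25, 1, seed = 1),
                   stride_seqs, max_iter = 2)$model
  tm <- baum_welch(init_left_right_model(trans_seqs, 5, 1, wrap_edge = TRUE,
                                         free_ends = TRUE, seed = 1),
                   trans_seqs, max_iter = 2)$model
  bouts <- list(
    list(list(class = "transition", features = trans_seqs[[1]]),
         list(class = "stride", features = stride_seqs[[1]]),
         list(class = "stride", features = stride_seqs[[2]]),
         list(class = "transition", features = trans_seqs[[2]])),
    list(list(class = "transition", features = trans_seqs[[3]]),
         list(class = "stride", features = stride_seqs[[3]]),
         list(class = "transition", features = trans_seqs[[4]])))
  cm <- combine_models(tm, sm, bouts)
  expect_identical(dim(cm$trans), c(30L, 30L))
  expect_identical(cm$state_class,
                   rep(c("transition", "stride"), c(5L, 25L)))
  expect_equal(unname(rowSums(cm$trans)), rep(1, 30), tolerance = 1e-12)
  # back-to-back strides put mass on the wrap edge of the stride block
  expect_gt(cm$trans[cm$stride_last_state, cm$stride_first_state], 0)
  expect_error(combine_models(tm, sm, list(list(
    list(class = "transition", features = trans_seqs[[1]])))), "no stride")
})

test_that("stride borders are extracted from class changes and wrap transitions", {
  cm <- toy_combined()
  fs <- 51.2
  # transition-only signal: no strides
  quiet <- matrix(rnorm(30, 0, 0.1), 30, 1)
  res <- predict_strides(cm, quiet, as.vector(quiet), fs)
  expect_identical(nrow(res$strides), 0L)
  # one stride: up (state 2), deep dip (state 3), settle (state 4)
  sig <- c(rep(0, 10), rep(4, 6), rep(-4, 4), rep(2, 6), rep(0, 10))
  res1 <- predict_strides(cm, matrix(sig, ncol = 1), sig, fs)
  expect_identical(nrow(res1$strides), 1L)
  # borders snapped to the signal minima of the flanking runs
  expect_lte(res1$strides[1, 1], 11)
  expect_gte(res1$strides[1, 2], 17)
  # two stride traversals joined by the wrap edge share one border sample
  one <- c(rep(4, 6), rep(-4, 4), rep(2, 6))
  sig2 <- c(rep(0, 10), one, one, rep(0, 10))
  res2 <- predict_strides(cm, matrix(sig2, ncol = 1), sig2, fs)
  expect_identical(nrow(res2$strides), 2L)
  expect_identical(unname(res2$strides[1, 2]), unname(res2$strides[2, 1]))
})

test_that("the fitted segmenter is deterministic and counts transitions per bout", {
  cfg <- gait_config(seed = 19)
  ds <- generate_dataset(2, bout_lengths = c(5, 8), config = cfg)
  f1 <- fit_stride_hmm(ds, n_stride_states = 8, n_transition_states = 3,
                       n_components = 1, seed = 4)
  f2 <- fit_stride_hmm(ds, n_stride_states = 8, n_transition_states = 3,
                       n_components = 1, seed = 4)
  expect_identical(f1$combined$trans, f2$combined$trans)
  expect_identical(f1$combined$emissions, f2$combined$emissions)
  # at least two transition sequences per processed bout
  expect_gte(f1$n_train$transitions, 2L * f1$n_train$bouts)
  expect_error(fit_stride_hmm(list()), "empty")
})
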
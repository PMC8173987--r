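strides_at <- function(starts, dur = 50) cbind(starts, starts + dur)

test_that("walking bouts require four strides and split at rests over 2.5 s", {
  fs <- 51.2
  # three strides only: no bout
  few <- list(left = strides_at(c(0, 100) * 1 + 1), right = strides_at(151))
  expect_identical(nrow(define_walking_bouts(few, fs)), 0L)
  # eight strides with a 3.0 s internal gap: two bouts of four
  gap <- round(3.0 * fs)
  s1 <- strides_at(1 + c(0, 50, 100, 150))
  s2 <- s1 + 201 + gap
  both <- list(left = rbind(s1[c(1, 3), ], s2[c(1, 3), ]),
               right = rbind(s1[c(2, 4), ], s2[c(2, 4), ]))
  wb <- define_walking_bouts(both, fs)
  expect_identical(nrow(wb), 2L)
  expect_identical(attr(wb, "n_strides"), c(4L, 4L))
  # a gap of exactly 2.5 s stays in one bout (boundary inclusive)
  gap2 <- 2.5 * fs
  s2b <- s1 + 200 + gap2   # next start minus previous end is exactly 2.5 s
  both2 <- list(left = rbind(s1[c(1, 3), ], s2b[c(1, 3), ]),
                right = rbind(s1[c(2, 4), ], s2b[c(2, 4), ]))
  wb2 <- define_walking_bouts(both2, fs)
  expect_identical(nrow(wb2), 1L)
  expect_identical(attr(wb2, "n_strides"), 8L)
  expect_error(define_walking_bouts(list(left = strides_at(c(500, 100)),
                                         right = NULL), fs), "sorted")
})

test_that("stride matching applies the +/-3 sample rule to both borders", {
  ref <- strides_at(c(100, 150, 200, 250, 300))
  mm <- match_strides(ref, ref)
  expect_identical(c(mm$tp, mm$fp, mm$fn), c(5L, 0L, 0L))
  # start offset of four samples: that stride fails, both counts suffer
  off <- ref
  off[3, 1] <- off[3, 1] + 4
  mm2 <- match_strides(off, ref)
  expect_identical(c(mm2$tp, mm2$fp, mm2$fn), c(4L, 1L, 1L))
  # offset of exactly three samples still matches
  off3 <- ref
  off3[3, ] <- off3[3, ] + 3
  expect_identical(match_strides(off3, ref)$tp, 5L)
  expect_error(match_strides(ref, ref, tol_samples = -1), ">= 0")
})

test_that("greedy matching equals exhaustive maximum matching on random instances", {
  rng <- rng_stream(99)
  for (i in 1:200) {
    inst <- with_rng(rng, random_matching_instance())
    mm <- match_strides(inst$predicted, inst$reference, 3)
    expect_identical(mm$tp + mm$fn, nrow(inst$reference))
    expect_identical(mm$tp + mm$fp, nrow(inst$predicted))
    compat <- compat_matrix(inst$predicted, inst$reference, 3)
    expect_identical(mm$tp, as.integer(oracle_max_matching(compat)))
  }
})

test_that("precision, recall and F1 follow their formulas with degenerate guards", {
  m <- compute_metrics(5, 1, 2)
  expect_equal(m$precision, 5 / 6)
  expect_equal(m$recall, 5 / 7)
  expect_equal(m$f1, 10 / 13)
  expect_false(m$degenerate)
  z <- compute_metrics(0, 0, 0)
  expect_identical(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  expect_true(z$degenerate)
  for (n in c(1, 7, 100)) {
    p <- compute_metrics(n, 0, 0)
    expect_identical(c(p$precision, p$recall, p$f1), c(1, 1, 1))
  }
  expect_error(compute_metrics(-1, 0, 0), ">= 0")
})

test_that("bout-length groups pool counts per bin", {
  df <- data.frame(n_strides = c(15, 16, 40, 75, 300),
                   tp = c(10, 14, 35, 70, 290),
                   fp = c(2, 1, 3, 2, 4),
                   fn = c(5, 2, 5, 5, 10))
  g <- group_metrics_by_bout_length(df)
  expect_identical(g$group[1], "4<=N<=15")
  expect_identical(g$group[2], "15<N<=30")
  expect_identical(nrow(g), 5L)            # empty 30<N<=50? no: 40 present
  expect_identical(g$tp[g$group == "N>200"], 290)
  # single bout: group metrics equal the bout's own metrics
  one <- group_metrics_by_bout_length(df[1, ])
  m1 <- compute_metrics(10, 2, 5)
  expect_equal(one$f1, m1$f1)
  # pooled counts are plain sums
  two <- group_metrics_by_bout_length(
    data.frame(n_strides = c(5, 10), tp = c(3, 4), fp = c(1, 0), fn = c(2, 6)))
  expect_identical(c(two$tp, two$fp, two$fn), c(7, 1, 8))
})

test_that("subject folds are disjoint, exhaustive and near-equal", {
  ids <- sprintf("P%02d", 1:28)
  folds <- make_subject_folds(ids, k = 4, seed = 3)
  sizes <- vapply(folds, function(f) length(f$test), integer(1))
  expect_identical(sizes, rep(7L, 4L))
  expect_setequal(unlist(lapply(folds, `[[`, "test")), ids)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_setequal(c(f$train, f$test), ids)
  }
  inner <- make_subject_folds(ids, k = 4, seed = 3, inner_k = 2)
  for (f in inner)
    for (g in f$inner)
      expect_true(all(c(g$train, g$test) %in% f$train))
  expect_error(make_subject_folds(ids[1:3], k = 4), "exceeds")
})

test_that("the full hyperparameter grid enumerates 720 configurations", {
  g <- hyperparameter_grid()
  expect_identical(nrow(g), 720L)          # 3 * 3 * 4 * 5 * 4
  expect_identical(anyDuplicated(g[, c("window_ms", "gmm_components",
                                       "stride_states",
                                       "transition_states")]) > 0, TRUE)
})

test_that("grid search ranks configurations, skips failures and is deterministic", {
  cfg <- gait_config(seed = 31)
  ds <- generate_dataset(4, bout_lengths = c(5, 6), config = cfg)
  grid <- hyperparameter_grid(window_ms = 220,
                              feature_sets = list(c("raw", "grad")),
                              gmm_components = 1,
                              stride_states = c(8, 1000),   # 1000 cannot train
                              transition_states = 3)
  folds <- make_subject_folds(vapply(ds, `[[`, character(1), "subject_id"),
                              k = 2, seed = 1)
  res1 <- grid_search(grid, folds, ds, seed = 5)
  res2 <- grid_search(grid, folds, ds, seed = 5)
  expect_identical(res1$table$mean_f1, res2$table$mean_f1)
  expect_identical(res1$best$stride_states, 8)
  expect_true(is.na(res1$table$mean_f1[res1$table$stride_states == 1000]))
  single <- grid_search(grid[1, , drop = FALSE], folds, ds, seed = 5)
  expect_identical(single$best$stride_states, 8)
})
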
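# Shared in-code fixtures.

make_recording <- function(n = 1000, fs = 102.4, seed = 1) {
  rng <- rng_stream(seed)
  df <- with_rng(rng, data.frame(
    acc_ml = rnorm(n), acc_pa = rnorm(n), acc_si = rnorm(n, 9.81),
    gyr_ml = rnorm(n, 0, 100), gyr_pa = rnorm(n), gyr_si = rnorm(n)))
  imu_recording(df, fs = fs)
}

flat_recording <- function(n, fs = 102.4, gyr = 0, acc = c(0, 0, 9.81)) {
  imu_recording(data.frame(acc_ml = rep(acc[1], n), acc_pa = rep(acc[2], n),
                           acc_si = rep(acc[3], n), gyr_ml = rep(gyr, n),
                           gyr_pa = 0, gyr_si = 0), fs = fs)
}

# minimal combined model with near-deterministic emissions, used to exercise
# border extraction without training: one transition state around 0, three
# stride states around (4, -4, 2) on a single feature
toy_combined <- function() {
  em <- function(mu) list(weights = 1, means = matrix(mu, 1, 1),
                          vars = matrix(0.25, 1, 1))
  m <- 1L; n <- 3L
  trans <- rbind(c(0.90, 0.10, 0, 0),
                 c(0, 0.60, 0.40, 0),
                 c(0, 0, 0.60, 0.40),
                 c(0.25, 0.15, 0, 0.60))   # stride_last -> wrap or exit
  structure(list(trans = trans, state_class = c("transition", rep("stride", n)),
                 m = m, n = n, stride_first_state = 2L, stride_last_state = 4L,
                 emissions = list(em(0), em(4), em(-4), em(2)),
                 start = c(0.7, 0.1, 0.1, 0.1), end = c(0.7, 0.1, 0.1, 0.1)),
            class = "combined_hmm")
}
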
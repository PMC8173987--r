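#' @keywords internal
"_PACKAGE"

## numerically stable log(sum(exp(x))); -Inf inputs are true zeros
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

#' Create an isolated random-number stream
#'
#' All stochastic operations in strideseg draw from an explicit stream object
#' instead of the global RNG, so that generating data, initializing models and
#' shuffling folds never interfere with each other or with user code.
#'
#' @param seed Integer seed.
#' @return An object of class `"rng_stream"`.
#' @export
rng_stream <- function(seed) {
  stopifnot_scalar(seed, "seed")
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

#' Evaluate an expression under a stream's RNG state
#'
#' Temporarily installs the stream's state as the active RNG, evaluates
#' `expr`, captures the advanced state back into the stream and restores the
#' global RNG state, so package randomness never leaks into user code.
#'
#' @param rng An [rng_stream()].
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_rng <- function(rng, expr) {
  stopifnot(inherits(rng, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

## draw a fresh integer seed from a stream (for sub-operations)
spawn_seed <- function(rng) {
  with_rng(rng, sample.int(.Machine$integer.max - 1L, 1L))
}

## intervals: 2-column matrices (start, end), 1-based inclusive
as_interval_matrix <- function(x) {
  if (is.null(x) || length(x) == 0L)
    return(matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (is.vector(x)) x <- matrix(x, ncol = 2L, byrow = TRUE)
  storage.mode(x) <- "double"
  colnames(x) <- c("start", "end")
  x
}
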
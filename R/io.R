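## IMU stream container and on-disk formats.
##
## The CSV dialect is fixed: one header row
##   time_s,acc_ml,acc_pa,acc_si,gyr_ml,gyr_pa,gyr_si
## with acceleration in m/s^2, angular velocity in deg/s and time in seconds
## from recording start. Annotations travel as JSON with 0-based inclusive
## sample indices; in-memory objects use 1-based inclusive indices.

IMU_COLUMNS <- c("time_s", "acc_ml", "acc_pa", "acc_si", "gyr_ml", "gyr_pa", "gyr_si")

#' Construct a body-frame IMU recording
#'
#' @param data Data frame with columns `time_s`, `acc_ml`, `acc_pa`, `acc_si`
#'   (m/s^2), `gyr_ml`, `gyr_pa`, `gyr_si` (deg/s). `time_s` may be omitted and
#'   is then derived from `fs`.
#' @param fs Sampling rate in Hz.
#' @param foot `"left"` or `"right"` (informational tag).
#' @return An object of class `"imu_recording"`.
#' @export
imu_recording <- function(data, fs, foot = c("left", "right")) {
  foot <- match.arg(foot)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  data <- as.data.frame(data)
  if (!"time_s" %in% names(data))
    data$time_s <- (seq_len(nrow(data)) - 1) / fs
  missing <- setdiff(IMU_COLUMNS, names(data))
  if (length(missing))
    stop("missing channel(s): ", paste(missing, collapse = ", "), call. = FALSE)
  data <- data[, IMU_COLUMNS]
  n <- nrow(data)
  if (n > 1L) {
    dt <- diff(data$time_s)
    if (any(dt <= 0)) stop("time_s must be strictly increasing", call. = FALSE)
  }
  structure(list(data = data, fs = fs, foot = foot), class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s foot, %d samples @ %.4g Hz (%.1f s)\n",
              x$foot, nrow(x$data), x$fs, nrow(x$data) / x$fs))
  invisible(x)
}

#' @export
length.imu_recording <- function(x) nrow(x$data)

#' Read an IMU stream from CSV
#'
#' Validates the exact column sequence and strict monotone time; the sampling
#' rate is inferred from the median time step and must be constant within 1%.
#'
#' @param path Path to a CSV file in the strideseg dialect.
#' @param foot Foot tag to attach (not stored in the CSV).
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, foot = "left") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  if (length(header) != length(IMU_COLUMNS) || any(header != IMU_COLUMNS)) {
    bad <- if (length(header) == length(IMU_COLUMNS))
      IMU_COLUMNS[which(header != IMU_COLUMNS)[1]] else "header"
    stop(sprintf("malformed IMU CSV header (expected column '%s'): %s",
                 bad, paste(header, collapse = ",")), call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "numeric")
  if (nrow(df) == 0L)
    return(structure(list(data = df, fs = NA_real_, foot = foot),
                     class = "imu_recording"))
  if (nrow(df) > 1L) {
    dt <- diff(df$time_s)
    if (any(dt <= 0)) stop("time_s must be strictly increasing", call. = FALSE)
    med <- stats::median(dt)
    if (any(abs(dt - med) > 0.01 * med))
      stop("sampling interval not constant within 1%", call. = FALSE)
    fs <- 1 / med
  } else {
    fs <- NA_real_
  }
  imu_recording(df, fs = if (is.na(fs)) 1 else fs, foot = foot)
}

#' Write an IMU stream to CSV
#'
#' Deterministic byte output: fixed column order and `%.12g` float formatting,
#' so identical recordings produce identical files.
#'
#' @param recording An [imu_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(recording, path) {
  stopifnot(inherits(recording, "imu_recording"))
  df <- recording$data
  lines <- paste(IMU_COLUMNS, collapse = ",")
  if (nrow(df) > 0L) {
    cols <- vapply(IMU_COLUMNS, function(cn) sprintf("%.12g", df[[cn]]),
                   character(nrow(df)))
    if (nrow(df) == 1L) cols <- matrix(cols, nrow = 1L)
    lines <- c(lines, apply(cols, 1L, paste, collapse = ","))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

validate_stride_matrix <- function(strides, n_samples = Inf, what = "stride") {
  strides <- as_interval_matrix(strides)
  if (nrow(strides) == 0L) return(strides)
  if (any(strides[, 1] < 1) || any(strides[, 2] > n_samples))
    stop(what, " interval outside recording", call. = FALSE)
  if (any(strides[, 1] >= strides[, 2]))
    stop(what, " interval with start >= end", call. = FALSE)
  if (is.unsorted(strides[, 1]))
    stop(what, " intervals must be sorted by start", call. = FALSE)
  if (nrow(strides) > 1L) {
    overlap <- strides[-1L, 1] < strides[-nrow(strides), 2]
    if (any(overlap))
      stop(what, " intervals overlap beyond a shared border sample", call. = FALSE)
  }
  strides
}

#' Construct a stride/bout annotation document
#'
#' Holds per-foot stride intervals and walking-bout intervals as 1-based
#' inclusive sample index pairs, plus the sampling rate they refer to.
#' A stride `[a, b]` owns samples `a..b`; consecutive strides of one foot may
#' share exactly the border sample `b`.
#'
#' @param strides Named list with elements `left` and `right`, each a 2-column
#'   matrix (start, end) or `NULL`.
#' @param bouts 2-column matrix of walking-bout intervals (may be empty).
#' @param fs Sampling rate in Hz the indices refer to.
#' @param n_samples Recording length (for validation); `Inf` to skip.
#' @param provenance Free-text origin note.
#' @return An object of class `"gait_annotations"`.
#' @export
gait_annotations <- function(strides, bouts = NULL, fs, n_samples = Inf,
                             provenance = "") {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  strides <- list(left = validate_stride_matrix(strides$left, n_samples),
                  right = validate_stride_matrix(strides$right, n_samples))
  bouts <- as_interval_matrix(bouts)
  if (nrow(bouts) && any(bouts[, 1] > bouts[, 2]))
    stop("bout interval with start > end", call. = FALSE)
  structure(list(sampling_rate_hz = fs, strides = strides, bouts = bouts,
                 provenance = provenance),
            class = "gait_annotations")
}

#' @export
print.gait_annotations <- function(x, ...) {
  cat(sprintf("<gait_annotations> %d left + %d right strides, %d bouts @ %.4g Hz\n",
              nrow(x$strides$left), nrow(x$strides$right), nrow(x$bouts),
              x$sampling_rate_hz))
  invisible(x)
}

#' Read annotations from JSON
#'
#' The JSON document stores 0-based inclusive `[start_sample, end_sample]`
#' pairs; they are converted to 1-based indices on read and validated against
#' the type invariants (start < end, sorted, no overlap beyond shared borders).
#'
#' @param path Path to a JSON annotation document.
#' @return A [gait_annotations()] object.
#' @export
read_annotations <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$sampling_rate_hz))
    stop("annotation document lacks sampling_rate_hz", call. = FALSE)
  fix <- function(m) {
    m <- as_interval_matrix(m)
    m + 1  # 0-based on disk -> 1-based in memory
  }
  gait_annotations(strides = list(left = fix(doc$strides$left),
                                  right = fix(doc$strides$right)),
                   bouts = fix(doc$bouts),
                   fs = doc$sampling_rate_hz,
                   provenance = if (is.null(doc$provenance)) "" else doc$provenance)
}

#' Write annotations to JSON
#'
#' @param doc A [gait_annotations()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(doc, path) {
  stopifnot(inherits(doc, "gait_annotations"))
  unfix <- function(m) {
    m <- unname(as_interval_matrix(m)) - 1  # back to 0-based
    if (nrow(m) == 0L) list() else m
  }
  out <- list(sampling_rate_hz = doc$sampling_rate_hz,
              strides = list(left = unfix(doc$strides$left),
                             right = unfix(doc$strides$right)),
              bouts = unfix(doc$bouts),
              provenance = doc$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
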
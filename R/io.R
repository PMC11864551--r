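#' Construct an acceleration series
#'
#' Canonical in-memory container for per-animal triaxial acceleration: a
#' data frame with columns `animal_id`, `timestamp` (integer seconds,
#' strictly increasing per animal), `ax`, `ay`, `az` (sensor units, carried
#' opaquely) and a derived `segment` column identifying maximal contiguous
#' runs. Any inter-sample interval different from the nominal sampling
#' period starts a new segment; windows never span segments.
#'
#' Sub-second timestamps are truncated to the second: both data streams the
#' pipeline consumes are coded at 1 Hz, so behaviours shorter than one
#' second are unrepresentable.
#'
#' @param df data frame with columns `animal_id`, `timestamp`, `ax`, `ay`, `az`.
#' @param sampling_rate_hz positive sampling rate, default 1.
#' @return an `accel_series` (a sorted data frame with a `segment` column and
#'   a `sampling_rate_hz` attribute).
#' @export
#' @examples
#' s <- accel_series(data.frame(animal_id = "a", timestamp = c(1:3, 10:11),
#'                              ax = 0, ay = 0, az = 1000))
#' table(s$segment)  # gap > 1 s splits into two segments
accel_series <- function(df, sampling_rate_hz = 1) {
  req <- c("animal_id", "timestamp", "ax", "ay", "az")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("format error: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a positive number")
  }
  df <- as.data.frame(df)[, unique(c(req, setdiff(names(df), req)))]
  df$animal_id <- as.character(df$animal_id)
  df$timestamp <- trunc(as.numeric(df$timestamp))
  for (v in c("ax", "ay", "az")) {
    if (!is.numeric(df[[v]])) stop("format error: column ", v, " not numeric")
    if (any(!is.finite(df[[v]]))) {
      stop("non-finite acceleration values in column ", v)
    }
  }
  df <- df[order(df$animal_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  dup <- duplicated(df[, c("animal_id", "timestamp")])
  if (any(dup)) {
    stop("duplicate-timestamp error: ", sum(dup),
         " duplicated (animal, timestamp) record(s), first at animal ",
         df$animal_id[dup][1], " t=", df$timestamp[dup][1])
  }
  period <- 1 / sampling_rate_hz
  new_seg <- c(TRUE, diff(df$timestamp) != period |
                 df$animal_id[-1] != df$animal_id[-nrow(df)])
  if (nrow(df) == 0) new_seg <- logical(0)
  df$segment <- cumsum(new_seg)
  attr(df, "sampling_rate_hz") <- sampling_rate_hz
  class(df) <- c("accel_series", "data.frame")
  df
}

#' Sampling rate of a series
#' @param x an `accel_series` or `labelled_series`.
#' @return sampling rate in Hz.
#' @export
sampling_rate <- function(x) {
  r <- attr(x, "sampling_rate_hz")
  if (is.null(r)) 1 else r
}

#' Read an acceleration stream from delimited text
#'
#' Expects a header row and columns `animal_id`, `timestamp`, `ax`, `ay`,
#' `az`; the delimiter (comma or tab) is auto-detected from the header.
#'
#' @param path file path.
#' @param sampling_rate_hz sampling rate of the stream, default 1 Hz.
#' @param sep field delimiter; `NULL` (default) auto-detects `,` vs tab.
#' @return an [accel_series()].
#' @export
read_accel <- function(path, sampling_rate_hz = 1, sep = NULL) {
  if (is.null(sep)) sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  accel_series(df, sampling_rate_hz = sampling_rate_hz)
}

.detect_sep <- function(path) {
  hdr <- readLines(path, n = 1)
  if (grepl("\t", hdr)) "\t" else ","
}

#' Write an acceleration (or labelled) series as CSV
#'
#' Writes the data columns only (no derived `segment` column) so that
#' `read_accel(write_accel(s))` round-trips exactly.
#'
#' @param series an `accel_series` or `labelled_series`.
#' @param path output file path.
#' @param sep field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_accel <- function(series, path, sep = ",") {
  cols <- intersect(c("animal_id", "timestamp", "ax", "ay", "az", "behaviour"),
                    names(series))
  utils::write.table(as.data.frame(series)[, cols], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a behaviour label table
#'
#' Columns `timestamp`, `behaviour` and optionally `animal_id`; labels must
#' come from [behaviour_levels()] (plus `Unknown`).
#'
#' @inheritParams read_accel
#' @return data frame of labels with truncated integer timestamps.
#' @export
read_labels <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- .detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("timestamp", "behaviour"), names(df))
  if (length(miss) > 0) {
    stop("format error: label file missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df$timestamp <- trunc(as.numeric(df$timestamp))
  .check_vocabulary(df$behaviour)
  df
}

.check_vocabulary <- function(labels) {
  bad <- setdiff(unique(as.character(labels)), .LABEL_LEVELS)
  if (length(bad) > 0) {
    stop("vocabulary error: unknown behaviour label(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Merge behaviour labels onto an acceleration series
#'
#' Inner join on timestamp (and `animal_id` when the label table carries
#' one; required if the series holds more than one animal). Acceleration
#' seconds without a label and labelled seconds without acceleration are
#' dropped; the counts of dropped records are attached as attributes
#' `dropped_accel` / `dropped_labels` and reported via a message.
#'
#' @param accel an [accel_series()].
#' @param labels data frame with `timestamp`, `behaviour`, optionally
#'   `animal_id`.
#' @param verbose message the dropped-record counts, default `TRUE`.
#' @return a `labelled_series`: the series with a `behaviour` factor column
#'   (levels = [behaviour_levels()] plus `Unknown`).
#' @export
merge_labels <- function(accel, labels, verbose = TRUE) {
  stopifnot(inherits(accel, "accel_series"))
  labels <- as.data.frame(labels)
  miss <- setdiff(c("timestamp", "behaviour"), names(labels))
  if (length(miss) > 0) {
    stop("format error: label table missing column(s): ",
         paste(miss, collapse = ", "))
  }
  labels$timestamp <- trunc(as.numeric(labels$timestamp))
  .check_vocabulary(labels$behaviour)
  by_animal <- "animal_id" %in% names(labels)
  if (!by_animal && length(unique(accel$animal_id)) > 1) {
    stop("label table needs an animal_id column when the series holds ",
         "several animals")
  }
  if (by_animal) {
    key_a <- paste(accel$animal_id, accel$timestamp)
    key_l <- paste(as.character(labels$animal_id), labels$timestamp)
  } else {
    key_a <- as.character(accel$timestamp)
    key_l <- as.character(labels$timestamp)
  }
  if (anyDuplicated(key_l)) stop("duplicate-timestamp error in label table")
  idx <- match(key_a, key_l)
  keep <- !is.na(idx)
  if (!any(keep)) stop("merge error: no overlapping timestamps")
  out <- as.data.frame(accel)[keep, , drop = FALSE]
  out$behaviour <- factor(as.character(labels$behaviour)[idx[keep]],
                          levels = .LABEL_LEVELS)
  dropped_accel <- sum(!keep)
  dropped_labels <- nrow(labels) - sum(keep)
  if (verbose) {
    message("merge_labels: kept ", nrow(out), " records; dropped ",
            dropped_accel, " unlabelled acceleration records and ",
            dropped_labels, " labels without acceleration")
  }
  out <- accel_series(out, sampling_rate_hz = sampling_rate(accel))
  out$behaviour <- factor(as.character(out$behaviour), levels = .LABEL_LEVELS)
  attr(out, "dropped_accel") <- dropped_accel
  attr(out, "dropped_labels") <- dropped_labels
  class(out) <- c("labelled_series", class(out))
  out
}

#' Promote a data frame to a labelled series
#'
#' Convenience constructor used by the simulator and by tests: validates the
#' acceleration columns and the `behaviour` vocabulary in one step.
#'
#' @inheritParams accel_series
#' @export
labelled_series <- function(df, sampling_rate_hz = 1) {
  if (!"behaviour" %in% names(df)) stop("missing behaviour column")
  .check_vocabulary(df$behaviour)
  beh <- as.character(df$behaviour)
  out <- accel_series(df[, setdiff(names(df), "behaviour")],
                      sampling_rate_hz = sampling_rate_hz)
  ## accel_series re-sorts; re-attach labels by key
  key_in <- paste(as.character(df$animal_id), trunc(as.numeric(df$timestamp)))
  key_out <- paste(out$animal_id, out$timestamp)
  out$behaviour <- factor(beh[match(key_out, key_in)], levels = .LABEL_LEVELS)
  class(out) <- c("labelled_series", class(out))
  out
}
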
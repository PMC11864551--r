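#' Jerk filter: first difference of acceleration
#'
#' The jerk filter replaces total acceleration by its change per second,
#' which is independent of tag orientation and of the gravitational
#' component -- essential for freely rotating ear tags. For each contiguous
#' segment the per-axis jerk is the first difference, optionally scaled by
#' the sampling rate (at 1 Hz the two conventions coincide; the flag is
#' exposed because the convention is not fixed by common usage). The angle
#' `dtheta` between consecutive 3-D acceleration vectors (degrees, in
#' `[0, 180]`) quantifies directional change and is computed with the
#' numerically stable two-argument arctangent of the cross- and dot-product
#' magnitudes; it is defined as 0 when either vector has zero norm.
#'
#' The jerk series of a segment is one sample shorter than the segment; the
#' returned rows carry the timestamp of the *later* sample of each pair, so
#' that windowing can drop the first sample of each segment and align jerk
#' with raw channels.
#'
#' @param series an [accel_series()] (or `labelled_series`); every segment
#'   must have at least 2 records.
#' @param scale_by_rate multiply differences by the sampling rate so jerk is
#'   a per-second rate, default `TRUE`.
#' @return data frame with `animal_id`, `timestamp`, `segment`, `jx`, `jy`,
#'   `jz`, `dtheta`.
#' @export
#' @examples
#' s <- accel_series(data.frame(animal_id = "a", timestamp = 1:3,
#'                              ax = c(0, 10, 30), ay = 0, az = 0))
#' jerk_filter(s)$jx  # first differences: 10, 20
jerk_filter <- function(series, scale_by_rate = TRUE) {
  stopifnot(inherits(series, "accel_series"))
  if (nrow(series) < 2) stop("insufficient data: need at least 2 records")
  seg_len <- table(series$segment)
  if (any(seg_len < 2)) {
    stop("insufficient data: segment(s) with fewer than 2 records: ",
         paste(names(seg_len)[seg_len < 2], collapse = ", "))
  }
  rate <- sampling_rate(series)
  fac <- if (scale_by_rate) rate else 1
  ## last row of each segment pairs with the first of the next: mask those out
  n <- nrow(series)
  same_seg <- series$segment[-1] == series$segment[-n]
  d <- function(v) (v[-1] - v[-n])[same_seg] * fac
  jx <- d(series$ax); jy <- d(series$ay); jz <- d(series$az)
  a1 <- cbind(series$ax, series$ay, series$az)[-n, , drop = FALSE][same_seg, , drop = FALSE]
  a2 <- cbind(series$ax, series$ay, series$az)[-1, , drop = FALSE][same_seg, , drop = FALSE]
  dtheta <- .angle_deg(a1, a2)
  data.frame(
    animal_id = series$animal_id[-1][same_seg],
    timestamp = series$timestamp[-1][same_seg],
    segment = series$segment[-1][same_seg],
    jx = jx, jy = jy, jz = jz, dtheta = dtheta
  )
}

## angle (degrees) between paired rows of two 3-column matrices
.angle_deg <- function(a, b) {
  dot <- rowSums(a * b)
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  cross <- sqrt(cx^2 + cy^2 + cz^2)
  ang <- atan2(cross, dot) * 180 / pi
  zero <- rowSums(a^2) == 0 | rowSums(b^2) == 0
  ang[zero] <- 0
  ang
}

#' Overall dynamic body acceleration (ODBA)
#'
#' ODBA separates each axis into a static (gravitational) component --
#' estimated as a centred moving average over a smoothing window (3 s by
#' default) -- and a dynamic component (raw minus static), and sums the
#' absolute dynamic components across the three axes. The moving average
#' shrinks symmetrically at segment edges rather than padding, so adding a
#' constant vector to all samples leaves ODBA unchanged everywhere,
#' including the edges. ODBA is non-negative and identically zero on a
#' constant signal; it is a standard proxy for movement intensity.
#'
#' @param series an [accel_series()].
#' @param smoothing_window_s odd positive smoothing window in seconds,
#'   default 3.
#' @return numeric vector of ODBA values, one per record of `series`.
#' @export
#' @examples
#' s <- accel_series(data.frame(animal_id = "a", timestamp = 1:6,
#'                              ax = c(0, 300, 0, 300, 0, 300),
#'                              ay = 0, az = 0))
#' odba(s)  # 0 200 200 200 200 0
odba <- function(series, smoothing_window_s = 3) {
  stopifnot(inherits(series, "accel_series"))
  if (!is.numeric(smoothing_window_s) || length(smoothing_window_s) != 1 ||
      smoothing_window_s <= 0) {
    stop("parameter error: smoothing window must be a positive number")
  }
  w <- as.integer(round(smoothing_window_s * sampling_rate(series)))
  if (w < 1) stop("parameter error: smoothing window shorter than one sample")
  if (w %% 2 == 0) stop("parameter error: smoothing window must span an odd ",
                        "number of samples")
  h <- (w - 1L) %/% 2L
  out <- numeric(nrow(series))
  for (seg in split(seq_len(nrow(series)), series$segment)) {
    n <- length(seg)
    dyn <- 0
    for (v in c("ax", "ay", "az")) {
      x <- series[[v]][seg]
      stat <- .centred_mean(x, h)
      dyn <- dyn + abs(x - stat)
    }
    out[seg] <- dyn
  }
  out
}

## centred moving average with symmetric shrink at the edges: at index i the
## half-width is min(h, i - 1, n - i)
.centred_mean <- function(x, h) {
  n <- length(x)
  if (h == 0 || n == 1) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  k <- pmin(h, i - 1L, n - i)
  (cs[i + k + 1L] - cs[i - k]) / (2 * k + 1)
}

#' Append signal transforms to a series
#'
#' Adds `jx`, `jy`, `jz`, `dtheta` (NA on the first record of each segment,
#' where the backward difference is undefined) and `odba` columns.
#'
#' @inheritParams jerk_filter
#' @param smoothing_window_s ODBA smoothing window in seconds.
#' @return the input data frame with transform columns appended.
#' @export
add_transforms <- function(series, smoothing_window_s = 3,
                           scale_by_rate = TRUE) {
  jk <- jerk_filter(series, scale_by_rate = scale_by_rate)
  out <- as.data.frame(series)
  key <- paste(out$animal_id, out$timestamp)
  idx <- match(key, paste(jk$animal_id, jk$timestamp))
  for (v in c("jx", "jy", "jz", "dtheta")) out[[v]] <- jk[[v]][idx]
  out$odba <- odba(series, smoothing_window_s = smoothing_window_s)
  out
}
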
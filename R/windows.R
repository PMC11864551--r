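#' Majority label of a window
#'
#' The behaviour occupying the most seconds in a window becomes the
#' window's class; this mirrors the applied situation where behaviours are
#' not known a priori and windows may mix behaviours. Ties are broken by
#' the earliest first occurrence within the window, which is deterministic
#' and order-stable.
#'
#' @param labels non-empty character (or factor) vector of per-second labels.
#' @return list with `label` (character) and `purity` (fraction of seconds
#'   carrying the majority label, in `(0, 1]`).
#' @export
#' @examples
#' majority_label(c(rep("Walking", 15), rep("Standing", 15)))  # tie -> Walking
majority_label <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop("empty label sequence")
  f <- factor(labels, levels = unique(labels))
  tab <- tabulate(f)
  i <- which.max(tab)
  list(label = levels(f)[i], purity = tab[i] / length(labels))
}

#' Cut a series into fixed-length overlapping windows
#'
#' Windows tile each contiguous segment from its start with stride
#' `window_s * (1 - overlap)`; the terminal remainder shorter than the
#' window is discarded, and no window ever spans a gap between segments. A
#' segment offering `N` usable samples yields `floor((N - W) / step) + 1`
#' windows (0 if `N < W`). Each window records the majority behaviour and
#' its purity; on an unlabelled series every window is labelled `Unknown`
#' (prediction mode).
#'
#' When jerk channels (`xj`, `yj`, `zj`, `dtheta`) are requested the first
#' sample of each segment is dropped from *all* channels so the jerk series
#' (one sample shorter) aligns with the raw channels; `N` above then equals
#' the segment length minus one.
#'
#' @param series an [accel_series()] or `labelled_series`.
#' @param window_s window length in seconds; `window_s * rate` must be an
#'   integer of at least 4.
#' @param overlap fractional overlap of consecutive windows in `[0, 1)`,
#'   default 0.5; the implied step must be a whole number of samples.
#' @param channels channels to slice: any of `"x" "y" "z" "xj" "yj" "zj"
#'   "dtheta"`. Default: the three raw axes and their jerk counterparts.
#' @param scale_by_rate passed to [jerk_filter()].
#' @return a `window_set`: list with `meta` (one row per window: `animal_id`,
#'   `start_time`, `segment`, `majority_label`, `label_purity`) and
#'   `channels` (named list of `window_len x n_windows` matrices), plus
#'   attributes `window_s`, `overlap`, `step_s`, `sampling_rate_hz`.
#' @export
make_windows <- function(series, window_s, overlap = 0.5,
                         channels = c("x", "y", "z", "xj", "yj", "zj"),
                         scale_by_rate = TRUE) {
  stopifnot(inherits(series, "accel_series"))
  rate <- sampling_rate(series)
  W <- window_s * rate
  if (abs(W - round(W)) > 1e-9 || round(W) < 4) {
    stop("window_s times the sampling rate must be an integer >= 4")
  }
  W <- as.integer(round(W))
  if (!is.numeric(overlap) || overlap < 0 || overlap >= 1) {
    stop("overlap must be in [0, 1)")
  }
  step <- W * (1 - overlap)
  if (abs(step - round(step)) > 1e-9 || round(step) < 1) {
    stop("window_s * (1 - overlap) must be a whole positive number of samples")
  }
  step <- as.integer(round(step))
  known <- c("x", "y", "z", "xj", "yj", "zj", "dtheta")
  bad <- setdiff(channels, known)
  if (length(bad) > 0) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  need_jerk <- any(channels %in% c("xj", "yj", "zj", "dtheta"))

  labelled <- "behaviour" %in% names(series)
  src_raw <- c(x = "ax", y = "ay", z = "az")
  meta_list <- list()
  chan_mats <- stats::setNames(vector("list", length(channels)), channels)
  for (ch in channels) chan_mats[[ch]] <- vector("list", 0)

  segs <- split(seq_len(nrow(series)), series$segment)
  for (seg_idx in segs) {
    n0 <- length(seg_idx)
    chans <- list()
    if (need_jerk) {
      if (n0 < 2) next
      sub <- series[seg_idx, , drop = FALSE]
      class(sub) <- c("accel_series", "data.frame")
      attr(sub, "sampling_rate_hz") <- rate
      jk <- jerk_filter(sub, scale_by_rate = scale_by_rate)
      usable <- seg_idx[-1]
      for (ch in channels) {
        chans[[ch]] <- switch(ch,
          x = series$ax[usable], y = series$ay[usable], z = series$az[usable],
          xj = jk$jx, yj = jk$jy, zj = jk$jz, dtheta = jk$dtheta)
      }
    } else {
      usable <- seg_idx
      for (ch in channels) chans[[ch]] <- series[[src_raw[[ch]]]][usable]
    }
    N <- length(usable)
    if (N < W) next
    nwin <- (N - W) %/% step + 1L
    starts <- (seq_len(nwin) - 1L) * step + 1L
    idx <- outer(0:(W - 1L), starts, `+`)  # W x nwin sample indices
    for (ch in channels) {
      m <- matrix(chans[[ch]][idx], nrow = W)
      chan_mats[[ch]] <- c(chan_mats[[ch]], list(m))
    }
    if (labelled) {
      labs <- as.character(series$behaviour[usable])
      maj <- lapply(starts, function(s) majority_label(labs[s:(s + W - 1L)]))
      mlab <- vapply(maj, `[[`, character(1), "label")
      mpur <- vapply(maj, `[[`, numeric(1), "purity")
    } else {
      mlab <- rep("Unknown", nwin)
      mpur <- rep(1, nwin)
    }
    meta_list[[length(meta_list) + 1L]] <- data.frame(
      animal_id = series$animal_id[usable[1]],
      start_time = series$timestamp[usable][starts],
      segment = series$segment[usable[1]],
      majority_label = mlab,
      label_purity = mpur,
      stringsAsFactors = FALSE
    )
  }

  if (length(meta_list) == 0) {
    warning("no segment long enough for a ", window_s, " s window; ",
            "returning an empty window set")
    meta <- data.frame(animal_id = character(0), start_time = numeric(0),
                       segment = integer(0), majority_label = character(0),
                       label_purity = numeric(0))
    mats <- stats::setNames(
      lapply(channels, function(ch) matrix(numeric(0), nrow = W, ncol = 0)),
      channels)
  } else {
    meta <- do.call(rbind, meta_list)
    mats <- lapply(chan_mats, function(lst) do.call(cbind, lst))
  }
  meta$majority_label <- factor(meta$majority_label, levels = .LABEL_LEVELS)
  out <- list(meta = meta, channels = mats)
  attr(out, "window_s") <- window_s
  attr(out, "overlap") <- overlap
  attr(out, "step_s") <- step / rate
  attr(out, "sampling_rate_hz") <- rate
  class(out) <- "window_set"
  out
}

#' @export
print.window_set <- function(x, ...) {
  cat("window_set:", nrow(x$meta), "windows of", attr(x, "window_s"),
      "s (overlap", attr(x, "overlap"), "), channels:",
      paste(names(x$channels), collapse = ", "), "\n")
  if (nrow(x$meta) > 0) {
    print(table(droplevels(x$meta$majority_label)))
  }
  invisible(x)
}

#' Number of windows in a window set
#' @param ws a `window_set`.
#' @return integer count.
#' @export
n_windows <- function(ws) nrow(ws$meta)
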
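## the 11 per-channel summary statistics, in stable column order
.STAT_NAMES <- c("mean", "median", "sd", "var", "skew", "kurt",
                 "min", "max", "range", "iqr", "rms")

#' Summary statistics of one window channel
#'
#' The 11 statistics computed per channel and window: mean, median,
#' standard deviation, variance (sample, n-1), skewness, kurtosis, minimum,
#' maximum, range, interquartile range and root-mean-square. Skewness is the
#' third standardised central moment and kurtosis the raw (non-excess)
#' fourth; both are imputed as 0 on a zero-variance window so every feature
#' stays finite. Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param values numeric vector of at least 4 values.
#' @return named numeric vector of length 11.
#' @export
#' @examples
#' window_statistics(rep(7, 10))  # degenerate window: dispersion all 0
window_statistics <- function(values) {
  if (length(values) < 4) stop("insufficient data: need at least 4 values")
  if (any(!is.finite(values))) stop("non-finite values in window")
  n <- length(values)
  m <- mean(values)
  cent <- values - m
  m2 <- mean(cent^2)
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), names = FALSE,
                       type = 7)
  mn <- min(values); mx <- max(values)
  ## zero-variance guard with a relative tolerance: a constant window may
  ## leave a tiny rounding residual in m2
  zero <- m2 <= 1e-20 * max(1, m^2)
  c(mean = m,
    median = q[2],
    sd = if (zero) 0 else sqrt(m2 * n / (n - 1)),
    var = if (zero) 0 else m2 * n / (n - 1),
    skew = if (zero) 0 else mean(cent^3) / m2^1.5,
    kurt = if (zero) 0 else mean(cent^4) / m2^2,
    min = mn, max = mx, range = mx - mn,
    iqr = q[3] - q[1],
    rms = sqrt(mean(values^2)))
}

#' Raw periodogram of one window channel
#'
#' Spectral power at every nonzero Fourier frequency `k / W` (cycles per
#' sample, reported in Hz), `k = 1..floor(W/2)`; the DC component is
#' excluded by mean-centring before the transform. No ordinate lies above
#' the Nyquist frequency (half the sampling rate) -- the physical ceiling
#' of a sampled signal. Normalisation satisfies Parseval's identity: the
#' ordinates sum to the sum of squared mean-centred values.
#'
#' @param values numeric vector, window length at least 4.
#' @param sampling_rate_hz sampling rate, default 1.
#' @return named numeric vector of `floor(length(values)/2)` powers; names
#'   give the frequency index `k`.
#' @export
#' @examples
#' x <- sin(2 * pi * 0.25 * (0:31))
#' which.max(spectral_power(x))  # k = 8: the 0.25 Hz Fourier frequency
spectral_power <- function(values, sampling_rate_hz = 1) {
  n <- length(values)
  if (n < 4) stop("insufficient data: need at least 4 values")
  xc <- values - mean(values)
  P <- Mod(stats::fft(xc))^2 / n
  kmax <- n %/% 2L
  pw <- P[2:(kmax + 1L)]
  ## fold in the conjugate frequencies (self-conjugate Nyquist bin at even n)
  if (n %% 2L == 0L) {
    if (kmax >= 2L) pw[1:(kmax - 1L)] <- pw[1:(kmax - 1L)] + P[n:(n - kmax + 2L)]
  } else {
    pw <- pw + P[n:(n - kmax + 1L)]
  }
  names(pw) <- as.character(seq_len(kmax))
  pw
}

## vectorised statistics over the columns of a W x nwin matrix;
## returns an 11 x nwin matrix (rows in .STAT_NAMES order)
.channel_stats <- function(M) {
  n <- nrow(M)
  cm <- colMeans(M)
  S <- M - rep(cm, each = n)
  m2 <- colMeans(S^2)
  zero <- m2 <= 1e-20 * pmax(1, cm^2)
  m2s <- ifelse(zero, 1, m2)  # safe denominator
  q <- apply(M, 2, stats::quantile, probs = c(0, 0.25, 0.5, 0.75, 1),
             names = FALSE, type = 7)
  if (is.null(dim(q))) q <- matrix(q, nrow = 5)
  rbind(mean = cm,
        median = q[3, ],
        sd = ifelse(zero, 0, sqrt(m2 * n / (n - 1))),
        var = ifelse(zero, 0, m2 * n / (n - 1)),
        skew = ifelse(zero, 0, colMeans(S^3) / m2s^1.5),
        kurt = ifelse(zero, 0, colMeans(S^4) / m2s^2),
        min = q[1, ], max = q[5, ], range = q[5, ] - q[1, ],
        iqr = q[4, ] - q[2, ],
        rms = sqrt(colMeans(M^2)))
}

## vectorised periodogram over columns; kmax x nwin matrix
.channel_power <- function(M) {
  n <- nrow(M)
  S <- M - rep(colMeans(M), each = n)
  P <- Mod(stats::mvfft(S))^2 / n
  kmax <- n %/% 2L
  pw <- P[2:(kmax + 1L), , drop = FALSE]
  if (n %% 2L == 0L) {
    if (kmax >= 2L) {
      pw[1:(kmax - 1L), ] <- pw[1:(kmax - 1L), ] +
        P[n:(n - kmax + 2L), , drop = FALSE]
    }
  } else {
    pw <- pw + P[n:(n - kmax + 1L), , drop = FALSE]
  }
  rownames(pw) <- as.character(seq_len(kmax))
  pw
}

#' Build the feature table of a window set
#'
#' One row per window, columns `<stat>_<channel>` for the 11 statistics of
#' every channel followed by `pow<k>_<channel>` for the periodogram
#' ordinate at Fourier frequency `k / W * rate` Hz, `k = 1..floor(W/2)`,
#' then the metadata columns `majority_label`, `animal_id`, `start_time`,
#' `label_purity`. The column set is identical for every row at a fixed
#' window length; rows are ordered by (animal, start time). Extraction is
#' pure: the same window set always yields the identical table.
#'
#' Channel names follow the field convention for freely rotating tags: raw
#' axes `x`, `y`, `z` and their jerk-filtered counterparts `xj`, `yj`,
#' `zj`. ODBA is deliberately not part of the default feature set: it adds
#' no information beyond the per-axis dispersion statistics for
#' classification, though it remains available via [odba()] for reporting.
#'
#' @param ws a `window_set` from [make_windows()].
#' @param stats_fun function mapping a numeric vector to a fixed-length
#'   named statistic vector; default [window_statistics()] (vectorised
#'   internally). Supply your own to change the statistic set.
#' @return a `feature_table` data frame with attributes `feature_cols`,
#'   `window_s`, `sampling_rate_hz`, `channels`.
#' @export
build_feature_table <- function(ws, stats_fun = NULL) {
  stopifnot(inherits(ws, "window_set"))
  if (nrow(ws$meta) == 0) stop("empty window set")
  lens <- unique(vapply(ws$channels, nrow, integer(1)))
  if (length(lens) != 1) {
    stop("consistency error: channels have mixed window lengths: ",
         paste(lens, collapse = ", "))
  }
  chans <- names(ws$channels)
  blocks <- list()
  for (ch in chans) {
    M <- ws$channels[[ch]]
    st <- if (is.null(stats_fun)) .channel_stats(M) else apply(M, 2, stats_fun)
    rownames(st) <- paste0(rownames(st), "_", ch)
    blocks[[length(blocks) + 1L]] <- t(st)
  }
  for (ch in chans) {
    pw <- .channel_power(ws$channels[[ch]])
    rownames(pw) <- paste0("pow", rownames(pw), "_", ch)
    blocks[[length(blocks) + 1L]] <- t(pw)
  }
  feat <- do.call(cbind, blocks)
  out <- data.frame(feat, check.names = FALSE)
  out$majority_label <- ws$meta$majority_label
  out$animal_id <- ws$meta$animal_id
  out$start_time <- ws$meta$start_time
  out$label_purity <- ws$meta$label_purity
  ord <- order(out$animal_id, out$start_time)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "feature_cols") <- colnames(feat)
  attr(out, "window_s") <- attr(ws, "window_s")
  attr(out, "sampling_rate_hz") <- attr(ws, "sampling_rate_hz")
  attr(out, "channels") <- chans
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Feature column names of a feature table
#' @param table a `feature_table` (or any data frame holding one).
#' @return character vector of feature column names (metadata excluded).
#' @export
feature_cols <- function(table) {
  fc <- attr(table, "feature_cols")
  if (!is.null(fc)) return(fc)
  setdiff(names(table),
          c("majority_label", "animal_id", "start_time", "label_purity"))
}

#' Write / read a feature table as CSV with a JSON schema sidecar
#'
#' The CSV is the interchange format between the featurize, train and
#' predict stages; `<path>.schema.json` records the feature columns, window
#' length and sampling rate so that prediction can verify schema
#' compatibility.
#'
#' @param table a `feature_table`.
#' @param path CSV path.
#' @return `path` invisibly (write) / a `feature_table` (read).
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  schema <- list(feature_cols = feature_cols(table),
                 window_s = attr(table, "window_s"),
                 sampling_rate_hz = attr(table, "sampling_rate_hz"),
                 channels = attr(table, "channels"))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  out$majority_label <- factor(out$majority_label, levels = .LABEL_LEVELS)
  sj <- paste0(path, ".schema.json")
  if (file.exists(sj)) {
    schema <- jsonlite::read_json(sj, simplifyVector = TRUE)
    attr(out, "feature_cols") <- schema$feature_cols
    attr(out, "window_s") <- schema$window_s
    attr(out, "sampling_rate_hz") <- schema$sampling_rate_hz
    attr(out, "channels") <- schema$channels
  }
  class(out) <- c("feature_table", "data.frame")
  out
}
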
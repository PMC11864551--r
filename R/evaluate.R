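#' Confusion matrix of actual versus predicted labels
#'
#' Rows are actual classes, columns predicted classes (beware: some metric
#' packages transpose this orientation, a classic source of silent error).
#' Classes with zero support are retained as zero rows so that rare,
#' never-predicted behaviours stay visible.
#'
#' @param actual,predicted equal-length label vectors.
#' @param classes ordered class list; defaults to the classes observed in
#'   either vector, in [behaviour_levels()] order where applicable.
#' @return a `confusion_matrix` (integer matrix with class dimnames).
#' @export
confusion_matrix <- function(actual, predicted, classes = NULL) {
  actual <- as.character(actual)
  predicted <- as.character(predicted)
  if (length(actual) != length(predicted)) {
    stop("input error: actual and predicted differ in length")
  }
  if (is.null(classes)) {
    seen <- unique(c(actual, predicted))
    classes <- c(intersect(.LABEL_LEVELS, seen), setdiff(seen, .LABEL_LEVELS))
  }
  if (length(classes) == 0) stop("input error: empty class list")
  out <- setdiff(unique(c(actual, predicted)), classes)
  if (length(out) > 0) {
    stop("input error: label(s) outside the class list: ",
         paste(out, collapse = ", "))
  }
  m <- table(factor(actual, levels = classes),
             factor(predicted, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(actual = classes, predicted = classes))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Treat a counts matrix as a confusion matrix
#'
#' For matrices entered from published tables: validates squareness,
#' non-negative integer counts and matching dimnames.
#'
#' @param m square numeric matrix, rows = actual, columns = predicted.
#' @return a `confusion_matrix`.
#' @export
as_confusion_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
  if (any(m < 0) || any(m != round(m))) {
    stop("confusion matrix cells must be non-negative integers")
  }
  if (is.null(rownames(m))) stop("confusion matrix needs class dimnames")
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column classes differ")
  }
  storage.mode(m) <- "integer"
  dimnames(m) <- list(actual = rownames(m), predicted = colnames(m))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Per-class and overall classification metrics
#'
#' For each class `i` (one-vs-rest): sensitivity (true-positive rate)
#' `100 * cm[i,i] / rowtotal_i`, specificity (true-negative rate)
#' `100 * (1 - (coltotal_i - cm[i,i]) / (total - rowtotal_i))`, balanced
#' accuracy (their mean -- the performance measure of choice under heavy
#' class imbalance), and the per-class error rate `1 - sensitivity/100`.
#' Overall: accuracy `100 * trace / total`, total error `1 - trace/total`,
#' and an exact (Clopper-Pearson) binomial 95% CI for the overall accuracy.
#'
#' A class that never occurs (zero row total) has undefined sensitivity and
#' is reported as `NA`; a class that occurs but is never predicted gets
#' sensitivity 0, specificity 100 and balanced accuracy exactly 50. All
#' percentages are exact cell-count ratios; rounding is left to
#' presentation (see [round_half_up()]).
#'
#' @param cm a `confusion_matrix`.
#' @return a `class_metrics` object: list with `per_class` (data frame:
#'   `class`, `support`, `sensitivity`, `specificity`, `balanced_accuracy`,
#'   `error_rate`) and `overall` (list: `accuracy_pct`, `total_error`,
#'   `ci_low_pct`, `ci_high_pct`, `n`).
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  diagc <- diag(cm)
  rowt <- rowSums(cm)
  colt <- colSums(cm)
  sens <- ifelse(rowt > 0, 100 * diagc / rowt, NA_real_)
  spec <- ifelse(total - rowt > 0,
                 100 * (1 - (colt - diagc) / (total - rowt)), NA_real_)
  ba <- (sens + spec) / 2
  per_class <- data.frame(
    class = rownames(cm),
    support = as.integer(rowt),
    sensitivity = unname(sens),
    specificity = unname(spec),
    balanced_accuracy = unname(ba),
    error_rate = unname(1 - sens / 100),
    stringsAsFactors = FALSE
  )
  if (any(rowt == 0)) {
    warning("class(es) with zero support: sensitivity undefined for ",
            paste(rownames(cm)[rowt == 0], collapse = ", "))
  }
  ci <- stats::binom.test(sum(diagc), total)$conf.int
  out <- list(per_class = per_class,
              overall = list(accuracy_pct = 100 * sum(diagc) / total,
                             total_error = 1 - sum(diagc) / total,
                             ci_low_pct = 100 * ci[1],
                             ci_high_pct = 100 * ci[2],
                             n = total))
  class(out) <- "class_metrics"
  out
}

#' @export
print.class_metrics <- function(x, digits = 2, ...) {
  pc <- x$per_class
  for (v in c("sensitivity", "specificity", "balanced_accuracy")) {
    pc[[v]] <- round_half_up(pc[[v]], digits)
  }
  pc$error_rate <- round_half_up(pc$error_rate, 3)
  print(pc, row.names = FALSE)
  cat(sprintf("overall accuracy %.1f%% (95%% CI %.1f-%.1f), total error %.3f, n = %d\n",
              x$overall$accuracy_pct, x$overall$ci_low_pct,
              x$overall$ci_high_pct, x$overall$total_error, x$overall$n))
  invisible(x)
}

#' Mean balanced accuracy across classes
#'
#' Unweighted mean of the per-class balanced accuracies -- the headline
#' performance number under class imbalance. Classes with undefined
#' metrics (zero support) are excluded with a warning; a class that occurs
#' but is never predicted contributes exactly 50, never 0.
#'
#' @param x a `class_metrics` or `confusion_matrix`.
#' @return mean balanced accuracy in percent.
#' @export
mean_balanced_accuracy <- function(x) {
  if (inherits(x, "confusion_matrix")) x <- suppressWarnings(class_metrics(x))
  stopifnot(inherits(x, "class_metrics"))
  ba <- x$per_class$balanced_accuracy
  if (anyNA(ba)) {
    warning("excluding ", sum(is.na(ba)),
            " class(es) with undefined balanced accuracy from the mean")
  }
  if (all(is.na(ba))) stop("no class with defined metrics")
  mean(ba, na.rm = TRUE)
}

#' Cohen's unweighted kappa
#'
#' Chance-corrected agreement between two label sequences over one
#' vocabulary: `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o` and chance agreement `p_e` from the marginal label frequencies.
#' When both raters are constant and identical (`p_e = 1`), kappa is
#' defined as 1.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  a <- as.character(labels_a)
  b <- as.character(labels_b)
  if (length(a) != length(b)) stop("input error: sequences differ in length")
  if (length(a) == 0) stop("input error: empty sequences")
  lev <- unique(c(a, b))
  ta <- table(factor(a, levels = lev))
  tb <- table(factor(b, levels = lev))
  n <- length(a)
  p_o <- mean(a == b)
  p_e <- sum(as.numeric(ta) * as.numeric(tb)) / n^2
  if (p_e >= 1) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Window-size sweep experiment
#'
#' Re-runs featurize / split / train / evaluate for several window lengths
#' and reports, per length, the number of windows and the mean and SD of
#' the per-class balanced accuracies on the test subset. Longer windows
#' summarise behaviour better but shrink the data base, so accuracy
#' typically rises to an optimum while window counts fall monotonically.
#'
#' To compare window sizes on identical test data, train/validation/test
#' membership is decided once per time block (default 120 s) shared across
#' all sizes: a window belongs to the subset of the block containing its
#' start second. Sizes where any observed behaviour class has fewer than
#' `min_class_train` training windows are skipped with a warning.
#'
#' @param series a `labelled_series`.
#' @param sizes window lengths in seconds, default `c(6, 10, 20, 30, 40, 50, 60)`.
#' @param seed integer seed controlling block assignment and model fits.
#' @param overlap window overlap, default 0.5.
#' @param n_trees forest size, default 100.
#' @param block_s time-block length for the shared split, default 120 s.
#' @param min_class_train minimum training windows per class, default 10.
#' @param channels passed to [make_windows()].
#' @param verbose message progress, default `TRUE`.
#' @return data frame with one row per run size: `window_s`, `n_windows`,
#'   `n_train`, `n_test`, `mean_balanced_accuracy`, `sd_balanced_accuracy`,
#'   `overall_accuracy`; the per-size `class_metrics` objects are attached
#'   as attribute `details`.
#' @export
window_size_sweep <- function(series, sizes = c(6, 10, 20, 30, 40, 50, 60),
                              seed = 1, overlap = 0.5, n_trees = 100,
                              block_s = 120, min_class_train = 10,
                              channels = c("x", "y", "z", "xj", "yj", "zj"),
                              verbose = TRUE) {
  stopifnot(inherits(series, "labelled_series"))
  ## shared block split: same seconds end up in the same subset at every size
  blocks <- unique(data.frame(animal_id = series$animal_id,
                              block = series$timestamp %/% block_s))
  nb <- nrow(blocks)
  set.seed(seed)
  perm <- sample.int(nb)
  grp <- rep(3L, nb)
  grp[perm[seq_len(round(0.5 * nb))]] <- 1L
  grp[perm[round(0.5 * nb) + seq_len(round(0.25 * nb))]] <- 2L
  blocks$subset <- grp
  block_key <- paste(blocks$animal_id, blocks$block)

  rows <- list(); details <- list()
  for (W in sizes) {
    ws <- suppressWarnings(make_windows(series, window_s = W,
                                        overlap = overlap,
                                        channels = channels))
    if (n_windows(ws) == 0) {
      warning("window size ", W, " s: no windows; skipped")
      next
    }
    ft <- build_feature_table(ws)
    sub <- blocks$subset[match(paste(ft$animal_id, ft$start_time %/% block_s),
                               block_key)]
    train <- ft[sub == 1L, , drop = FALSE]
    test <- ft[sub == 3L, , drop = FALSE]
    for (tab in list(train, test)) class(tab) <- class(ft)
    for (a in c("feature_cols", "window_s", "sampling_rate_hz", "channels")) {
      attr(train, a) <- attr(ft, a); attr(test, a) <- attr(ft, a)
    }
    cls_all <- as.character(unique(droplevels(ft$majority_label)))
    tr_counts <- table(factor(as.character(train$majority_label),
                              levels = cls_all))
    if (any(tr_counts < min_class_train)) {
      warning("window size ", W, " s skipped: class(es) with fewer than ",
              min_class_train, " training windows: ",
              paste(names(tr_counts)[tr_counts < min_class_train],
                    collapse = ", "))
      next
    }
    model <- train_rf(train, n_trees = n_trees, seed = seed, verbose = FALSE)
    pr <- stats::predict(model, test)
    cm <- confusion_matrix(as.character(test$majority_label),
                           as.character(pr$label), classes = cls_all)
    met <- suppressWarnings(class_metrics(cm))
    ba <- met$per_class$balanced_accuracy
    rows[[length(rows) + 1L]] <- data.frame(
      window_s = W,
      n_windows = n_windows(ws),
      n_train = nrow(train),
      n_test = nrow(test),
      mean_balanced_accuracy = mean(ba, na.rm = TRUE),
      sd_balanced_accuracy = stats::sd(ba, na.rm = TRUE),
      overall_accuracy = met$overall$accuracy_pct
    )
    details[[as.character(W)]] <- met
    if (verbose) {
      message(sprintf("sweep W=%d s: %d windows, mean balanced accuracy %.1f%%",
                      W, n_windows(ws), mean(ba, na.rm = TRUE)))
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(window_s = numeric(0), n_windows = integer(0),
               n_train = integer(0), n_test = integer(0),
               mean_balanced_accuracy = numeric(0),
               sd_balanced_accuracy = numeric(0),
               overall_accuracy = numeric(0))
  attr(out, "details") <- details
  out
}
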
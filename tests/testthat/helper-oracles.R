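# Independent brute-force oracles, written against the definitions rather
# than the package's implementation paths.

# per-class metrics computed directly from label pairs (never via a table)
oracle_metrics <- function(actual, predicted, classes) {
  n <- length(actual)
  out <- lapply(classes, function(cl) {
    tp <- sum(actual == cl & predicted == cl)
    fn <- sum(actual == cl & predicted != cl)
    fp <- sum(actual != cl & predicted == cl)
    tn <- sum(actual != cl & predicted != cl)
    sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    spec <- if (fp + tn > 0) 100 * tn / (fp + tn) else NA_real_
    c(sensitivity = sens, specificity = spec,
      balanced_accuracy = (sens + spec) / 2)
  })
  res <- do.call(rbind, out)
  rownames(res) <- classes
  list(per_class = res, accuracy_pct = 100 * sum(actual == predicted) / n)
}

# type-7 quantile by explicit sort-and-interpolate
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# modal label with earliest-first-occurrence tie-break, by explicit counting
oracle_mode_first <- function(labels) {
  labels <- as.character(labels)
  uniq <- unique(labels)
  counts <- vapply(uniq, function(u) sum(labels == u), integer(1))
  best <- uniq[counts == max(counts)][1]
  list(label = best, purity = max(counts) / length(labels))
}

# small labelled series builders ---------------------------------------------

series_df <- function(ts, ax = 0, ay = 0, az = 1000, id = "a") {
  data.frame(animal_id = id, timestamp = ts,
             ax = rep_len(ax, length(ts)), ay = rep_len(ay, length(ts)),
             az = rep_len(az, length(ts)))
}

labelled_from <- function(ts, labels, ax = NULL, id = "a", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ax)) ax <- stats::rnorm(length(ts))
  df <- series_df(ts, ax = ax, ay = stats::rnorm(length(ts)),
                  az = stats::rnorm(length(ts)), id = id)
  df$behaviour <- rep_len(labels, length(ts))
  labelled_series(df)
}

# a small but realistic two-class scenario for fast model tests
small_scenario <- function(seed = 1, duration = 3000,
                           mix = c(Foraging = 0.6, RSP = 0.4)) {
  simulate_scenario(mix, duration_s = duration, n_animals = 2, seed = seed)
}
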
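#' Default run configuration
#'
#' Plain-list configuration for [run_pipeline()] and the command-line
#' wrapper; serialisable losslessly to JSON via [write_run_config()].
#'
#' @param ... overrides of the defaults.
#' @return named list.
#' @export
run_config <- function(...) {
  cfg <- list(window_s = 30, overlap = 0.5,
              channels = c("x", "y", "z", "xj", "yj", "zj"),
              n_trees = 100, engine = "rf", seed = 1,
              sizes = c(6, 10, 20, 30, 40, 50, 60))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' @rdname run_config
#' @param cfg a configuration list.
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- run_config()
  base[names(cfg)] <- cfg
  base
}

#' Run the full classification pipeline
#'
#' Wires the stages featurize (windowing + feature extraction), random
#' 50/25/25 split, model training, and test-set evaluation, with the
#' bookkeeping every run should report: input record counts, discarded
#' terminal seconds, and window counts per class. Artifacts (feature CSV,
#' model archive, confusion matrix and metric CSVs, run config) are
#' written when `out_dir` is given.
#'
#' @param series a `labelled_series` (e.g. from [simulate_scenario()] or
#'   [merge_labels()]).
#' @param window_s window length in seconds, default 30.
#' @param overlap window overlap, default 0.5.
#' @param channels channels to featurise.
#' @param n_trees forest size, default 100.
#' @param engine `"rf"` (default) or `"ann"`.
#' @param seed integer seed for split and fit.
#' @param out_dir optional artifact directory.
#' @param verbose message progress, default `TRUE`.
#' @return list with `features`, `split`, `model`, `confusion`, `metrics`,
#'   `mean_balanced_accuracy`, `importance` (RF only) and `log` (named
#'   counts).
#' @export
run_pipeline <- function(series, window_s = 30, overlap = 0.5,
                         channels = c("x", "y", "z", "xj", "yj", "zj"),
                         n_trees = 100, engine = c("rf", "ann"), seed = 1,
                         out_dir = NULL, verbose = TRUE) {
  engine <- match.arg(engine)
  stopifnot(inherits(series, "labelled_series"))
  say <- function(...) if (verbose) message(...)
  log <- list(n_records = nrow(series),
              n_animals = length(unique(series$animal_id)),
              n_segments = length(unique(series$segment)),
              dropped_accel = attr(series, "dropped_accel") %||% 0L,
              dropped_labels = attr(series, "dropped_labels") %||% 0L)
  say("pipeline: ", log$n_records, " records, ", log$n_animals, " animals, ",
      log$n_segments, " contiguous segments")

  ws <- make_windows(series, window_s = window_s, overlap = overlap,
                     channels = channels)
  rate <- sampling_rate(series)
  need_jerk <- any(channels %in% c("xj", "yj", "zj", "dtheta"))
  usable <- sum(pmax(0L, as.integer(table(series$segment)) -
                       if (need_jerk) 1L else 0L))
  W <- as.integer(round(window_s * rate))
  step <- as.integer(round(W * (1 - overlap)))
  seg_counts <- table(factor(ws$meta$segment,
                             levels = unique(series$segment)))
  covered <- sum(ifelse(seg_counts > 0, (seg_counts - 1L) * step + W, 0L))
  log$n_windows <- n_windows(ws)
  log$discarded_terminal_s <- (usable - covered) / rate
  log$windows_per_class <- table(droplevels(ws$meta$majority_label))
  say("pipeline: ", log$n_windows, " windows of ", window_s, " s; ",
      log$discarded_terminal_s, " terminal seconds discarded")
  say("pipeline: windows per class: ",
      paste(names(log$windows_per_class), as.integer(log$windows_per_class),
            sep = "=", collapse = ", "))

  ft <- build_feature_table(ws)
  sp <- split_data(ft, seed = seed)
  model <- if (engine == "rf") {
    train_rf(sp$train, sp$validation, n_trees = n_trees, seed = seed,
             verbose = verbose)
  } else {
    train_ann(sp$train, sp$validation, seed = seed, verbose = verbose)
  }
  pr <- stats::predict(model, sp$test)
  cls <- as.character(unique(droplevels(ft$majority_label)))
  cm <- confusion_matrix(as.character(sp$test$majority_label),
                         as.character(pr$label), classes = cls)
  met <- suppressWarnings(class_metrics(cm))
  mba <- suppressWarnings(mean_balanced_accuracy(met))
  say(sprintf("pipeline: test overall accuracy %.2f%%, mean balanced accuracy %.2f%%",
              met$overall$accuracy_pct, mba))
  imp <- if (engine == "rf") variable_importance(model) else NULL

  out <- list(features = ft, split = sp, model = model, confusion = cm,
              metrics = met, mean_balanced_accuracy = mba, importance = imp,
              log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(ft, file.path(out_dir, "features.csv"))
    save_model(model, file.path(out_dir, "model.rds"))
    utils::write.csv(as.data.frame(unclass(cm)),
                     file.path(out_dir, "confusion.csv"))
    utils::write.csv(met$per_class, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    if (!is.null(imp)) {
      utils::write.csv(imp, file.path(out_dir, "importance.csv"),
                       row.names = FALSE)
    }
    write_run_config(run_config(window_s = window_s, overlap = overlap,
                                channels = channels, n_trees = n_trees,
                                engine = engine, seed = seed),
                     file.path(out_dir, "run_config.json"))
    writeLines(utils::capture.output(utils::str(log)),
               file.path(out_dir, "run_log.txt"))
  }
  out
}
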
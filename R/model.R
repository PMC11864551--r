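#' Random train/validation/test split
#'
#' Windows are assigned at random to training (50%), validation (25%) and
#' test (25%) subsets, the protocol used to fit and judge the behaviour
#' classifiers. The split must leave every behaviour class present in all
#' three subsets; if a draw fails this, the assignment is redrawn with an
#' incremented seed up to `max_retry` times before failing.
#'
#' @param table a `feature_table`.
#' @param fractions numeric length-3 vector summing to 1, default
#'   `c(0.5, 0.25, 0.25)`.
#' @param seed integer seed; identical seeds give identical assignments.
#' @param max_retry bound on coverage redraws, default 100.
#' @return list with elements `train`, `validation`, `test`
#'   (feature tables) and `seed_used`.
#' @export
split_data <- function(table, fractions = c(train = 0.5, validation = 0.25,
                                            test = 0.25),
                       seed = 1, max_retry = 100) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9)
  y <- droplevels(factor(table$majority_label))
  counts <- table(y)
  small <- names(counts)[counts < 3]
  if (length(small) > 0) {
    stop("stratification error: class(es) with fewer than 3 windows: ",
         paste(small, collapse = ", "))
  }
  n <- nrow(table)
  n_tr <- round(n * fractions[[1]])
  n_va <- round(n * fractions[[2]])
  for (s in seed + 0:max_retry) {
    set.seed(s)
    perm <- sample.int(n)
    grp <- rep(3L, n)
    grp[perm[seq_len(n_tr)]] <- 1L
    grp[perm[n_tr + seq_len(n_va)]] <- 2L
    covered <- all(vapply(1:3, function(g) {
      all(levels(y) %in% as.character(y[grp == g]))
    }, logical(1)))
    if (covered) {
      take <- function(g) {
        out <- table[grp == g, , drop = FALSE]
        for (a in c("feature_cols", "window_s", "sampling_rate_hz", "channels")) {
          attr(out, a) <- attr(table, a)
        }
        class(out) <- class(table)
        out
      }
      return(list(train = take(1L), validation = take(2L), test = take(3L),
                  seed_used = s))
    }
  }
  stop("could not produce a split with all classes in all subsets after ",
       max_retry + 1, " attempts")
}

.model_obj <- function(fit, engine, table, classes, meta) {
  structure(list(fit = fit, engine = engine,
                 schema = feature_cols(table),
                 classes = classes, meta = meta),
            class = "ethoaccel_model")
}

.check_schema <- function(model, table) {
  have <- feature_cols(table)
  missing <- setdiff(model$schema, have)
  extra <- setdiff(have, model$schema)
  if (length(missing) > 0 || length(extra) > 0) {
    stop("schema error: feature table does not match the model schema.",
         if (length(missing) > 0)
           paste0(" Missing: ", paste(missing, collapse = ", "), "."),
         if (length(extra) > 0)
           paste0(" Extra: ", paste(extra, collapse = ", "), "."))
  }
  invisible(TRUE)
}

#' Train a random-forest behaviour classifier
#'
#' Fits a probability random forest on the feature table. Only the number
#' of trees departs from the backing library's defaults (100 trees); class
#' imbalance is deliberately left untreated -- performance is instead
#' judged with balanced accuracy, which is insensitive to class frequency.
#' The forest runs single-threaded with a fixed seed, making the whole
#' train-to-predict path deterministic. The validation subset is used for
#' logging only (no early stopping); its mean balanced accuracy is stored
#' in the returned metadata.
#'
#' @param train training `feature_table` (labels in `majority_label`).
#' @param validation optional validation `feature_table` for logged metrics.
#' @param n_trees number of trees, default 100.
#' @param seed integer seed.
#' @param verbose message validation metrics, default `TRUE`.
#' @return an `ethoaccel_model`.
#' @export
train_rf <- function(train, validation = NULL, n_trees = 100, seed = 1,
                     verbose = TRUE) {
  if (!is.numeric(n_trees) || n_trees < 1) {
    stop("parameter error: n_trees must be a positive integer")
  }
  y <- droplevels(factor(train$majority_label))
  if (nlevels(y) < 2) {
    stop("degenerate-label error: training set has a single class")
  }
  fc <- feature_cols(train)
  x <- as.data.frame(train)[, fc, drop = FALSE]
  fit <- ranger::ranger(x = x, y = y, num.trees = as.integer(n_trees),
                        probability = TRUE, importance = "impurity",
                        seed = as.integer(seed), num.threads = 1)
  model <- .model_obj(fit, "rf", train, levels(y),
                      list(seed = seed, n_trees = n_trees,
                           window_s = attr(train, "window_s")))
  pr <- stats::predict(model, train)
  model$meta$train_accuracy <- mean(as.character(pr$label) == as.character(y))
  if (!is.null(validation)) {
    model$meta$validation_metrics <- .logged_metrics(model, validation,
                                                     verbose = verbose)
  }
  model
}

.logged_metrics <- function(model, table, verbose = TRUE) {
  pr <- stats::predict(model, table)
  cls <- union(model$classes,
               as.character(unique(droplevels(factor(table$majority_label)))))
  cm <- confusion_matrix(as.character(table$majority_label),
                         as.character(pr$label), classes = cls)
  met <- suppressWarnings(class_metrics(cm))
  mba <- suppressWarnings(mean_balanced_accuracy(met))
  if (verbose) {
    message(sprintf("validation: overall accuracy %.2f%%, mean balanced accuracy %.2f%%",
                    met$overall$accuracy_pct, mba))
  }
  list(confusion = cm, metrics = met, mean_balanced_accuracy = mba)
}

#' Train a feed-forward network behaviour classifier
#'
#' Parity alternative to [train_rf()] using a single-hidden-layer network
#' (softmax output, weight decay, features standardised with training
#' means/SDs). Provided so the two classifier families can be compared on
#' the same feature tables; the random forest is the default and no
#' accuracy claim is attached to the network. The defaults here
#' (`hidden = 64`, `decay = 1e-3`, `maxit = 300`) are this package's own.
#' The validation subset is used for logged metrics only.
#'
#' @inheritParams train_rf
#' @param hidden hidden-layer size, default 64.
#' @param decay L2 weight decay, default 1e-3.
#' @param maxit optimiser iteration cap, default 300.
#' @return an `ethoaccel_model`.
#' @export
train_ann <- function(train, validation = NULL, hidden = 64, decay = 1e-3,
                      maxit = 300, seed = 1, verbose = TRUE) {
  y <- droplevels(factor(train$majority_label))
  if (nlevels(y) < 2) {
    stop("degenerate-label error: training set has a single class")
  }
  fc <- feature_cols(train)
  x <- as.matrix(as.data.frame(train)[, fc, drop = FALSE])
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, center = ctr, scale = scl)
  set.seed(seed)
  fit <- nnet::nnet(xs, nnet::class.ind(y), size = hidden, softmax = TRUE,
                    decay = decay, maxit = maxit, MaxNWts = 1e6, trace = FALSE)
  model <- .model_obj(fit, "ann", train, levels(y),
                      list(seed = seed, hidden = hidden, decay = decay,
                           maxit = maxit, center = ctr, scale = scl,
                           window_s = attr(train, "window_s")))
  pr <- stats::predict(model, train)
  model$meta$train_accuracy <- mean(as.character(pr$label) == as.character(y))
  if (!is.null(validation)) {
    model$meta$validation_metrics <- .logged_metrics(model, validation,
                                                     verbose = verbose)
  }
  model
}

#' Predict behaviour for a feature table
#'
#' Returns one label per window together with class probabilities (rows sum
#' to 1). The feature schema of `newdata` must equal the schema stored in
#' the model; any `majority_label` column in `newdata` (for instance all
#' `Unknown` in prediction mode) is ignored.
#'
#' @param object an `ethoaccel_model`.
#' @param newdata a `feature_table`.
#' @param ... unused.
#' @return data frame with `label` (factor over the model's classes) and one
#'   probability column `p_<class>` per class.
#' @export
predict.ethoaccel_model <- function(object, newdata, ...) {
  .check_schema(object, newdata)
  x <- as.data.frame(newdata)[, object$schema, drop = FALSE]
  if (object$engine == "rf") {
    loadNamespace("ranger")  # registers predict.ranger for models from disk
    prob <- stats::predict(object$fit, data = x,
                           num.threads = 1)$predictions
    prob <- prob[, object$classes, drop = FALSE]
  } else {
    xs <- scale(as.matrix(x), center = object$meta$center,
                scale = object$meta$scale)
    prob <- stats::predict(object$fit, xs)
    colnames(prob) <- object$fit$lev %||% object$classes
    prob <- prob[, object$classes, drop = FALSE]
  }
  lab <- object$classes[max.col(prob, ties.method = "first")]
  out <- data.frame(label = factor(lab, levels = object$classes))
  colnames(prob) <- paste0("p_", object$classes)
  cbind(out, as.data.frame(prob))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ranked variable importance of a random-forest model
#'
#' Mean-decrease-in-impurity importances scaled so the most important
#' feature equals 1.0, in descending order -- the presentation used when
#' asking *which* channels and statistics drive the classification (e.g.
#' whether dispersion statistics such as the interquartile range outrank
#' spectral-power features).
#'
#' @param model a fitted `ethoaccel_model` from [train_rf()].
#' @return data frame with columns `feature` and `importance` (in `[0, 1]`).
#' @export
variable_importance <- function(model) {
  if (!inherits(model, "ethoaccel_model")) stop("not an ethoaccel_model")
  if (model$engine != "rf") {
    stop("state error: variable importance is available for random-forest ",
         "models only")
  }
  imp <- model$fit$variable.importance
  if (is.null(imp)) stop("state error: model carries no importance scores")
  imp <- sort(imp, decreasing = TRUE)
  top <- max(imp)
  data.frame(feature = names(imp),
             importance = if (top > 0) unname(imp) / top else unname(imp))
}

#' Persist / restore a trained model
#'
#' The model archive bundles the fitted estimator, the feature schema it
#' expects, the class list and training metadata in a single file.
#'
#' @param model an `ethoaccel_model`.
#' @param path file path.
#' @return `path` invisibly (save) / an `ethoaccel_model` (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ethoaccel_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ethoaccel_model")) {
    stop("file does not contain an ethoaccel model")
  }
  model
}

#' @export
print.ethoaccel_model <- function(x, ...) {
  cat("ethoaccel_model (", x$engine, "): ", length(x$classes), " classes, ",
      length(x$schema), " features", sep = "")
  if (!is.null(x$meta$window_s)) cat(", window", x$meta$window_s, "s")
  cat("\n  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}
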
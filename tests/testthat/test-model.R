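# shared small feature tables, built once per session
.mod_cache <- new.env(parent = emptyenv())

two_class_ft <- function() {
  if (is.null(.mod_cache$ft)) {
    s <- small_scenario(seed = 51, duration = 3000)
    .mod_cache$ft <- build_feature_table(make_windows(s, 10))
  }
  .mod_cache$ft
}

test_that("split fractions round to the requested subset sizes", {
  ft <- two_class_ft()
  n <- nrow(ft)
  sp <- split_data(ft, seed = 52)
  expect_equal(nrow(sp$train), round(0.5 * n))
  expect_equal(nrow(sp$validation), round(0.25 * n))
  expect_equal(nrow(sp$test), n - round(0.5 * n) - round(0.25 * n))
  ## disjoint and exhaustive
  expect_equal(nrow(sp$train) + nrow(sp$validation) + nrow(sp$test), n)
  ## all classes everywhere
  for (part in sp[c("train", "validation", "test")]) {
    expect_setequal(unique(as.character(part$majority_label)),
                    unique(as.character(ft$majority_label)))
  }
})

test_that("splitting is deterministic under a fixed seed", {
  ft <- two_class_ft()
  sp1 <- split_data(ft, seed = 53)
  sp2 <- split_data(ft, seed = 53)
  expect_identical(sp1$train$start_time, sp2$train$start_time)
  expect_identical(sp1$seed_used, sp2$seed_used)
})

test_that("a class with exactly 3 windows lands once in each subset", {
  ft <- two_class_ft()
  ft$majority_label[c(2, 30, 60)] <- "Walking"
  sp <- split_data(ft, seed = 54)
  for (part in sp[c("train", "validation", "test")]) {
    expect_equal(sum(part$majority_label == "Walking"), 1)
  }
})

test_that("a class below 3 windows is a stratification error naming it", {
  ft <- two_class_ft()
  ft$majority_label[1:2] <- "Scrubbing"
  expect_error(split_data(ft, seed = 55), "stratification error.*Scrubbing")
})

test_that("well-separated two-class data reaches high validation accuracy", {
  sp <- split_data(two_class_ft(), seed = 56)
  model <- suppressMessages(train_rf(sp$train, sp$validation, seed = 56,
                                     verbose = FALSE))
  mba <- model$meta$validation_metrics$mean_balanced_accuracy
  expect_gte(mba, 95)
  ## resubstitution sanity bound: predicting the training data reproduces
  ## at least the accuracy logged at fit time
  pr <- predict(model, sp$train)
  acc <- mean(as.character(pr$label) == as.character(sp$train$majority_label))
  expect_gte(acc, model$meta$train_accuracy)
})

test_that("permuted labels collapse balanced accuracy to chance", {
  s <- small_scenario(seed = 57, duration = 1200)
  ft <- build_feature_table(make_windows(s, 10))
  set.seed(58)
  bas <- replicate(12, {
    ft2 <- ft
    ft2$majority_label <- sample(ft2$majority_label)
    sp <- split_data(ft2, seed = sample.int(1e6, 1))
    model <- train_rf(sp$train, seed = sample.int(1e6, 1), verbose = FALSE)
    pr <- predict(model, sp$test)
    cm <- confusion_matrix(as.character(sp$test$majority_label),
                           as.character(pr$label))
    suppressWarnings(mean_balanced_accuracy(cm))
  })
  expect_lt(abs(mean(bas) - 50), 5)
  expect_true(all(bas > 30 & bas < 70))
})

test_that("degenerate training inputs are rejected", {
  ft <- two_class_ft()
  expect_error(train_rf(ft, n_trees = 0), "parameter error")
  ft1 <- ft[ft$majority_label == "Foraging", ]
  class(ft1) <- class(ft)
  attr(ft1, "feature_cols") <- feature_cols(ft)
  expect_error(train_rf(ft1), "degenerate-label")
})

test_that("prediction returns normalised probabilities and honours schema", {
  sp <- split_data(two_class_ft(), seed = 59)
  model <- train_rf(sp$train, seed = 59, verbose = FALSE)
  pr <- predict(model, sp$test)
  probs <- as.matrix(pr[, grep("^p_", names(pr))])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(pr)), tolerance = 1e-9)
  ## schema mismatch lists the offending columns
  bad <- sp$test
  attr(bad, "feature_cols") <- c(feature_cols(sp$test)[-1], "bogus")
  expect_error(predict(model, bad), "schema error.*mean_x.*bogus")
  ## an all-Unknown label column is ignored for prediction
  unk <- sp$test
  unk$majority_label <- factor("Unknown", levels = behaviour_levels(TRUE))
  expect_equal(predict(model, unk)$label, pr$label)
})

test_that("the train-predict path is deterministic under a fixed seed", {
  sp <- split_data(two_class_ft(), seed = 60)
  m1 <- train_rf(sp$train, seed = 60, verbose = FALSE)
  m2 <- train_rf(sp$train, seed = 60, verbose = FALSE)
  expect_identical(predict(m1, sp$test), predict(m2, sp$test))
})

test_that("importance is scaled to 1 and finds the informative channel", {
  ## two classes that differ only in the x channel
  set.seed(61)
  n <- 2400
  lab <- rep(rep(c("Foraging", "RSP"), each = 100), 12)
  df <- series_df(seq_len(n) - 1,
                  ax = rnorm(n, sd = ifelse(lab == "Foraging", 60, 6)),
                  ay = rnorm(n, sd = 15), az = rnorm(n, sd = 15) + 1000)
  df$behaviour <- lab
  ft <- build_feature_table(make_windows(labelled_series(df), 10))
  sp <- split_data(ft, seed = 61)
  model <- train_rf(sp$train, seed = 61, verbose = FALSE)
  vi <- variable_importance(model)
  expect_equal(vi$importance[1], 1)
  expect_true(all(vi$importance >= 0))
  expect_true(all(diff(vi$importance) <= 0))
  top5_chan <- sub(".*_", "", vi$feature[1:5])
  expect_true(all(top5_chan %in% c("x", "xj")))
  ## importance is defined for forests only
  expect_error(variable_importance(structure(list(engine = "ann"),
                                             class = "ethoaccel_model")),
               "state error")
})

test_that("model archives round-trip through disk", {
  sp <- split_data(two_class_ft(), seed = 62)
  model <- train_rf(sp$train, seed = 62, verbose = FALSE)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  m2 <- load_model(path)
  expect_identical(predict(m2, sp$test), predict(model, sp$test))
  expect_identical(m2$schema, model$schema)
})

test_that("the network classifier separates easy classes and is reproducible", {
  sp <- split_data(two_class_ft(), seed = 63)
  m1 <- train_ann(sp$train, hidden = 16, maxit = 150, seed = 63,
                  verbose = FALSE)
  pr <- predict(m1, sp$test)
  cm <- confusion_matrix(as.character(sp$test$majority_label),
                         as.character(pr$label))
  expect_gte(suppressWarnings(mean_balanced_accuracy(cm)), 90)
  probs <- as.matrix(pr[, grep("^p_", names(pr))])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(pr)), tolerance = 1e-6)
  m2 <- train_ann(sp$train, hidden = 16, maxit = 150, seed = 63,
                  verbose = FALSE)
  expect_equal(predict(m2, sp$test)$label, pr$label)
})
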
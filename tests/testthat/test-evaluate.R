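test_that("perfect agreement gives a diagonal matrix with full trace", {
  lab <- sample(behaviour_levels()[1:3], 10, replace = TRUE)
  cm <- confusion_matrix(lab, lab)
  expect_equal(sum(diag(cm)), 10)
  expect_equal(sum(cm) - sum(diag(cm)), 0)
})

test_that("confusion matrix validates its inputs", {
  expect_error(confusion_matrix(c("RSP", "RLP"), "RSP"), "length")
  expect_error(confusion_matrix(character(0), character(0)), "empty class")
  expect_error(confusion_matrix("RSP", "RLP", classes = "RSP"),
               "outside the class list")
})

test_that("an identity matrix scores 100 everywhere", {
  m <- diag(5L, 3)
  dimnames(m) <- list(c("RLP", "RSP", "Foraging"), c("RLP", "RSP", "Foraging"))
  met <- class_metrics(as_confusion_matrix(m))
  expect_equal(met$per_class$sensitivity, rep(100, 3))
  expect_equal(met$per_class$specificity, rep(100, 3))
  expect_equal(met$overall$accuracy_pct, 100)
  expect_equal(mean_balanced_accuracy(met), 100)
})

test_that("forcing all predictions into one class zeroes the right metrics", {
  actual <- rep(c("RLP", "RSP", "Foraging"), times = c(5, 5, 10))
  predicted <- rep("Foraging", 20)
  met <- class_metrics(confusion_matrix(actual, predicted))
  pc <- met$per_class
  expect_equal(pc$specificity[pc$class == "Foraging"], 0)
  expect_equal(pc$sensitivity[pc$class != "Foraging"], c(0, 0))
})

test_that("a never-predicted class contributes exactly 50, never 0", {
  actual <- c(rep("RSP", 8), rep("Walking", 2))
  predicted <- rep("RSP", 10)
  met <- class_metrics(confusion_matrix(actual, predicted))
  pc <- met$per_class
  expect_equal(pc$balanced_accuracy[pc$class == "Walking"], 50)
  expect_equal(mean_balanced_accuracy(met),
               mean(c(50, pc$balanced_accuracy[pc$class == "RSP"])))
})

test_that("a zero-support class is reported missing and excluded with warning", {
  m <- rbind(c(5, 0, 0), c(0, 5, 0), c(0, 0, 0))
  dimnames(m) <- list(c("RLP", "RSP", "Walking"), c("RLP", "RSP", "Walking"))
  expect_warning(met <- class_metrics(as_confusion_matrix(m)), "zero support")
  expect_true(is.na(met$per_class$sensitivity[3]))
  expect_warning(mba <- mean_balanced_accuracy(met), "excluding")
  expect_equal(mba, 100)
})

test_that("the published wild-boar matrix reproduces its printed metrics", {
  cm <- boar_confusion()
  ## internal consistency of the printed totals
  expect_equal(sum(cm), 1200)
  expect_equal(unname(rowSums(cm)), c(35, 72, 1017, 17, 2, 32, 25))
  expect_equal(unname(colSums(cm)), c(36, 66, 1059, 14, 0, 25, 0))
  met <- class_metrics(cm)
  pc <- met$per_class
  get <- function(v, cl) pc[[v]][pc$class == cl]
  ## several cells of the published table are truncated rather than
  ## rounded (94.28 for 33/35 = 94.2857, 99.64 for 99.6454, 92.87, 0.468);
  ## agreement there is to the printed truncation, not a rounding equality
  expect_equal(get("sensitivity", "RLP"), 94.2857, tolerance = 1e-4)
  expect_equal(get("specificity", "RSP"), 99.6454, tolerance = 1e-4)
  expect_equal(get("balanced_accuracy", "RSP"), 92.8783, tolerance = 1e-4)
  expect_equal(get("error_rate", "Standing"), 0.46875, tolerance = 1e-9)
  expect_equal(get("sensitivity", "Standing"), 53.125)  # printed as 53.12
  expect_equal(get("error_rate", "Walking"), 1)
})

test_that("kappa matches hand computations and edge conventions", {
  lab <- sample(behaviour_levels()[1:4], 50, replace = TRUE)
  expect_equal(cohen_kappa(lab, lab), 1)
  ## 2x2 agreement table [[20,5],[10,15]]: p_o = 0.7, p_e = 0.5
  a <- c(rep("RSP", 25), rep("RLP", 25))
  b <- c(rep("RSP", 20), rep("RLP", 5), rep("RSP", 10), rep("RLP", 15))
  expect_equal(cohen_kappa(a, b), 0.4)
  ## both raters constant and identical
  expect_equal(cohen_kappa(rep("RSP", 5), rep("RSP", 5)), 1)
})

test_that("kappa of independent random labels is near zero", {
  set.seed(71)
  a <- sample(behaviour_levels()[1:5], 1e4, replace = TRUE)
  b <- sample(behaviour_levels()[1:5], 1e4, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)), 0.05)
})

test_that("metrics agree with the pair-level oracle on random data", {
  set.seed(72)
  for (i in 1:25) {
    k <- sample(2:7, 1)
    classes <- behaviour_levels()[seq_len(k)]
    n <- sample(20:300, 1)
    actual <- sample(classes, n, replace = TRUE)
    predicted <- sample(classes, n, replace = TRUE)
    cm <- confusion_matrix(actual, predicted, classes = classes)
    met <- suppressWarnings(class_metrics(cm))
    orc <- oracle_metrics(actual, predicted, classes)
    expect_equal(met$per_class$sensitivity, unname(orc$per_class[, 1]),
                 tolerance = 1e-12)
    expect_equal(met$per_class$specificity, unname(orc$per_class[, 2]),
                 tolerance = 1e-12)
    expect_equal(met$overall$accuracy_pct, orc$accuracy_pct,
                 tolerance = 1e-12)
  }
})

test_that("the overall accuracy CI is the exact binomial interval", {
  m <- diag(c(40L, 40L))
  dimnames(m) <- list(c("RSP", "RLP"), c("RSP", "RLP"))
  m[1, 2] <- 20L
  met <- suppressWarnings(class_metrics(as_confusion_matrix(m)))
  ref <- stats::binom.test(80, 100)$conf.int
  expect_equal(met$overall$ci_low_pct, 100 * ref[1])
  expect_equal(met$overall$ci_high_pct, 100 * ref[2])
})

test_that("the sweep runs, is deterministic, and respects the shared split", {
  s <- small_scenario(seed = 73, duration = 2400)
  sw1 <- suppressMessages(window_size_sweep(s, sizes = c(10, 20), seed = 73,
                                            n_trees = 50,
                                            min_class_train = 5,
                                            verbose = FALSE))
  expect_equal(sw1$window_s, c(10, 20))
  expect_true(all(diff(sw1$n_windows) < 0))
  expect_true(all(sw1$mean_balanced_accuracy > 50))
  sw2 <- suppressMessages(window_size_sweep(s, sizes = c(10, 20), seed = 73,
                                            n_trees = 50,
                                            min_class_train = 5,
                                            verbose = FALSE))
  expect_equal(sw1, sw2)
})
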
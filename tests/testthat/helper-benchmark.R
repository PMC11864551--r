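# The full wild-boar-like benchmark is expensive, so it is computed lazily
# and cached for the whole test session. Seed fixed once for the suite.

.bench_cache <- new.env(parent = emptyenv())

BENCH_SEED <- 421

bench_series <- function() {
  if (is.null(.bench_cache$series)) {
    .bench_cache$series <- boar_benchmark(seed = BENCH_SEED)
  }
  .bench_cache$series
}

bench_run <- function() {
  if (is.null(.bench_cache$run)) {
    .bench_cache$run <- suppressMessages(
      run_pipeline(bench_series(), window_s = 30, seed = BENCH_SEED,
                   verbose = FALSE))
  }
  .bench_cache$run
}

# the published confusion matrix of a 1 Hz ear-tag wild-boar RF classifier
# (1200 test windows), used as a fixed input for metric reconstruction
boar_confusion <- function() {
  path <- system.file("extdata", "boar_rf_confusion.csv",
                      package = "ethoaccel")
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  as_confusion_matrix(m)
}
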
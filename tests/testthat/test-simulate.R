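test_that("the same seed reproduces the simulation bit for bit", {
  s1 <- simulate_scenario(c(Foraging = 0.7, Walking = 0.3), duration_s = 500,
                          seed = 81)
  s2 <- simulate_scenario(c(Foraging = 0.7, Walking = 0.3), duration_s = 500,
                          seed = 81)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("realised label proportions approach the requested mix", {
  profiles <- behaviour_profiles()
  ## short bouts so the renewal-theory SD of the realised share is ~1.5%
  profiles$Foraging$bout_mean_s <- 30
  profiles$RSP$bout_mean_s <- 30
  s <- simulate_scenario(c(Foraging = 0.8, RSP = 0.2), duration_s = 40000,
                         profiles = profiles, seed = 82)
  p <- mean(s$behaviour == "Foraging")
  expect_lt(abs(p - 0.8), 0.03)
})

test_that("a motionless noiseless profile yields zero ODBA inside the bout", {
  quiet <- behaviour_profile("Standing", c(0, 0, 1), wobble_sd_deg = 0,
                             dynamic_amplitude = 0, noise_sd = 0,
                             amplitude_cv = 0, bout_mean_s = 1000)
  s <- simulate_scenario(c(Standing = 1), duration_s = 200,
                         profiles = list(Standing = quiet), seed = 83)
  expect_equal(odba(s), rep(0, 200), tolerance = 1e-9)
})

test_that("an oscillatory profile shows its line in the window spectrum", {
  osc <- behaviour_profile("Scrubbing", c(0, 0, 1), wobble_sd_deg = 0,
                           dynamic_amplitude = 200,
                           oscillation_freq_hz = 0.25, noise_sd = 1,
                           amplitude_cv = 0, bout_mean_s = 1000)
  s <- simulate_scenario(c(Scrubbing = 1), duration_s = 400,
                         profiles = list(Scrubbing = osc), seed = 84)
  ws <- make_windows(s, 32, channels = c("x", "y", "z"))
  ## strongest ordinate across raw channels should sit at 0.25 Hz (k = 8)
  pw <- ws$channels$x[, 1] |> spectral_power()
  pw <- pw + spectral_power(ws$channels$y[, 1]) +
    spectral_power(ws$channels$z[, 1])
  expect_equal(as.integer(names(which.max(pw))), 8)
})

test_that("unknown behaviours in the mix are a config error", {
  expect_error(simulate_scenario(c(Flying = 1), duration_s = 100, seed = 85),
               "config error")
  expect_error(simulate_scenario(c(Foraging = 0.5, RSP = 0.4),
                                 duration_s = 100, seed = 85),
               "sum to 1")
})

test_that("the benchmark reproduces the field ODBA ordering of behaviours", {
  s <- bench_series()
  m <- tapply(odba(s), s$behaviour, mean)
  ord <- m[c("RSP", "RLP", "Lactating", "Standing", "Foraging", "Walking",
             "Scrubbing")]
  expect_false(is.unsorted(ord))
  ## resting ~50, scrubbing >500 sensor units, as on real ear tags
  expect_lt(ord[["RSP"]], 80)
  expect_gt(ord[["Scrubbing"]], 450)
})

test_that("the benchmark has the expected scale and imbalance", {
  s <- bench_series()
  expect_equal(length(unique(s$animal_id)), 13)
  expect_equal(nrow(s), 146880)  # 40.8 h at 1 Hz
  p_forage <- mean(s$behaviour == "Foraging")
  expect_lt(abs(p_forage - 0.809), 0.05)
})

test_that("more noise never helps: balanced accuracy degrades monotonically", {
  ## two classes whose contrast lives in the dynamic amplitude (25 vs 50);
  ## a shared measurement-noise floor blurs exactly that contrast
  run_ba <- function(noise_sd, seed) {
    profs <- behaviour_profiles()
    for (b in c("Foraging", "RSP")) {
      profs[[b]]$noise_sd <- noise_sd
      profs[[b]]$bout_mean_s <- 60
    }
    profs$RSP$dynamic_amplitude <- 25
    profs$Foraging$dynamic_amplitude <- 50
    s <- simulate_scenario(c(Foraging = 0.6, RSP = 0.4), duration_s = 2500,
                           profiles = profs, seed = seed)
    ft <- build_feature_table(make_windows(s, 10))
    sp <- split_data(ft, seed = seed)
    model <- train_rf(sp$train, seed = seed, verbose = FALSE)
    pr <- predict(model, sp$test)
    cm <- confusion_matrix(as.character(sp$test$majority_label),
                           as.character(pr$label))
    suppressWarnings(mean_balanced_accuracy(cm))
  }
  for (seed in c(86, 87, 88)) {
    ## small slack: the comparison is between noisy estimates of a
    ## monotone population quantity
    expect_gte(run_ba(20, seed), run_ba(40, seed) - 2)
  }
})

test_that("decimating a 32 Hz noise simulation matches simulating at 1 Hz", {
  prof <- list(Standing = behaviour_profile("Standing", c(0, 0, 1),
                                            wobble_sd_deg = 0,
                                            dynamic_amplitude = 80,
                                            amplitude_cv = 0,
                                            bout_mean_s = 1e6))
  s32 <- simulate_scenario(c(Standing = 1), duration_s = 2000,
                           profiles = prof, sampling_rate_hz = 32, seed = 89)
  dec <- s32[seq(1, nrow(s32), by = 32), ]
  s1 <- simulate_scenario(c(Standing = 1), duration_s = 2000,
                          profiles = prof, sampling_rate_hz = 1, seed = 90)
  ## broadband (f = 0) dynamics are white, so decimation preserves the
  ## distribution: compare the per-axis summary statistics
  for (v in c("ax", "ay")) {
    expect_lt(abs(mean(dec[[v]]) - mean(s1[[v]])), 6)
    expect_lt(abs(sd(dec[[v]]) / sd(s1[[v]]) - 1), 0.1)
    expect_gt(suppressWarnings(stats::ks.test(dec[[v]], s1[[v]]))$p.value,
              0.001)
  }
})
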
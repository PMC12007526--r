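fs <- 1250
t_ms <- seq(-500, 2500 - 1000 / fs, by = 1000 / fs)
onsets <- c(0, 412.5, 825, 1237.5, 1650)

test_that("response window holds exactly N = 188 samples", {
  expect_equal(assr_window(fs)$N, 188L)
  # every onset-locked window, on- or off-grid, uses 188 samples
  for (o in onsets) {
    w <- assr40:::.assr_window_idx(o, -500, fs)
    expect_equal(length(w$idx), 188L)
    expect_gte(min(w$t_n_s), 0.250 - 1e-12)
    expect_lt(max(w$t_n_s), 0.4006)
  }
})

test_that("trial preparation removes DC and applies the printed band-pass", {
  # constant input vanishes
  prep <- prepare_average(matrix(7.3, length(t_ms), 3), t_ms, fs)
  expect_lt(max(abs(prep$x)), 1e-9)
  # measured -3 dB edges of the designed filter
  taps <- design_assr_bandpass(fs)
  expect_equal(length(taps), 512L)
  edge <- function(lo, hi) {
    f <- seq(lo, hi, by = 0.02)
    g <- assr40:::fir_gain(taps, f, fs)
    range(f[g >= 10^(-3 / 20)])
  }
  expect_equal(edge(20, 40)[1], 28, tolerance = 0.5 / 28)
  expect_equal(edge(40, 70)[2], 56, tolerance = 0.5 / 56)
  # pure 40-Hz sinusoid passes with < 1% ripple
  x <- sin(2 * pi * 40 * t_ms / 1000)
  prep <- prepare_average(matrix(x), t_ms, fs)
  i <- t_ms > 200 & t_ms < 2300
  expect_equal(mean(Mod(prep$analytic[i])), 1, tolerance = 0.01)
  expect_error(prepare_average(matrix(x), t_ms[-1], fs), "unequal")
})

test_that("ASSR estimator matches the direct-summation oracle", {
  x <- assr40:::burst_locked_cosine(t_ms, fx_spec(), 0)
  prep <- prepare_average(matrix(x), t_ms, fs)
  est <- compute_assr(prep, onsets)
  # oracle: plain loop over the same prepared waveform
  oracle <- mean(vapply(onsets, function(o) {
    w <- assr40:::.assr_window_idx(o, t_ms[1], fs)
    sum(prep$x[w$idx] * exp(-2i * pi * 40 * w$t_n_s)) / 187
  }, complex(1)))
  expect_equal(est$value, oracle, tolerance = 1e-12)
  # single-window gain on a continuous unit cosine: N / (2 (N - 1))
  xc <- cos(2 * pi * 40 * t_ms / 1000)
  eg <- compute_assr(prepare_average(matrix(xc), t_ms, fs), 0)
  expect_equal(eg$amplitude, 188 / (2 * 187), tolerance = 0.02)
  expect_lt(abs(eg$phase), 0.01)
  # zero signal
  e0 <- compute_assr(prepare_average(matrix(0, length(t_ms), 1), t_ms, fs),
                     onsets)
  expect_equal(e0$amplitude, 0)
  expect_error(compute_assr(prep, 2400), "span")
})

test_that("estimator is shift-invariant and linear; phases agree", {
  x <- assr40:::burst_locked_cosine(t_ms, fx_spec(), 3)
  est <- compute_assr(prepare_average(matrix(x), t_ms, fs), onsets)
  # joint 16-sample shift of data and onsets changes nothing
  x2 <- c(numeric(16), x)[seq_along(x)]
  e2 <- compute_assr(prepare_average(matrix(x2), t_ms, fs), onsets + 12.8)
  expect_lt(abs(e2$amplitude - est$amplitude), 1e-10)
  expect_lt(abs(assr40:::wrap_angle(e2$phase - est$phase)), 1e-10)
  # scaling
  e3 <- compute_assr(prepare_average(matrix(2.5 * x), t_ms, fs), onsets)
  expect_equal(e3$amplitude, 2.5 * est$amplitude, tolerance = 1e-12)
  expect_equal(e3$phase, est$phase, tolerance = 1e-12)
  # DFT phase vs Hilbert mean angle at several configured lags
  for (lag in c(0, 3, 7.7, 12.1)) {
    xl <- assr40:::burst_locked_cosine(t_ms, fx_spec(), lag)
    el <- compute_assr(prepare_average(matrix(xl), t_ms, fs), onsets)
    expect_lt(abs(assr40:::wrap_angle(el$phase - el$phase_hilbert)), 0.05)
  }
  # the mean-angle alternative agrees on clean input
  ea <- compute_assr(prepare_average(matrix(x), t_ms, fs), onsets,
                     phase_method = "mean_angle")
  expect_lt(abs(assr40:::wrap_angle(ea$phase - est$phase)), 0.01)
})

test_that("phase-randomization bootstrap calibrates and detects", {
  spec <- fx_spec()
  row <- fx_cohort1()[1, ]
  # strong entrained response: observed exceeds every null sample
  sw <- simulate_source_waveform(row, "quiet", spec, n_trials = 40,
                                 seed = 4, background_sd = 5)
  bs <- bootstrap_significance(sw$left, sw$t_ms, sw$fs, onsets,
                               n_resamples = 1000, seed = 9)
  expect_equal(bs$p, 1 / 1001)
  expect_equal(length(bs$null), 1000)
  # determinism
  bs2 <- bootstrap_significance(sw$left, sw$t_ms, sw$fs, onsets,
                                n_resamples = 1000, seed = 9)
  expect_identical(bs$p, bs2$p)
  # null distribution is invariant to the true phase of the signal
  row_b <- row; row_b$lag_quiet_ms <- row$lag_quiet_ms + 6
  swb <- simulate_source_waveform(row_b, "quiet", spec, n_trials = 40,
                                  seed = 4, background_sd = 5)
  bsb <- bootstrap_significance(swb$left, sw$t_ms, sw$fs, onsets,
                                n_resamples = 1000, seed = 9)
  expect_gt(suppressWarnings(ks.test(bs$null, bsb$null)$p.value), 0.01)
  expect_error(bootstrap_significance(sw$left[, 1, drop = FALSE], sw$t_ms,
                                      sw$fs, onsets), "2 trials")
  expect_warning(bootstrap_significance(sw$left, sw$t_ms, sw$fs, onsets,
                                        n_resamples = 50), "unstable")
})

test_that("latency, laterality, and attenuation follow their closed forms", {
  # dphi = pi/5 at 40 Hz corresponds to 2.5 ms
  lc <- latency_contrast(0, -pi / 5)
  expect_equal(lc$dt_ms, 2.5)
  expect_equal(latency_contrast(1.1, 1.1)$dt_ms, 0)
  # contrasts stay in the half-period unwrap window
  expect_lte(abs(latency_contrast(3.0, -3.0)$dt_ms), 12.5)

  expect_equal(laterality_index(1, 1), 0)
  expect_equal(laterality_index(1, 0), 1)
  expect_equal(laterality_index(1.13, 0.87), 0.13)
  expect_error(laterality_index(0, 0), "zero")

  expect_equal(attenuation_ratio(4, 1), 75)
  expect_equal(attenuation_ratio(2.2, 2.2), 0)
  expect_error(attenuation_ratio(0, 1), "positive")
})

test_that("end-to-end attenuation recovers a configured 2:1 ratio", {
  spec <- fx_spec()
  row <- fx_cohort1()[1, ]
  row$amp_quiet <- 3; row$amp_noise <- 1.5
  row$li_quiet <- 0; row$li_noise <- 0
  amp <- vapply(c("quiet", "noise"), function(cond) {
    sw <- simulate_source_waveform(row, cond, spec, n_trials = 60,
                                   seed = 13, background_sd = 5)
    compute_assr(prepare_average(sw$left, sw$t_ms, sw$fs), onsets)$amplitude
  }, numeric(1))
  expect_equal(unname(attenuation_ratio(amp["quiet"], amp["noise"])), 50,
               tolerance = 3 / 50)
})
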
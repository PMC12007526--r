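test_that("cohort generator realizes the configured linear structure", {
  # large-n recovery of the hearing-loss slope against the generator
  coh <- generate_cohort(0, 2000, seed = 42)
  old <- coh[coh$group == "older", ]
  expect_equal(unname(coef(lm(pta_db ~ age, old))[2]), 1.5, tolerance = 0.05)
  # amplitude-age slope on the target scale
  expect_equal(unname(coef(lm(amp_quiet ~ age, old))[2]), 0.16,
               tolerance = 0.02)
  # ages stay inside the group ranges
  expect_true(all(old$age >= 69 & old$age <= 87))
  coh2 <- generate_cohort(500, 0, seed = 1)
  expect_true(all(coh2$age >= 19 & coh2$age <= 28))
  # SIN loss only measured in the older group
  expect_true(all(is.na(coh2$sin_loss_db)))
  expect_true(all(!is.na(old$sin_loss_db)))
})

test_that("null effect config yields independent covariates", {
  coh <- generate_cohort(0, 3000, null_effect_config(), seed = 9)
  old <- coh[coh$group == "older", ]
  for (v in c("pta_db", "sin_loss_db", "gaba_total_right"))
    expect_lt(abs(cor(old$age, old[[v]])), 0.06)
})

test_that("cohort generation is seed-deterministic", {
  a <- generate_cohort(5, 5, seed = 7)
  b <- generate_cohort(5, 5, seed = 7)
  c <- generate_cohort(5, 5, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$age, c$age))
  expect_error(
    generate_cohort(2, 2, modifyList(default_effect_config(),
                                     list(amp = modifyList(
                                       default_effect_config()$amp,
                                       list(quiet_sd = -1))))),
    "infeasible")
})

test_that("spherical forward model: linearity, radial silence, symmetry", {
  head <- fx_head(); arr <- fx_array()
  pos <- c(40, 0, 30)
  tb <- assr40:::tangential_basis(pos, head)
  d1 <- dipole_source(pos, tb[, 1])
  g1 <- forward_field(d1, head, arr)
  # linearity: doubling the moment doubles the field (gain is per nAm)
  L <- lead_field(pos, head, arr)
  expect_equal(drop(L %*% (2 * tb[, 1])), 2 * g1, tolerance = 1e-12)
  # radial dipole is silent
  grad <- forward_field(dipole_source(pos, pos), head, arr)
  expect_lt(max(abs(grad)), 1e-12 * max(abs(g1)))
  # dipole outside the sphere is rejected
  expect_error(forward_field(dipole_source(c(100, 0, 0), c(0, 1, 0)),
                             head, arr), "outside")

  # mirror-symmetric pair on a mirror-symmetric array: field patterns are
  # the negated mirror of each other (the field is a pseudovector)
  arr2 <- sensor_array(layout = "rings", disabled = 1L)
  gl <- forward_field(dipole_source(c(-48, -17, 8), c(0, 1, 0.3)), head, arr2)
  gr <- forward_field(dipole_source(c(48, -17, 8), c(0, 1, 0.3)), head, arr2)
  P <- arr2$pos[arr2$usable, ]
  mir <- apply(P, 1, function(p)
    which.min(colSums((t(P) - c(-p[1], p[2], p[3]))^2)))
  expect_lt(max(abs(gl + gr[mir])), 1e-12 * max(abs(gl)))
})

test_that("array has 150 usable channels and field decays with distance", {
  arr <- fx_array()
  expect_equal(nrow(arr$pos), 151)
  expect_equal(length(arr$usable), 150)
  # farther helmet, weaker fields
  near <- sensor_array(helmet_radius_mm = 110)
  far <- sensor_array(helmet_radius_mm = 220)
  head <- fx_head()
  d <- dipole_source(c(40, 0, 30), c(0, 1, 0))
  expect_gt(max(abs(forward_field(d, head, near))),
            3 * max(abs(forward_field(d, head, far))))
})

test_that("source waveform carries the configured 40-Hz structure", {
  spec <- fx_spec()
  row <- fx_cohort1()[1, ]
  row$buildup_quiet_ms <- 0
  row$onset_transient <- FALSE
  sw <- simulate_source_waveform(row, "quiet", spec, n_trials = 1,
                                 background_sd = 0)
  # pure entrained component from each onset: downstream amplitude equals
  # the target (the generator converts by the estimator gain)
  est <- compute_assr(prepare_average(sw$left, sw$t_ms, sw$fs),
                      burst_onsets_ms(spec))
  target <- hemisphere_amplitudes(row, "quiet")[["left"]]
  expect_equal(est$amplitude, target, tolerance = 0.03)
  # configured lag is recovered from the phase
  lag_meas <- (-1000 * est$phase / (2 * pi * 40)) %% 25
  expect_equal(lag_meas, row$lag_quiet_ms %% 25, tolerance = 0.05)
  # zero amplitude: pure background
  row0 <- row; row0$amp_quiet <- 0; row0$li_quiet <- 0
  sw0 <- simulate_source_waveform(row0, "quiet", spec, n_trials = 2,
                                  background_sd = 0)
  expect_equal(max(abs(sw0$left)), 0)
  expect_error(simulate_source_waveform(row, "unknown", spec), "condition")
})

test_that("latency contrast between two parameter sets is recovered", {
  spec <- fx_spec()
  row <- fx_cohort1()[1, ]
  row_b <- row
  row_b$lag_quiet_ms <- row$lag_quiet_ms + 2.38
  est <- lapply(list(row, row_b), function(r) {
    sw <- simulate_source_waveform(r, "quiet", spec, n_trials = 30,
                                   seed = 21, background_sd = 5)
    compute_assr(prepare_average(sw$left, sw$t_ms, sw$fs),
                 burst_onsets_ms(spec))
  })
  lc <- latency_contrast(est[[1]]$phase, est[[2]]$phase)
  expect_equal(lc$dt_ms, 2.38, tolerance = 0.2)
})

test_that("simulated recordings have the configured block structure", {
  recs <- fx_recording()
  expect_equal(length(recs), 2)
  expect_equal(vapply(recs, `[[`, character(1), "condition"),
               c("quiet", "noise"))
  r <- recs[[1]]
  expect_equal(nrow(r$data), 150)
  # sample count matches trials x inter-onset interval
  expect_equal(ncol(r$data) / r$fs, 20 * 4000 / 1000)
  expect_equal(nrow(r$events), 20)
  expect_equal(diff(r$events$onset_ms)[1], 4000)
  expect_equal(block_duration_s(fx_spec(), 75), 300)
  # ground truth reconstructs the clean projection
  clean <- outer(r$truth$gain_left, r$truth$moment_left) +
    outer(r$truth$gain_right, r$truth$moment_right)
  art <- outer(r$truth$blink_topo * 1, r$truth$blink_reg) +
    outer(r$truth$cardiac_topo * 1, r$truth$cardiac_reg)
  resid <- r$data - clean - art
  # what remains is the stationary sensor noise, at the configured scale
  expect_equal(stats::sd(resid), scaled_noise_config(20)$sensor_noise_t,
               tolerance = 0.05)
  expect_error(simulate_recording(fx_cohort1(),
                                  spec = stimulus_spec(inter_onset_ms = 2000),
                                  blocks_per_condition = 1,
                                  trials_per_block = 2), "inter-onset")
})

test_that("artifact-free recordings equal forward projection plus noise", {
  r <- fx_clean_recording()[[1]]
  expect_equal(length(r$truth$blink_times_s), 0)
  clean <- outer(r$truth$gain_left, r$truth$moment_left) +
    outer(r$truth$gain_right, r$truth$moment_right)
  resid <- r$data - clean
  # residual is sensor noise, uncorrelated with the source moment; compare
  # in the ASSR band, where 1/f long-range dependence cannot dominate
  taps <- design_assr_bandpass(r$fs)
  mom_b <- assr40:::zero_phase_apply(r$truth$moment_left, taps)
  cors <- vapply(1:10, function(c_)
    abs(cor(assr40:::zero_phase_apply(resid[c_, ], taps), mom_b)),
    numeric(1))
  expect_lt(max(cors), 0.1)
})
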
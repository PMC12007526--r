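# Shared fixtures, built once per test run and cached (simulation is the
# expensive part). Sensor noise for reduced-trial recordings is scaled so
# the per-sub-average SNR matches the full-scale (75-trial, 4-block)
# operating point.

.fx <- new.env(parent = emptyenv())

fx_spec <- function() stimulus_spec()
fx_head <- function() head_model()

fx_array <- function() {
  if (is.null(.fx$array)) .fx$array <- sensor_array()
  .fx$array
}

scaled_noise_config <- function(trials, epochs_per_type = 3 * trials,
                                full_epochs = 3 * 75) {
  cfg <- default_recording_config()
  cfg$sensor_noise_t <- 200e-15 * sqrt(epochs_per_type / full_epochs)
  cfg
}

# one participant, one quiet + one noise block, 20 trials, with artifacts
fx_recording <- function() {
  if (is.null(.fx$recs)) {
    coh <- generate_cohort(1, 0, seed = 3)
    .fx$cohort1 <- coh
    .fx$recs <- simulate_recording(coh, blocks_per_condition = 1,
                                   trials_per_block = 20, seed = 5,
                                   config = scaled_noise_config(20))
  }
  .fx$recs
}

fx_cohort1 <- function() {
  fx_recording()
  .fx$cohort1
}

# the same participant's quiet block without artifacts
fx_clean_recording <- function() {
  if (is.null(.fx$clean)) {
    cfg <- scaled_noise_config(20)
    cfg$blink_rate_hz <- 0
    cfg$cardiac_rate_hz <- 0
    .fx$clean <- simulate_recording(fx_cohort1(), blocks_per_condition = 1,
                                    trials_per_block = 20, seed = 5,
                                    config = cfg)
  }
  .fx$clean
}

truth_pos <- function(row) {
  rbind(c(row$pos_left_x, row$pos_left_y, row$pos_left_z),
        c(row$pos_right_x, row$pos_right_y, row$pos_right_z))
}

# noiseless bilateral field for a 500-ms epoch (ground truth for fits)
fx_noiseless_subaverage <- function(seed = 1) {
  set.seed(seed)
  head <- fx_head(); arr <- fx_array()
  pl <- c(-48, -17, 8); pr <- c(48, -17, 8)
  TbL <- assr40:::tangential_basis(pl, head)
  TbR <- assr40:::tangential_basis(pr, head)
  oL <- drop(TbL %*% c(0.8, 0.6))
  oR <- drop(TbR %*% c(0.7, -sqrt(1 - 0.49)))
  gL <- drop(lead_field(pl, head, arr) %*% oL)
  gR <- drop(lead_field(pr, head, arr) %*% oR)
  t <- seq(0, by = 1 / 1250, length.out = 625)
  mL <- 5 * sin(2 * pi * 40 * t)
  mR <- 4 * sin(2 * pi * 40 * t + 0.4)
  list(sub = list(data = outer(gL, mL) + outer(gR, mR), members = 1:3,
                  block = 1, condition = "quiet", fs = 1250),
       pos = rbind(pl, pr), ori = rbind(oL, oR), mL = mL, mR = mR,
       gL = gL, gR = gR)
}
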
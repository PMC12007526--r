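#' ASSR estimator gain on a pure sinusoid
#'
#' The 40-Hz ASSR statistic normalizes the N-sample single-bin Fourier sum
#' by 1/(N - 1), so a unit-amplitude entrained sinusoid yields an amplitude
#' of about N / (2 (N - 1)) (plus a small spectral-leakage term). The
#' simulator uses this gain to convert target ASSR amplitudes into source
#' moment amplitudes.
#'
#' @param N window sample count (188 at 1250 Hz for a 250-400 ms window).
#' @export
assr_estimator_gain <- function(N = 188) {
  N / (2 * (N - 1))
}

# Burst-locked 40-Hz oscillation: within each burst the phase is locked to
# that burst's own onset (minus the response lag), mirroring the stimulus
# modulation envelope, which restarts at every onset. Because the 12.5-ms
# gap is half a modulation period, the bursts are phase-offset by pi in
# absolute time; onset-locked analysis windows see a common phase.
burst_locked_cosine <- function(t_ms, spec, lag_ms) {
  osc <- numeric(length(t_ms))
  onsets <- burst_onsets_ms(spec)
  for (o in onsets) {
    inb <- t_ms >= o & t_ms < o + spec$burst_ms
    osc[inb] <- cos(2 * pi * spec$mod_hz * (t_ms[inb] - o - lag_ms) / 1000)
  }
  osc
}

# Stimulus-locked response envelope: zero during gaps, ramping from a reset
# level to 1 over buildup_ms after each burst onset (full reset at the first
# onset, partial reset after the 12.5-ms gaps).
response_envelope <- function(t_ms, spec, buildup_ms, gap_reset = 0.3) {
  env <- numeric(length(t_ms))
  onsets <- burst_onsets_ms(spec)
  for (k in seq_along(onsets)) {
    o <- onsets[k]
    base <- if (k == 1) 0 else gap_reset
    inb <- t_ms >= o & t_ms < o + spec$burst_ms
    tl <- t_ms[inb] - o
    ramp <- if (buildup_ms > 0) pmin(tl / buildup_ms, 1) else rep(1, sum(inb))
    env[inb] <- base + (1 - base) * ramp
  }
  env
}

#' Simulate entrained source-moment waveforms for one participant
#'
#' The deterministic part is a 40-Hz oscillation at the participant's
#' configured amplitude and phase lag, enveloped by the stimulus burst
#' structure with amplitude buildup after the AM onset and after each gap,
#' plus (quiet condition) a decaying onset transient. Each trial adds an
#' independent 1/f background. Target amplitudes from the cohort table are
#' on the ASSR-estimate scale and are converted to moment amplitude by
#' [assr_estimator_gain()].
#'
#' @param row one row of a [generate_cohort()] table.
#' @param condition `"quiet"` or `"noise"`.
#' @param spec a [stimulus_spec()] defining the burst timeline.
#' @param n_trials number of trials to draw.
#' @param seed integer seed.
#' @param fs field sampling rate (Hz).
#' @param span_ms trial window relative to AM onset (ms).
#' @param background_sd 1/f background SD in nAm (0 = noiseless).
#' @return list with `left` and `right` (samples x trials matrices, nAm),
#'   `t_ms`, `fs`, and `truth` (the deterministic waveforms and parameters).
#' @export
simulate_source_waveform <- function(row, condition, spec = stimulus_spec(),
                                     n_trials = 1, seed = 1L, fs = 1250,
                                     span_ms = c(-500, 2500),
                                     background_sd = NULL) {
  if (!condition %in% c("quiet", "noise"))
    stop("no source parameters for condition '", condition, "'")
  if (is.null(background_sd))
    background_sd <- default_effect_config()$source$background_sd
  set.seed(seed)
  t_ms <- seq(span_ms[1], span_ms[2] - 1000 / fs, by = 1000 / fs)
  n <- length(t_ms)
  amps <- hemisphere_amplitudes(row, condition) / assr_estimator_gain()
  lag <- if (condition == "quiet") row$lag_quiet_ms else row$lag_noise_ms
  buildup <- if (condition == "quiet") row$buildup_quiet_ms else
    row$buildup_noise_ms
  env <- response_envelope(t_ms, spec, buildup)
  osc <- burst_locked_cosine(t_ms, spec, lag)
  det <- list()
  for (h in c("left", "right")) {
    w <- amps[[h]] * env * osc
    if (condition == "quiet" && isTRUE(row$onset_transient)) {
      post <- t_ms >= 0
      w[post] <- w[post] + amps[[h]] * 1.2 * exp(-t_ms[post] / 50) *
        cos(2 * pi * spec$mod_hz * t_ms[post] / 1000)
    }
    det[[h]] <- w
  }
  out <- list(t_ms = t_ms, fs = fs,
              truth = list(deterministic = det, amp_moment = amps,
                           lag_ms = lag, buildup_ms = buildup,
                           condition = condition))
  for (h in c("left", "right")) {
    m <- matrix(det[[h]], n, n_trials)
    if (background_sd > 0)
      for (j in seq_len(n_trials))
        m[, j] <- m[, j] + powerlaw_noise(n, fs, 1, background_sd)
    out[[h]] <- m
  }
  out
}

#' Stimulation block duration
#'
#' A block holds `trials_per_block` trials at the stimulus inter-onset
#' interval; 75 trials at 4000 ms give the 300-s block. The same arithmetic
#' sets the sample count of simulated blocks.
#'
#' @param spec a [stimulus_spec()].
#' @param trials_per_block trials per block.
#' @return duration in seconds.
#' @export
block_duration_s <- function(spec = stimulus_spec(), trials_per_block = 75) {
  trials_per_block * spec$inter_onset_ms / 1000
}

#' Default recording noise and artifact configuration
#'
#' Sensor noise and artifact statistics are free parameters of the
#' generator (field units are tesla): a 1/f + white sensor-noise floor
#' scaled so single-trial ASSRs are buried and ~300-trial averaging is
#' needed; ocular blinks at ~0.2/s with a frontal topography and sub-6-Hz
#' energy; quasi-periodic cardiac artifacts at ~1.1 Hz with interval and
#' amplitude jitter and a broad topography.
#'
#' @export
default_recording_config <- function() {
  list(sensor_noise_t = 200e-15, blink_rate_hz = 0.2, blink_amp_t = 1500e-15,
       blink_dur_ms = 350, cardiac_rate_hz = 1.1, cardiac_amp_t = 800e-15,
       cardiac_jitter = 0.05, head_drift_mm = 1)
}

cardiac_template <- function(fs) {
  t <- seq(-60, 60, by = 1000 / fs)  # ms
  w <- exp(-(t / 10)^2) - 0.35 * exp(-((t - 25) / 18)^2) -
    0.30 * exp(-((t + 20) / 15)^2)
  w / max(abs(w))
}

blink_waveform <- function(fs, dur_ms) {
  n <- round(dur_ms * fs / 1000)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))^1.5
}

#' Simulate sensor-level MEG block recordings for a cohort
#'
#' Per participant, `2 * blocks_per_condition` blocks in alternating
#' quiet/noise order. Each block holds `trials_per_block` trials at the
#' stimulus inter-onset interval; sensor data are the forward-projected
#' bilateral source moments plus sensor noise, ocular blinks, and cardiac
#' artifacts. Head positions are registered pre and post block with a
#' configurable drift applied along a random coordinate axis.
#'
#' @param cohort a [generate_cohort()] table (or subset of rows).
#' @param blocks_per_condition blocks per condition (default 4).
#' @param trials_per_block trials per block (default 75; 75 trials at a
#'   4000-ms inter-onset interval give a 300-s block).
#' @param spec a [stimulus_spec()].
#' @param array,head sensor array and head model.
#' @param config see [default_recording_config()]; set artifact rates or
#'   amplitudes to 0 for clean recordings.
#' @param background_sd source 1/f background SD (nAm).
#' @param seed integer seed.
#' @return list of `assr_recording` objects, each with fields `data`
#'   (usable channels x samples, tesla), `fs`, `events`, `headpos_pre`,
#'   `headpos_post`, `participant`, `condition`, `block`, and `truth`.
#' @export
simulate_recording <- function(cohort, blocks_per_condition = 4,
                               trials_per_block = 75,
                               spec = stimulus_spec(),
                               array = sensor_array(), head = head_model(),
                               config = default_recording_config(),
                               background_sd = NULL, seed = 1L) {
  if (spec$inter_onset_ms < total_am_ms(spec) + 450)
    stop("inter-onset interval too short for the trial duration")
  if (is.null(background_sd))
    background_sd <- default_effect_config()$source$background_sd
  set.seed(seed)
  fs <- 1250
  block_ms <- trials_per_block * spec$inter_onset_ms
  n_samp <- round(block_ms * fs / 1000)
  n_ch <- length(array$usable)
  conds <- rep(c("quiet", "noise"), blocks_per_condition)
  coils <- rbind(nasion = c(0, 90, -60), lpa = c(-70, 0, -60),
                 rpa = c(70, 0, -60))
  recs <- list()
  for (i in seq_len(nrow(cohort))) {
    row <- cohort[i, ]
    posL <- c(row$pos_left_x, row$pos_left_y, row$pos_left_z)
    posR <- c(row$pos_right_x, row$pos_right_y, row$pos_right_z)
    # fixed tangential orientation per hemisphere, jittered per participant
    ori <- lapply(list(posL, posR), function(p) {
      Tb <- tangential_basis(p, head)
      th <- stats::rnorm(1, 0, 10 * pi / 180)
      drop(Tb %*% c(cos(th), sin(th)))
    })
    gL <- drop(lead_field(posL, head, array) %*% ori[[1]])
    gR <- drop(lead_field(posR, head, array) %*% ori[[2]])
    cardiac_topo <- {
      u <- array$pos[array$usable, ] / 110
      w <- 0.6 + 0.4 * drop(u %*% stats::rnorm(3))
      w / max(abs(w))
    }
    blink_topo <- {
      y <- array$pos[array$usable, 2]
      w <- exp(-((y - max(y)) / 35)^2)
      w / max(w)
    }
    for (b in seq_along(conds)) {
      cond <- conds[b]
      amps <- hemisphere_amplitudes(row, cond) / assr_estimator_gain()
      lag <- if (cond == "quiet") row$lag_quiet_ms else row$lag_noise_ms
      buildup <- if (cond == "quiet") row$buildup_quiet_ms else
        row$buildup_noise_ms
      onset_samples <- round((seq_len(trials_per_block) - 1) *
                               spec$inter_onset_ms * fs / 1000) + 1L
      t_ms <- (seq_len(n_samp) - 1) * 1000 / fs
      # deterministic entrained moment, tiled at each trial onset
      pat_t <- seq(0, total_am_ms(spec) - 1000 / fs, by = 1000 / fs)
      env <- response_envelope(pat_t, spec, buildup)
      osc <- burst_locked_cosine(pat_t, spec, lag)
      trans <- if (cond == "quiet" && isTRUE(row$onset_transient))
        1.2 * exp(-pat_t / 50) * cos(2 * pi * spec$mod_hz * pat_t / 1000)
      else 0
      mL <- numeric(n_samp); mR <- numeric(n_samp)
      for (s0 in onset_samples) {
        idx <- s0:(s0 + length(pat_t) - 1L)
        mL[idx] <- mL[idx] + amps[["left"]] * (env * osc + trans)
        mR[idx] <- mR[idx] + amps[["right"]] * (env * osc + trans)
      }
      if (background_sd > 0) {
        mL <- mL + powerlaw_noise(n_samp, fs, 1, background_sd)
        mR <- mR + powerlaw_noise(n_samp, fs, 1, background_sd)
      }
      data <- outer(gL, mL) + outer(gR, mR)
      truth_art <- list(blink_times_s = numeric(0), beat_times_s = numeric(0))
      if (config$sensor_noise_t > 0) {
        for (c_ in seq_len(n_ch))
          data[c_, ] <- data[c_, ] +
            powerlaw_noise(n_samp, fs, 1, config$sensor_noise_t)
      }
      if (config$blink_rate_hz > 0 && config$blink_amp_t > 0) {
        nb <- stats::rpois(1, config$blink_rate_hz * block_ms / 1000)
        bt <- sort(stats::runif(nb, 1, block_ms / 1000 - 1))
        bw <- blink_waveform(fs, config$blink_dur_ms)
        reg <- numeric(n_samp)
        for (s in round(bt * fs)) {
          idx <- s:(s + length(bw) - 1L)
          reg[idx] <- reg[idx] + bw * stats::rnorm(1, 1, 0.15)
        }
        data <- data + outer(blink_topo * config$blink_amp_t, reg)
        truth_art$blink_times_s <- bt
        truth_art$blink_dur_ms <- config$blink_dur_ms
        truth_art$blink_reg <- reg * config$blink_amp_t
      }
      if (config$cardiac_rate_hz > 0 && config$cardiac_amp_t > 0) {
        mean_ibi <- 1 / config$cardiac_rate_hz
        ibis <- stats::rnorm(ceiling(block_ms / 1000 / mean_ibi) + 5,
                             mean_ibi, config$cardiac_jitter * mean_ibi)
        beats <- cumsum(pmax(ibis, 0.4))
        beats <- beats[beats < block_ms / 1000 - 0.1 & beats > 0.1]
        tmpl <- cardiac_template(fs)
        half <- (length(tmpl) - 1L) %/% 2L
        reg <- numeric(n_samp)
        for (s in round(beats * fs)) {
          idx <- (s - half):(s - half + length(tmpl) - 1L)
          ok <- idx >= 1 & idx <= n_samp
          reg[idx[ok]] <- reg[idx[ok]] + tmpl[ok] * stats::rnorm(1, 1, 0.15)
        }
        data <- data + outer(cardiac_topo * config$cardiac_amp_t, reg)
        truth_art$beat_times_s <- beats
        truth_art$cardiac_reg <- reg * config$cardiac_amp_t
      }
      drift <- numeric(3)
      if (config$head_drift_mm > 0) {
        ax <- sample(3, 1)
        drift[ax] <- config$head_drift_mm * sample(c(-1, 1), 1)
      }
      recs[[length(recs) + 1L]] <- structure(list(
        data = data, fs = fs,
        events = data.frame(sample = onset_samples,
                            onset_ms = (onset_samples - 1) * 1000 / fs,
                            trial = seq_len(trials_per_block),
                            label = "am_onset"),
        headpos_pre = coils,
        headpos_post = coils + matrix(drift, 3, 3, byrow = TRUE),
        participant = row$id, condition = cond, block = b,
        truth = c(list(moment_left = mL, moment_right = mR,
                       gain_left = gL, gain_right = gR,
                       pos_left = posL, pos_right = posR,
                       ori_left = ori[[1]], ori_right = ori[[2]],
                       blink_topo = blink_topo, cardiac_topo = cardiac_topo),
                  truth_art)
      ), class = "assr_recording")
    }
  }
  recs
}

#' @export
print.assr_recording <- function(x, ...) {
  cat(sprintf("<assr_recording> %s block %d (%s): %d ch x %d samples @ %g Hz\n",
              x$participant, x$block, x$condition,
              nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}
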
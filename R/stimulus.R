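#' Stimulus specification
#'
#' Parameters of the 40-Hz amplitude-modulated tone-burst stimulus and its
#' notch-filtered babble masker. The carrier is a 400-Hz tone, sinusoidally
#' amplitude modulated between 0 and 100% at 40 Hz, presented as five 400-ms
#' bursts separated by 12.5-ms silent gaps (one half modulation period), for
#' a total AM duration of 2050 ms. In the noise condition a masker leads and
#' trails the AM sound by 500 ms (3050 ms total) at a +6 dB AM-to-masker SNR.
#'
#' @param carrier_hz carrier frequency (Hz).
#' @param mod_hz modulation frequency f_m (Hz).
#' @param mod_depth modulation depth, 1 = 100% (envelope spans 0..1).
#' @param burst_ms burst duration (ms); must hold an integer number of
#'   modulation periods.
#' @param gap_ms silent gap between bursts (ms); must equal half a
#'   modulation period.
#' @param n_bursts number of bursts.
#' @param inter_onset_ms trial onset-to-onset interval (ms).
#' @param noise_lead_ms masker lead/lag around the AM sound (ms).
#' @param ramp_ms masker cosine on/off ramp duration (ms).
#' @param audio_fs_hz audio sampling rate (Hz); an integer multiple of the
#'   1250-Hz field sampling rate.
#' @param snr_db AM-to-masker power ratio (dB).
#' @return object of class `assr_stimspec`.
#' @export
stimulus_spec <- function(carrier_hz = 400, mod_hz = 40, mod_depth = 1,
                          burst_ms = 400, gap_ms = 12.5, n_bursts = 5,
                          inter_onset_ms = 4000, noise_lead_ms = 500,
                          ramp_ms = 200, audio_fs_hz = 25000, snr_db = 6) {
  spec <- structure(list(
    carrier_hz = carrier_hz, mod_hz = mod_hz, mod_depth = mod_depth,
    burst_ms = burst_ms, gap_ms = gap_ms, n_bursts = n_bursts,
    inter_onset_ms = inter_onset_ms, noise_lead_ms = noise_lead_ms,
    ramp_ms = ramp_ms, audio_fs_hz = audio_fs_hz, snr_db = snr_db
  ), class = "assr_stimspec")
  validate_stimspec(spec)
  spec
}

validate_stimspec <- function(spec) {
  cycles <- spec$burst_ms * spec$mod_hz / 1000
  if (abs(cycles - round(cycles)) > 1e-9)
    stop("burst_ms must hold an integer number of modulation periods")
  if (abs(spec$gap_ms - 1000 / (2 * spec$mod_hz)) > 1e-9)
    stop("gap_ms must equal one half modulation period")
  if (spec$audio_fs_hz <= 2 * (spec$carrier_hz + spec$mod_hz))
    stop("audio_fs_hz must exceed twice the upper sideband frequency")
  if (spec$mod_depth < 0 || spec$mod_depth > 1)
    stop("mod_depth must be in [0, 1]")
  invisible(spec)
}

#' Total duration of the AM sound (ms)
#' @param spec a [stimulus_spec()].
#' @export
total_am_ms <- function(spec) {
  spec$n_bursts * spec$burst_ms + (spec$n_bursts - 1) * spec$gap_ms
}

#' Burst onset times (ms, relative to AM onset)
#' @param spec a [stimulus_spec()].
#' @export
burst_onsets_ms <- function(spec) {
  (seq_len(spec$n_bursts) - 1) * (spec$burst_ms + spec$gap_ms)
}

#' Construct the AM tone-burst stimulus
#'
#' Each burst carries the raised-cosine envelope
#' `1 - d + d * 0.5 * (1 - cos(2 pi f_m t))`, with `t` measured from the
#' burst onset, so a 100%-depth envelope starts at zero at every onset.
#' The waveform is zero during the 12.5-ms gaps. At full depth the spectrum
#' holds the 400-Hz carrier plus sidebands at 360 and 440 Hz.
#'
#' @param spec a [stimulus_spec()].
#' @return object of class `assr_timeline` with fields `condition`, `am`
#'   (audio samples), `masker` (empty here), `burst_onsets_ms`,
#'   `total_am_ms`, `events` (data.frame onset_ms/label), and `fs`.
#' @export
make_am_stimulus <- function(spec) {
  validate_stimspec(spec)
  fs <- spec$audio_fs_hz
  dur_ms <- total_am_ms(spec)
  n <- round(dur_ms * fs / 1000)
  t <- (seq_len(n) - 1) / fs            # seconds from AM onset
  am <- numeric(n)
  onsets <- burst_onsets_ms(spec)
  for (o in onsets) {
    i0 <- round(o * fs / 1000) + 1L
    i1 <- i0 + round(spec$burst_ms * fs / 1000) - 1L
    tl <- t[i0:i1] - o / 1000           # time from this burst's onset
    env <- 1 - spec$mod_depth +
      spec$mod_depth * 0.5 * (1 - cos(2 * pi * spec$mod_hz * tl))
    am[i0:i1] <- env * sin(2 * pi * spec$carrier_hz * t[i0:i1])
  }
  structure(list(
    condition = "quiet", am = am, masker = numeric(0),
    burst_onsets_ms = onsets, total_am_ms = dur_ms,
    events = data.frame(onset_ms = onsets,
                        label = paste0("burst", seq_along(onsets))),
    fs = fs, spec = spec
  ), class = "assr_timeline")
}

#' Design the octave notch filter around the AM band
#'
#' Arbitrary-magnitude FIR designed to the attenuation template: unity in
#' the passband, -6 dB at 283 and 566 Hz (the octave edges around 400 Hz),
#' and at least -60 dB at 400 Hz. Applied zero-phase. Errors if the realized
#' response misses the template.
#'
#' @param fs audio sampling rate (Hz).
#' @param n_taps filter length.
#' @return taps vector.
#' @export
design_notch_filter <- function(fs = 25000, n_taps = 4097) {
  nyq <- fs / 2
  f <- c(0, 200, 245, 283, 315, 345, 455, 500, 566, 650, 740, nyq) / nyq
  m <- c(1, 1, 0.95, 10^(-6 / 20), 0.04, 0, 0, 0.04, 10^(-6 / 20), 0.95, 1, 1)
  taps <- as.numeric(signal::fir2(n_taps - 1, f, m))
  g_band <- 20 * log10(fir_gain(taps, seq(360, 440, by = 5), fs))
  g_edges <- 20 * log10(fir_gain(taps, c(283, 566), fs))
  g_pass <- 20 * log10(fir_gain(taps, c(100, 1500), fs))
  if (max(g_band) > -60)
    stop(sprintf("notch design failed: %.1f dB in the AM band (need <= -60)",
                 max(g_band)))
  if (any(abs(g_edges + 6) > 2))
    stop("notch design failed: -6 dB octave edges not met")
  if (any(abs(g_pass) > 1))
    stop("notch design failed: passband not flat")
  taps
}

#' Generate the notch-filtered babble masker surrogate
#'
#' Seeded speech-shaped noise: four independent streams of spectrally shaped
#' noise (flat to 500 Hz, then falling ~8 dB/octave), each multiplied by its
#' own syllabic-rate (2-8 Hz) envelope, summed, notch-filtered in the octave
#' around the AM sound, and gated with cosine on/off ramps. Duration is
#' `total_am_ms + 2 * noise_lead_ms`.
#'
#' @param spec a [stimulus_spec()].
#' @param seed integer seed for the noise streams.
#' @return numeric masker waveform at `spec$audio_fs_hz`.
#' @export
make_notched_babble <- function(spec, seed = 1L) {
  validate_stimspec(spec)
  fs <- spec$audio_fs_hz
  dur_ms <- total_am_ms(spec) + 2 * spec$noise_lead_ms
  n <- round(dur_ms * fs / 1000)
  set.seed(seed)
  streams <- matrix(0, n, 4)
  lp_env <- design_lowpass(fs, 8, 2049)
  for (s in 1:4) {
    x <- speech_shaped_noise(n, fs)
    env <- zero_phase_apply(abs(stats::rnorm(n)), lp_env)
    env <- pmax(env - stats::quantile(env, 0.1), 0)
    streams[, s] <- x * env / max(abs(x * env))
  }
  babble <- rowSums(streams)
  taps <- design_notch_filter(fs)
  babble <- zero_phase_apply(babble, taps)
  # cosine on/off gates
  nr <- round(spec$ramp_ms * fs / 1000)
  gate <- rep(1, n)
  gate[1:nr] <- 0.5 * (1 - cos(pi * (seq_len(nr) - 1) / (nr - 1)))
  gate[(n - nr + 1):n] <- rev(gate[1:nr])
  babble * gate
}

# Noise with a speech-like long-term spectrum: flat below 500 Hz, then
# falling at about 8 dB per octave.
speech_shaped_noise <- function(n, fs) {
  nfft <- stats::nextn(n, 2)
  f <- seq(0, fs / 2, length.out = nfft / 2 + 1)
  shape <- ifelse(f < 500, 1, (f / 500)^(-8 / 6.02))
  shape[1] <- 0
  half <- (stats::rnorm(nfft / 2 + 1) + 1i * stats::rnorm(nfft / 2 + 1)) * shape
  half[nfft / 2 + 1] <- Re(half[nfft / 2 + 1])
  spec <- c(half, Conj(rev(half[2:(nfft / 2)])))
  x <- Re(stats::fft(spec, inverse = TRUE))[1:n]
  x / stats::sd(x)
}

#' Calibrate the masker level and build the noise-condition timeline
#'
#' Rescales the masker so that the power of the AM sound divided by the
#' power of the masker, both measured over the AM-sound interval, equals
#' `snr_db` (within 0.1 dB). The AM waveform is left untouched. In the
#' returned timeline the masker starts `noise_lead_ms` before AM onset.
#'
#' @param am quiet-condition timeline from [make_am_stimulus()], or a bare
#'   AM waveform plus `spec`.
#' @param masker masker waveform from [make_notched_babble()].
#' @param snr_db target SNR in dB (default from the spec).
#' @param spec the [stimulus_spec()] (taken from `am` when it is a timeline).
#' @return `assr_timeline` with `condition = "noise"`, the scaled masker,
#'   and attribute `realized_snr_db`.
#' @export
calibrate_and_mix <- function(am, masker, snr_db = NULL, spec = NULL) {
  if (inherits(am, "assr_timeline")) {
    spec <- am$spec
    tl <- am
    am <- tl$am
  } else {
    if (is.null(spec)) stop("spec required when `am` is a bare waveform")
    tl <- make_am_stimulus(spec)
  }
  if (is.null(snr_db)) snr_db <- spec$snr_db
  fs <- spec$audio_fs_hz
  lead <- round(spec$noise_lead_ms * fs / 1000)
  n_am <- length(am)
  if (length(masker) < lead + n_am)
    stop("masker shorter than lead + AM interval")
  seg <- masker[(lead + 1):(lead + n_am)]
  p_mask <- mean(seg^2)
  if (p_mask <= 0) stop("masker has zero power over the AM interval")
  p_am <- mean(am^2)
  scale <- sqrt(p_am / (p_mask * 10^(snr_db / 10)))
  masker <- masker * scale
  realized <- 10 * log10(p_am / mean(masker[(lead + 1):(lead + n_am)]^2))
  if (abs(realized - snr_db) > 0.1)
    stop("SNR calibration failed")
  tl$condition <- "noise"
  tl$masker <- masker
  tl$masker_lead_ms <- spec$noise_lead_ms
  attr(tl, "realized_snr_db") <- realized
  attr(tl, "masker_scale") <- scale
  tl
}

#' Export timeline events as TSV
#' @param timeline an `assr_timeline`.
#' @param path output file.
#' @export
write_events_tsv <- function(timeline, path) {
  utils::write.table(timeline$events, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a stimulus spec as JSON
#' @param spec a [stimulus_spec()].
#' @param path output file.
#' @export
write_stimspec_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
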
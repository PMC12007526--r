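#' Screen a block for head motion
#'
#' Compares the head-coil positions registered before and after the block.
#' The block is rejected if the absolute pre/post displacement of any coil
#' exceeds 4 mm along any axis (strictly larger than; a displacement of
#' exactly 4 mm is kept).
#'
#' @param recording an `assr_recording`.
#' @param threshold_mm rejection threshold (default 4).
#' @return list of class `assr_motion_report`: `displacement_mm` (coils x
#'   axes), `max_mm`, `keep`.
#' @export
screen_head_motion <- function(recording, threshold_mm = 4) {
  if (is.null(recording$headpos_pre) || is.null(recording$headpos_post))
    stop("missing head position record")
  d <- abs(recording$headpos_post - recording$headpos_pre)
  structure(list(displacement_mm = d, max_mm = max(d),
                 keep = !any(d > threshold_mm),
                 threshold_mm = threshold_mm),
            class = "assr_motion_report")
}

# power of x in time windows (list of index vectors)
.window_power <- function(x, windows) {
  mean(unlist(lapply(windows, function(i) x[i]^2)))
}

#' Remove ocular artifacts by frontal-sensor ICA regression
#'
#' An independent-component decomposition is run on the 20 most frontal
#' sensors (largest anterior coordinate). The `n_remove` components with
#' the strongest blink/eye-movement signature (ranked by kurtosis weighted
#' by sub-6-Hz spectral concentration) are selected, their waveforms
#' low-pass filtered at 6 Hz, and regressed out of *all* channels. No
#' trials are rejected. The 6-Hz low-pass confines the regression to the
#' artifact band and protects the 40-Hz response.
#'
#' @param recording an `assr_recording`.
#' @param array the [sensor_array()] the recording was simulated with
#'   (used to identify frontal channels).
#' @param n_frontal number of frontal channels for the decomposition.
#' @param n_remove number of artifact components to regress out.
#' @return list `recording` (cleaned) and `model` (an `assr_artifact_model`
#'   with component waveforms, regressors, and per-channel coefficients).
#' @export
remove_ocular <- function(recording, array, n_frontal = 20, n_remove = 2) {
  y <- array$pos[array$usable, 2]
  frontal <- order(y, decreasing = TRUE)[seq_len(n_frontal)]
  if (length(frontal) < n_frontal) stop("fewer than 20 frontal channels")
  X <- recording$data[frontal, , drop = FALSE]
  ica <- fast_ica(X, n_comp = 10)
  fs <- recording$fs
  # score components: spiky (kurtosis) and concentrated below 6 Hz
  score <- apply(ica$S, 1, function(s) {
    k <- mean((s - mean(s))^4) / stats::var(s)^2 - 3
    spec <- Mod(stats::fft(s - mean(s)))^2
    f <- (seq_along(spec) - 1) * fs / length(spec)
    lowfrac <- sum(spec[f <= 6]) / sum(spec[f <= fs / 2])
    max(k, 0) * lowfrac
  })
  plausible <- which(score > 0.5)
  if (length(plausible) < n_remove)
    warning("fewer than ", n_remove, " plausible ocular components found; ",
            "regressing ", length(plausible))
  sel <- plausible[order(score[plausible], decreasing = TRUE)]
  sel <- sel[seq_len(min(n_remove, length(sel)))]
  if (!length(sel))
    return(list(recording = recording,
                model = structure(list(kind = "ocular", components = NULL,
                                       scores = score),
                                  class = "assr_artifact_model")))
  lp <- design_lowpass(fs, 6)
  R <- vapply(sel, function(j) zero_phase_apply(ica$S[j, ], lp),
              numeric(ncol(X)))
  # regress the filtered component waveforms out of every channel
  coef <- recording$data %*% R %*% solve(crossprod(R))
  recording$data <- recording$data - tcrossprod(coef, R)
  model <- structure(list(kind = "ocular", components = ica$S[sel, , drop = FALSE],
                          regressors = R, coef = coef,
                          frontal_channels = frontal, scores = score),
                     class = "assr_artifact_model")
  list(recording = recording, model = model)
}

#' Remove cardiac artifacts by cepstrum-guided template regression
#'
#' A full-channel independent-component decomposition is computed (in a
#' reduced principal-component space). For each component the real cepstrum
#' of the waveform is evaluated; the component with the largest cepstral
#' peak in the 0.6-1.6 s quefrency range is taken as the cardiac component,
#' provided the peak exceeds `peak_sd` standard deviations of the local
#' cepstrum background. Peaks in that component's waveform mark the beats;
#' the channel-wise average around beats forms an artifact template, which
#' is regressed out at all beat times. If no component passes the
#' threshold, the recording is returned unchanged with a warning.
#'
#' @param recording an `assr_recording` of at least 60 s.
#' @param n_comp components retained in the decomposition.
#' @param peak_sd cepstral peak threshold in background SDs.
#' @return list `recording` (cleaned) and `model` (NULL when nothing was
#'   removed; otherwise an `assr_artifact_model` with beat times, the
#'   template, and per-channel coefficients).
#' @export
remove_cardiac <- function(recording, n_comp = 30, peak_sd = 4) {
  fs <- recording$fs
  n <- ncol(recording$data)
  if (n / fs < 60) stop("recording shorter than 60 s")
  ica <- fast_ica(recording$data, n_comp = min(n_comp, nrow(recording$data)))
  q_lo <- round(0.6 * fs); q_hi <- round(1.6 * fs)
  smooth_k <- round(0.01 * fs)  # ~10 ms moving average tames bin noise
  best <- list(z = -Inf, comp = NA, quef = NA)
  for (j in seq_len(nrow(ica$S))) {
    cep <- real_cepstrum(ica$S[j, ])
    band <- as.numeric(stats::filter(cep[q_lo:q_hi],
                                     rep(1 / smooth_k, smooth_k), sides = 2))
    pk <- which.max(band)
    if (is.na(pk) || !length(pk)) next
    bg <- band[abs(seq_along(band) - pk) > round(0.08 * fs)]
    z <- (band[pk] - stats::median(bg, na.rm = TRUE)) /
      stats::mad(bg, na.rm = TRUE)
    if (is.finite(z) && z > best$z)
      best <- list(z = z, comp = j, quef = (q_lo + pk - 1) / fs)
  }
  if (best$z < peak_sd) {
    warning("no component with sufficient cepstral periodicity; skipping")
    return(list(recording = recording, model = NULL))
  }
  s <- ica$S[best$comp, ]
  if (abs(min(s)) > abs(max(s))) s <- -s   # make beat deflection positive
  min_dist <- round(0.6 * best$quef * fs)
  thr <- max(5 * stats::mad(s), 0.35 * max(s))
  pk <- pracma::findpeaks(s, minpeakheight = thr,
                          minpeakdistance = min_dist)
  if (is.null(pk) || nrow(pk) < 5) {
    warning("too few beats detected; skipping cardiac removal")
    return(list(recording = recording, model = NULL))
  }
  beats <- sort(pk[, 2])
  half <- round(0.2 * best$quef * fs)
  ok <- beats > half & beats <= n - half
  beats <- beats[ok]
  win <- -half:half
  # per-channel template: average field around beats
  tmpl <- matrix(0, nrow(recording$data), length(win))
  for (b in beats) tmpl <- tmpl + recording$data[, b + win]
  tmpl <- tmpl / length(beats)
  tmpl <- tmpl - rowMeans(tmpl)
  # per-channel regressor track: template placed at each beat
  reg <- numeric(n)
  clean <- recording$data
  coef <- numeric(nrow(clean))
  for (c_ in seq_len(nrow(clean))) {
    a <- numeric(n)
    for (b in beats) a[b + win] <- a[b + win] + tmpl[c_, ]
    beta <- sum(clean[c_, ] * a) / sum(a^2)
    clean[c_, ] <- clean[c_, ] - beta * a
    coef[c_] <- beta
  }
  recording$data <- clean
  model <- structure(list(kind = "cardiac", component = best$comp,
                          cepstral_peak_sd = best$z,
                          period_s = best$quef,
                          beat_samples = beats,
                          beat_times_s = (beats - 1) / fs,
                          template = tmpl, coef = coef),
                     class = "assr_artifact_model")
  list(recording = recording, model = model)
}
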
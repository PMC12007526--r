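#' Parse onset-locked epochs and build sub-averages
#'
#' Trials are parsed into five 500-ms epoch types time-locked to the AM
#' onset and to the onset after each of the four gaps (onsets at 0, 412.5,
#' 825, 1237.5, 1650 ms). Per block, the five epoch-type averages are
#' combined into the C(5, 3) = 10 sub-averages of all three-of-five
#' combinations; with four blocks per condition this yields 40 sub-averages
#' per participant and condition.
#'
#' Since the dipoles model the 40-Hz activity, the epoch-type averages are
#' band-pass filtered (28-56 Hz, zero phase) before combination; set
#' `filter_band = FALSE` for broadband sub-averages.
#'
#' @param recordings list of `assr_recording` blocks (one condition).
#' @param spec a [stimulus_spec()].
#' @param epoch_ms epoch duration (ms).
#' @param filter_band band-pass the epoch averages at 28-56 Hz.
#' @return list of sub-averages, each a list with `data` (channels x
#'   samples), `members` (epoch types used), `block`, `condition`; empty
#'   list with a warning when no usable blocks are supplied.
#' @export
build_subaverages <- function(recordings, spec = stimulus_spec(),
                              epoch_ms = 500, filter_band = TRUE) {
  if (length(recordings) == 0) {
    warning("no usable blocks; returning empty sub-average list")
    return(list())
  }
  onsets <- burst_onsets_ms(spec)
  combos <- utils::combn(length(onsets), 3)
  out <- list()
  for (rec in recordings) {
    if (is.null(rec$events) || nrow(rec$events) == 0)
      stop("recording has no events")
    fs <- rec$fs
    n_ep <- round(epoch_ms * fs / 1000)
    type_avg <- vector("list", length(onsets))
    for (k in seq_along(onsets)) {
      acc <- matrix(0, nrow(rec$data), n_ep)
      n_used <- 0L
      for (s0 in rec$events$sample) {
        i0 <- s0 + round(onsets[k] * fs / 1000)
        if (i0 + n_ep - 1L <= ncol(rec$data)) {
          acc <- acc + rec$data[, i0:(i0 + n_ep - 1L)]
          n_used <- n_used + 1L
        }
      }
      acc <- acc / n_used
      if (filter_band) {
        taps <- .assr_taps(fs)
        acc <- t(apply(acc, 1, zero_phase_apply, taps = taps))
      }
      type_avg[[k]] <- acc
    }
    for (j in seq_len(ncol(combos))) {
      mem <- combos[, j]
      out[[length(out) + 1L]] <- list(
        data = Reduce(`+`, type_avg[mem]) / length(mem),
        members = mem, block = rec$block, condition = rec$condition,
        fs = fs)
    }
  }
  out
}

# tangential lead-field pattern pair (channels x 2) of one dipole position
.tan_gain <- function(pos, head, array) {
  lead_field(pos, head, array) %*% tangential_basis(pos, head)
}

# residual sum of squares of a bilateral tangential-dipole fit with free
# per-sample moments; returns RSS (and the fit pieces when extras = TRUE)
.pair_rss <- function(D, posL, posR, head, array, extras = FALSE,
                      GL = NULL, GR = NULL) {
  if (is.null(GL)) GL <- .tan_gain(posL, head, array)
  if (is.null(GR)) GR <- .tan_gain(posR, head, array)
  G <- cbind(GL, GR)
  qrG <- qr(G)
  M <- qr.coef(qrG, D)
  rss <- sum(D^2) - sum((G %*% M) * D)
  if (!extras) return(rss)
  list(rss = rss, G = G, M = M,
       TL = tangential_basis(posL, head), TR = tangential_basis(posR, head))
}

#' Fit a bilateral dipole pair to a sub-average
#'
#' Spatiotemporal least-squares fit: one position per hemisphere is held
#' fixed over the epoch while the (tangential) moment vectors are free per
#' sample. Starting from mirror-symmetric initial positions in the left and
#' right temporal regions, the fit alternates between hemispheres -
#' optimizing one dipole position while the other is held constant - until
#' the position change falls below 0.1 mm or 50 alternations are reached.
#' Positions are constrained inside 95% of the conductor radius.
#'
#' @param sub one sub-average from [build_subaverages()].
#' @param head a [head_model()].
#' @param array a [sensor_array()].
#' @param init optional 2 x 3 matrix of initial positions (left; right).
#' @return `assr_dipole_fit`: `pos` (2 x 3 mm), `ori` (2 x 3 unit),
#'   `amplitude` (2 x samples moment series, nAm), `gof` (variance
#'   explained), `converged`, `n_iter`.
#' @export
fit_dipole_pair <- function(sub, head, array, init = NULL) {
  D <- sub$data
  if (!all(is.finite(D))) stop("field contains non-finite values")
  if (is.null(init)) init <- rbind(c(-50, -20, 10), c(50, -20, 10))
  posL <- init[1, ]; posR <- init[2, ]
  rmax <- 0.95 * head$radius_mm
  ss <- sum(D^2)
  clamp <- function(p) {
    r <- sqrt(sum((p - head$center)^2))
    if (r > rmax) head$center + (p - head$center) * rmax / r else p
  }
  # normalized RSS of the free hemisphere, the other pattern held fixed
  obj <- function(p, Gfix, side) {
    p <- clamp(p)
    Gp <- .tan_gain(p, head, array)
    if (side == "L") .pair_rss(D, GL = Gp, GR = Gfix) / ss
    else .pair_rss(D, GL = Gfix, GR = Gp) / ss
  }
  converged <- FALSE
  it <- 0L
  for (it in seq_len(50L)) {
    oldL <- posL; oldR <- posR
    GR <- .tan_gain(posR, head, array)
    posL <- clamp(stats::optim(posL, obj, Gfix = GR, side = "L",
                               method = "Nelder-Mead",
                               control = list(maxit = 250,
                                              reltol = 1e-11))$par)
    GL <- .tan_gain(posL, head, array)
    posR <- clamp(stats::optim(posR, obj, Gfix = GL, side = "R",
                               method = "Nelder-Mead",
                               control = list(maxit = 250,
                                              reltol = 1e-11))$par)
    if (max(sqrt(sum((posL - oldL)^2)), sqrt(sum((posR - oldR)^2))) < 0.1) {
      converged <- TRUE
      break
    }
  }
  fit <- .pair_rss(D, posL, posR, head, array, extras = TRUE)
  gof <- 1 - fit$rss / sum(D^2)
  # orientation = dominant direction of the tangential moment series
  ori <- matrix(0, 2, 3)
  amp <- matrix(0, 2, ncol(D))
  for (h in 1:2) {
    Mh <- fit$M[(2 * h - 1):(2 * h), , drop = FALSE]
    Tb <- if (h == 1) fit$TL else fit$TR
    sv <- svd(Mh)
    u <- sv$u[, 1]
    ori[h, ] <- drop(Tb %*% u)
    amp[h, ] <- drop(u %*% Mh)
  }
  structure(list(pos = rbind(posL, posR), ori = ori, amplitude = amp,
                 gof = gof, converged = converged, n_iter = it,
                 block = sub$block, members = sub$members),
            class = "assr_dipole_fit")
}

#' Consolidate repeated dipole fits into a participant model
#'
#' Two-stage acceptance: (1) keep fits explaining at least `min_gof` of the
#' field variance; (2) among those, keep fits whose position lies within
#' two standard deviations of the stage-1 mean (Euclidean distance on
#' positions, per hemisphere, applied once). The model is the mean of the
#' accepted dipoles.
#'
#' @param fits list of [fit_dipole_pair()] results.
#' @param min_gof stage-1 variance-explained threshold (default 0.90).
#' @return `assr_dipole_model`: mean `pos` (2 x 3), mean unit `ori`
#'   (2 x 3), `n_accepted`, `n_total`, `accepted` (logical), `log`.
#' @export
consolidate_dipole_model <- function(fits, min_gof = 0.90) {
  if (length(fits) == 0) stop("no dipole fits supplied")
  gof <- vapply(fits, `[[`, numeric(1), "gof")
  stage1 <- gof >= min_gof
  if (!any(stage1))
    stop("no dipole fit reached ", min_gof,
         " variance explained; inspect the data")
  idx1 <- which(stage1)
  posL <- t(vapply(fits[idx1], function(f) f$pos[1, ], numeric(3)))
  posR <- t(vapply(fits[idx1], function(f) f$pos[2, ], numeric(3)))
  accept2 <- rep(TRUE, length(idx1))
  for (P in list(posL, posR)) {
    mu <- colMeans(P)
    d <- sqrt(rowSums(sweep(P, 2, mu)^2))
    s <- sqrt(mean(d^2))   # positional standard deviation about the mean
    accept2 <- accept2 & (d <= 2 * s + 1e-9)
  }
  idx <- idx1[accept2]
  if (!length(idx)) stop("no dipole fits survived the 2-SD position filter")
  mean_ori <- function(h) {
    O <- t(vapply(fits[idx], function(f) f$ori[h, ], numeric(3)))
    # align signs to the first accepted fit before averaging
    ref <- O[1, ]
    O <- O * sign(O %*% ref + 1e-15)[, 1]
    v <- colMeans(O)
    v / sqrt(sum(v^2))
  }
  accepted <- logical(length(fits))
  accepted[idx] <- TRUE
  structure(list(
    pos = rbind(colMeans(t(vapply(fits[idx], function(f) f$pos[1, ],
                                  numeric(3)))),
                colMeans(t(vapply(fits[idx], function(f) f$pos[2, ],
                                  numeric(3))))),
    ori = rbind(mean_ori(1), mean_ori(2)),
    n_accepted = length(idx), n_total = length(fits),
    accepted = accepted,
    log = data.frame(gof = gof, stage1 = stage1, accepted = accepted)),
    class = "assr_dipole_model")
}

#' Project sensor trials onto the dipole model source waveforms
#'
#' Least-squares projection of each trial's sensor data onto the two fixed
#' dipole field patterns (source-space projection), giving left and right
#' source-moment waveforms in nAm for the trial window `span_ms` around
#' each AM onset.
#'
#' @param recording an `assr_recording`.
#' @param model an `assr_dipole_model`.
#' @param head,array head model and sensor array.
#' @param span_ms trial window (ms relative to AM onset).
#' @return list `left`, `right` (samples x trials, nAm), `t_ms`, `fs`.
#' @export
project_sources <- function(recording, model, head, array,
                            span_ms = c(-500, 2500)) {
  G <- cbind(lead_field(model$pos[1, ], head, array) %*% model$ori[1, ],
             lead_field(model$pos[2, ], head, array) %*% model$ori[2, ])
  gram <- crossprod(G)
  if (rcond(gram) < 1e-12)
    stop("singular dipole pattern matrix (coincident field patterns)")
  P <- solve(gram, t(G))
  fs <- recording$fs
  i_rel <- round(span_ms[1] * fs / 1000):(round(span_ms[2] * fs / 1000) - 1L)
  trials <- recording$events$sample
  keep <- trials + min(i_rel) >= 1 & trials + max(i_rel) <= ncol(recording$data)
  trials <- trials[keep]
  L <- matrix(0, length(i_rel), length(trials))
  R <- matrix(0, length(i_rel), length(trials))
  for (j in seq_along(trials)) {
    M <- P %*% recording$data[, trials[j] + i_rel]
    L[, j] <- M[1, ]
    R[, j] <- M[2, ]
  }
  list(left = L, right = R, t_ms = i_rel * 1000 / fs, fs = fs,
       n_trials = length(trials))
}
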
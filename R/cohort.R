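#' Default effect configuration for the synthetic cohort
#'
#' The configuration encodes the cohort-level structure the generator
#' injects: group age ranges, hearing-loss and speech-in-noise (SIN) loss
#' slopes, GABA levels and their age dependence, and the per-condition ASSR
#' source parameters (target amplitudes, phase lags, buildup times,
#' laterality). Target amplitudes are expressed on the ASSR-estimate scale
#' (nAm); the simulator converts them to source-moment amplitude by the
#' estimator gain `N / (2 (N - 1))` (see [assr_estimator_gain()]).
#'
#' Slopes are per year of age, centered on the older-group mean age.
#' Setting every slope and coupling to zero yields mutually independent
#' covariates.
#'
#' @return a nested list; see the field names for meaning and units.
#' @export
default_effect_config <- function() {
  list(
    age = list(young_range = c(19, 28),
               older_range = c(69, 87),
               older_mean = 76.1, older_sd = 6.2),
    pta = list(young_mean = 8, young_sd = 4,
               older_mean = 28.6, slope_age = 1.5, sd = 5.4),   # dB HL
    sin = list(older_mean = 3.5, slope_age = 0.15,
               slope_gaba = -8, sd = 1.3),                      # dB
    gaba = list(total_mean = 1.25, total_slope_age = -0.010, total_sd = 0.07,
                gm_mean = 2.0, gm_sd = 0.25,
                cr_mean = 1.6, cr_sd = 0.20,
                young_total_mean = 1.40),                       # mMol/L
    amp = list(                                                  # nAm (ASSR scale)
      subject_cv = 0.30,   # shared multiplicative gain across conditions
      quiet_young_mean = 3.66, quiet_young_sd = 0.7,
      quiet_older_mean = 3.37, quiet_slope_age = 0.16,
      quiet_slope_gaba_gm_left = 0.9, quiet_sd = 1.0,
      noise_young_mean = 1.04, noise_young_sd = 0.30,
      noise_older_mean = 1.63, noise_slope_age = 0.12,
      noise_slope_sin = 0.20, noise_sd = 0.35,
      floor = 0.25,
      li_quiet = 0.13, li_noise = 0.03, li_sd = 0.08),
    # Latency structure (ms): quiet-condition lag for young adults, the
    # noise-condition shortening per group, and the aging delay in quiet.
    # The aging delay in noise (age_diff_quiet - cond_diff_older +
    # cond_diff_young = 3.525) and the grand means (age delay 4.39,
    # condition shortening 2.385) follow from these.
    lag = list(
      quiet_young = 33, cond_diff_young = 1.52, cond_diff_older = 3.25,
      age_diff_quiet = 5.255,
      subject_sd = 1.2, cond_sd = 0.5),
    buildup = list(quiet_ms = 200, noise_ms = 240, sd = 15),
    source = list(pos_left = c(-48, -17, 8), pos_right = c(48, -17, 8),
                  pos_jitter_mm = 3, background_sd = 5)          # nAm
  )
}

#' Null effect configuration (all slopes and couplings zero)
#' @export
null_effect_config <- function() {
  cfg <- default_effect_config()
  cfg$pta$slope_age <- 0
  cfg$sin$slope_age <- 0
  cfg$sin$slope_gaba <- 0
  cfg$gaba$total_slope_age <- 0
  cfg$amp$quiet_slope_age <- 0
  cfg$amp$quiet_slope_gaba_gm_left <- 0
  cfg$amp$noise_slope_age <- 0
  cfg$amp$noise_slope_sin <- 0
  cfg$amp$quiet_older_mean <- cfg$amp$quiet_young_mean
  cfg$amp$noise_older_mean <- cfg$amp$noise_young_mean
  cfg$lag$cond_diff_young <- 0
  cfg$lag$cond_diff_older <- 0
  cfg$lag$age_diff_quiet <- 0
  cfg
}

validate_effect_config <- function(cfg) {
  sds <- c(cfg$age$older_sd, cfg$pta$young_sd, cfg$pta$sd, cfg$sin$sd,
           cfg$gaba$total_sd, cfg$gaba$gm_sd, cfg$gaba$cr_sd,
           cfg$amp$quiet_sd, cfg$amp$noise_sd, cfg$amp$li_sd,
           cfg$lag$subject_sd, cfg$lag$cond_sd, cfg$buildup$sd)
  if (any(sds < 0)) stop("effect config infeasible: negative noise SD")
  if (abs(cfg$amp$li_quiet) >= 1 || abs(cfg$amp$li_noise) >= 1)
    stop("effect config infeasible: |laterality index| must be < 1")
  invisible(cfg)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

#' Generate a synthetic cohort
#'
#' Draws per-participant covariates (age, pure-tone average, SIN loss, six
#' GABA measures) and per-condition ASSR source parameters realizing the
#' linear structure in `effect_config` in expectation. SIN loss is generated
#' for the older group only (the speech-in-noise test is not administered to
#' the young group, where little variation is expected).
#'
#' The generative chain for the older group is: age -> PTA; age -> right
#' total GABA (negative); {age, right total GABA} -> SIN loss; {age, left GM
#' GABA} -> quiet amplitude; {age, SIN residual} -> noise amplitude. This
#' realizes the amplitude-age, amplitude-SIN-loss, and GABA-age correlations
#' as well as the age -> GABA -> SIN mediation path.
#'
#' @param n_young,n_older group sizes.
#' @param effect_config see [default_effect_config()].
#' @param seed integer seed.
#' @return data.frame, one row per participant, with ground-truth source
#'   parameters in columns (`amp_*`, `lag_*`, `buildup_*`, `pos_*`); the
#'   configuration is attached as attribute `effect_config`.
#' @export
generate_cohort <- function(n_young = 19, n_older = 19,
                            effect_config = default_effect_config(),
                            seed = 1L) {
  cfg <- validate_effect_config(effect_config)
  set.seed(seed)
  n <- n_young + n_older
  group <- rep(c("young", "older"), c(n_young, n_older))
  age <- c(stats::runif(n_young, cfg$age$young_range[1], cfg$age$young_range[2]),
           rtrunc_norm(n_older, cfg$age$older_mean, cfg$age$older_sd,
                       cfg$age$older_range[1], cfg$age$older_range[2]))
  dage <- ifelse(group == "older", age - cfg$age$older_mean, 0)

  pta <- ifelse(group == "young",
                stats::rnorm(n, cfg$pta$young_mean, cfg$pta$young_sd),
                cfg$pta$older_mean + cfg$pta$slope_age * dage +
                  stats::rnorm(n, 0, cfg$pta$sd))
  pta <- pmax(pta, 0)

  g <- cfg$gaba
  gaba_total_right <- ifelse(group == "older",
                             g$total_mean + g$total_slope_age * dage,
                             g$young_total_mean) +
    stats::rnorm(n, 0, g$total_sd)
  gaba_total_left <- ifelse(group == "older", g$total_mean,
                            g$young_total_mean) +
    stats::rnorm(n, 0, g$total_sd)
  gaba_gm_left <- stats::rnorm(n, g$gm_mean, g$gm_sd)
  gaba_gm_right <- stats::rnorm(n, g$gm_mean, g$gm_sd)
  # Cr-referenced tracks the GM concentration with extra measurement noise
  gaba_cr_left <- g$cr_mean + 0.6 * (gaba_gm_left - g$gm_mean) +
    stats::rnorm(n, 0, g$cr_sd)
  gaba_cr_right <- g$cr_mean + 0.6 * (gaba_gm_right - g$gm_mean) +
    stats::rnorm(n, 0, g$cr_sd)

  sin_resid <- stats::rnorm(n, 0, cfg$sin$sd)
  sin_loss <- ifelse(group == "older",
                     cfg$sin$older_mean + cfg$sin$slope_age * dage +
                       cfg$sin$slope_gaba *
                         (gaba_total_right - cfg$gaba$total_mean) + sin_resid,
                     NA_real_)

  a <- cfg$amp
  # mean-one multiplicative gain shared by both conditions (participants
  # with strong quiet responses also respond strongly in noise)
  subj_gain <- exp(stats::rnorm(n, -a$subject_cv^2 / 2, a$subject_cv))
  amp_quiet <- ifelse(group == "young",
                      stats::rnorm(n, a$quiet_young_mean, a$quiet_young_sd),
                      a$quiet_older_mean + a$quiet_slope_age * dage +
                        a$quiet_slope_gaba_gm_left *
                          (gaba_gm_left - cfg$gaba$gm_mean) +
                        stats::rnorm(n, 0, a$quiet_sd)) * subj_gain
  amp_noise <- ifelse(group == "young",
                      stats::rnorm(n, a$noise_young_mean, a$noise_young_sd),
                      a$noise_older_mean + a$noise_slope_age * dage +
                        a$noise_slope_sin * sin_resid +
                        stats::rnorm(n, 0, a$noise_sd)) * subj_gain
  amp_quiet <- pmax(amp_quiet, a$floor)
  amp_noise <- pmax(amp_noise, a$floor)
  li_q <- pmin(pmax(stats::rnorm(n, a$li_quiet, a$li_sd), -0.9), 0.9)
  li_n <- pmin(pmax(stats::rnorm(n, a$li_noise, a$li_sd), -0.9), 0.9)

  l <- cfg$lag
  subj_lag <- stats::rnorm(n, 0, l$subject_sd)
  mean_quiet <- l$quiet_young + ifelse(group == "older", l$age_diff_quiet, 0)
  lag_quiet <- mean_quiet + subj_lag + stats::rnorm(n, 0, l$cond_sd)
  lag_noise <- mean_quiet -
    ifelse(group == "older", l$cond_diff_older, l$cond_diff_young) +
    subj_lag + stats::rnorm(n, 0, l$cond_sd)

  b <- cfg$buildup
  buildup_quiet <- pmin(pmax(stats::rnorm(n, b$quiet_ms, b$sd), 0), 400)
  buildup_noise <- pmin(pmax(stats::rnorm(n, b$noise_ms, b$sd), 0), 400)

  s <- cfg$source
  posj <- function(base) {
    t(vapply(seq_len(n), function(i)
      base + stats::rnorm(3, 0, s$pos_jitter_mm), numeric(3)))
  }
  pl <- posj(s$pos_left)
  pr <- posj(s$pos_right)

  out <- data.frame(
    id = sprintf("P%03d", seq_len(n)), group = group, age = age,
    pta_db = pta, sin_loss_db = sin_loss,
    gaba_total_left = gaba_total_left, gaba_total_right = gaba_total_right,
    gaba_gm_left = gaba_gm_left, gaba_gm_right = gaba_gm_right,
    gaba_cr_left = gaba_cr_left, gaba_cr_right = gaba_cr_right,
    amp_quiet = amp_quiet, amp_noise = amp_noise,
    li_quiet = li_q, li_noise = li_n,
    lag_quiet_ms = lag_quiet, lag_noise_ms = lag_noise,
    buildup_quiet_ms = buildup_quiet, buildup_noise_ms = buildup_noise,
    onset_transient = group == "young" | TRUE,  # transient present in quiet
    pos_left_x = pl[, 1], pos_left_y = pl[, 2], pos_left_z = pl[, 3],
    pos_right_x = pr[, 1], pos_right_y = pr[, 2], pos_right_z = pr[, 3],
    stringsAsFactors = FALSE
  )
  attr(out, "effect_config") <- cfg
  attr(out, "seed") <- seed
  out
}

#' Per-hemisphere target ASSR amplitudes for a participant row
#'
#' Splits the hemisphere-mean target amplitude by the participant's
#' laterality index: right = A (1 + LI), left = A (1 - LI).
#'
#' @param row one row of a [generate_cohort()] table.
#' @param condition `"quiet"` or `"noise"`.
#' @return named vector `c(left=, right=)`, nAm on the ASSR-estimate scale.
#' @export
hemisphere_amplitudes <- function(row, condition) {
  A <- if (condition == "quiet") row$amp_quiet else row$amp_noise
  li <- if (condition == "quiet") row$li_quiet else row$li_noise
  c(left = A * (1 - li), right = A * (1 + li))
}
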
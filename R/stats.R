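#' Fit the psychometric function and derive SNR_50 / SIN loss
#'
#' Maximum-likelihood fit of a two-parameter logistic
#' `p(snr) = 1 / (1 + exp(-slope (snr - loc)))` to proportion-correct data
#' over SNR levels. `SNR_50` is the location; the speech-in-noise (SIN)
#' loss is `SNR_50` minus the normative -2 dB, i.e. `SNR_50 + 2`.
#'
#' @param snr_levels_db SNR levels (dB), at least 4.
#' @param proportion_correct proportions in [0, 1], one per level.
#' @param n_per_level optional trial counts per level (binomial weights;
#'   default equal weights).
#' @return list `snr50_db`, `slope`, `sin_loss_db`.
#' @export
fit_snr50 <- function(snr_levels_db, proportion_correct, n_per_level = NULL) {
  x <- as.numeric(snr_levels_db)
  p <- as.numeric(proportion_correct)
  if (length(x) < 4) stop("at least 4 SNR levels required")
  if (any(p < 0 | p > 1)) stop("proportions must be in [0, 1]")
  if (all(p == 0) || all(p == 1))
    stop("degenerate psychometric data (all 0 or all 1)")
  w <- if (is.null(n_per_level)) rep(1, length(x)) else as.numeric(n_per_level)
  nll <- function(par) {
    loc <- par[1]
    slope <- exp(par[2])
    q <- stats::plogis(slope * (x - loc))
    q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
    -sum(w * (p * log(q) + (1 - p) * log(1 - q)))
  }
  # note: psychometric slope is positive (performance rises with SNR in the
  # score convention used here)
  init <- c(stats::weighted.mean(x, w * p * (1 - p) + 1e-6), 0)
  fit <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  loc <- fit$par[1]
  list(snr50_db = loc, slope = exp(fit$par[2]), sin_loss_db = loc + 2)
}

#' Mixed-design ANOVA with generalized eta squared
#'
#' Classic mixed-measures ANOVA with one between-participant factor and up
#' to two within-participant factors, on a long-format table. Sums of
#' squares come from `stats::aov` with `Error(subject/(w1*w2))` strata;
#' generalized eta squared for each effect is
#' `SS_effect / (SS_effect + sum of all error-stratum SS)`.
#'
#' @param table long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param within character vector of within-factor column names (1 or 2).
#' @param between name of the between-group factor column.
#' @param subject name of the participant-id column.
#' @return data.frame with effect, df1, df2, F, p, ges.
#' @export
mixed_anova <- function(table, dv, within = c("hemisphere", "condition"),
                        between = "group", subject = "id") {
  d <- table[, c(subject, between, within, dv)]
  if (anyNA(d)) stop("missing cells in the ANOVA table")
  names(d) <- c(".id", ".grp", paste0(".w", seq_along(within)), ".y")
  for (v in setdiff(names(d), ".y")) d[[v]] <- factor(d[[v]])
  counts <- table(d[, grep("^\\.w", names(d)), drop = FALSE])
  if (length(unique(as.vector(counts))) != 1)
    stop("within-participant design is unbalanced")
  wterms <- paste(grep("^\\.w", names(d), value = TRUE), collapse = "*")
  form <- stats::as.formula(paste0(
    ".y ~ .grp*", wterms, " + Error(.id/(", wterms, "))"))
  fit <- stats::aov(form, data = d)
  sm <- summary(fit)
  rows <- list()
  err_ss <- 0
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    for (r in seq_along(terms)) {
      if (terms[r] == "Residuals") {
        err_ss <- err_ss + tab[r, "Sum Sq"]
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          effect = terms[r], df1 = tab[r, "Df"],
          df2 = tab[nrow(tab), "Df"], ss = tab[r, "Sum Sq"],
          F = tab[r, "F value"], p = tab[r, "Pr(>F)"])
      }
    }
  }
  out <- do.call(rbind, rows)
  out$ges <- out$ss / (out$ss + err_ss)
  out$effect <- gsub("\\.grp", between, out$effect)
  for (k in seq_along(within))
    out$effect <- gsub(paste0("\\.w", k), within[k], out$effect)
  rownames(out) <- NULL
  out[, c("effect", "df1", "df2", "ss", "F", "p", "ges")]
}

#' Ordinary least-squares linear model summary
#'
#' Simple regression of y on x via `stats::lm`, reporting the quantities
#' used throughout the cohort analyses: slope and intercept with 95% CIs,
#' R^2, the model F test, and p.
#'
#' @param x,y numeric vectors (n >= 3; x must vary).
#' @return list slope, intercept, r.squared, F, df, p.value, ci_slope,
#'   ci_intercept.
#' @export
fit_linear <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (stats::var(x) == 0) stop("x is constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r.squared = sm$r.squared,
       F = unname(sm$fstatistic[1]),
       df = unname(sm$fstatistic[2:3]),
       p.value = unname(stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                                  sm$fstatistic[3], lower.tail = FALSE)),
       ci_slope = unname(ci[2, ]), ci_intercept = unname(ci[1, ]),
       n = length(x))
}

#' Two-sample (Welch) or paired group contrast
#'
#' t statistics with 95% CIs on the means and the difference. With zero
#' variance in both groups and equal means the convention t = 0, p = 1 is
#' returned.
#'
#' @param x,y numeric samples.
#' @param paired paired contrast (default two-sample Welch).
#' @return list t, df, p.value, estimate (mean difference), ci.
#' @export
group_contrast <- function(x, y, paired = FALSE) {
  ok <- if (paired) stats::complete.cases(x, y) else NULL
  if (paired) { x <- x[ok]; y <- y[ok] }
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  degenerate <- if (paired) stats::var(x - y) == 0 else
    stats::var(x) == 0 && stats::var(y) == 0
  if (degenerate) {
    d <- if (paired) mean(x - y) else mean(x) - mean(y)
    if (d == 0)
      return(list(t = 0, df = NA_real_, p.value = 1, estimate = 0,
                  ci = c(0, 0)))
  }
  tt <- stats::t.test(x, y, paired = paired)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value,
       estimate = if (paired) unname(tt$estimate) else
         unname(diff(rev(tt$estimate))),
       ci = as.numeric(tt$conf.int))
}

# fast OLS path coefficients for the mediation triple
.med_paths <- function(X, M, Y) {
  a <- stats::cov(X, M) / stats::var(X)
  c_tot <- stats::cov(X, Y) / stats::var(X)
  # Y ~ X + M
  sxx <- stats::var(X); smm <- stats::var(M)
  sxm <- stats::cov(X, M); sxy <- stats::cov(X, Y); smy <- stats::cov(M, Y)
  det <- sxx * smm - sxm^2
  cp <- (sxy * smm - smy * sxm) / det
  b <- (smy * sxx - sxy * sxm) / det
  c(a = a, b = b, c = c_tot, cp = cp, ab = a * b)
}

#' Bootstrap mediation analysis
#'
#' Tests whether the relationship between X and Y is transmitted through a
#' mediator M: path a (M ~ X), paths b and c' (Y ~ X + M), total effect c
#' (Y ~ X), indirect effect a*b. Significance by case-resampling bootstrap
#' with percentile confidence intervals and two-sided bootstrap p-values.
#' The OLS identity c = c' + a*b holds exactly on any data.
#'
#' @param X,M,Y numeric vectors (complete triples, n >= 10).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return `assr_mediation`: data.frame `paths` (estimate, ci_lo, ci_hi, z,
#'   p per path), `n`, `n_boot`, `seed`.
#' @export
mediate <- function(X, M, Y, n_boot = 1000, seed = 1L, conf = 0.95) {
  ok <- stats::complete.cases(X, M, Y)
  X <- X[ok]; M <- M[ok]; Y <- Y[ok]
  n <- length(X)
  if (n < 10) stop("need at least 10 complete triples")
  if (stats::var(X) == 0) stop("X is constant")
  est <- .med_paths(X, M, Y)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(est))
  for (b in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    if (stats::var(X[i]) == 0) i <- seq_len(n)
    boot[b, ] <- .med_paths(X[i], M[i], Y[i])
  }
  alpha <- 1 - conf
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2))
  pvals <- vapply(seq_along(est), function(k) {
    lo <- mean(boot[, k] <= 0); hi <- mean(boot[, k] >= 0)
    max(2 * min(lo, hi), 1 / n_boot)
  }, numeric(1))
  z <- est / apply(boot, 2, stats::sd)
  paths <- data.frame(path = names(est), estimate = unname(est),
                      ci_lo = ci[1, ], ci_hi = ci[2, ], z = unname(z),
                      p = pvals)
  rownames(paths) <- NULL
  structure(list(paths = paths, n = n, n_boot = n_boot, seed = seed),
            class = "assr_mediation")
}

#' Four-frequency pure-tone average
#'
#' Mean hearing threshold over the octave frequencies 500-4000 Hz.
#'
#' @param thresholds named numeric: `hz500`, `hz1000`, `hz2000`, `hz4000`.
#' @export
pure_tone_average <- function(thresholds) {
  need <- c("hz500", "hz1000", "hz2000", "hz4000")
  if (!all(need %in% names(thresholds)))
    stop("thresholds must include ", paste(need, collapse = ", "))
  mean(unlist(thresholds[need]))
}
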
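test_that("psychometric fit recovers SNR_50 and converts to SIN loss", {
  # symmetric step-like data: the midpoint level is the location
  lev <- c(-2, 0, 2, 4, 6)
  fit <- fit_snr50(lev, c(0, 0, 0.5, 1, 1))
  expect_equal(fit$snr50_db, 2, tolerance = 1e-3)
  expect_equal(fit$sin_loss_db, 4, tolerance = 1e-3)
  # recovery from binomial draws off a known logistic
  set.seed(31)
  lev <- seq(-4, 7, by = 1)
  p_true <- plogis(1 * (lev - 1.5))
  k <- rbinom(length(lev), 500, p_true)
  fit <- fit_snr50(lev, k / 500, n_per_level = rep(500, length(lev)))
  expect_equal(fit$snr50_db, 1.5, tolerance = 0.2)
  expect_equal(fit$slope, 1, tolerance = 0.25)
  # shifting all levels shifts the location equally
  fit3 <- fit_snr50(lev + 3, k / 500, n_per_level = rep(500, length(lev)))
  expect_equal(fit3$snr50_db - fit$snr50_db, 3, tolerance = 1e-6)
  expect_error(fit_snr50(lev, rep(0, length(lev))), "degenerate")
  expect_error(fit_snr50(c(0, 1), c(0.2, 0.8)), "4 SNR levels")
})

test_that("mixed ANOVA matches the brute-force sums-of-squares oracle", {
  set.seed(12)
  d <- expand.grid(id = paste0("s", 1:8),
                   hemisphere = c("left", "right"),
                   condition = c("quiet", "noise"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$id %in% paste0("s", 1:4), "young", "older")
  d$y <- rnorm(nrow(d)) + 2 * (d$condition == "quiet") +
    0.5 * (d$group == "older") * (d$condition == "quiet")
  res <- mixed_anova(d, "y")
  oracle <- brute_force_mixed_anova(d)
  pick <- function(eff) res[res$effect == eff, ]
  pairs <- list(c("group", "A"), c("hemisphere", "B"),
                c("condition", "C"), c("group:hemisphere", "A:B"),
                c("group:condition", "A:C"),
                c("hemisphere:condition", "B:C"),
                c("group:hemisphere:condition", "A:B:C"))
  for (pr in pairs) {
    expect_equal(pick(pr[1])$F, oracle$F[oracle$effect == pr[2]],
                 tolerance = 1e-10, label = pr[1])
    expect_equal(pick(pr[1])$p, oracle$p[oracle$effect == pr[2]],
                 tolerance = 1e-10)
  }
  # generalized eta squared stays in [0, 1]
  expect_true(all(res$ges >= 0 & res$ges <= 1))
  # all cells equal: every effect sum of squares vanishes
  d0 <- d; d0$y <- 5
  res0 <- mixed_anova(d0, "y")
  expect_true(all(res0$ss < 1e-20))
  dm <- d[-1, ]
  expect_error(mixed_anova(dm, "y"), "unbalanced|missing")
})

test_that("a pure condition effect is detected at nominal null rates", {
  set.seed(77)
  n_rep <- 120
  p_cond <- p_grp <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    d <- expand.grid(id = paste0("s", 1:10),
                     hemisphere = c("l", "r"), condition = c("q", "n"),
                     stringsAsFactors = FALSE)
    d$group <- ifelse(d$id %in% paste0("s", 1:5), "young", "older")
    d$y <- rnorm(nrow(d), sd = 0.5) + 2 * (d$condition == "q")
    res <- mixed_anova(d, "y")
    p_cond[r] <- res$p[res$effect == "condition"]
    p_grp[r] <- res$p[res$effect == "group"]
  }
  expect_true(all(p_cond < 0.001))
  # null group effect rejected at ~alpha (binomial upper bound)
  expect_lt(mean(p_grp < 0.05), 0.05 + 2.6 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("linear model equals the closed-form normal equations", {
  x <- c(1, 2, 3, 5, 8, 9)
  y <- 2 * x
  f <- suppressWarnings(fit_linear(x, y))   # exact fit trips lm warnings
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$r.squared, 1)
  set.seed(4)
  y <- 1.3 + 0.7 * x + rnorm(6, 0, 0.4)
  f <- fit_linear(x, y)
  sxx <- sum((x - mean(x))^2)
  slope_cf <- sum((x - mean(x)) * (y - mean(y))) / sxx
  expect_equal(f$slope, slope_cf, tolerance = 1e-12)
  expect_equal(f$intercept, mean(y) - slope_cf * mean(x), tolerance = 1e-12)
  expect_error(fit_linear(rep(1, 5), 1:5), "constant")
  # null calibration: p uniform over replicates
  set.seed(8)
  pv <- replicate(1000, fit_linear(rnorm(20), rnorm(20))$p.value)
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("group contrasts match the closed-form t statistics", {
  x <- c(1.1, 2.3, 3.1); y <- c(2.0, 2.9, 4.2)
  gc <- group_contrast(x, y)
  se <- sqrt(var(x) / 3 + var(y) / 3)
  expect_equal(gc$t, (mean(x) - mean(y)) / se, tolerance = 1e-12)
  expect_equal(gc$estimate, mean(x) - mean(y), tolerance = 1e-12)
  gp <- group_contrast(x, y, paired = TRUE)
  d <- x - y
  expect_equal(gp$t, mean(d) / (sd(d) / sqrt(3)), tolerance = 1e-12)
  # identical degenerate groups: t = 0, p = 1 convention
  same <- group_contrast(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p.value, 1)
})

test_that("mediation: identity, recovery, and null calibration", {
  set.seed(19)
  X <- rnorm(60); M <- 0.4 * X + rnorm(60); Y <- 0.5 * M - 0.2 * X + rnorm(60)
  med <- mediate(X, M, Y, n_boot = 300, seed = 2)
  p <- med$paths
  est <- function(nm) p$estimate[p$path == nm]
  # OLS identity c = c' + a b, exact on any data
  expect_equal(est("c"), est("cp") + est("ab"), tolerance = 1e-10)
  # chain recovery at large n
  set.seed(23)
  X <- rnorm(2000); M <- 0.5 * X + rnorm(2000); Y <- 0.5 * M + rnorm(2000)
  med <- mediate(X, M, Y, n_boot = 500, seed = 3)
  p <- med$paths
  expect_equal(p$estimate[p$path == "ab"], 0.25, tolerance = 0.02 / 0.25)
  ci_cp <- unlist(p[p$path == "cp", c("ci_lo", "ci_hi")])
  expect_true(ci_cp[1] <= 0 && ci_cp[2] >= 0)
  expect_lt(p$p[p$path == "ab"], 0.01)
  # independent mediator: indirect effect rejected at most at alpha
  set.seed(29)
  rej <- mean(replicate(400, {
    X <- rnorm(50); M <- rnorm(50); Y <- 0.3 * X + rnorm(50)
    m <- mediate(X, M, Y, n_boot = 200, seed = sample.int(1e6, 1))
    m$paths$p[m$paths$path == "ab"] < 0.05
  }))
  expect_lt(rej, 0.05 + 2.6 * sqrt(0.05 * 0.95 / 400))
  expect_error(mediate(rep(1, 20), rnorm(20), rnorm(20)), "constant")
  expect_error(mediate(rnorm(5), rnorm(5), rnorm(5)), "10")
})

test_that("statistics are invariant to row order", {
  set.seed(40)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  o <- sample(30)
  f1 <- fit_linear(x, y); f2 <- fit_linear(x[o], y[o])
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  m1 <- mediate(x, y, x + y, n_boot = 50, seed = 1)
  m2 <- mediate(x[o], y[o], x[o] + y[o], n_boot = 50, seed = 1)
  expect_equal(m1$paths$estimate, m2$paths$estimate, tolerance = 1e-12)
})

test_that("pure-tone average is the mean over 500-4000 Hz", {
  expect_equal(pure_tone_average(list(hz500 = 10, hz1000 = 20,
                                      hz2000 = 30, hz4000 = 40)), 25)
  expect_error(pure_tone_average(list(hz500 = 10)), "hz1000")
})
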
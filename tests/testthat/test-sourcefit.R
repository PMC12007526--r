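test_that("sub-average construction yields C(5,3) = 10 per block", {
  recs <- fx_recording()
  quiet <- recs[1]
  subs <- build_subaverages(quiet)
  expect_equal(length(subs), 10)
  expect_equal(unique(vapply(subs, function(s) ncol(s$data), numeric(1))),
               round(0.5 * 1250))
  members <- t(vapply(subs, `[[`, numeric(3), "members"))
  expect_equal(nrow(unique(members)), 10)
  # four blocks give 40
  four <- build_subaverages(rep(quiet, 4))
  expect_equal(length(four), 40)
  # no usable blocks: empty with a warning
  expect_warning(none <- build_subaverages(list()), "no usable")
  expect_equal(length(none), 0)
  bad <- quiet[[1]]; bad$events <- NULL
  expect_error(build_subaverages(list(bad)), "events")
})

test_that("noiseless dipole pair is recovered within 1 mm", {
  fx <- fx_noiseless_subaverage()
  fit <- fit_dipole_pair(fx$sub, fx_head(), fx_array())
  expect_true(fit$converged)
  expect_gt(fit$gof, 0.999)
  expect_lt(sqrt(sum((fit$pos[1, ] - fx$pos[1, ])^2)), 1)
  expect_lt(sqrt(sum((fit$pos[2, ] - fx$pos[2, ])^2)), 1)
  # orientations recovered up to sign
  expect_gt(abs(sum(fit$ori[1, ] * fx$ori[1, ])), 0.99)
  # moment time series recovered
  expect_equal(stats::sd(fit$amplitude[1, ]), stats::sd(fx$mL),
               tolerance = 0.01)
})

test_that("a single left source leaves the right dipole silent", {
  fx <- fx_noiseless_subaverage()
  sub <- fx$sub
  sub$data <- outer(fx$gL, fx$mL)
  fit <- fit_dipole_pair(sub, fx_head(), fx_array())
  expect_gt(fit$gof, 0.999)
  expect_lt(sqrt(sum((fit$pos[1, ] - fx$pos[1, ])^2)), 1)
  expect_lt(stats::sd(fit$amplitude[2, ]), 0.01 * stats::sd(fit$amplitude[1, ]))
})

test_that("noisy sub-averages localize within 5 mm", {
  recs <- fx_clean_recording()
  subs <- build_subaverages(recs[1])
  fits <- lapply(subs[1:5], fit_dipole_pair, head = fx_head(),
                 array = fx_array())
  tp <- truth_pos(fx_cohort1()[1, ])
  errs <- vapply(fits, function(f)
    max(sqrt(sum((f$pos[1, ] - tp[1, ])^2)),
        sqrt(sum((f$pos[2, ] - tp[2, ])^2))), numeric(1))
  expect_gte(mean(errs < 5), 0.9)
  expect_true(all(vapply(fits, function(f) f$gof >= 0.9, logical(1))))
})

test_that("two-stage acceptance filters by fit quality and position", {
  mk <- function(pos_shift = c(0, 0, 0), gof = 0.99) {
    structure(list(pos = rbind(c(-48, -17, 8) + pos_shift,
                               c(48, -17, 8) + pos_shift),
                   ori = rbind(c(0, 1, 0), c(0, 1, 0)),
                   gof = gof, converged = TRUE),
              class = "assr_dipole_fit")
  }
  # identical perfect fits: all accepted, model equals the common fit
  fits <- replicate(40, mk(), simplify = FALSE)
  m <- consolidate_dipole_model(fits)
  expect_equal(m$n_accepted, 40)
  expect_equal(m$pos[1, ], c(-48, -17, 8))
  # one gross outlier among clustered fits is dropped
  set.seed(2)
  fits <- c(lapply(1:39, function(i) mk(rnorm(3, 0, 0.5))),
            list(mk(c(30, 0, 0))))
  m <- consolidate_dipole_model(fits)
  expect_equal(m$n_accepted, 39)
  expect_false(m$accepted[40])
  # fits below 90% variance explained never enter
  expect_error(consolidate_dipole_model(replicate(5, mk(gof = 0.85),
                                                  simplify = FALSE)),
               "variance")
  mixed <- c(replicate(3, mk(), simplify = FALSE), list(mk(gof = 0.5)))
  expect_equal(consolidate_dipole_model(mixed)$n_accepted, 3)
})

test_that("source projection is self-consistent, linear, low-crosstalk", {
  fx <- fx_noiseless_subaverage()
  model <- structure(list(pos = fx$pos, ori = fx$ori, n_accepted = 1),
                     class = "assr_dipole_model")
  # build a fake one-trial recording: 3.5 nAm moment on the left dipole
  fs <- 1250
  n <- 3750 + 1250
  m <- 3.5 * sin(2 * pi * 40 * seq_len(n) / fs)
  rec <- list(data = outer(fx$gL, m), fs = fs,
              events = data.frame(sample = 626, onset_ms = 500, trial = 1,
                                  label = "am_onset"))
  pr <- project_sources(rec, model, fx_head(), fx_array())
  i <- 100:3000
  expect_lt(max(abs(pr$left[i, 1] - m[625 + i])) / 3.5, 1e-6)
  # crosstalk bounded by the pattern correlation
  expect_lt(stats::sd(pr$right[, 1]), 0.02 * stats::sd(pr$left[, 1]))
  # linearity of the projection
  rec2 <- rec; rec2$data <- 2 * rec$data
  pr2 <- project_sources(rec2, model, fx_head(), fx_array())
  expect_equal(pr2$left, 2 * pr$left, tolerance = 1e-12)
  # white sensor noise projects to zero-mean output with the analytic gain
  set.seed(5)
  sigma <- 100e-15
  recn <- rec
  recn$data <- matrix(rnorm(length(rec$data), 0, sigma), nrow(rec$data))
  prn <- project_sources(recn, model, fx_head(), fx_array())
  G <- cbind(lead_field(fx$pos[1, ], fx_head(), fx_array()) %*% fx$ori[1, ],
             lead_field(fx$pos[2, ], fx_head(), fx_array()) %*% fx$ori[2, ])
  gain <- solve(crossprod(G))[1, 1]    # variance gain for unit noise
  expect_equal(stats::var(prn$left[, 1]), sigma^2 * gain, tolerance = 0.05)
  expect_lt(abs(mean(prn$left[, 1])), 3 * sigma * sqrt(gain) / sqrt(3750))
  # coincident dipoles: singular pattern matrix
  model_bad <- model; model_bad$pos[2, ] <- model$pos[1, ]
  model_bad$ori[2, ] <- model$ori[1, ]
  expect_error(project_sources(rec, model_bad, fx_head(), fx_array()),
               "singular|computationally")
})
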
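#' Study run configuration
#'
#' Bundles every knob of a simulated study run. Two analysis levels are
#' supported: `"source"` runs the cohort analysis on simulated source
#' waveforms directly (fast; used for cohort-scale statistics), while
#' `"sensor"` runs the full chain - sensor simulation, motion screening,
#' artifact removal, sub-averaging, dipole fitting, and source projection -
#' before the ASSR statistics (slow; used at reduced scale).
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param n_young,n_older cohort sizes.
#' @param effect_config see [default_effect_config()].
#' @param blocks_per_condition,trials_per_block block structure.
#' @param n_trials_source trials per condition for the source-level path.
#' @param level `"source"` or `"sensor"`.
#' @param bootstrap run the phase-randomization bootstrap per participant.
#' @param n_boot bootstrap resamples.
#' @param recording_config see [default_recording_config()].
#' @param stages stages to run (subset of simulate/assr/stats; later stages
#'   can be run alone by passing tables through `run_study`'s `inputs`).
#' @param out_dir optional output directory for the results bundle.
#' @export
run_config <- function(seed = 1L, n_young = 19, n_older = 19,
                       effect_config = default_effect_config(),
                       blocks_per_condition = 4, trials_per_block = 75,
                       n_trials_source = 100,
                       level = c("source", "sensor"),
                       bootstrap = TRUE, n_boot = 1000,
                       recording_config = default_recording_config(),
                       stages = c("simulate", "assr", "stats"),
                       out_dir = NULL) {
  structure(list(seed = as.integer(seed), n_young = n_young,
                 n_older = n_older, effect_config = effect_config,
                 blocks_per_condition = blocks_per_condition,
                 trials_per_block = trials_per_block,
                 n_trials_source = n_trials_source,
                 level = match.arg(level), bootstrap = bootstrap,
                 n_boot = n_boot, recording_config = recording_config,
                 stages = stages, out_dir = out_dir),
            class = "assr_config")
}

.stage_seed <- function(config, i, offset = 0L) {
  as.integer((config$seed * 7919 + i * 104729 + offset) %% 2147483647L)
}

#' ASSR outcomes for one participant, source-level path
#'
#' Simulates per-trial source waveforms for both conditions, prepares the
#' trial averages, and computes the per-hemisphere ASSR estimates (and
#' optionally the bootstrap p).
#'
#' @param row cohort row; see [generate_cohort()].
#' @param config an [run_config()].
#' @param i participant index (seeding).
#' @param spec stimulus spec.
#' @return one-row data.frame of amplitudes, phases, and p-values.
#' @keywords internal
participant_assr_source <- function(row, config, i, spec = stimulus_spec()) {
  out <- list(id = row$id)
  onsets <- burst_onsets_ms(spec)
  bg <- config$effect_config$source$background_sd
  for (cond in c("quiet", "noise")) {
    sw <- simulate_source_waveform(
      row, cond, spec, n_trials = config$n_trials_source,
      seed = .stage_seed(config, i, if (cond == "quiet") 1L else 2L),
      background_sd = bg)
    for (h in c("left", "right")) {
      prep <- prepare_average(sw[[h]], sw$t_ms, sw$fs)
      est <- compute_assr(prep, onsets)
      out[[paste0("amp_", cond, "_", h)]] <- est$amplitude
      out[[paste0("phase_", cond, "_", h)]] <- est$phase
      if (config$bootstrap) {
        bs <- bootstrap_significance(
          sw[[h]], sw$t_ms, sw$fs, onsets, n_resamples = config$n_boot,
          seed = .stage_seed(config, i, 10L))
        out[[paste0("p_", cond, "_", h)]] <- bs$p
      }
    }
  }
  as.data.frame(out)
}

#' ASSR outcomes for one participant, full sensor-level path
#'
#' Simulates block recordings, screens head motion, removes ocular and
#' cardiac artifacts, builds sub-averages, fits and consolidates the
#' bilateral dipole model per condition, projects single-trial source
#' waveforms, and computes the ASSR estimates.
#'
#' @inheritParams participant_assr_source
#' @param array,head sensor array and head model.
#' @return list: `row` (one-row data.frame as in the source path), `models`
#'   (dipole models per condition), `motion` (reports per block).
#' @keywords internal
participant_assr_sensor <- function(row, config, i, spec = stimulus_spec(),
                                    array = sensor_array(),
                                    head = head_model()) {
  recs <- simulate_recording(
    row, blocks_per_condition = config$blocks_per_condition,
    trials_per_block = config$trials_per_block, spec = spec, array = array,
    head = head, config = config$recording_config,
    background_sd = config$effect_config$source$background_sd,
    seed = .stage_seed(config, i, 3L))
  motion <- lapply(recs, screen_head_motion)
  keep <- vapply(motion, `[[`, logical(1), "keep")
  recs <- recs[keep]
  rc <- config$recording_config
  recs <- lapply(recs, function(r) {
    if (rc$blink_rate_hz > 0 && rc$blink_amp_t > 0)
      r <- remove_ocular(r, array)$recording
    if (rc$cardiac_rate_hz > 0 && rc$cardiac_amp_t > 0)
      r <- suppressWarnings(remove_cardiac(r)$recording)
    r
  })
  out <- list(id = row$id)
  models <- list()
  onsets <- burst_onsets_ms(spec)
  for (cond in c("quiet", "noise")) {
    blocks <- Filter(function(r) r$condition == cond, recs)
    subs <- build_subaverages(blocks, spec)
    fits <- lapply(subs, fit_dipole_pair, head = head, array = array)
    model <- consolidate_dipole_model(fits)
    models[[cond]] <- model
    trials <- list(left = NULL, right = NULL)
    for (b in blocks) {
      pr <- project_sources(b, model, head, array)
      trials$left <- cbind(trials$left, pr$left)
      trials$right <- cbind(trials$right, pr$right)
      t_ms <- pr$t_ms
      fs <- pr$fs
    }
    for (h in c("left", "right")) {
      prep <- prepare_average(trials[[h]], t_ms, fs)
      est <- compute_assr(prep, onsets)
      out[[paste0("amp_", cond, "_", h)]] <- est$amplitude
      out[[paste0("phase_", cond, "_", h)]] <- est$phase
      if (config$bootstrap) {
        bs <- bootstrap_significance(
          trials[[h]], t_ms, fs, onsets, n_resamples = config$n_boot,
          seed = .stage_seed(config, i, 10L))
        out[[paste0("p_", cond, "_", h)]] <- bs$p
      }
    }
  }
  list(row = as.data.frame(out), models = models, motion = motion)
}

#' Assemble the per-participant measures table
#'
#' Joins the cohort covariates with the ASSR outcomes and adds the
#' hemisphere-averaged amplitudes `(L + R) / 2` used for the linear models.
#'
#' @param cohort [generate_cohort()] table.
#' @param assr_table per-participant ASSR outcome rows.
#' @return data.frame, one row per participant.
#' @export
build_measures_table <- function(cohort, assr_table) {
  keep <- c("id", "group", "age", "pta_db", "sin_loss_db",
            grep("^gaba_", names(cohort), value = TRUE))
  tab <- merge(cohort[, keep], assr_table, by = "id", sort = FALSE)
  tab$amp_quiet_mean <- (tab$amp_quiet_left + tab$amp_quiet_right) / 2
  tab$amp_noise_mean <- (tab$amp_noise_left + tab$amp_noise_right) / 2
  tab$phase_quiet_mean <- Arg(exp(1i * tab$phase_quiet_left) +
                                exp(1i * tab$phase_quiet_right))
  tab$phase_noise_mean <- Arg(exp(1i * tab$phase_noise_left) +
                                exp(1i * tab$phase_noise_right))
  tab[order(match(tab$id, cohort$id)), ]
}

# long format for the mixed ANOVA
.measures_long <- function(tab, what = c("amplitude", "latency")) {
  what <- match.arg(what)
  rows <- list()
  for (cond in c("quiet", "noise")) for (h in c("left", "right")) {
    y <- if (what == "amplitude") tab[[paste0("amp_", cond, "_", h)]] else
      -1000 * tab[[paste0("phase_", cond, "_", h)]] / (2 * pi * 40)
    rows[[length(rows) + 1L]] <- data.frame(
      id = tab$id, group = tab$group, hemisphere = h, condition = cond,
      y = y)
  }
  do.call(rbind, rows)
}

#' Cohort statistics over the measures table
#'
#' Runs the group-level analyses: mixed ANOVAs on amplitude and phase-based
#' latency (within: hemisphere, condition; between: age group), group and
#' condition contrasts, laterality indices, noise-attenuation ratios,
#' age/hearing/GABA linear models within the older group, and the three
#' mediation models (age -> GABA -> SIN loss; age -> gamma -> SIN loss;
#' gamma -> GABA -> SIN loss).
#'
#' @param tab a [build_measures_table()] result.
#' @param n_boot mediation bootstrap resamples.
#' @param seed integer seed.
#' @return nested list of results.
#' @export
cohort_statistics <- function(tab, n_boot = 1000, seed = 1L) {
  old <- tab[tab$group == "older", ]
  yng <- tab[tab$group == "young", ]
  res <- list()
  res$anova_amplitude <- mixed_anova(.measures_long(tab, "amplitude"), "y")
  res$anova_latency <- mixed_anova(.measures_long(tab, "latency"), "y")

  res$amp_quiet_mean <- mean(c(tab$amp_quiet_left, tab$amp_quiet_right))
  res$amp_noise_mean <- mean(c(tab$amp_noise_left, tab$amp_noise_right))
  res$amp_condition_contrast <- group_contrast(
    (tab$amp_quiet_left + tab$amp_quiet_right) / 2,
    (tab$amp_noise_left + tab$amp_noise_right) / 2, paired = TRUE)

  res$li_quiet <- mean(laterality_index(tab$amp_quiet_right,
                                        tab$amp_quiet_left))
  res$li_noise <- mean(laterality_index(tab$amp_noise_right,
                                        tab$amp_noise_left))

  # per-participant latency contrasts via the half-period unwrap
  cond_dt <- mapply(function(pq, pn)
    latency_contrast(pn, pq)$dt_ms,      # quiet later than noise -> positive
    tab$phase_quiet_mean, tab$phase_noise_mean)
  res$latency_condition_ms <- mean(cond_dt)
  res$latency_condition_ms_young <- mean(cond_dt[tab$group == "young"])
  res$latency_condition_ms_older <- mean(cond_dt[tab$group == "older"])
  age_dt <- function(cond) {
    ph <- tab[[paste0("phase_", cond, "_mean")]]
    py <- Arg(mean(exp(1i * ph[tab$group == "young"])))
    po <- Arg(mean(exp(1i * ph[tab$group == "older"])))
    latency_contrast(py, po)$dt_ms       # older later -> positive
  }
  res$latency_age_ms <- mean(c(age_dt("quiet"), age_dt("noise")))

  res$attenuation_young <- mean(attenuation_ratio(yng$amp_quiet_mean,
                                                  yng$amp_noise_mean))
  res$attenuation_older <- mean(attenuation_ratio(old$amp_quiet_mean,
                                                  old$amp_noise_mean))

  res$lm_quiet_age <- fit_linear(old$age, old$amp_quiet_mean)
  res$lm_noise_age <- fit_linear(old$age, old$amp_noise_mean)
  res$lm_noise_pta <- fit_linear(old$pta_db, old$amp_noise_mean)
  res$lm_noise_sin <- fit_linear(old$sin_loss_db, old$amp_noise_mean)
  res$lm_quiet_gaba_gm_left <- fit_linear(old$gaba_gm_left,
                                          old$amp_quiet_mean)
  res$lm_pta_age <- fit_linear(old$age, old$pta_db)
  res$lm_sin_age <- fit_linear(old$age, old$sin_loss_db)
  res$lm_gaba_total_right_age <- fit_linear(old$age, old$gaba_total_right)

  res$mediation_age_gaba_sin <- mediate(old$age, old$gaba_total_right,
                                        old$sin_loss_db, n_boot, seed)
  res$mediation_age_gamma_sin <- mediate(old$age, old$amp_noise_mean,
                                         old$sin_loss_db, n_boot, seed + 1L)
  res$mediation_gamma_gaba_sin <- mediate(old$amp_noise_mean,
                                          old$gaba_total_right,
                                          old$sin_loss_db, n_boot, seed + 2L)
  res
}

#' Run a full simulated study
#'
#' Orchestrates simulate -> (preprocess -> sourcefit, sensor level) ->
#' assr -> stats as a seeded run. Re-running with an identical config
#' reproduces the bundle. When `config$out_dir` is set, the cohort table
#' (CSV), the ASSR table (TSV), and a run log (JSON) are written there.
#'
#' @param config an [run_config()].
#' @param inputs optional precomputed pieces (e.g. `list(cohort = ...,
#'   assr_table = ...)`) so that later stages can be re-run alone.
#' @return bundle list: `config`, `cohort`, `assr_table`, `measures`,
#'   `stats`.
#' @export
run_study <- function(config = run_config(), inputs = list()) {
  bundle <- list(config = config)
  if ("simulate" %in% config$stages) {
    bundle$cohort <- generate_cohort(config$n_young, config$n_older,
                                     config$effect_config, config$seed)
  } else {
    bundle$cohort <- inputs$cohort
    if (is.null(bundle$cohort)) stop("stage 'simulate' skipped but no cohort supplied")
  }
  if ("assr" %in% config$stages) {
    rows <- vector("list", nrow(bundle$cohort))
    for (i in seq_len(nrow(bundle$cohort))) {
      rows[[i]] <- if (config$level == "source")
        participant_assr_source(bundle$cohort[i, ], config, i)
      else
        participant_assr_sensor(bundle$cohort[i, ], config, i)$row
    }
    bundle$assr_table <- do.call(rbind, rows)
  } else {
    bundle$assr_table <- inputs$assr_table
    if (is.null(bundle$assr_table)) stop("stage 'assr' skipped but no ASSR table supplied")
  }
  bundle$measures <- build_measures_table(bundle$cohort, bundle$assr_table)
  if ("stats" %in% config$stages)
    bundle$stats <- cohort_statistics(bundle$measures,
                                      n_boot = config$n_boot,
                                      seed = config$seed)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(bundle$cohort,
                     file.path(config$out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.table(bundle$assr_table,
                       file.path(config$out_dir, "assr.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    log <- list(seed = config$seed, level = config$level,
                n_young = config$n_young, n_older = config$n_older,
                r_version = as.character(getRversion()),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                         auto_unbox = TRUE)
  }
  bundle
}
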
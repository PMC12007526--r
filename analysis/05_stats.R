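#!/usr/bin/env Rscript
# Group statistics over the measures table written by 04_assr_cohort.R:
# mixed ANOVAs, laterality, latency contrasts, attenuation, linear models
# within the older group, and the bootstrap mediation models.

library(assr40)
dir.create("results", showWarnings = FALSE)

tab <- read.csv("results/measures_table.csv")
s <- cohort_statistics(tab, n_boot = 1000, seed = 505)

write.table(s$anova_amplitude, "results/anova_amplitude.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(s$anova_latency, "results/anova_latency.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

lm_rows <- do.call(rbind, lapply(
  grep("^lm_", names(s), value = TRUE), function(nm) {
    f <- s[[nm]]
    data.frame(model = sub("^lm_", "", nm), slope = f$slope,
               r2 = f$r.squared, F = f$F, p = f$p.value, n = f$n)
  }))
write.table(lm_rows, "results/linear_models.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

med_rows <- do.call(rbind, lapply(
  grep("^mediation_", names(s), value = TRUE), function(nm) {
    p <- s[[nm]]$paths
    p$model <- sub("^mediation_", "", nm)
    p
  }))
write.table(med_rows, "results/mediation.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

jsonlite::write_json(list(
  amp_quiet_nam = s$amp_quiet_mean, amp_noise_nam = s$amp_noise_mean,
  li_quiet = s$li_quiet, li_noise = s$li_noise,
  latency_condition_ms = s$latency_condition_ms,
  latency_age_ms = s$latency_age_ms,
  attenuation_young_pct = s$attenuation_young,
  attenuation_older_pct = s$attenuation_older),
  "results/summary.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("amplitudes: quiet %.2f vs noise %.2f nAm\n",
            s$amp_quiet_mean, s$amp_noise_mean))
cat(sprintf("laterality: quiet %.2f, noise %.2f\n", s$li_quiet, s$li_noise))
cat(sprintf("latency: quiet - noise %.2f ms; older - young %.2f ms\n",
            s$latency_condition_ms, s$latency_age_ms))
cat(sprintf("attenuation by noise: young %.0f%%, older %.0f%%\n",
            s$attenuation_young, s$attenuation_older))
a <- s$anova_amplitude
cat(sprintf("amplitude ANOVA, condition: F(%d,%d) = %.1f, p = %.2g, ges = %.2f\n",
            a$df1[a$effect == "condition"], a$df2[a$effect == "condition"],
            a$F[a$effect == "condition"], a$p[a$effect == "condition"],
            a$ges[a$effect == "condition"]))
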
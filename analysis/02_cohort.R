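#!/usr/bin/env Rscript
# Draw the synthetic study cohort: 19 young and 19 older adults with
# hearing measures, GABA levels, and ground-truth ASSR source parameters.

library(assr40)
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(19, 19, seed = 202)
write.csv(cohort, "results/cohort.csv", row.names = FALSE)

old <- cohort[cohort$group == "older", ]
cat(sprintf("cohort: %d young (%.1f-%.1f y), %d older (%.1f-%.1f y)\n",
            sum(cohort$group == "young"),
            min(cohort$age[cohort$group == "young"]),
            max(cohort$age[cohort$group == "young"]),
            nrow(old), min(old$age), max(old$age)))
cat(sprintf("PTA: young %.1f dB, older %.1f dB (difference %.1f dB)\n",
            mean(cohort$pta_db[cohort$group == "young"]),
            mean(old$pta_db),
            mean(old$pta_db) - mean(cohort$pta_db[cohort$group == "young"])))
f <- fit_linear(old$age, old$pta_db)
cat(sprintf("hearing loss in the older group: %.2f dB/year (R2 = %.2f)\n",
            f$slope, f$r.squared))
f <- fit_linear(old$age, old$gaba_total_right)
cat(sprintf("right total GABA vs age: slope %.4f (p = %.3f)\n",
            f$slope, f$p.value))
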
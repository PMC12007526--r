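#!/usr/bin/env Rscript
# Build the 40-Hz AM tone-burst stimulus and the notch-filtered babble
# masker, calibrate the mix to +6 dB SNR, and record the realized filter
# and timing measurements.

library(assr40)
dir.create("results", showWarnings = FALSE)

spec <- stimulus_spec()
tl <- make_am_stimulus(spec)
masker <- make_notched_babble(spec, seed = 101)
mix <- calibrate_and_mix(tl, masker)

notch <- design_notch_filter(spec$audio_fs_hz)
gdb <- function(f) 20 * log10(assr40:::fir_gain(notch, f, spec$audio_fs_hz))

meas <- data.frame(
  quantity = c("am_duration_ms", "masker_duration_ms", "inter_onset_ms",
               "block_duration_s", "realized_snr_db",
               "notch_gain_283hz_db", "notch_gain_400hz_db",
               "notch_gain_566hz_db"),
  value = c(tl$total_am_ms, length(masker) / spec$audio_fs_hz * 1000,
            spec$inter_onset_ms, block_duration_s(spec, 75),
            attr(mix, "realized_snr_db"),
            gdb(283), gdb(400), gdb(566)))
write.table(meas, "results/stimulus_measurements.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write_events_tsv(tl, "results/stimulus_events.tsv")
write_stimspec_json(spec, "results/stimulus_spec.json")

cat("AM sound:", tl$total_am_ms, "ms in", spec$n_bursts, "bursts;",
    "masker:", length(masker) / spec$audio_fs_hz * 1000, "ms;",
    "realized SNR:", round(attr(mix, "realized_snr_db"), 2), "dB\n")
cat("notch gain at 400 Hz:", round(gdb(400), 1), "dB\n")
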
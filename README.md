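# assr40

Simulation-driven analysis of 40-Hz auditory steady-state responses
(ASSRs) in MEG.

The 40-Hz ASSR is a cortical gamma oscillation entrained by an
amplitude-modulated (AM) tone; its amplitude indexes gamma synchrony in
auditory cortex and its phase indexes response latency. Aging studies
record it in young and older adults, with the AM tone presented alone
("quiet") or against notch-filtered multi-talker babble ("noise"), and
relate it to hearing loss, speech-in-noise (SIN) performance, and cortical
GABA levels. `assr40` implements that complete analysis chain as tested R
code, driven by a synthetic-data generator with retained ground truth, so
every stage can be validated without access to human recordings:

* **stimulus** — 400-Hz carrier, 100% AM at 40 Hz, five 400-ms bursts with
  12.5-ms gaps (2050 ms total); a speech-shaped babble surrogate,
  notch-filtered in the octave around the AM band (−6 dB at 283/566 Hz,
  < −60 dB at 400 Hz), mixed at +6 dB SNR.
* **synthetic_meg** — a cohort generator (ages, hearing, SIN loss, six GABA
  measures, per-condition source parameters with configurable slopes and
  couplings) and a spherical-conductor forward model projecting bilateral
  auditory-cortex dipoles to a 151-channel axial-gradiometer helmet, plus
  1/f sensor noise, ocular blinks and quasi-periodic cardiac artifacts.
* **preprocess** — ±4-mm head-motion screening, ocular ICA regression on
  20 frontal sensors (6-Hz low-passed regressors), cepstrum-guided cardiac
  template regression; no trial rejection.
* **sourcefit** — onset-locked 500-ms epochs, C(5,3) = 10 sub-averages per
  block, alternating bilateral spatiotemporal dipole fits, two-stage
  acceptance (≥ 90% variance explained, 2-SD position filter), and
  least-squares source-space projection to nAm waveforms.
* **assr** — the complex 40-Hz statistic `1/(N−1) Σ x(t_n) e^(−i2πf_m t_n)`
  over five 250–400-ms windows (N = 188 at 1250 Hz), phase-randomization
  bootstrap significance, Hilbert-phase latency contrasts
  `Δt = Δφ/(2πf_m)`, laterality index `(R−L)/(R+L)`, attenuation ratios.
* **stats** — mixed-design ANOVA with generalized η², Welch/paired
  contrasts, linear models, logistic `SNR_50` psychometric fits, and
  case-resampling bootstrap mediation (a, b, c, c′, a·b).

## Worked example

Simulate a small cohort, run the source-level pipeline, and look at the
group structure:

```r
library(assr40)
cfg <- run_config(seed = 11, n_young = 19, n_older = 19,
                  n_trials_source = 60, bootstrap = FALSE)
bundle <- run_study(cfg)
s <- bundle$stats
round(c(amp_quiet = s$amp_quiet_mean, amp_noise = s$amp_noise_mean,
        li_quiet = s$li_quiet, latency_cond_ms = s$latency_condition_ms,
        atten_young = s$attenuation_young,
        atten_older = s$attenuation_older), 2)
#>       amp_quiet       amp_noise        li_quiet latency_cond_ms
#>            3.37            1.41            0.12            2.13
#>     atten_young     atten_older
#>           69.25           37.01
```

Quiet-condition responses are about 3.4 nAm and right-lateralized
(LI ≈ 0.12); concurrent babble attenuates them to ~1.4 nAm — by about 69%
in the young but substantially less in the older group — and shortens the
latency by ~2.1 ms, because the noise suppresses the later, higher-order
response component. (At 19 participants per group these estimates carry
visible sampling noise; the acceptance script runs the same recovery at
120 per group.) `bundle$measures` holds the per-participant table;
`cohort_statistics()` adds ANOVAs, linear models within the older group,
and the mediation analyses.

The numbered drivers under `analysis/` narrate the same workflow in
stages (stimulus construction, cohort, a full sensor-level demonstration
with artifact removal and dipole fitting, cohort ASSR outcomes with
bootstrap p-values, group statistics) and write their tables under
`results/`.

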
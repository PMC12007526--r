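---
title: "Methods: simulation and analysis of 40-Hz auditory steady-state responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis of 40-Hz auditory steady-state responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

The auditory steady-state response (ASSR) is a brain oscillation that
phase-locks to the modulation of a periodic sound; it is largest for
modulation rates near 40 Hz, inside the gamma band. In aging research the
40-Hz ASSR is used as a window on cortical gamma synchrony: its amplitude
indexes how strongly neural populations in auditory cortex entrain to the
stimulus, and its phase indexes the response latency. Studies of this kind
compare young and older listeners, with the amplitude-modulated (AM) tone
presented either alone ("quiet") or against multi-talker babble noise
("noise"), and relate the ASSR to hearing loss, speech-in-noise (SIN)
performance, and GABA concentrations in auditory cortex.

`assr40` implements that whole analysis chain as reusable, tested R code,
driven by a synthetic-data generator, so that every stage - stimulus
construction, MEG preprocessing, dipole source estimation, the complex ASSR
statistic with bootstrap significance, and the cohort statistics - can be
exercised and validated without access to any human recording.

# Stimulus model

The stimulus is a 400-Hz carrier, 100% sinusoidally amplitude-modulated at
`f_m` = 40 Hz, presented as five 400-ms bursts separated by 12.5-ms silent
gaps (2050 ms of AM sound in total, one trial every 4000 ms; 75 trials make
a 300-s block). Two conventions deserve note:

* **Envelope phase.** Each burst's envelope is the raised cosine
  `0.5 (1 - cos(2 pi f_m t))` with `t` measured from that burst's onset, so
  a 100%-depth envelope starts at zero at every onset. Because the gap
  equals half a modulation period, bursts sit at opposite modulation phase
  in absolute time; analysis windows locked to each onset see a common
  phase (see below).
* **Audio rate.** 25 kHz, an integer multiple of the 1250-Hz field rate.

The babble masker is a surrogate: seeded speech-shaped noise (flat to
500 Hz, then about -8 dB per octave) in four independently
syllabically-modulated (2-8 Hz) streams. Only its contract-bound properties
are meaningful - duration 3050 ms (500-ms lead and trail around the AM
sound, 200-ms cosine gates), an octave notch around the AM band (-6 dB at
283 and 566 Hz, below -60 dB across 360-440 Hz so that masking cannot be
cochlear in the AM band), and a +6-dB AM-to-masker power ratio measured
over the AM interval. Realism of the surrogate beyond these properties is
not claimed and not testable.

# Synthetic cohort and recordings

`generate_cohort()` draws 19 young (19-28 y) and 19 older (69-87 y)
participants by default. The older group's structure is generated as a
causal chain: age raises the pure-tone average (1.5 dB/year around a
28.6-dB mean); age lowers right-hemisphere total GABA; age and (low) GABA
raise SIN loss; age and left-hemisphere gray-matter GABA raise the
quiet-condition ASSR amplitude; age and the SIN-loss residual raise the
noise-condition amplitude. This realizes the amplitude-age,
amplitude-SIN-loss and GABA-age correlations and an age -> GABA -> SIN
mediation path. Where the underlying study prints a value (group means,
slopes, latency contrasts, laterality indices), that value is the generator
default; where it does not (noise SDs, GABA units, the young group's SIN
performance), defaults were chosen once at plausible physiological scales
and are documented in `default_effect_config()`.

Amplitude defaults are expressed on the *ASSR-estimate scale* (the numbers
a reader of such a study would recognize, e.g. 3.66 nAm for young adults in
quiet) and converted to source-moment amplitude by the estimator gain
`N / (2 (N - 1))` described below. A mean-one log-normal subject gain (CV
0.30) multiplies both conditions, so that participants with strong quiet
responses also respond strongly in noise; condition-specific residuals are
drawn on top. Left/right amplitudes split a hemisphere-mean target by the
participant's laterality index, `R = A (1 + LI)`, `L = A (1 - LI)`.

Latencies are parameterized by the young quiet-condition lag (33 ms; only
lag *differences* matter, since the absolute 40-Hz latency is ambiguous by
25-ms periods), the noise-condition shortening per group (1.52 ms young,
3.25 ms older), and the aging delay in quiet (5.255 ms). The aging delay in
noise (3.525 ms) and the grand means (4.39-ms age delay, 2.385-ms condition
shortening) follow arithmetically.

The source waveform is a 40-Hz oscillation whose phase is locked to each
burst's own onset (mirroring the stimulus modulation), enveloped by the
burst structure with a linear amplitude buildup after the AM onset (200 ms
in quiet, 240 ms in noise - the noise value was chosen just below the
250-ms analysis-window onset so that buildup never contaminates the
windows) and a partial (30%) re-buildup after each gap, plus a decaying
onset transient in quiet and an additive 1/f background (SD 5 nAm).

Sensor recordings are forward-simulated in a spherical conductor (origin at
the sphere center, x right, y anterior, z superior) through a synthetic
151-position axial-gradiometer helmet (Fibonacci spiral layout, 50-mm
baseline, one disabled channel, 150 usable). The magnetic field of a
current dipole in a sphere is evaluated in closed form; radial dipoles are
silent, so sources are parameterized in the tangential plane. Artifacts are
injected with known ground truth: ocular blinks (0.2/s, 350-ms bumps,
frontal topography, per-blink amplitude jitter) and quasi-periodic cardiac
artifacts (1.1 Hz with 5% interval jitter, a stereotyped multiphasic
120-ms template, broad topography, per-beat amplitude jitter). The cardiac
model is deliberately schematic: cepstrum-based detection needs
quasi-periodicity, not electrocardiographic realism. Sensor noise is 1/f
plus a white floor at 200 fT RMS per channel, set so a single trial buries
the ASSR and a few hundred trials of averaging recover it - the regime the
paradigm is designed for.

**Desk-scale convention.** Tests and the acceptance script simulate 20-
trial blocks instead of 75-trial x 4-block conditions, and scale the
sensor-noise SD by `sqrt(epochs_desk / epochs_full)` so the per-sub-average
SNR sits exactly at the full-scale operating point. Goodness-of-fit
distributions of the dipole fits then match what full-length blocks would
give, at a fraction of the compute. Cohort-level recoveries in the
acceptance script use 120 participants per group (instead of 19) purely to
shrink Monte-Carlo error around the configured values; every generator
default is unchanged.

# Preprocessing

* **Motion screen.** A block is rejected if any head-coil position differs
  by more than 4 mm (strictly) along any axis between the pre- and
  post-block registrations.
* **Ocular removal.** An independent-component decomposition on the 20 most
  anterior sensors; components are ranked by kurtosis weighted by sub-6-Hz
  spectral concentration, the top two (or however many pass a plausibility
  floor, with a warning) are low-pass filtered at 6 Hz and regressed out of
  all channels. No trials are rejected. The 6-Hz low-pass is what protects
  the 40-Hz band: the removed waveform has essentially no energy there.
* **Cardiac removal.** A full-array decomposition (30 retained components);
  for each component the real cepstrum of the waveform is scanned in the
  0.6-1.6-s quefrency band after a ~10-ms moving-average smoothing (raw
  cepstral bins are too noisy for stable peak-picking). The component with
  the largest peak is accepted if the peak exceeds 4 SDs of the local
  cepstrum background - a threshold chosen once; below it the recording is
  returned unchanged with a warning. Beats are peaks of that component's
  waveform (5 x MAD floor, minimum spacing 0.6 periods); the channel-wise
  beat-locked average forms a template regressed out at all beat times with
  one least-squares coefficient per channel.

Since no ICA implementation ships with the environment's R stack, the
package carries a compact symmetric fixed-point ICA (tanh contrast, PCA
whitening, subsampled estimation on long recordings). The artifact-removal
contracts are on outcomes (power reduction, band protection, idempotence),
not on the decomposition.

# Source analysis

Trials are parsed into five 500-ms epoch types locked to the AM onset and
the four post-gap onsets; per block, all C(5,3) = 10 three-of-five
combinations of the epoch-type averages form sub-averages (40 per condition
with four blocks). Because the dipoles model the 40-Hz activity, epoch
averages are band-pass filtered (28-56 Hz, zero phase) before combination.

Each sub-average receives a spatiotemporal bilateral dipole fit: one
position per hemisphere fixed over the epoch, tangential moment vectors
free per sample (a linear subproblem), positions optimized by Nelder-Mead
on the variance-normalized residual, alternating between hemispheres from
mirror-symmetric initial positions at (+/-50, -20, 10) mm until the
position change falls below 0.1 mm (at most 50 alternations). Positions are
constrained inside 95% of the conductor radius. The fitted orientation is
the dominant singular vector of the tangential moment series.

Fits are consolidated per participant and condition by a two-stage
acceptance applied once: (1) variance explained of at least 90%; (2)
position within two standard deviations of the stage-1 mean, where the
standard deviation is the RMS distance of the positions about their mean
(the positional scatter SD - the natural reading for a vector-valued
quantity; the SD *of the distances* would reject most points under
isotropic scatter). The model is the mean of the accepted dipoles.
Source-space projection then maps each trial's sensor data onto the two
fixed dipole field patterns by least squares, giving left and right
moment waveforms in nAm for the -500 to +2500 ms trial window.

# The ASSR statistic

The trial average is DC-corrected by the 500-ms pre-stimulus mean,
band-pass filtered with a 512-tap FIR whose single-pass -3-dB edges are
calibrated to 28 and 56 Hz (one octave around 40 Hz) and which is applied
with exactly zero phase in the frequency domain, and expanded into the
complex domain by the Hilbert transform.

The statistic is the single-bin Fourier sum over each of the five
onset-locked response windows,

    ASSR = 1/(N-1) * sum_{n=1..N} x(t_n) exp(-i 2 pi f_m t_n),

with `t_n` measured from each window's *own* burst onset, and the five
complex values averaged. Three numerical conventions matter:

* **Window rule.** The window is 250-400 ms after each onset. At 1250 Hz an
  inclusive rule on the sample grid yields N = 188 samples for the on-grid
  first onset, but later onsets (multiples of 412.5 ms) fall between
  samples, where an inclusive rule would sometimes give 187. The package
  therefore takes the first sample at or after onset + 250 ms and exactly
  N = 188 consecutive samples, with `t_n` the exact onset-relative sample
  times; for on-grid onsets this reproduces the inclusive rule.
* **Onset-relative time.** The five onsets are spaced 16.5 modulation
  periods apart, so absolute-time phases would alternate by pi and the
  five-window complex mean would cancel; onset-relative `t_n` makes the
  windows coherent.
* **Normalization.** The 1/(N-1) normalization is implemented verbatim, so
  a unit-amplitude entrained sinusoid yields an amplitude of
  `N / (2 (N-1))` (about 0.5027) plus a small leakage term (188 samples
  cover 12.03 modulation periods, not an integer). The generator uses this
  gain to convert target ASSR amplitudes into moment amplitudes; recovery
  tests work on ratios and contrasts wherever possible, since band-pass
  smoothing of the half-period burst transitions costs a further ~2% of
  amplitude, which cancels in ratios.

Amplitude is the modulus of the complex mean; phase is its argument (the
circular mean of the five window phases is available behind
`phase_method = "mean_angle"`; the two agree to well under 0.05 rad on
clean input, and the complex mean is the default because it weights windows
by their amplitude). A Hilbert-route phase - the circular mean angle of the
analytic signal demodulated at `f_m` over the same windows - is reported
alongside the Fourier phase and agrees with it on entrained input.

**Significance** uses a phase-randomization bootstrap: the per-trial
complex contributions (by linearity, the statistic of the trial average is
their mean) are each rotated by an independent uniform phase, 1000 times;
`p = (1 + #(null >= observed)) / (1001)`, never exactly zero.

**Latency.** With the `exp(-i 2 pi f_m t)` kernel, a later response has a
more negative phase, so the package computes contrasts as
`dt = wrap(phase_ref - phase_cmp) / (2 pi f_m)`, positive when the
comparison is *later* than the reference - e.g. +4.39 ms for older
relative to young. (The opposite subtraction order would flip the sign of
every printed contrast.) Contrasts are meaningful only within the
half-period window of +/-12.5 ms; absolute latencies are ambiguous by
25-ms multiples and never reported.

**Laterality** is `(R - L) / (R + L)` on amplitudes; **attenuation** is
`100 (1 - amp_noise / amp_quiet)` percent.

# Cohort statistics

The measures table joins the cohort covariates with the ASSR outcomes and
hemisphere-averaged amplitudes `(L + R)/2` (the ASSR is strongly correlated
across hemispheres; GABA is analyzed per hemisphere because it acts
locally). On it the package runs:

* mixed-design ANOVAs (within: hemisphere, condition; between: age group)
  via base R `aov()` error strata, with generalized eta squared assembled
  as `SS_effect / (SS_effect + sum of all error-stratum SS)`; an
  independent brute-force sums-of-squares oracle in the tests confirms the
  F statistics to 1e-10;
* Welch two-sample and paired t contrasts with 95% CIs (equal variances are
  not assumed; the paired variant serves hemisphere and condition
  contrasts);
* ordinary least-squares linear models (slope, R^2, F, p, CIs), run within
  each age group;
* a two-parameter logistic psychometric fit by maximum likelihood for
  `SNR_50`, with SIN loss defined as `SNR_50 + 2` dB against the normative
  -2-dB reference; QuickSIN list content is proprietary, so the interface
  is abstract `(level, proportion-correct)` pairs;
* bootstrap mediation (`a` from M ~ X, `b` and `c'` from Y ~ X + M, `c`
  from Y ~ X, indirect `a*b`), with case-resampling percentile CIs and
  two-sided bootstrap p-values. Percentile intervals were chosen over
  bias-corrected ones as the plainer default; the OLS identity
  `c = c' + a*b` holds to machine precision on any data and is asserted in
  the tests. No multiple-testing correction is applied by default,
  matching how unadjusted p-values are conventionally reported in this
  literature.

# What passing tests do and do not show

The generator produces exactly the structure the pipeline assumes: a
point-dipole pair in a spherical conductor, artifacts with stereotyped
topographies, stationary 1/f noise. Recovery of configured amplitudes,
lags, slopes, and mediation paths therefore validates the *computation*,
not the physiological model: real heads are not spheres, real gamma sources
are distributed, real blinks are less stereotyped, and real cohort
correlations are not exactly linear. Conversely, structural results -
window arithmetic, filter contracts, estimator identities, acceptance
logic, bootstrap calibration - are data-independent and transfer directly.

Known limitations: no anatomical coregistration or atlas localization
(coordinates live in the synthetic head frame); no trial rejection or
SSP/SSS denoising; the masker is a statistical surrogate, not recorded
babble; MR-spectroscopy quantification is out of scope (GABA enters as
per-participant numbers); and dipole fitting assumes exactly one dominant
source per hemisphere.
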
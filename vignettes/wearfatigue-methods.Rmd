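---
title: "Digital measures of fatigue and sleep from wearable physiology: methods"
author: "wearfatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital measures of fatigue and sleep from wearable physiology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fatigue and sleep disturbance in chronic neurodegenerative (NDD) and
immune-mediated inflammatory (IMID) disease are usually assessed with
patient-reported outcomes (PROs) — Likert self-ratings that are subjective,
recall-biased and insensitive to within-day change. A chest-worn ECG patch
provides continuous physiological channels — heart rate (HR), beat-by-beat
R-to-R intervals, respiratory rate, skin temperature at a nominal 0.25 Hz,
and steps/posture at 1 Hz — from which objective digital measures can be
derived in free-living conditions. This package implements the full
analysis chain from raw channels to three kinds of results:

1. **PRO association**: statistical aggregates and heart-rate-variability
   (HRV) features over the 2 h preceding each PRO response, normalized to
   the participant's own rest state, correlated with the PRO by
   repeated-measures correlation (rmcorr).
2. **Rest-state physiology**: the least-active 5-hour period of each day
   (L5), a steps/posture proxy for the major sleep episode, summarised
   per group.
3. **Heart-rate recovery (HRR)**: the HR drop in the minute following a
   sustained free-living walk, compared across groups by ANCOVA.

Because the motivating study's data are sensitive and not deposited, a
synthetic cohort generator with known ground truth stands in for them;
every stage is tested against that ground truth and against independent
brute-force oracles.

## Cleaning model

Each physiological channel is sorted, deduplicated (first-seen record kept
on timestamp ties) and cleaned in a fixed order:

1. **invalid values** — the manufacturer marks unsuccessful measurements
   with an out-of-band code; we use a single documented sentinel (−1), as
   the real device codes are not published;
2. **range outliers** — values outside the accepted physiological ranges
   (HR 30–200 beats/min, R-to-R 300–2000 ms, respiratory rate 4–60
   breaths/min, skin temperature 28–40 °C), bounds inclusive on both ends;
3. **contextual outliers** — values deviating from their local
   sliding-window mean by more than 30 % (50 % for respiratory rate, which
   is under voluntary control), with time-centred windows of 1 min (HR,
   R-to-R), 3 min (respiratory rate) and 5 min (skin temperature).

Three choices here were genuinely open and are fixed as follows. The
window mean *excludes the centre sample*: a large spike would otherwise
drag the mean toward itself and mask its own deviation. The contextual
pass is *single-pass* against the range-filtered series: window means are
not recomputed as outliers are removed, because iterating to convergence
is a different (and unstated) algorithm. Edge samples are judged against
whatever neighbours exist; a sample with no in-window neighbour is kept,
and a sample whose window mean is non-positive is kept but flagged rather
than divided by.

Removed values become gaps, except for R-to-R range/contextual outliers,
which are re-filled by linear interpolation between the nearest surviving
neighbours so that HRV analysis sees a continuous tachogram; invalid
R-to-R values stay gaps, and boundary outliers are dropped rather than
extrapolated.

Self-reported bed/wake times come from a 24-h clock widget that users
sometimes misread by 12 h. A bedtime implying a non-positive or
implausibly long (> 16 h, configurable) sleep duration is shifted by 12 h
when that yields a plausible duration, otherwise the pair is marked
unusable. The 16-h bound operationalises "considerably late" and lives in
`cleaning_config()`, not in code.

## Coverage

Daily coverage is computed midnight-to-midnight (timezone fixed per
participant; the synthetic epoch is UTC) as observed/expected samples for
the regularly sampled channels, capped at 1 to absorb timestamp jitter.
The R-to-R channel is a chain of interbeat intervals, so its coverage is
the summed interval duration divided by the measurement period — the
intersection of the query interval with the wear sessions, where sessions
are split at gaps longer than 30 min (configurable; the study does not
state a boundary). PRO coverage counts responses against the slot schedule
(four daily slots at 9:00, 13:00, 17:00, 21:00; sleep items morning-only,
sleepiness at the three later slots, daily-activity items in the evening)
on days the patch was worn. Partial first/last days are included in the
daily means; the study leaves this unstated either way.

## HRV battery

R-to-R segments are first reduced to normal-to-normal (NN) intervals with
the Malik 20 % rule: an interval deviating more than 20 % from the
previous *accepted* interval is replaced by interpolation between that
interval and the next acceptable one. Two details are deliberate: the
reference is the accepted (not raw previous) interval, so a drifting
artefact run cannot legitimise itself; and interpolation is beat-index
based, because the timestamps of a corrupted run are distorted by the very
artefact being repaired. Segments with fewer than 3 intervals are
rejected.

Time-domain features use the unbiased (n−1) SD estimator, strict
inequalities for NN50/NN20 (|Δ| > 50/20 ms), and compute the "HRV HR"
block on the beatwise rate 60000/NN (the device HR channel is an
alternative reading; the beatwise definition keeps the battery a pure
function of the NN series). CVSD follows the common convention
RMSSD/mean(NN).

Frequency-domain features interpolate the irregular tachogram to an even
4 Hz grid (cubic spline), detrend linearly, and estimate the PSD by
Welch's method with 256-s Hann segments at 50 % overlap — the de-facto
standard estimator; the study names only the bands (VLF 0.003–0.04, LF
0.04–0.15, HF 0.15–0.40 Hz). Band powers are rectangle-rule integrals of
the one-sided PSD; total power is their sum and LFnu = LF/(LF+HF).
Segments shorter than 5 min, or whose grid has more than 20 % of points
farther than 5 s from any beat, yield missing features.

Geometric/non-linear features: triangular index with the conventional
1/128-s histogram bin; Poincaré SD1 = √(var(ΔNN)/2),
SD2 = √(2·var(NN) − var(ΔNN)/2) (matching estimators make
SD1² + SD2² = 2·SDNN² an exact identity); CSI = SD2/SD1;
CVI = log10((4·SD1)(4·SD2)); and the modified sympathetic index in
Toichi's longitudinal²/transverse form, mCSI = (4·SD2)²/(4·SD1) — the
study cites only the name, so the formula is recorded here and the
feature column is clearly labelled. SD1 = 0 makes the sympathetic indices
undefined (NA).

## Windows, L5 and normalization

Aggregates (mean, SD, min, max per channel, plus the HRV battery and
per-channel coverage) are computed over half-open 2-h windows
`(t − 2h, t]` anchored at the PRO *submission* time, not the nominal slot.

L5 windows are searched noon-to-noon so nocturnal rest is not bisected at
midnight (the study says only "in the day"). Candidate 5-h windows start
at 1-min resolution and must contain ≤ 100 steps and ≥ 80 % lying
posture; overlapping candidate runs are resolved to the window maximising
the lying fraction, ties to fewer steps, then earlier start. The lying
denominator is the posture samples actually present, so wear gaps do not
dilute it; conversely a candidate must contain at least half its nominal
samples, so a sliver of data at a recording edge cannot qualify. No
constraint prevents an L5 window from covering a daytime nap; the study
imposes none.

Normalization maps each aggregate x to (x − µ_L5)/σ_L5. For raw-channel
aggregates, µ and σ are the channel's in-window mean and SD — so
normalizing the L5 window's own samples gives exactly mean 0, SD 1. For
HRV feature aggregates a single window yields one value and no SD; we
therefore use the across-window distribution of the window-level feature:
variant (b) takes both moments across all of the participant's L5
windows, and variant (a) takes µ from the nearest previous window with σ
across windows. Variant (a) excludes aggregates with no previous L5
window, exactly as the source analysis does; σ_L5 = 0 marks the feature
missing rather than producing infinities.

## Association

The repeated-measures correlation is computed from the
analysis-of-covariance formulation (participant as factor, feature as
covariate): r = sign(slope)·√(SS_x/(SS_x + SS_err)), which equals the
Pearson correlation of within-participant-centred observations; df =
n_pairs − n_participants − 1, p from F(1, df), and the 95 % CI from the
Fisher z-transform with standard error 1/√(df − 3). Inclusion filters
mirror the source analysis: windows with feature coverage below 70 % are
excluded (the boundary itself is kept: "lower than 70 %… excluded"),
participants need at least 3 surviving pairs, and missing normalized
features are dropped pairwise per feature, not listwise. Cells are
flagged at raw p < 0.05; no multiple-testing correction is applied by
default (matching the cellwise flagging convention), with an optional
Benjamini–Hochberg flag.

## Heart-rate recovery

Walks are maximal runs of walking-classified posture bridging
interruptions of up to 3 s, at least 6 min long, with mean cadence
(steps/duration) ≥ 60 steps/min and no upper limit. The rest window is
the 60 s immediately after the walk ends — no latency allowance, which
the source leaves unstated — and must have 100 % HR coverage (all 15
samples at 0.25 Hz), zero steps, and no walking resumption. "Maximum
difference in the HR signal during the resting minute" is read as
max − min within the window; the alternative reading (first rest sample
minus the minimum) is implemented behind `method = "onset_min"` because
the phrase is genuinely ambiguous. Only the single post-walk minute is
scanned. A participant's representative value is their highest HRR,
earliest on ties.

Groups are compared by one-way, two-sided ANCOVA (`hrr ~ group + age +
sex`, Type II F for the group term), with partial η² =
SS_term/(SS_term + SS_residual) and Tukey HSD on the covariate-adjusted
means (model-based, since the omnibus test is covariate-adjusted). The
fatigue split median-splits each group on mean physical-fatigue score and
compares HRR halves with a Welch t test, skipping groups with fewer than
4 participants or constant fatigue.

## The synthetic cohort

The generator emulates the study conditions: three participant categories
(healthy/NDD/IMID), 5-day wear periods, PROs at four daily slots with
15 % slot dropout, nightly rest of roughly 23:00–07:00, two daily
sustained walks (8 min at 100 steps/min) each followed by a seated
zero-step recovery, daytime wear gaps, and outlier contamination at the
rates observed in real patch data (about 0.1–0.5 % for the ECG-derived
channels; 2.3 % range outliers for skin temperature).

Because no generative model is published, the minimal structure that
makes L5 detection and rest-referenced normalization meaningful was
chosen: HR = group baseline (62/68/66 beats/min) + circadian cosinor
(amplitude 8 beats/min, acrophase 15:00) + activity term (lying −3,
standing +5, walking +25) + 5·(latent daily fatigue) + AR(1) noise; skin
temperature carries an anti-phase cosinor; R-to-R is emitted beat by beat
as 60000/HR plus 15-ms jitter (the duration-based coverage definition and
HRV analysis both require a beatwise channel); respiratory rate is an
independent cosinor-plus-noise channel. Latent daily fatigue is an AR(1)
per-participant trajectory (mean 2, within-SD 1, between-SD 0.8, Likert
units); PRO responses are the discretised latent state plus N(0, 0.7)
noise clipped to 0–6. Planted HRR is 30 + group shift (0/−10/−5) −
0.2·(age − 50) + N(0, 5) beats/min, encoded in the post-walk minute as a
decay from the walk peak by exactly the planted value, with low noise
(smooth parasympathetic reactivation). The 12-h sleep-time entry error is
injected at rate 0.05. Wear gaps total `wear_gap_rate` (default 0.22,
matching ~78 % median daily coverage) of each day, placed in daytime
regions that never touch the night or the planted walks. Posture has four
classes (lying/sitting/standing/walking) although only two matter to the
analysis — the extra classes exercise threshold logic.

What the generator does *not* emulate: raw ECG waveforms and realistic
accelerometry; compliance-coupled wear (in the study, participants
responding to PROs were usually wearing the patch, so 2-h windows had
~100 % median coverage, whereas synthetic gaps fall independently of PRO
times and the 70 % filter bites harder); device-specific invalid-value
codes; and any calibration of per-group HRV distributions to the
published figures, which report no numeric parameters. Passing tests
therefore demonstrate correctness of the algorithms under a plausible
physiological model, not agreement with any real cohort's numbers. With a
desk-scale demo cohort (9 participants) the pooled fatigue–HR rmcorr is
reliably positive but its magnitude varies noticeably from seed to seed
once the coverage filter prunes pairs.

## Numerical and testing choices

Problem sizes were chosen to keep the default test run comfortably fast
while preserving statistical meaning: the cleaning oracle uses 1,000
random series (most 30–400 samples, a few up to 10,000); L5 recovery uses
50 synthetic participant-days; rmcorr calibration uses 1,000 null
replicates (20 participants × 6 pairs) and 500 slope-recovery replicates
(30 × 8); ANCOVA calibration uses 1,000 null and 200 powered cohorts of
20 per group, simulated at participant level via `simulate_hrr_cohort()`
rather than full signal synthesis. All RNG flows through per-participant
seeds derived once from a master seed, so regenerating any participant
never perturbs another — and identical (config, seed) reruns are
byte-identical, which `run_pipeline()` certifies with an MD5 report hash.

Degenerate inputs are handled explicitly rather than by NaN propagation:
empty windows give NA aggregates with coverage 0, σ = 0 normalization
references mark features missing, SD1 = 0 disables the sympathetic
indices, rank-deficient ANCOVA designs raise an error (the pipeline
retries with fewer covariates, since a 9-person demo cohort can make sex
collinear with group), and the Tukey table is suppressed below 3 residual
degrees of freedom where the studentized range degenerates.

## Known limitations

Single-pass contextual filtering and the centre-excluded window mean are
documented choices, not established facts about the source analysis; both
are configurable in spirit (thresholds and windows live in
`cleaning_config()`). The mCSI formula and the HRV-HR source are flagged
ambiguities resolved by documented convention. The rmcorr CI uses the
conventional df-based Fisher interval, which is slightly conservative for
small cohorts. L5 windows are a proxy for sleep, not a staging algorithm.
The HRR definition deliberately excludes any latency between walk end and
rest, and scans a single minute.
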
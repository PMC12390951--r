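---
title: "Simulating and analysing neonatal fNIRS responses to auditory rhythm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing neonatal fNIRS responses to auditory rhythm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neorhythm)
```

## The scientific problem

Newborns — including prematurely born neonates — appear to extract the
periodic *beat* underlying an auditory rhythm, and beat-based regularity is
thought to recruit not only auditory cortex but sensorimotor and premotor
regions. Testing this with functional near-infrared spectroscopy (fNIRS)
requires a long chain of machinery: matched rhythmic and arrhythmic stimulus
sets, a block-design protocol, conversion of raw dual-wavelength intensities
into oxyhemoglobin (HbO) concentration changes, aggressive quality control
(neonates move), and group statistics that survive small cohorts —
cluster-based permutation tests and repeated-measures ANOVA.

`neorhythm` implements that chain end to end, together with a synthetic-data
generator that produces fully specified neonatal fNIRS sessions. Because
every stage of the pipeline can be exercised on data whose ground truth is
known, the statistical machinery can be validated (type-I error, parameter
recovery) in a way that is impossible with real, non-shareable infant
recordings.

## Stimulus design

Rhythms are sequences of 43–46 tones whose onset-to-onset intervals come
from a four-member inventory: the fastest interval is 1 *time unit* and the
others are 2, 3, and 4 units. `compose_rhythmic_bases()` assembles five base
sequences from cells spanning whole 2-unit beats (`[1,1]`, `[2]`, `[4]`,
`[3,1]`/`[1,3]`), so every cell starts on the beat grid and at least 80% of
beat positions carry a tone onset. Totals are even and drawn from 94–102
units; combined with the fixed 0.5 s tone tail this guarantees that every
rendering at the three tempi (1 unit = 140, 185, 230 ms) and two pitches
(440/880 Hz) lasts 13–24 s.

`make_arrhythmic()` derives the matched control: within each interval
category a random third of intervals is shortened by 20/25/33%, a third kept,
a third lengthened by 20/25/33% (remainders spread at random), and the whole
sequence is shuffled. This destroys the beat grid while preserving the tone
count and, in expectation, total duration and envelope energy.

Tones are synthesised as decaying sinusoids (5 ms attack, 60 ms decay time
constant) at a fixed gain. The gain is deliberately *not* peak-normalised
per stimulus: overlapping tones raise waveform peaks more often in
arrhythmic sequences (shortened intervals), and normalising by the peak
would systematically rescale one condition's envelope.

`validate_stimulus_sets()` reproduces the design check used for such
stimulus sets: paired t-tests across the 30 matched pairs on duration and on
mean envelope power from 0–10 Hz (envelope = |analytic signal| via the FFT
half-spectrum construction; spectra zero-padded to a common 0.1 Hz grid so
the 0–10 Hz average is well defined for unequal durations). Because the 30
pairs replicate only five independent arrhythmic draws, an unlucky draw can
leave the whole set mismatched; `generate_stimulus_set()` therefore redraws
the perturbations until its own equivalence criterion (both p > 0.05) holds,
exactly as a stimulus designer iterates until the matched set passes the
equivalence check it reports. One to three redraws typically suffice.

`build_protocol()` orders the 60 blocks by constrained sequential sampling:
no more than two same-condition blocks in a row, no consecutive blocks from
the same base with a different tempo or pitch, inter-stimulus intervals
jittered uniformly in 25–35 s.

## The synthetic cohort

`build_montage()` constructs the bilateral high-density patch: per
hemisphere 10 emitters and 8 detectors on a staggered grid (18 mm column,
17 mm row pitch), yielding channels at 17–38.5 mm separations — all within
the 15–40 mm validity range. The right hemisphere keeps the 40
shortest-separation pairs, the left 39, matching the reference counts.
A channel lives at the emitter–detector midpoint (the deepest point of the
banana-shaped sensitivity profile), and analysis ROIs (auditory,
sensorimotor, premotor; plus frontal/parietal/temporal labels) are declared
from midpoint coordinates, mirrored across hemispheres. A full photon
transport model is intentionally out of scope; ROI membership is what the
group statistics consume.

The hemodynamic response (`neonatal_hrf()`) is a gamma kernel with its mode
at 10 s — the peak latency seen in premature neonates — effectively back to
baseline by 25 s; HbR is modelled as −1/3 of HbO (typical neurovascular
coupling; only HbO is analysed downstream). Each block contributes
`amplitude x HRF(t - onset)`: an event-related approximation chosen over
convolution with the full stimulus boxcar so that the response peak stays at
10 s and noise-free trial averages equal the injected kernel exactly — the
invariant the round-trip tests rely on.

Ground-truth amplitudes (`ground_truth_map()`) are 1.0 µM HbO peak for
non-auditory channels, 1.3 µM for auditory channels, and — under the default
effect map — 1.5 µM (rhythmic) vs 0.75 µM (arrhythmic) on right
sensorimotor and left premotor channels, the regions where beat-based
regularity modulates the response. These defaults are physiologically
plausible for neonatal HbO and were fixed at design time so that the
participant-level effect corresponds to Cohen's d ≈ 2, i.e. an effect a
cohort of 11 detects reliably — mirroring a robustly detected finding.
Between-participant variability is lognormal (sdlog 0.25) with per-channel
lognormal jitter (sdlog 0.10).

Noise: cardiac (~2.5 Hz, 0.3 µM), respiratory (~1 Hz, 0.2 µM), Mayer waves
(~0.1 Hz, 0.3 µM — the only oscillation inside the analysis band), a slow
random-walk drift and white measurement noise. Motion artifacts come in two
kinds: transient spikes (0.5–2 s, 4–10 times the 0.01 Molar x mm detection
threshold, occasionally hitting > 10 channels at once) and step baseline
shifts (2–4 times threshold, 1–3 channels). Artifact amplitudes sit orders
of magnitude above physiology — which is what makes the rejection-only QC
strategy meaningful. Hemoglobin is pushed through the Beer–Lambert forward
model (standard extinction coefficients at 690/830 nm; neonatal DPF 5.4/4.7)
to optical density and raw intensity (`I = I0 10^-OD`, `I0 = 1`; the
arbitrary unit cancels in OD).

## Preprocessing

`preprocess_session()` runs: intensity → OD (reference = temporal mean per
channel) → zero-phase band-pass 0.03–0.5 Hz → inverse Beer–Lambert →
motion-artifact mask → per-channel z-scoring (statistics over unmasked
samples) → 30 s epochs (−5 s baseline, +25 s post-onset; half-open window,
0-based indexing) with whole-epoch linear detrending then baseline
correction → four rejection rules → channel exclusion → condition averages
decimated to 1 Hz by 1 s bin means (the 0.5 Hz low-pass already
anti-aliases; bins are defined on the time axis so the non-integer 10.1215
Hz rate cannot drift the grid).

The band-pass is a 3rd-order Butterworth applied forward–backward.
Internally the two passes are applied as |H(ω)|² in the frequency domain
over all channels at once (with odd-reflection padding longer than the
high-pass transient); this is numerically equivalent to `filtfilt` away
from the edges and an order of magnitude faster, which matters for the
recovery simulations. Passband gain at 0.1 Hz exceeds 0.9 and attenuation
at 0.005 and 2 Hz exceeds 20 dB — both asserted by tests.

The four trial-rejection rules, evaluated in order per trial x channel:

1. **z-amplitude** — any |z| > 3 within the trial;
2. **gradient** — any change over 0.4 s steps exceeding 1.5 (z units, on
   the z-scored signal, which precedes trial screening in the chain);
3. **area under curve** — *rectified* post-onset area below 10 z·s. The
   signed reading of this rule is unworkable on a band-passed signal:
   the 0.03 Hz high-pass forces every epoch towards zero mean (the
   filtered response undershoots), so the signed integral of even a
   clean, strong response hovers at the threshold while |z| < 3 caps the
   peak. The rectified integral is a flat/dead-trial screen — a z-scored
   trial of session-typical variance integrates to ≈ 0.8 × 25 = 20 z·s,
   and channels crushed by artifact-inflated variance fall far below 10.
   The threshold is kept verbatim and configurable;
4. **artifact overlap** — any sample in the motion mask (±1.5 s around
   every exceedance of 0.01 Molar × mm on |Hb| × separation; exceedances
   on more than 10 channels mask all channels).

A channel is excluded for a condition when *strictly more* than 80% of its
trials are rejected; averages are over the surviving trials, pooling tempi
and pitches. Group statistics keep channels with at least 4 contributing
participants. Under default noise this yields roughly 5–15 excluded
channels per participant — the bookkeeping scale reported for real neonatal
cohorts. The visual channel-screening step used with real recordings has no
synthetic counterpart and is intentionally absent.

## Statistics

**Rising slope.** Per participant, channel and condition on the 1 Hz
average: `slope = (HbO_peak - HbO_onset) / (t_peak - t_onset)` with the
peak the maximum strictly after onset within 0–25 s (onset value taken at
t = 0); the normalized slope is
`(Slope_RC - Slope_AC) / (Slope_RC + Slope_AC)`, antisymmetric under
condition swap, and undefined (NA with a warning) when the denominator
vanishes.

**Cluster-based permutation.** Pointwise paired/one-sample t statistics are
thresholded at two-sided p < 0.05; clusters are contiguous same-sign runs
(temporal) or connected components of the channel neighbour graph
(spatial; neighbours within the smallest radius that gives every channel at
least two neighbours, ≈ 12.4 mm on the default montage). Cluster mass is
the summed t; the null distribution of the maximal mass comes from
participant-level sign flips — the exact scheme for a within-subject
contrast. With 11 participants there are 2^11 = 2048 distinct patterns;
sampled draws may repeat, and an exhaustive mode enumerates all patterns
when n ≤ 12. p = (1 + #{null ≥ observed}) / (1 + n_perm), so p can never
drop below 1/(n_perm+1). Singleton clusters are permitted (the
minimum-neighbour parameter is 1), with `min_cluster_size` available to
require company. NA-aware statistics tolerate participant-missing channels;
channels below 4 contributors are dropped from the map.

**ROI table and rANOVA.** The 8–12 s window (4 s around the 10 s peak) is
averaged per channel, then over ROI channels, per hemisphere, yielding the
participant × condition × ROI × hemisphere table. `rm_anova()` computes the
classical within-subject decomposition (aov/Error strata) with partial eta
squared per effect, plus Mauchly sphericity tests and Greenhouse–Geisser
corrected p values for multi-df effects via the multivariate route;
uncorrected values are always reported alongside. `anova_suite()` adds the
follow-ups: ROI × hemisphere per condition, condition × hemisphere per
ROI, and Tukey–Kramer post-hocs on ROI. Incomplete tables are rejected
with the missing cells named — the design must be balanced.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: analytical
envelope spectra for AM tones, brute-force enumeration of the sign-flip
null, hand-computed sums of squares for a 2×2 within design, and the
Beer–Lambert forward/inverse identity (max error < 1e-9). Study-level
checks run at sizes chosen to finish on a single desktop core: family-wise
error of the temporal test on 500 null cohorts of n = 11 (200 permutations
each); parameter recovery on 50 effect cohorts and 30 null cohorts of
n = 11 participants with 12-block sessions and 400 permutations. The
12-block sessions halve the trial count of the full design, which the
d ≈ 2 effect size comfortably tolerates; the full 60-block study is what
`analysis/02_simulate.R`–`04_stats.R` run.

## What the generator does and does not emulate

Emulated: dual-wavelength intensities at 10.1215 Hz on the reference
montage geometry, block timing with its ordering constraints, a 10 s-peak
HbO/HbR response with condition-dependent amplitudes over sensorimotor and
premotor channels, in-band and out-of-band physiological oscillations,
drift, and the two motion-artifact families the QC rules target.

Not emulated: photon transport through real neonatal anatomy (channel
sensitivity profiles, partial volume effects), serially correlated
physiological noise beyond sinusoids and random walk, state changes across
a 52-minute sleeping session, or optode-coupling degradation. Passing
recovery tests therefore demonstrates that the *pipeline* is correct and
well calibrated — not that real neonatal data would show these effect
sizes. The acceptance checks deliberately target design properties
(stimulus numbers, geometry, error control, recovery) rather than the
irreproducible group-level findings of any particular cohort.

## Numerical choices

- Epoch length is `round(30 x fs)` samples; events too close to the
  recording edge are skipped with a warning.
- FFT sizes are padded to 5-smooth lengths (R's mixed-radix FFT degrades
  on large prime sizes, which arrhythmic durations otherwise produce).
- Rejection-rule codes are assigned in the documented order; each rule is
  individually triggerable (tested with dedicated fixtures).
- The protocol sampler restarts from scratch on dead ends (cap 10,000);
  tiny protocol subsets that cannot be ordered (one base at two
  renderings) are redrawn.
- All randomness flows from explicit integer seeds; identical seeds give
  bit-identical sessions, averages and permutation draws.
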
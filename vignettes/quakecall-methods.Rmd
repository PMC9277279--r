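---
title: "Methods: before/after analysis of blue whale calling around earthquakes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: before/after analysis of blue whale calling around earthquakes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quakecall)
```

# The question and the design

Blue whales vocalize constantly in some regions: males produce a
stereotyped song (in New Zealand, three pulsed units and a tonal unit in
the 17–24 Hz band, with dominant energy at 23–24 Hz), and both sexes
produce downswept "D calls" (~100 → 20 Hz) associated with foraging.
Earthquakes are an episodic natural noise source that overlaps these
bands. `quakecall` implements a before/after-control-impact style
analysis of whether calling activity changes after an earthquake.

The design compares three call metrics — the number of D calls, their
mean relative received level (RL), and a song intensity index — in
windows **before** versus **after** each selected earthquake, at four
temporal scales (4, 3, 2 and 1 h) plus a 15-min binned time series, and
repeats the identical analysis around matched **null** timestamps where
no earthquake occurred. The null arm is essential: calling has strong
endogenous dynamics, and any "change vs. prior level" relationship must
be compared against what those dynamics produce on their own.

Assumptions worth stating explicitly:

- Pairing is by (event, station); each hydrophone recording an event
  contributes one pair. Stations enter the linear models only as a fixed
  factor; station-level pseudo-replication is acknowledged, not modelled.
- RL is relative (dBFS), not calibrated sound pressure; only before/after
  *differences* are interpreted, so any fixed reference that preserves dB
  differences is valid.
- No multiple-testing correction is applied across metrics and scales;
  tests are reported raw, and interpretation rests on the null-period
  comparison rather than on any single p-value.

# Signal measurements

## Spectrograms

All analysis uses a magnitude-squared short-time Fourier transform with a
2048-sample Hann window and 50% overlap (the `detection` preset; at 2 kHz
sampling this gives 0.977 Hz bins and 0.512 s hops). Two other presets
are provided for display purposes (`display`: 2048/90%; `songfig`:
3072/50%). Power is stored one-sided with non-DC bins doubled, so a
column's total equals `n_fft` times the windowed frame's time-domain
energy (discrete Parseval); the Nyquist bin is not represented, which is
irrelevant for signals confined well below 1 kHz.

## Relative received level (dBFS)

The "Energy" of a time–frequency selection is the summed linear power
inside it, expressed in dB relative to the energy a full-scale DC signal
would contribute over the same number of frames. This reference makes the
value of a full-scale sine a closed form (−3.01 dBFS), keeps every
unclipped measurement ≤ 0 dBFS, and guarantees the exact gain law: a
waveform gain *g* shifts every measurement by 20·log₁₀(g). Commercial
tools do not document their normalization; since only differences are
analysed, the choice of reference is immaterial as long as it is fixed,
and this one is analytically checkable.

## Earthquake received time and level

Around each catalog origin time (±120 s by default) the recording is cut
into 1-s frames and the 5–100 Hz band energy of each frame is computed.
Frames exceeding a robust threshold — median + 5·MAD over the search
window — are flagged, and the longest contiguous flagged run is taken as
the earthquake: its first frame gives the received time, its length the
duration, and its dBFS energy the RL at the hydrophone. Field workflows
typically do this by hand in an annotation tool; any robust onset rule is
acceptable, so the multiplier, band and frame length are all exposed as
arguments. If no frame exceeds the threshold the event is reported as not
found and the caller falls back to the catalog time with a nominal
duration.

# The D-call detector

Detection is by spectrogram template correlation. Each template is a
`detection`-preset power spectrogram of an exemplar call, cropped to the
15–110 Hz band and normalized to zero mean and unit norm, so that sliding
it across a recording's spectrogram yields a Pearson correlation in
[−1, 1] at each lag — invariant to both the exemplar's and the
recording's gain. Thirteen templates are shipped: the grid of durations
{1.5, 2, 2.5, 3} s × sweep ranges {100→20, 90→25, 80→30} Hz plus one
curvilinear 100→20 Hz sweep. The real detector this architecture follows
also used 13 templates chosen to span call variability; the actual
exemplars are analyst-selected recordings and are not reproducible, so
synthetic exemplars stand in (and user exemplars can replace them). What
matters structurally — and what the tests exercise — is the
multi-template maximum-score architecture.

Scores from all templates are combined by pointwise maximum;
supra-threshold candidates are collapsed by greedy non-maximum
suppression to one detection per local maximum with a minimum onset
separation of 1 s (the score-collapse rule is not dictated by the
methodology; one-per-local-maximum is the natural choice). The default
threshold is 0.80. Because a 0.512 s lag grid can place a call onset
half a hop away from the nearest frame boundary — enough to shave a
borderline score below threshold — the correlation is evaluated on two
half-hop-offset frame grids by default (`lag_oversample = 2`); each grid
uses the standard preset per frame.

Detector post-processing mirrors analyst review as a pure set operation:
`merge_annotations()` removes false detections by id and adds missed
calls flagged `source = "manual"`. Tabulation counts detections whose
midpoint falls in a half-open window [start, end) — midpoints, so that a
call straddling a boundary is counted exactly once, and half-open, so
that adjacent windows partition time.

# The song intensity index

Chorusing makes individual song counting infeasible, so chorus level is
summarized as a band-energy ratio: mean spectral power across the bins in
23–24 Hz divided by the mean power at the single bins nearest 11 and
39 Hz, averaged per 60-s bin anchored at the recording start. The
background frequencies bracket the song band on both sides; using point
bins (with an option for ±0.5 Hz bands) follows the source methodology,
which does not state a bandwidth. The ratio is computed on linear power —
"ratio of energy" reads as linear, and linearity gives the exact gain
invariance the tests assert. White noise has a flat expected spectrum, so
the index calibrates to ≈ 1 in the absence of song, rises with song
energy, and is pulled back toward 1 by added broadband noise.

# Catalog selection

Selection reproduces the published rules: magnitude strictly greater
than 3.0; epicentre inside the closed study box (38–43° S, 172–176° E by
default); origin time inside the analysis period; and an 8-h isolation
rule that keeps only events with no other catalog event within 8 h —
applied symmetrically, so both members of a close pair are dropped
(swarms should contribute no events at all; the source text does not
specify the boundary or symmetry, and a gap of exactly 8 h counts as
isolated here). A stratified weekly sample then guarantees at least one
selected event per non-empty 7-day stratum (anchored at the period start,
not at calendar weeks) before filling the quota uniformly at random.

Epicentral distance uses the haversine formula on a sphere of mean
radius 6371.0088 km. The reference implementation in the field defaults
to ellipsoidal distance; at regional catalog scales the difference is
below 0.5% and immaterial to the models, while the spherical form has a
closed-form oracle (one equatorial degree = R·π/180 = 111.19508 km) and
no dependency. Tests cross-check against both a numerical great-circle
integration and the `geosphere` haversine.

# Windows, null periods, statistics

For each event and scale *s*, the before window is
[origin − s·3600 s, origin) and the after window starts at the *end* of
the earthquake signal, so the rumble's own energy never contaminates the
"after" RL (the source is ambiguous; anchoring at signal end is the
conservative choice). Calls are extracted once at the largest scale and
sub-windowed to the shorter scales, which makes cross-scale consistency
exact by construction; the test suite verifies that a direct extraction
at a shorter scale agrees.

Null timestamps are placed 24 h before each analysed earthquake
(configurable; the source states only "the time prior") and shifted
earlier in ~1-h seeded random steps while any catalog event lies within
the isolation radius or the analysis windows would leave recording
coverage. Each earthquake gets exactly one null, preserving season and
local behavioural context.

Paired t-tests are two-sided on after − before differences with
df = n − 1. Two degenerate cases are handled explicitly: identical
vectors return t = 0, p = 1, and a constant non-zero difference is an
error rather than an infinite t. Pairs with undefined mean RL (no calls
in a window) are dropped for the RL test only.

The linear models are OLS with intercept: the full predictor set is
depth + magnitude + epicentral distance + RL at the hydrophone + the
metric in the prior window + day of year (a plain linear term, not a
circular encoding) + station factor (reference level: first station id
lexicographically); the context-only set drops the earthquake terms.
Rank-deficient designs fail loudly, naming the collinear columns. With a
single station the factor is omitted with a message rather than fitting a
constant column.

## Regression to the mean

If before/after values are i.i.d. per event with no event effect, then
regressing Δ = after − before on the before value gives slope ρ − 1
(ρ = before/after correlation), hence −1 for independent counts:
cov(Δ, before) = −var(before). A negative "change vs. prior calling"
relationship is therefore expected under the null and is *not* evidence
of an earthquake response — the decisive comparison is that the slope is
statistically indistinguishable between earthquake- and null-labelled
events. `simulate_rtm_control()` reproduces exactly this: 2000 simulated
events per label, per-label slopes with 95% CIs, and an interaction test
for the label difference.

# The synthetic-data generator

`gen_scenario()` produces recordings with the statistical structure the
analysis assumes, plus exact truth tables: D calls arrive as a Poisson
process whose rate switches from the "before" to the "after" intensity at
the first earthquake time; song units (13 s: three 2-s Hann-enveloped
19 Hz pulses with 3 Hz amplitude modulation, 1-s gaps, then 4 s of
23.5 Hz tonal) are tiled at a fixed period with a before/after gain
switch; earthquake rumbles are 5–100 Hz Butterworth-filtered noise bursts
with fast onset and exponential decay; and Gaussian background noise sits
underneath. Waveforms are mono float at ±1 full scale, written as 16-bit
PCM WAV after clipping (with a warning — extreme-amplitude scenarios
should run, not crash). Everything is reproducible from one seed, and the
truth tables are identical whether or not audio is rendered, so
count-level simulations can skip waveform synthesis.

Deliberate simplifications — and therefore limits on what passing tests
show about real data: no propagation or transmission-loss model, no
whale movement (RL of a call does not drift within a window), no diel or
seasonal rate structure, call shapes drawn from the same family the
templates span (real recall will be lower on out-of-family calls), no
instrument response (all signals of interest lie inside the recorder's
flat 15–585 Hz band, so the 10 Hz high-pass is an optional extra rather
than a default), and earthquake rumbles that are statistically, not
seismologically, realistic. The default study conditions mirror the
emulated study where stated — 2 kHz sampling, magnitudes 3–4.5, rumbles
≤ 1 min, 32 events with matched nulls — and otherwise use fixed,
documented choices (60-s song period; call amplitudes giving in-band SNR
well above 10 dB over 0.01 RMS noise; D-call durations and song spacing
are not published for this population and are configurable placeholders).

# Numerical choices and problem sizes

- Spectrogram frame count is floor((N − n_fft)/hop) + 1; selections use
  closed bounds on bin/frame centers; zero-energy selections return a
  −Inf sentinel with a warning rather than an error.
- Constant (zero-variance) spectrogram patches get correlation 0;
  detector ties are broken toward earlier times, so output is fully
  deterministic.
- Poisson dispersion of generated counts is verified across 500
  replicates; paired-test calibration uses 50 replicates of 32 events
  (type-I at equal rates, power at a 3× rate increase); the
  regression-to-the-mean control uses 2000 events per label. The
  detector benchmark is 50 calls in a 25-min recording; end-to-end
  pipeline tests run a 2-h recording at 12- and 6-min window scales —
  window logic is scale-free, so short scales exercise the same code
  paths as hour-long ones at a fraction of the cost.
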
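---
title: "Methods: acoustic monitoring of broiler vocalizations at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic monitoring of broiler vocalizations at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The monitoring problem

Broiler chickens produce four well-characterized vocalization types whose
daily and ontogenetic patterns carry welfare information: distress calls
(DC; repetitive, high-intensity, descending), short peeps (SP; short,
descending, lower energy), warbles (W; low, bow-shaped frequency contour),
and pleasure notes (PN; short, ascending pitch swing). Anything else is
collected in a catch-all class (OV). Continuous barn recordings (48 kHz,
one microphone per half-pen) are converted into the headline quantity
*seconds of vocalization per minute* (s/min) per type, then aggregated
hourly, binned into four diurnal periods — night [22,4), morning [4,10),
midday [10,16), evening [16,22) — and three rearing phases (starter days
0–9, grower 10–22, finisher 23–41), and analyzed for time-of-day,
enrichment (MP/NMP) and heat-stress (HS/TN) effects.

`broilervoc` implements that whole chain, and — because no farm recordings
are distributed with it — a seeded synthetic soundscape generator with
exact ground truth so the chain can be validated end to end.

## The synthetic soundscape generator

Each call is a windowed harmonic tone (fundamental plus two harmonics at
−6 and −12 dB, raised-cosine attack/decay) whose instantaneous fundamental
follows the type's contour. No public corpus pins numeric ranges for the
four types, so the generator fixes one realistic envelope per type and
treats it as a study condition:

| type | per-syllable duration | syllables | contour | f0 (day-1) | level |
|------|----------------------|-----------|---------|------------|-------|
| DC | 0.2–0.5 s | 2–4 | descending | 3.6–4.0 → 2.6–3.0 kHz | +10 dB |
| SP | 0.05–0.2 s | 1 | descending | 3.3–3.7 → 2.3–2.7 kHz | 0 dB |
| W  | 0.2–0.4 s | 1–2 | bow (peak +40%) | 1.0–1.6 kHz | −6 dB |
| PN | 0.05–0.15 s | 1 | ascending | 2.9–3.1 → 3.6–3.9 kHz | −6 dB |
| OV | 0.15–0.5 s | 1 | random, shallow | 1.7–2.4 kHz | −6…+2 dB |

OV has no accepted acoustic definition; it is generated as shallow sweeps
and mid-band bows outside the four named envelopes, and that arbitrariness
is a stated limitation. All fundamentals stay above the 500 Hz analysis
high-pass at every age. The age-dependent pitch shift is modeled as
log-linear: the multiplier is 1.0 at day 1 and 0.6 at day 42; only the
existence and direction of the shift are established, so the 0.6 endpoint
is a package choice that tests treat as the reference.

Events are drawn per type from an inhomogeneous Poisson process (thinning
of a homogeneous process at the profile's maximum rate), with the event
rate `profile(hour) / 60 / E[duration]` so the expected *active seconds
per minute* equals the profile. Overlaps are allowed by default (real
flocks overlap); `allow_overlap = FALSE` gives greedy non-overlapping
sampling for oracle tests, where realized (not intended) events are the
ground truth. Background noise (white, pink, or ventilation-like "fan")
is scaled so that the mean per-call RMS over the background RMS in the
500 Hz–8 kHz band equals the configured SNR.

The default diurnal preset (`diurnal_profile_starter()`) anchors the four
bin rates per type on observed starter-phase farm values (SP
17.7/27.3/29.7/17.4 s/min for morning/midday/evening/night, DC peaking at
midday, W maximal at night, PN nocturnal). A second preset
(`diurnal_profile_validation()`) preserves every qualitative ordering but
adjusts the scales toward desk-scale measurability in two ways. The
rare-call rates are raised (W night ≈ 1 s/min): a variance calculation
shows that at the observed W rates (~0.1 s/min, call length ~0.5 s)
separating the night and morning bin means requires more than 200 minutes
of audio per bin — weeks of recording, which is exactly why farm studies
record continuously. And the busiest rates are halved (SP evening
15 s/min): detections count the *union* of call time per frame while the
ground truth sums per event, so at ~50% duty cycle call self-overlap
compresses bin contrasts; at ≤25% occupancy the union stays near-linear.

**Ground-truth frame labels use the frame-midpoint rule**: a 240 ms
prediction frame is labeled with the call active at the frame's center
instant. Under uniform call phase the number of covered midpoints has
expectation `duration / 0.24` for *any* call length, so counting detected
frames is an unbiased duration estimator even for 0.1 s pleasure notes —
whereas any overlap-threshold rule is provably biased for calls shorter
than the threshold. Because the 100 frames/s input resolves call onsets
far finer than the 240 ms output step, midpoint coverage is a deterministic
function of the audio and therefore learnable, not irreducible label noise.
When overlapping calls cover the same midpoint the loudest wins. Exact
per-minute durations are computed separately by interval intersection of
events with minute windows, so the ground truth mirrors both stages of the
quantification output.

## Acoustic front-end

The four preprocessing steps run per 60-second, minute-aligned segment:

1. **Resampling to 8 kHz** — polyphase FIR with a Kaiser window (β ≈ 7.85,
   12·q taps for integer decimation q), falling back to
   `signal::resample` for non-integer ratios.
2. **High-pass filtering** — 5th-order Butterworth, 500 Hz cutoff. The
   pipeline applies it forward–backward (zero phase) to avoid group-delay
   smearing of the 240 ms frame labels; the plain forward pass with the
   textbook −3 dB point at the cutoff is available and is what the filter
   contract tests measure.
3. **Spectral gating** — STFT (256-sample Hann, hop 64); per-band noise
   floor estimated as a running 20th-percentile of the short-time
   magnitude over 2 s blocks, linearly interpolated; cells not exceeding
   the floor by 20 dB are attenuated −40 dB through a pass-preserving
   soft mask (cells above the gate always keep unit gain; a 3×3 box
   smoothing only feathers the pass region outward). The gate must sit
   well above the floor because per-cell gating of Rayleigh-distributed
   noise retains the energy fraction (1 + u)e^(−u) above a gate at
   u = t²/2s², and a ≥10 dB per-band suppression of stationary noise
   needs u ≳ 4; at the study SNR of 20 dB the narrowband call components
   still clear the gate by ~10–15 dB since call energy concentrates in a
   few STFT bins. The low percentile keeps the floor from riding up on
   call-dense bands (SP can occupy ~50% of its band at evening rates).
   Anything stationary over the 2 s estimation blocks is by definition
   treated as noise floor — a continuous tone is gated; transient calls
   are not.
4. **Log-mel spectrogram** — 25 ms Hann window, 10 ms hop (100 frames/s),
   64 HTK-mel triangular filters from 50 Hz to 8 kHz with the top edge
   clamped to the post-resampling Nyquist (4 kHz; the nominal 8 kHz upper
   edge exceeds Nyquist at an 8 kHz rate — the package clamps rather than
   resolves this), log(x + 1e-10) compression. The frame-count contract is
   exact: `round(duration × 100)` frames, so 60 s → 6000 × 64.

## The recognizer

Eleven 3×3 conv2d stages (channels 16→192, batch normalization + ReLU,
mel strides halving 64 bands to 1 over the first six layers, temporal
strides 2,2,2 and 3 composing to 24) followed by a kernel-3 conv1d head
emitting 7 channels: 6 class logits (softmax, so every output row sums to
1) and a softplus age channel. Exactly 1,000,183 trainable parameters —
enforced at build time to stay within ±20% of the nominal 1.2 million.
Output sizes use floor division per stride, so any input of `T` frames
yields `floor(T/24)` predictions (one per 240 ms) and inputs shorter than
24 frames give an empty raster.

Training minimizes class cross-entropy plus 0.1 × L1 age regression
(days), with Adam (10⁻³, step decay to 2×10⁻⁴ for the final third of the
epochs) on 2.4 s snippets — longer than the network's ±1.1 s receptive
field so central outputs see full context, as they do in 60 s segments.
Class weights are *tempered* inverse frequency (1/n^0.5): full inverse
frequency weighting was observed to produce confident minority-class
false positives on pure background, which at the 0.7 detection threshold
adds a spurious ~0.5 s/min floor to every rare type. Short call types get
several calls per snippet so their 240 ms rows are not vanishingly rare.
An optional two-phase schedule (head-only, then all layers at lower rate)
is provided for fine-tuning from existing weights; training here is from
scratch, so single-phase is the default. Everything is seeded; identical
seeds and data give identical parameters on a fixed BLAS configuration.

## Quantification and statistics

Durations: frames with a class score ≥ 0.7 (inclusive; the choice at
exact equality is pinned for oracle tests) count 0.24 s each toward that
type's wall-clock minute. Row normalization plus a threshold above 0.5
makes detections mutually exclusive per frame, so the five types sum to
at most 60 s/min. Minutes aggregate to hourly means (s/min); hours with
no recorded minutes yield missing values, never zeros, which would bias
diurnal means. Bins are half-open `[start, end)`; the finisher phase is
days 23–41, following the feed-phase definition where the published
table captions overlap at day 22.

The duration model is REML `lmer` with random intercepts for pen (the
experimental unit) and compartment and Satterthwaite denominator degrees
of freedom; microphone nesting can be added as a third random level via
the `random` argument (one observation per microphone is the default
granularity). One refinement proved necessary for calibration: factors
constant within pens (the treatments) are tested against between-pen
variation using the classical balanced split-plot F on pen means, with
compartment as a fixed block. In null simulations of the trial design
the Satterthwaite omnibus test for such whole-plot factors rejected at
~7.5% (nominal 5%) because the pen variance estimate collapses to the
boundary in a sizeable fraction of replicates, effectively testing a
pen-level contrast against residual degrees of freedom; Kenward–Roger
over-corrected to ~2.5–3%. The whole-plot F is exact under normality for
balanced designs, and within-pen factors (time bin, interactions) keep
the Satterthwaite tests, which are well calibrated there. This is the
classical split-plot analysis implied by treating the pen as the
experimental unit. Treatment × bin interactions are dropped when p ≥ 0.05 and
the model refitted. Significant factors get Tukey-corrected pairwise
comparisons (`emmeans`) and a compact letter display computed by
insert-and-absorb from the pairwise p-matrix (letters are checked in the
tests to be exactly reconstructible from the p-values). Outliers
(|studentized residual| > 3) and residual normality are reported as
diagnostics, never acted on automatically. A singular or failed mixed fit
falls back to fixed-effects least squares with a warning.

THI: the exact index formula behind the original climate analysis is not
public, so `compute_thi()` exposes a registry — the default
`poultry_wb = 0.85·T_db + 0.15·T_wb` (Stull wet-bulb approximation) is a
clearly-flagged stand-in, with Thom and NRC variants as alternatives.
The THI ANOVA is a three-factor fixed-effects model
(treatment × round × time of day, read as 10:00/12:00/14:00) with Tukey
post hoc on significant factors; rank-deficient designs are rejected with
the aliased terms named.

## Validation design and problem sizes

All validation runs on synthetic data; sizes were fixed by a-priori
variance calculations, and state what passing shows about real data —
and what it cannot.

* **Recognition**: 1,280 training snippets (240 background + 200–220 per
  call type; ages uniform over days 1–42; SNR 20 dB; 48 kHz synthesis),
  10 epochs, held-out balanced accuracy measured on 240 fresh snippets.
  Typical held-out balanced accuracy is ~0.93; the acceptance bound (0.5,
  three times the 6-class chance rate) is deliberately a property bound,
  not a reproduction claim for accuracies obtained on manually labeled
  farm recordings.
* **Duration recovery** uses a 60-minute overlap-free soundscape whose
  per-type rates ramp within the hour (staggered directions, total
  occupancy < 40%). Under a *flat* profile, between-minute variance is
  pure Poisson noise of the same order as the 0.24 s quantization noise,
  which caps the attainable Pearson r near 0.85 for 0.1 s calls however
  good the detector — correlation against ground truth is only a
  well-posed recovery metric when real rate variation exists, which a
  dawn-like ramp provides.
* **Diurnal ordering** uses the validation preset over one simulated day,
  two minutes sampled per hour (48 processed minutes).
* **Statistical calibration**: 1,000 null replicates of the trial design
  (4 compartments × 2 pens × 2 microphones × 4 bins) for the type-I rate
  of the treatment test; 200 replicates with a +3 SD evening effect for
  power; an end-to-end null (identical profiles for MP and NMP pens
  through audio, front-end, recognizer and model) checked at α = 0.01 on
  one seeded replicate.

What the synthetic conditions do *not* emulate: reverberation and
microphone coloration, the union-vs-sum saturation of dense overlapping
choruses (estimated s/min is bounded by 60 per minute jointly across
types, while per-type true activity is not), overlapping flock chorus at commercial density,
age-dependent *rate* drift within a run (age affects pitch only), feeder
and machinery transients, and OV's true acoustic diversity. Passing tests
therefore demonstrates the computational chain's correctness and its
statistical calibration, not field performance.

## Numerical choices

* Log compression offset 1e-10 with floor log(1e-10).
* Batch-norm ε = 1e-5; running statistics with momentum 0.1.
* He-normal initialization; Adam β = (0.9, 0.999), ε = 1e-8.
* Raster rows are validated to sum to 1 within 1e-4 before thresholding;
  the network's softmax satisfies 1e-5 everywhere.
* Detection threshold comparisons are inclusive (≥ 0.7).
* Empty inputs: zero-length audio resamples/filters to zero length;
  spectrograms shorter than one window yield a single padded frame;
  rasters shorter than 24 frames are empty; empty hours are missing.
* Seeds: every stochastic stage (event sampling, noise, weight
  initialization, batch shuffling, simulation replicates) draws from an
  explicit integer seed; generator and trainer restore the caller's RNG
  state.
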
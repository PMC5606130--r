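---
title: "Methods: automatic sleep staging from ear-EEG"
author: "earsleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic sleep staging from ear-EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its method: the model, the
constants and why they have the values they have, what the synthetic
generator does and does not emulate, and the numerical and design choices
made where more than one defensible option existed. It states no
empirical numbers beyond those the test suite and `scripts/acceptance.R`
compute themselves.

## The staging problem

An overnight ear-EEG recording is a 12-channel time series (electrodes
`ELA ELB ELE ELI ELG ELK` in the left ear, `ERA ... ERK` in the right;
`A`/`B` sit in the concha, `E`/`I`/`G`/`K` in the ear canal), sampled at
200 Hz against a common reference. Manual scoring assigns one of five
AASM labels — W, REM, N1, N2, N3 — to every non-overlapping 30-s epoch.
The pipeline learns this mapping: per epoch it extracts 99 features and
classifies them with an ensemble of bagged decision trees trained on
manually scored epochs.

## Channel rejection

Electrode-skin contact degrades overnight (gel dries, the ear deforms on
the pillow), and a high-impedance electrode shows excess high-frequency
noise in *every* derivation it takes part in. The rule exploits exactly
that: for each same-ear pair $(i,j)$, let $p_{ij}$ be the mean Welch
density of $x_i - x_j$ over 10–35 Hz, computed on the whole night; reject
electrode $i$ when $m_i = \mathrm{median}_j\, p_{ij} > 5\cdot10^{-12}\,
\mathrm{V^2/Hz}$.

Design points:

* $p_{ij}$ is a mean spectral **density** (V²/Hz), not an integrated band
  power — the threshold's units force this reading.
* The 10–35 Hz limitation exists only inside this rule (realised as
  Welch-bin selection, equivalent to band-pass filtering and simpler);
  unfiltered data proceed to feature extraction.
* Rejection operates once per recording on the full night: electrodes are
  rejected, not epochs.
* The median over an electrode's pairwise powers makes the statistic
  robust to a *minority* of bad partners. That is also its identifiability
  limit: once half or more of an ear's electrodes are bad, every clean
  electrode's median is elevated and the clean/bad partition is no longer
  recoverable from pairwise powers alone. The recovery experiments in the
  test suite therefore plant at most two bad electrodes per ear; a
  whole-ear failure is instead handled downstream by derivation
  substitution.
* An ear contributing fewer than two electrodes forms no intra-ear pair;
  its electrodes are flagged unusable with a warning rather than silently
  kept.

## Derivations

Surviving electrodes form three analysis derivations:
$\mathrm{LR} = \langle\text{left 6}\rangle - \langle\text{right 6}\rangle$,
$\mathrm{L} = \langle ELA, ELB\rangle - \langle ELE, ELI, ELG, ELK\rangle$,
and $\mathrm{R}$ analogously — concha-minus-canal potentials within each
ear, and the across-head difference. Differencing removes the common
reference; averaging suppresses uncorrelated electrode noise.

Rejected electrodes are excluded from the averages, and a one-electrode
"mean" is that electrode. A derivation whose minuend or subtrahend group
is emptied is substituted with a byte-identical copy of another
derivation, with deterministic priority: a missing L copies R, a missing
R copies L, a missing LR copies L (else R). LR is considered uncomputable
whenever a *whole* ear is missing — a one-sided "difference" would just
be that ear's mean, which is not the same physical quantity — so a
one-eared subject carries three identical derivations.

## Filtering and spectral estimation

All filters are applied once to the full-night derivation signals, and
epochs are cut afterwards; per-epoch filtering would put start-up
transients into every epoch. Four zero-phase paths are computed (4th-order
Butterworth, forward–backward, so waveform-shape features such as
skewness and percentiles are not phase-distorted):

| path  | band      | consumers                 |
|-------|-----------|---------------------------|
| EEG   | 2–32 Hz   | F1–F7, F13–F28, F29–F33   |
| EOG proxy | 0.5–30 Hz | F11–F12               |
| EMG proxy | 32–80 Hz  | F8–F10                |
| sigma | 11–16 Hz  | spindle envelope (F29, F33) |

A 50 Hz biquad notch (quality factor 30, standard mains rejection) is
applied before all four paths. Whether the notch belongs on every path or
only the EEG one was left open by the method's description; it is applied
to all here, which is harmless for the EOG/EMG proxies (50 Hz lies inside
the EMG band, and mains power would otherwise masquerade as muscle tone).
The EMG band demands a sampling rate above 160 Hz; at 200 Hz its upper
edge sits safely below Nyquist. The EOG and EMG proxies are computed from
ear-EEG alone — no actual EOG/EMG electrodes exist in this montage; the
passbands distil what eye movement and muscle tone leak into the ear.

Every frequency-domain quantity uses one Welch configuration: 2-s
segments, 1-s overlap, Hann taper, one-sided density scaled so that
density × bin width sums to the signal variance. A 30-s epoch at 200 Hz
yields 29 segments and 0.5 Hz bins.

## The 33 features

Per derivation and epoch (99 columns in derivation-major order
`F1_LR ... F33_LR, F1_L ..., F1_R ...`):

* **F1–F7, time domain** (EEG path): skewness and kurtosis as population
  moments — kurtosis is *non-excess*, a normal signal scores 3 (the
  convention had to be picked; it is documented rather than implied);
  zero-crossing rate in crossings/s with exact zeros skipped; Hjorth
  mobility $\sqrt{\mathrm{var}(x')/\mathrm{var}(x)}$ with $x'$ the first
  difference scaled by $f_s$ (units s⁻¹; a pure $f$ Hz tone scores
  $\approx 2\pi f$); Hjorth complexity; the 75th percentile of $|x|$
  (volts); and the correlation between the derivation's two constituent
  group means — the only channel pair intrinsic to a derivation, which is
  how "channel correlation" stays meaningful per derivation.
* **F8–F10, EMG proxy**: epoch variance; minimum variance over the thirty
  1-s windows (tonic floor); relative burst amplitude
  (P95 − median)/median of the 1-s window RMS sequence.
* **F11–F12, EOG proxy**: mean Welch density over 0.5–1.5 Hz (slow eye
  movements) and 1.5–4 Hz (rapid eye movements). The precise proxy bands
  were not fixed by the method's public description; these defaults are
  the package's choice and are marked as such.
* **F13–F28, EEG spectrum**: band powers integrated over δ 2–4, θ 4–8,
  α 8–13, β 13–32 Hz. δ starts at 2 Hz because the EEG path itself starts
  there — the four bands then tile the passband exactly and the relative
  powers F13–F16 sum to 1 by construction. F17–F23 are the printed power
  ratios; F24/F25 the 95% and 50% spectral edge frequencies; F26 the mean
  absolute SEF95 difference across the fifteen 2-s sub-segments; F27 the
  peak-density frequency; F28 the Shannon entropy of the bin-normalised
  density divided by log(#bins), so a flat spectrum scores exactly 1 and
  a single line scores 0.
* **F29–F33, sleep events**: the sigma envelope is the sliding 0.25-s RMS
  of the 11–16 Hz path; the spindle threshold is twice the epoch-median
  envelope (median, not mean, so the bursts themselves barely move the
  threshold). F29 is the supra-threshold sample fraction, F33 the longest
  supra-threshold run in seconds, F32 the largest modulus of a Morlet
  (centre 13 Hz, 6-cycle) continuous wavelet transform, F30/F31 the
  stationarity of the 2-s sub-segment spectra (SD of median power
  frequency; minimum adjacent-spectrum correlation).

Numerical guards: ratio denominators carry ε = 10⁻³⁰ V² (negligible at
µV² scales, decisive at 0); every feature undefined on a flat or empty
epoch returns the documented sentinel 0, keeping the classifier input
finite. Spectral edges interpolate linearly *within* a bin treated as a
cell of width Δf centred on its frequency — the convention under which a
flat 2–32 Hz spectrum has its median power frequency at exactly 17 Hz.

## The stager

One hundred classification trees, each grown on a bootstrap resample of
the training set of the same size (duplicates allowed), split by Gini
impurity until leaves are pure or hold one sample. Every feature is a
candidate at every split: this is *bagging*, not a random-subspace
forest; per-split feature subsampling is exposed as a knob (`mtry`) but
defaults to all 99, because subsampling would be a different classifier.
No class weighting or prior rebalancing is applied — rare stages (N1
especially, typically a few percent of epochs) are expected to suffer
from their prevalence, and that behaviour is part of the method.
Prediction is an unweighted majority vote; ties break deterministically
toward the class with higher training prevalence, then by the fixed order
W, REM, N1, N2, N3. Determinism is mandatory for reproducible validation,
so a documented arbitrary rule beats a platform default.

Training requires at least two classes. The ensemble is seeded; the seed
fully determines the bootstrap draws.

## Cross-validation and agreement

Adjacent 30-s epochs are highly correlated — usually the same stage of
the same night with near-identical spectra. If test epochs are scattered
through the sequence, most have training neighbours on both sides, and a
min-leaf-1 interpolating ensemble effectively reads the test label off
its neighbours. Test sets are therefore *contiguous*:

* `leave_one_out` — one fold per subject; hardest, no subject-specific
  information.
* `total` — all subjects pooled in input order, 20 contiguous near-equal
  blocks (sizes differ by at most one; earlier blocks take the extra
  epoch, a deterministic convention).
* `individual` — 10 contiguous blocks within each subject, trained only
  on that subject's remaining blocks; models the personally calibrated
  device.

A deliberately leaky interleaved mode (`scattered = TRUE`, labelled
`_leaky` in output) exists solely to measure the neighbor effect: the
test suite asserts its direction (scattered accuracy strictly above
contiguous), not a magnitude, since the magnitude depends on the
autocorrelation structure of the data at hand.

Agreement: confusion matrices with manual labels in rows and automatic in
columns over the full stage vocabulary of the level; accuracy as the
trace fraction; one-vs-rest sensitivity and specificity per stage; and
Cohen's κ = (p₀ − pₑ)/(1 − pₑ). The degenerate single-cell table returns
κ = 0 (observed and chance agreement coincide at 1; claiming perfect
chance-corrected agreement would be vacuous). Coarser scorings are pure
relabellings of the 5-stage output — N1/N2/N3 → NREM at 3 stages,
everything but W → Sleep at 2 — applied to manual and automatic labels
alike, never retrained; relabelling commutes (5→3→2 equals 5→2).
Per-subject κ tables are averaged unweighted: each subject counts once,
regardless of epoch count.

## The synthetic cohort generator

The generator exists so that every stage of the pipeline is testable
without clinical recordings. It emulates precisely the phenomenology the
features rely on, and nothing more:

* **Hypnograms**: first-order Markov chains over the five stages starting
  in W, self-transition 0.9, physiologically ordered moves (W enters
  sleep through N1; N3 is reached via N2). Real sleep has longer memory;
  first-order dynamics already give realistic bout structure and the
  temporal autocorrelation the contiguity arguments need.
* **Signals**: per epoch, a 1/f background (5 µV RMS) plus stage-profiled
  band-limited Gaussian components — δ/θ/α/β, a 32–80 Hz EMG tone, and
  slow/rapid eye-movement surrogates — shared across channels through
  per-channel gains, plus 2 µV RMS independent sensor noise. Concha and
  canal electrodes carry different gains (1.0 vs 0.4 left, slightly
  asymmetric on the right), so within-ear derivations retain signal while
  same-group pairwise differences cancel it, exactly the geometry the QC
  rule and derivations assume. The stage profiles encode the clinical
  contrasts: δ strongest in N3, then N2; α strongest in W; EMG tone
  W > N1 > REM (atonia); rapid-eye activity in REM.
* **Events**: N2 epochs receive Poisson-placed spindle bursts (3/min,
  0.5–2 s, 11–16 Hz, Hann-enveloped) and biphasic ~1 Hz K-complexes
  (1/min, 100 µV peak, morphologically qualitative only).
* **Drift**: each band amplitude follows a log-AR(1) walk across epochs
  (ρ = 0.95, stationary SD 0.3), making neighbouring epochs genuinely
  more alike than distant same-stage epochs — without this, scattered
  and contiguous folds would be equivalent and the neighbor effect
  untestable.
* **Bad electrodes**: designated channels receive added broadband noise,
  50 µV RMS by default — two orders of magnitude above the clean pairwise
  level, so the 5·10⁻¹² V²/Hz threshold bisects clean and bad cleanly.

What it does **not** emulate: volume-conduction forward physics, real
spindle/K-complex morphology, circadian sleep architecture, arousal
microstates, movement artefacts, inter-subject variability of spectra
beyond the seeded randomness. Consequently, passing end-to-end tests
demonstrates that the pipeline is correctly assembled and recovers
structure it is designed for — it does not certify clinical performance
on real recordings, whose stage signatures are far less separable.

## Problem sizes and determinism

The test suite and acceptance script use desk-scale cohorts chosen to
exercise every code path while keeping runs reproducible on one CPU:
three subjects × 400 epochs (3.3 h each) for end-to-end staging, two
subjects × 300 epochs for the neighbor-effect comparison, and twenty
single-subject fixtures for rejection recovery. Every random quantity —
hypnograms, signals, bootstrap draws, fold seeds — derives from a single
master seed; per-subject and per-fold seeds are fixed arithmetic
functions of it, so any run is reproducible byte-for-byte from
(configuration, seed).

## Known limitations

* EDF support covers the classic 16-bit format (one sampling rate per
  channel, physical/digital linear scaling); EDF+ annotations and
  scoring-software proprietary exports are out of scope.
* The per-subject κ in small simulations is fragile for rare stages — a
  subject whose night contains three N2 epochs can swing its κ by one
  misclassification. That mirrors the prevalence sensitivity of the real
  method rather than a defect of the implementation.
* The feature set is fixed at the documented 99; feature selection was
  deliberately left out of scope (the underlying method explored and
  abandoned it).
* Sleep-event and EOG-proxy feature definitions marked "package's
  choice" above are defensible defaults, not community standards; anyone
  comparing against another implementation should check those
  definitions first.
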
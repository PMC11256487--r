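---
title: "Simulating and validating remote wearable-EEG sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and validating remote wearable-EEG sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remoteEEG)
```

## Scope and model of the platform

remoteEEG re-expresses a remote EEG collection platform — the kind built
around four-electrode consumer headbands (Muse-class hardware: TP9, AF7,
AF8, TP10 referenced to Fpz) — as a hardware-free, fully testable toolkit.
It has three layers:

1. **Acquisition and session control.** A device registry
   (`getDeviceSpec()`), a replay streaming backend (`streamRecording()`)
   standing in for a live Bluetooth thread, a pre-session electrode
   quality gate (`assessQuality()`), and a session engine
   (`runSession()`) that schedules tasks, draws oddball stimulus
   sequences and merges integer marker codes into the timestamped sample
   stream.
2. **The recording artifact.** `writeRecording()` / `readRecording()`
   serialize a session to a ZIP archive holding a timestamped CSV with a
   `Marker` column plus JSON metadata (session echo, device, manifest) —
   the portable unit a field study would ship back for analysis.
3. **Validation analyses.** Resting-state relative band power and the
   alpha-blocking contrast, a per-channel band-change table,
   cluster-based permutation t-tests on oddball/standard event-related
   potentials (ERPs), and a single-epoch minimum-distance-to-means (MDM)
   classifier in the Riemannian geometry of covariance matrices.

Because no hardware is attached, a first-class synthetic-signal module
(`simulateRecording()`) emulates what the wearable would deliver, with
enough physiological structure that every analysis above has a true
effect to recover — and a matching null to be calibrated against.

## The signal simulator

A simulated channel is the sum of four components:

- **Background noise**: Gaussian white noise spectrally shaped to
  power ∝ 1/f^a (`genColoredNoise()`), rescaled to an exact target RMS.
  Default a = 1 (the conventional pink EEG background) and 10 µV RMS, an
  order of magnitude typical of clean scalp EEG from dry-electrode
  wearables. The inverse-FFT shaping gives exact control of the
  exponent, which the tests verify as a log–log periodogram slope of −1
  over 2–50 Hz. An optional mains sinusoid (60 Hz by default) can be
  added to exercise the filter.
- **State-gated oscillations** (`addOscillation()`): a sinusoid whose
  amplitude is multiplied by a per-state gain over a behavioral timeline.
  The default is a 10 Hz, 5 µV alpha rhythm with gain 2 when the eyes
  are closed and 1 when open — the alpha-blocking contrast. Gains act on
  amplitude, so the default doubles alpha amplitude and quadruples alpha
  power when the eyes close.
- **Stimulus-locked ERP templates** (`renderErp()`): sums of signed
  Gaussian bumps. A component peaks at its latency with value
  amplitude × channel gain and decays with standard deviation equal to
  its width. The default oddball template is an N200 (−3 µV at 0.20 s,
  width 0.03 s) plus a P300 (+5 µV at 0.30 s, width 0.05 s) on all four
  channels; standards carry no deflection. Gaussians are the simplest
  parameterization with testable peak semantics.
- **Markers**: one positive integer code per scheduled event, placed on
  the sample whose timestamp is nearest the event onset (collisions move
  the later event one sample forward, so no marker is ever lost).

The defaults above are the study conditions the whole validation suite
runs under. The amplitudes are conventions — wearable hardware vendors do
not publish reference amplitudes, and the point of the simulator is
controlled recoverability, not biophysical realism. What the simulator
deliberately does *not* model: volume-conduction forward models,
eye-blink/EMG artifact taxonomies, electrode drift, or packet loss.
Passing tests therefore demonstrate that the *pipeline* is correct and
calibrated, not that it is robust to every failure mode of real field
data.

Determinism is a contract: an identical `SimulationPlan` (including its
seed) yields a bitwise-identical recording. Per-channel noise and
per-oscillation phases draw from sub-seeds derived from the master seed,
so channels are independent but jointly reproducible.

## Session design and timing

The shipped default session mirrors the classic remote protocol: a free
recording, one minute each of eyes-open and eyes-closed rest, then two
200-trial oddball blocks separated by a recovery rest. Oddball trials are
independently deviant with probability 0.1 (green circle standards, blue
circle oddballs in the display descriptors), with runs of more than two
consecutive oddballs repaired by re-drawing from the same generator so
the sequence stays deterministic given the seed. Stimulus timing defaults
to a 1.0 s onset-to-onset interval and 0.2 s display duration; the first
stimulus of a block comes one interval after block start and the block
lasts (n + 1) intervals, which keeps stimulus onsets clear of the
task-boundary markers and leaves room for the last epoch window. None of
these timing values are physiological constants; all are configurable in
the YAML session dialect.

Marker codes: `standard = 1`, `oddball = 2` (0 is reserved for "no
event"); task boundaries use 100 + task index at start and 200 + task
index at the last sample of the task. Configuration validation is eager
and names the offending field (reserved code 0, duplicate codes,
probabilities outside [0, 1], unknown task kinds).

## The quality gate

Signal variability is measured as the per-electrode standard deviation
over the most recent second of the assessed window, classified
against two thresholds: accepted at ≤ 20 µV, rejected at ≥ 40 µV, "near"
in between. The thresholds are order-of-magnitude conventions (clean
scalp EEG vs. motion artifact), exposed as arguments. The state is by
construction monotone in the variability, and a flat (σ = 0) electrode
counts as accepted — the gate checks variability only, and deliberately
adds no disconnected-electrode heuristic.

## Spectral analysis

All analyses start from a zero-phase 1–55 Hz bandpass. The filter is a
linear-phase windowed-sinc FIR (2·fs + 1 taps, reflection-padded centered
convolution) rather than a forward–backward IIR: at fs = 256 the 55 Hz
edge sits close enough to 60 Hz that even an 8th-order Butterworth
bandpass applied forward and backward attenuates mains by only ~11 dB,
while the FIR design passes 10 Hz at unity gain and attenuates 60 Hz by
~58 dB (and higher IIR orders are numerically unstable with a 1 Hz low
edge). Zero phase matters because cluster boundaries and ERP latencies
must not be shifted by filtering.

Rest intervals are cut into consecutive non-overlapping two-second
epochs. Per epoch and channel, a Welch estimate (1 s Hann segments, 50%
overlap) yields the power spectral density; band powers integrate the
PSD over delta 1–4, theta 4–8, alpha 8–13, beta 13–30 and gamma 30–55 Hz
and are normalized by total 1–55 Hz power, so each row of the band-power
table sums to one and is invariant to overall amplitude scaling. The
alpha-blocking test is a two-sample Welch t-test on relative alpha power
with the sign convention closed − open; the band-change table runs the
same contrast for every channel × band cell and reports raw and
Benjamini–Hochberg adjusted p-values (symmetric channel pairs TP9/TP10
and AF7/AF8 ordered side by side). Whether epochs are pooled across
sessions or aggregated per session is an open design choice in such
studies; the table pools, and accepts any list of sessions so callers
can aggregate upstream instead.

## Cluster-based permutation ERP statistics

Epochs span −0.2 to 0.8 s around each stimulus marker (a conventional
P300 window), baseline-corrected by the mean over −0.2 to 0 s;
edge-crossing epochs are dropped with a reported count. The test per
channel is the standard max-statistic construction: a pooled-variance
two-sample t at every time sample; contiguous runs with |t| above the
two-sided threshold at p = 0.05 form clusters scored by mass (summed
|t|); condition labels are permuted (default 1000 times) and the maximal
cluster mass per permutation forms the null; each observed cluster gets
p = (1 + #{null ≥ mass}) / (n + 1), so the smallest attainable p with
1000 permutations is 1/1001 ≈ 0.001. The cluster-forming threshold
(0.05) and the display significance level (0.01) are distinct knobs and
both exposed. The observed clusters are a pure function of the data —
only the permutation draw consumes the seed — and the implementation is
cross-checked in the tests against an independent loop-based
re-implementation on small instances (identical boundaries and masses,
p within Monte-Carlo tolerance at matched permutation counts).

Calibration and power at the study conditions (verified by the test
suite): on 200 null sessions (no injected deflection) the fraction of
runs with any cluster p < 0.05 is ≈ 0.035; with a +5 µV deflection
spanning 0.25–0.40 s at ~40 oddball / ~360 standard epochs, a p ≤ 0.01
cluster overlapping the injected window is recovered on a
temporo-parietal electrode (TP9 or TP10 — the pair such studies report
oddball effects on, and the deflection is injected on all channels) in
20 of 20 seeded runs. On a single fixed electrode the recovery is 17–18
of 20, with misses at p = 0.02–0.04: at this signal-to-noise ratio the
per-electrode power genuinely sits near 85–90%.

## The MDM classifier

Single-epoch classification uses ERP super-trial covariances: the
prototype waveform (the mean training oddball epoch) is stacked over each
epoch, giving a 2C × 2C sample covariance whose prototype–epoch block
measures how well the epoch aligns with the average oddball response.
Covariances are shrunk toward a scaled identity,
(1 − λ)S + λ·mean(diag(S))·I with λ = 0.1 by default, guaranteeing
positive definiteness. Class centers are geometric (Karcher) means under
the affine-invariant Riemannian metric
d(A, B) = sqrt(Σ log² λᵢ(A⁻¹B)), computed by fixed-point iteration on
the tangent-space average (tolerance 1e-8, 50-iteration cap, convergence
error reporting the final norm); a Euclidean/arithmetic ablation is one
argument away. Prediction assigns the nearest class mean; the continuous
score d(x, mean_standard) − d(x, mean_oddball) feeds a rank-based AUC.
Exact ties go to the lexicographically first class and are flagged.

Evaluation is stratified 5-fold cross-validation with the prototype
refit inside each training fold (no leakage), pooling out-of-fold
predictions into one confusion matrix scored by accuracy, AUC and the
Pearson chi-square test without continuity correction. On the default
synthetic oddball dataset (~40/360 epochs, N200+P300 template, 10 µV RMS
noise) the pipeline reaches accuracy ≈ 0.87 and AUC ≈ 0.90 — the
synthetic analogue of single-epoch oddball separability on real
wearable data, not a reproduction of any particular study's numbers.

The chance-level check deserves a note. Shuffling the labels of a
90/10-imbalanced dataset does *not* push accuracy to 0.5: any classifier
that predicts the majority class with rate q scores 0.915q + 0.085(1−q)
under shuffled labels, ≈ 0.75 for this pipeline. A meaningful chance
benchmark needs a balanced design, so the null check shuffles the labels
of a balanced (p = 0.5) oddball session, where chance is 0.5 by
construction; the measured mean over 20 shuffles is ≈ 0.51.

## Numerical choices and degenerate inputs

- Colored noise is rescaled to the target RMS exactly; amplitude 0 gives
  an all-zero trace rather than a degenerate draw.
- Welch segments fall back to the full window when the epoch is shorter
  than one segment; epochs under 1 s are rejected.
- The alpha-blocking test returns p = 1 with a `degenerate` flag when
  both groups are constant and equal (rather than NaN from a 0/0 t).
- Rank-deficient super-trial covariances (T < 2C with λ = 0) raise an
  error instructing λ > 0; all-zero inputs fall back to a tiny identity
  scale so the output stays positive definite.
- Cluster tests with no suprathreshold sample return zero clusters, and
  permutations with no clusters contribute mass 0 to the null.
- CSV voltages are written in round-trip decimal form (read-back exact to
  well below 1e-6 µV); markers are integers and round trip exactly.
- Archives are standard ZIP with stored members, so reading needs no
  external unzip binary; a CRC-32 in compiled code keeps writing fast.

## Problem sizes used by the validation suite

The test suite and the acceptance script run everything at desk scale:
100 short randomized sessions for marker fidelity, 100 short recordings
for round-trip checks, 20 two-minute rest sessions for alpha blocking,
200 null sessions × 1000 permutations for type-I calibration, 20
400-trial sessions for ERP power, and one 400-trial session (plus a
balanced 200-trial session for the null) for the classifier. These sizes
were chosen so each property is measured with useful Monte-Carlo
precision while the whole suite stays fast enough to run on every
change.

## Known limitations

- The simulator's stationarity (fixed noise spectrum, fixed template)
  understates real-session variability; per-electrode gains and artifact
  bursts exist but default off.
- Cluster inference is per-channel, as in the figure-style reporting it
  mirrors; no multi-channel cluster connectivity is implemented.
- The EPOC-class registry entry is provisional (the vendor montage is
  not fully documented here), and real Bluetooth pairing, GUI rendering
  and media playback are out of scope by design — the engine emits
  display descriptors and records markers, nothing more.
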
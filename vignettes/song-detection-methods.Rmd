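---
title: "Detecting songs in passive acoustic recordings: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting songs in passive acoustic recordings: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songsieve)
```

## The problem

Passive acoustic monitoring (PAM) campaigns for loud-calling species produce
recordings far faster than anyone can listen to them. The deployment this
package is built around — AudioMoth and Song Meter SM4 recorders in a
Madagascan rainforest surveying the indri (*Indri indri*), the only singing
lemur — collected 66,443 ten-minute files (over 11,000 hours) in three years
on a 10-min-every-30-min schedule. The indri's song is a loud, stereotyped
display built from *descending phrases*: an initial note followed by one to
four notes of gradually lower fundamental frequency, with the fundamental
and first harmonics below 2,500 Hz. A recording is "song-containing" when at
least one descending phrase is present.

`songsieve` implements the full detection workflow: compact spectral
features, a small convolution-only classifier with cyclic temporal
covariates, class balancing by slice-shuffle augmentation, transfer learning
across recorder types and years, cross-validated evaluation with paired
statistical comparisons, and diel/seasonal activity estimation. A seeded
soundscape simulator stands in for the field recordings (which are not
publicly deposited), so every stage is testable end to end.

## Features: one-third-octave band energies

Each recording is reduced to a T×B matrix: T consecutive 20-s intervals by
B = 18 one-third-octave bands (a 600-s file becomes 30×18). The band system
is the base-ten convention: band *n* is centred at $10^{n/10}$ Hz with edges
a factor $10^{\pm 1/20}$ away, so adjacent bands tile the axis exactly and
band 30 is the 1 kHz reference. Bands 26–43 (≈398 Hz–20 kHz) are retained:
the low edge sits below the song's fundamental range and the high edge
matches the presumed upper bound of the species' hearing. A 20-s interval
is long enough to compress the data by a factor of several thousand
(a 30×18 CSV is ~5 kB against a ~58 MB WAV) and short enough that a typical
song (~89 s) spans several intervals.

Numerical choices, none of which a band-energy definition pins down by
itself:

* Per interval, the power spectrum is estimated by Welch-averaged
  periodograms (8192-sample segments, periodic Hann window, 50% overlap)
  rather than one ~10⁶-point FFT; the averaging makes band sums stable and
  any consistent estimator that localises a pure tone in its own band is
  acceptable.
* The estimator is scaled so the two-sided spectrum sums to the interval's
  mean-square power; band powers are therefore disjoint shares of frame
  power (a Parseval bound the test suite checks).
* Band energies are reported as $10\log_{10}(P + \varepsilon)$ dB with a
  floor $\varepsilon = 10^{-12}$; silence maps to −120 dB instead of −∞.
* Bands whose upper edge exceeds the Nyquist frequency are set to the
  floor, flagged, and reported with a warning; a trailing partial interval
  is discarded (moot for 600-s files, which divide evenly).

## Normalization

Features are mapped to [0, 1] per band using quantile thresholds fit on
*training data only*: values at or below the `q_lo` quantile (default 0.01)
become 0, values at or above `q_hi` (default 0.99) become 1, and the rest
scale linearly. Truncating the tails keeps rare loud transients (rain,
thunder, handling noise) from compressing the usable dynamic range. The
defaults are a package choice — the original study selected its truncation
by comparing model performance — and both quantiles are exposed. The fitted
normalizer travels inside the saved model bundle so that inference and
transfer never re-estimate statistics from data they should not see; a
degenerate band (constant in training) maps to 0.5.

## Augmentation and class balancing

Song-containing recordings are rare (9–14% in the reference campaign), and
a binary cross-entropy learner left unbalanced mostly learns to say "no".
The training set is balanced by *slice-shuffle* augmentation: a normalized
30×18 matrix is cut into six 5×18 time slices (100 s each — wide enough to
contain a song or a recognisable portion of one) which are rearranged in a
random order to form a novel matrix. Permutations are drawn uniformly over
all 6! = 720 orders, identity included; the frequency axis is untouched, so
per-band value multisets are preserved exactly. Augmented copies of
positives are appended — cycling through the positives, fresh permutation
each time — until half the training set is positive. Three deliberate
restrictions: augmentation happens after normalization, it is applied to
training splits only (validation and test keep their natural class
balance, the conservative reading), and a single static augmented set is
built per training run rather than re-augmenting each epoch.

## The detector

The classifier is convolution-only on the feature path (no pooling): small
images lose too much to pooling, and strided convolutions do the
downsampling instead. The shipped default is

```
input 30×18×1
conv1: 16 filters 3×5, stride 1×1   → 28×14×16
conv2: 32 filters 3×5, stride 2×2   → 13×5×32
conv3: 32 filters 3×3, stride 1×1   → 11×3×32
flatten (1056) + 4 cyclic covariates
dense 64 (ReLU, dropout 0.3) → dense 32 (ReLU) → sigmoid
```

for 87,233 trainable parameters, near the ~84k-parameter scale at which
this family of detectors was originally calibrated; the conv2 stride of
2×2 was chosen precisely to land the default near that scale while keeping
two fully connected layers before the output. Kernels are non-square
(time×frequency) so each layer's aspect ratio is tunable. The exact
reference hyperparameters are unpublished, so every field of
`detector_config()` is externalized and the parameter count is always
reported analytically (`count_parameters()`), with the toy and default
configurations checked against hand-computed sums in the tests.

**Cyclic covariates.** Hour of day (hour + minute/60, period 24) and week
of year (day-of-year blocks of 7 clamped to 52 weeks, period 52) are each
mapped to a unit circle and represented by their sine and cosine, so
23:30 neighbours 00:00 and week 51 neighbours week 0. The four numbers are
concatenated after the flatten, entering the fully connected layers only.
They are in [−1, 1] by construction and are used unstandardized.

**Training.** Binary cross-entropy, Adam (default learning rate 10⁻³),
minibatches of 32, at most `epochs` passes with early stopping: the weights
with the best validation loss are retained and training stops after 10
epochs without improvement. All randomness (initialization, shuffling,
dropout) derives from one seed; identical seed and data give bit-identical
weights. Layers use He-scaled initialization. The implementation is a
compact native one — convolutions are expressed as im2col gathers through a
precomputed sparse matrix, so forward and backward passes are dense matrix
products, fast enough on one CPU at this input size.

**Transfer learning.** `transfer_detector()` reuses a trained model on a
new dataset (different recorder, sites, or years): by default all
convolutional layers are frozen (their weights are bit-identical before and
after, a tested contract) and the dense head is retrained on 5% of the new
files with 15% for validation, at a third of the original learning rate;
the remaining 80% stays untouched for testing. The normalizer is refit on
the 5% training fraction — normalization statistics are training artifacts,
and a recorder gain shift would otherwise saturate the inputs. Which layers
to freeze and the retraining rate are exposed because the right choice is
validation-set-dependent. Controlled simulations in the test suite show
what transfer does and does not buy: under a +10 dB recorder sensitivity
shift the unadapted model collapses (near-constant positive output), and
transfer restores F1 and accuracy while keeping recall high; under milder
shifts transfer can trade recall for precision — the same trade-off the
original study observed on its commercial-recorder dataset.

## Evaluation

`compute_metrics()` reports confusion counts with accuracy, precision,
recall and F1 by their standard definitions. Degenerate denominators are
flagged rather than silently scored: with no predicted positives, precision
is NA-with-flag and F1 is 0 (reporting 1.0 would flatter exactly the
failure mode that matters here). Cohen's kappa (`cohen_kappa()`) implements
the chance-corrected agreement used for inter-observer reliability; it is
checked against a hand-computed contingency oracle and a Monte-Carlo null
in the tests.

`cross_validate()` runs file-grouped, label-stratified k-fold
cross-validation (default k = 10; folds differ by at most one file per
class). Everything that can leak — normalizer fit, augmentation, early
stopping's validation split — happens inside each fold's training portion.
Duplicated file ids are rejected outright. Per-fold metrics are summarised
as mean ± sample SD.

`compare_paired()` compares a metric across two paired configurations
(e.g. the same folds with and without augmentation): a Shapiro–Wilk test on
the *paired differences* — the quantity whose normality the paired t-test
actually assumes — gates at α = 0.05 (a package default) between the paired
t-test and the Wilcoxon signed-rank test. Wilcoxon uses R's `stats`
implementation (zero-discard, exact distribution for small samples without
ties, normal approximation otherwise). All-zero differences are reported as
"no difference" without running a test, and constant nonzero differences
take the Wilcoxon branch since their normality statistic is degenerate.

## Activity patterns

Detections aggregate into a diel distribution over 48 30-min bins (bin =
⌊(hour·60+min)/30⌋, matching the recording schedule; every start time maps
to exactly one bin) and a seasonal distribution over 52 weeks (week =
min(⌊(day-of-year − 1)/7⌋, 51), so day 365/366 clamps into week 51). The
reported "probability" is the per-bin positive rate — positives divided by
recordings in the bin — not a density over bins; that is why sparsely
sampled weeks need an exclusion rule: a week with fewer than 250 recordings
(~40 h) is flagged unsampled and its recordings are dropped from the
computation. The threshold is exposed (`min_recordings`) so small synthetic
runs can scale it, with 250 as the fielded default, applied to whatever
table is passed in (per fold test set when called per fold).
`aggregate_folds()` combines per-fold distributions into per-bin means and
sample SDs, reporting a bin excluded if any fold excluded it along with the
count of contributing folds. Diel bins are clock-time bins; no
sunrise-anchored re-alignment is attempted (at the latitude of the
reference site, sunrise time moves little through the year).

## The soundscape simulator

`sim_config()` + `generate_dataset()` emulate the study conditions so the
pipeline can be exercised without the undeposited field data: 600-s
recordings at 48 kHz, 48 per site-day on :00/:30 boundaries; song durations
N(88.61, 39.51²) s; songs made of descending phrases (2–5 harmonic-stack
notes, follower fundamentals strictly decreasing inside 500–2,000 Hz by
default); pink (1/f) background noise; occurrence driven by a diel profile
peaking in the hours around sunrise and a seasonal profile peaking in the
austral warm season, scaled so the overall positive rate is roughly 10%,
near the labelled fractions of the reference campaign.

Simulator-specific design decisions:

* **Duration truncation.** Draws are clamped (winsorised) to [10, 240] s.
  Clamping rather than redrawing keeps the realized mean within sampling
  error of 88.61 s — rejection-truncation at these bounds would inflate it
  by ~2.2 s because the lower tail holds far more mass than the upper.
* **Note-level timing** (1.5–4 s notes, 0.2–1 s gaps within phrases,
  0.5–2 s between phrases) is invented: values are chosen so a 20-s
  interval nearly always contains at least one full note.
* **Pink noise** is generated by a three-pole filter cascade; it has
  roughly equal energy per third-octave band, which exercises the per-band
  normalizer realistically and is a reasonable stand-in for forest
  ambience. Songs mix in at `snr_db` (overall RMS ratio, default 10 dB).
* **Fast mode** draws the 30×18 matrices directly in feature space. Its
  injection levels are calibrated to what `extract_features()` measures on
  audio-mode recordings: because the song concentrates power into one or
  two third-octave bands while pink noise spreads over ~10× more, the
  f0-band bump is `snr_db` plus a ~10 dB spectral-concentration gain,
  spread over 2–3 adjacent bands as phrases descend, with first harmonics
  ~6 dB down three band indices up, scaled by overlap fraction in edge
  intervals. Fast and audio mode share the labelling criterion (label 1
  iff ≥ 1 song overlaps the window).
* **Independence.** Song events are placed independently given the
  profiles. Real indri choruses trigger answers from neighbouring groups,
  so real positives cluster in time; the simulator does not reproduce
  that, nor formant structure, group overlap, or propagation effects. A
  detector that passes on synthetic data has demonstrated that the
  pipeline's plumbing, balancing, and statistics are sound — not that the
  learned features transfer to real rainforest recordings.
* All randomness flows from `cfg$seed`: identical configuration gives
  byte-identical datasets.

## Problem sizes used by the tests

The test and verification runs use deliberately small instances chosen to
demonstrate each property at desk scale: the headline synthetic experiment
uses 1,008 feature matrices (21 days × 48 slots, one site; 10% positive
before balancing, SNR 10 dB, default detector, ≤ 50 epochs, 70/20/10 file
split); activity-pattern recovery uses a full simulated year (17,520
recordings, labels only); transfer experiments use 240-recording domains
with 5 seeds; the paired-comparison power check uses 500 replicates at
k = 10. `scripts/acceptance.R` re-runs the headline experiment from scratch
and writes held-out accuracy and recall as percentages.

## Known limitations

* The native network trains on one CPU at the 30×18 scale it was designed
  for; it is not a general-purpose deep-learning stack and has no GPU path.
* Recorder local time is the time basis everywhere; no timezone or DST
  arithmetic is applied. Deployments spanning a DST boundary would need
  their timestamps normalised upstream.
* The synthetic benchmark is easier than the field task (clean phrase
  structure, no chorus overlap, no rain bursts by default); reported
  synthetic metrics bound the plumbing, not field performance.
* `decision_threshold` defaults to 0.5; a deployment prioritising recall —
  as a pre-screening workflow does — should lower it and accept more false
  positives for later manual review.
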
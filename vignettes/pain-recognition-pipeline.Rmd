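---
title: "Comparing EDA feature extractors for heat-pain recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing EDA feature extractors for heat-pain recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(painfex)
```

## The problem

Electrodermal activity (EDA) is the most pain-responsive single channel in
physiological pain recognition: a slowly varying skin conductance level
(SCL, the *tonic* component) carries fast, spike-shaped skin conductance
responses (SCRs, the *phasic* component) evoked by noxious stimuli.
Automated pain recognition pipelines differ mainly in how they turn an EDA
window into a feature vector; everything else — windowing, normalisation,
the classifier, the validation scheme — can be held fixed so that feature
extractors are compared on equal footing. `painfex` implements exactly that
fixed harness:

1. a **simulator** of two thermode study protocols with objective
   (stimulus temperature) and subjective (CoVAS slider) labels,
2. a **preprocessing** stage (resampling to a common 256 Hz rate,
   stimulus-aligned windows, per-window min-max normalisation, label
   construction),
3. two families of **feature extractors** — a 38-dimensional hand-crafted
   vector, and four small neural networks truncated to their feature
   layers — behind one pluggable interface, and
4. a fixed **evaluation** stage: a 100-tree random forest in repeated
   leave-one-subject-out (LOSO) cross-validation scored with accuracy and
   macro-F1, plus paired t-tests between methods.

## The simulated study protocols

Each subject is calibrated by a pain threshold `TP` and a pain tolerance
threshold `TT` (°C). With `R = (TT - TP)/4`, the continuous-recording
protocol ("pmdb") stimulates at a non-painful level `NP = TP - R` and four
painful levels `Pi = TP + i·R` (so `P4 = TT`), eight 10-s stimuli per
level with 20–30 s rest between them, while the subject rates pain
continuously on a 0–100 CoVAS slider. The pre-windowed-style protocol
("bvdb") uses a 32 °C baseline level `T0` plus `Ti = TP + (i-1)·R`, twenty
4-s stimuli per level with 8–12 s pauses. Note the deliberate asymmetry,
taken from the printed level formulas: in the second scheme the highest
applied temperature is `TP + 3R`, below `TT`; in the first it is `TT`
itself. Calibration itself (the staircase procedure) is not simulated —
downstream stages consume only `TP` and `TT`, so profiles draw
`TP ~ U(40, 46)` and `TT = TP + U(2, 4)` capped at 49 °C. Whether the
non-painful level is stimulated the same number of times as the painful
ones is ambiguous in the field's protocol descriptions; the simulator
includes `NP` at the full repetition count, since the baseline-vs-NP task
requires NP windows.

The EDA channel is

    signal(t) = tonic(t) + sum over painful events of A_e · h(t - onset_e - latency) + noise

* `tonic(t)`: the subject's conductance level plus slow sinusoidal drift
  (components at 0.010 and 0.023 Hz, i.e. strictly below the 0.05 Hz
  tonic/phasic split), amplitude 8% of the level.
* `h`: a bi-exponential SCR kernel, `exp(-t/6) - exp(-t/0.7)` (seconds),
  peaking about 1.7 s after response onset — the canonical "fast rise,
  slow recovery" SCR shape. The tail is taken smoothly to zero by 18 s
  (raised-cosine taper from 12 s). Full recovery matters: the protocol
  guarantees at least ~18.5 s between a response onset and the earliest
  sample of any later window, so a truncated-but-smooth kernel prevents
  decay tails from leaking systematic intensity information into
  nominally neutral baseline windows — leakage real skin does not exhibit
  at these inter-stimulus intervals.
* `A_e = scr_gain · g(level) · habituation^repetition · jitter_e` with
  `g = 0` for baseline and non-painful levels and `g = i/4` for the i-th
  painful level; `jitter_e` is a per-event lognormal factor
  (`amplitude_jitter_sd`, default 0.15) representing trial-to-trial
  variability in perceived intensity.
* The CoVAS trace is built from the **same** `g(level) · habituation ·
  jitter_e` quantity: after a 1 s reaction lag it ramps (2 s) to a plateau
  of `100 · covas_gain · percept`, holds, and falls back (3 s) after
  stimulus offset; it is exactly zero elsewhere and clipped to [0, 100].
  Sharing the per-event perceived intensity between the physiology and
  the rating is what gives subjective labels their advantage: they encode
  the trial's actual response magnitude, which the temperature label
  cannot.

Two presets fix the study conditions: `default`
(`scr_gain 0.6`, `noise_sd 0.02`, `habituation 0.98`, jitter 0.15) for
realistic variability, and `clean` (`scr_gain 1`, `noise_sd 0.005`, no
habituation, jitter 0.05) for parameter-recovery checks where the effect
should be unambiguous. What the simulator does **not** emulate: motion and
pressure artefacts, electrode drift or detachment, spontaneous
(non-stimulus-locked) SCRs, sensor-site repositioning mid-session, and
any channel other than EDA, temperature and CoVAS. Passing tests on this
data therefore show that the pipeline recovers a stimulus-locked
electrodermal effect under controlled conditions — not that it reaches any
particular accuracy on real recordings.

## Preprocessing and labels

All channels are linearly interpolated onto a uniform 256 Hz grid. In the
continuous protocol each stimulus yields one window covering the full 10-s
stimulus, labelled with its level, plus the 10-s window immediately
preceding the onset labelled `B`; in the pre-windowed protocol each event
yields one 5.5-s window starting 3 s after onset (taken literally from the
published geometry, although it extends past the 4-s stimulus). Windows
are normalised per channel to [0, 1] by min-max; a constant channel maps
to zeros (the bounded-output choice that avoids division by zero). Windows
that would leave the recording are dropped with a warning rather than
zero-padded — padding would distort both the min-max scale and SCR
statistics. Window indices follow a half-open `[start, end)` convention
with `start_idx = round(start_s × fs)`.

Subjective labels: the CoVAS samples inside each window are summed, sums
are scaled by the subject's maximum segment sum, and the scaled value is
binned as `C0` for exactly 0 and `C1`–`C4` for the quarter intervals
`]0, 0.25]` … `]0.75, 1]`. Sums are computed on the common 256 Hz grid;
the per-subject scaling makes the labels invariant to both the sampling
rate and any positive rescaling of a subject's ratings.

## Hand-crafted features

Each normalised window is decomposed by a zero-phase (forward-backward)
second-order Butterworth filter with a 0.05 Hz cutoff — low-pass output =
tonic, complement = phasic. The cutoff is read in Hz: a normalised cutoff
of 0.05 at 256 Hz would be 6.4 Hz, far above tonic dynamics. Because two
passes square the magnitude response, the implementation is validated
against the closed form `|H(f)|² = 1/(1 + (f/0.05)⁴)` on test sinusoids.
Each filter pass is seeded with its steady state for the signal's edge
value and the signal is extended by short odd reflections; with a cutoff
this far below the window length, naive zero-state filtering would
otherwise produce transients larger than the signal itself.

SCRs are detected on the phasic component: an event opens where the
signal rises through 0.01, peaks at the maximum of the supra-threshold
excursion, and is kept only if the peak exceeds the onset value by 0.05
(both thresholds in normalised-window units, since normalisation precedes
feature extraction; the onset threshold is applied to the phasic *value*,
not its derivative). Offset is the fall back through the onset level,
half-recovery the first drop below onset + amplitude/2 after the peak.

The 38-dimensional feature vector combines global signal statistics,
tonic/phasic summaries, SCR-event statistics (zero when no SCR is
detected) and an auxiliary block (max, min, median, IQR, least-squares
slope, area under the curve). The exact composition of the classical
38-item list is not fully published; the auxiliary block is this
package's documented reconstruction to the stated dimensionality, and
every feature carries a name so downstream analyses are auditable.
"Variation of the first and second moment" is implemented as the
coefficient of variation of the signal and of its squares; "recovery
range of tonic" as `tonic(offset) − tonic(onset)` per SCR. Local extrema
use strict 3-point comparison. More elaborate extractors (convex-optimis-
ation decompositions, spectral sympathetic-activity indices) are out of
scope, but the registry (`register_feature_extractor()`) accepts any
extractor under the same contract, and `hcf_combined` concatenates all
registered hand-crafted extractors.

## Learned features

Four small networks are trained per LOSO fold and truncated to feature
extractors: an MLP (Dense 250 → Dense 100 → softmax, dropout 0.1), a CNN
(two blocks of 16 kernels, size 7, stride 2, ReLU, max-pool 4, dropout),
a ConvLSTM (three blocks of 32/16/8 kernels, sizes 11/7/3, strides 8/8/2,
tanh/hard-sigmoid, batch-norm, pooling; the window is split into 4 equal
sub-segments forming the recurrence axis) and a convolutional autoencoder
(encoder 64/32/16 kernels with pools of 4; mirrored decoder; trained
unsupervised with MSE). Classifier features come from the penultimate
100-unit dense layer; autoencoder features from the flattened encoder
bottleneck (640 values for 10-s windows, 352 for 5.5-s windows).

The networks run on a purpose-built engine in this package (base R with
BLAS matrix products; the convolution im2col/col2im and pooling inner
loops in compiled code), with Adam (learning rate 1e-4), batch size 8 and
50 training epochs as protocol defaults. Design points where the
published tables are silent: convolutions use same padding throughout (so
the autoencoder's pool/upsample chain restores the input length exactly —
2560 = 4³·40 and 1408 = 4³·22); pooling after ConvLSTM blocks acts on the
within-segment temporal axis only with ceil semantics (a pool of 4 on all
axes would annihilate the singleton sensor axis); ConvLSTM blocks 2–3
reuse the first block's tanh activation; weight initialisation is
Glorot-uniform; dropout and batch statistics are active only during
training, and extractors always run in inference mode. All randomness
(initialisation, shuffling, dropout) is routed through one seed, so
training histories are bit-reproducible; the 5× evaluation repetitions
use seeds `base_seed + r`. No early stopping is used — training runs a
fixed epoch budget.

The autoencoder is pretrained per fold on a subsample of at most 64
training segments. Reconstruction pretraining needs no labels and its
features stabilise quickly; the cap keeps per-fold training costs
proportionate to the other extractors at the study sizes this package
targets.

## Evaluation

`make_binary_task()` builds no-pain-vs-pain problems (`B` vs `NP`/`P1`–`P4`
by temperature, `C0` vs `C1`–`C4` by rating) and balances the two classes
within every subject by subsampling the majority class (seeded). Balance
matters: continuous-protocol segmentation yields one baseline window per
stimulus, so the baseline class outnumbers each stimulus class five to
one, and an unbalanced task would score ~83% by majority vote alone —
incompatible with chance-level behaviour on uninformative tasks and with
the reported accuracy ranges this harness mirrors.

`loso_evaluate()` runs the LOSO loop `n_runs` times (default 5): each
subject is the test set once per run, a 100-tree random forest (other
hyperparameters at library defaults) is fitted on the remaining subjects
and scored on the held-out subject with accuracy and macro-F1 (per-class
one-vs-rest F1, averaged; metrics with zero denominators are 0).
Learned extractors are refitted inside every fold on training subjects
only — anything else would leak test subjects into feature learning — and
fold hygiene is asserted at runtime. Aggregates follow the convention of
reporting the mean over subjects per run, averaged over runs, with the
per-run standard deviation over subjects averaged over runs as the
spread. Method pairs are compared by a two-sided paired t-test on
per-subject accuracies averaged over runs (direction reported; zero-
variance differences handled explicitly; no multiple-testing correction
across the method grid, matching per-pair 5% reporting).

## Problem sizes

The package's reference experiment simulates 12 subjects under the
`clean` preset: 960 windows, 5 binary temperature tasks and the
subjective-label tasks, 5 LOSO repetitions for the hand-crafted
extractor, and single-repetition, 10-epoch runs for the learned
extractors. These sizes exercise every stage — including per-fold network
retraining — while a full comparison remains a single-command run
(`run_experiment()` or `scripts/acceptance.R`). The protocol constants
(256 Hz, 100 trees, batch 8, learning rate 1e-4, 50 epochs) are the
defaults throughout.

## Known limitations

* The simulator's effect is, by construction, recoverable; results on it
  bound nothing about real recordings.
* Only the EDA channel is simulated and classified; the multi-channel
  fusion questions (wrist vs finger sensors, early fusion) are out of
  scope.
* The reconstruction of the 38-feature list and the auxiliary block is
  this package's own; numerical values of individual features need not
  match any other implementation, though dimensionality and naming are
  fixed.
* Multi-class classification, regression on the continuous traces, and
  per-subject personalisation are deliberately not implemented.
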
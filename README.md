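# painfex

Fair comparison of feature extraction methods for heat-pain recognition
from electrodermal activity (EDA).

## The problem

Automated pain recognition trains classifiers on physiological signals
recorded during calibrated thermode stimulation. The EDA channel — a slow
skin conductance level (SCL) carrying fast, stimulus-evoked skin
conductance responses (SCRs) — is the most informative single channel, and
the open methodological question is how best to turn an EDA window into a
feature vector: expert-defined hand-crafted features (HCF), or
representations learned by neural networks. Published comparisons are hard
to interpret when every method also brings its own preprocessing,
windowing and classifier.

`painfex` holds the rest of the pattern recognition chain fixed so only
the feature extractor varies:

* **Simulation** of two thermode study protocols, driven by per-subject
  calibration thresholds `TP` (pain threshold) and `TT` (pain tolerance):
  a continuous 10-s-stimulus protocol with a non-painful level
  `NP = TP − R` and painful levels `Pᵢ = TP + i·R` (`R = (TT−TP)/4`) plus
  a continuous 0–100 CoVAS rating channel, and a pre-windowed-style
  protocol with baseline `T0 = 32 °C` and levels `Tᵢ = TP + (i−1)·R`.
  Stimulus-locked bi-exponential SCRs grow with level, habituate across
  repetitions, and share their per-trial perceived intensity with the
  simulated rating trace.
* **Preprocessing**: linear resampling to 256 Hz, stimulus-aligned
  windows (10 s / 2560 samples, or 5.5 s / 1408 samples with a 3-s onset
  delay), per-window min-max normalisation, objective temperature labels
  and subjective CoVAS classes `C0`–`C4` from per-subject-scaled rating
  sums binned over `]0,0.25], ]0.25,0.5], ]0.5,0.75], ]0.75,1]`.
* **Feature extraction** behind one registry interface: a named
  38-dimensional hand-crafted vector built on a zero-phase second-order
  Butterworth tonic/phasic split at 0.05 Hz and threshold-based SCR
  detection (onset 0.01, peak amplitude 0.05); and four truncated
  networks — MLP, CNN, ConvLSTM and a convolutional autoencoder — trained
  by the package's own engine (Adam, categorical cross-entropy or MSE)
  and cut back to their feature layers.
* **Evaluation**: a 100-tree random forest in repeated
  leave-one-subject-out (LOSO) cross-validation, accuracy and macro-F1
  aggregated as mean over subjects per run averaged over runs, and paired
  t-tests between methods on per-subject accuracies.

## Worked example

```r
library(painfex)

ds  <- generate_dataset(n_subjects = 6, scheme = "pmdb",
                        master_seed = 7, preset = "clean")
seg <- segment_dataset(ds)
seg
#> <pain_segments> 480 windows of 2560 samples x 1 channel(s) at 256 Hz (pmdb)
#>
#>   B  NP  P1  P2  P3  P4
#> 240  48  48  48  48  48

res <- loso_evaluate(make_binary_task(seg, "B", "P4"),
                     extractor = "hcf", n_runs = 2, base_seed = 7)
res
#> <pain_loso> 6 subjects x 2 run(s), 100-tree random forest
#>   accuracy: 100.00% +/- 0.00   macro-F1: 100.00% +/- 0.00

np <- loso_evaluate(make_binary_task(seg, "B", "NP"),
                    extractor = "hcf", n_runs = 2, base_seed = 7)
np
#> <pain_loso> 6 subjects x 2 run(s), 100-tree random forest
#>   accuracy: 50.52% +/- 5.63   macro-F1: 49.90% +/- 5.79

paired_method_test(subject_accuracies(res), subject_accuracies(np))
#> Paired t-test: t = 24.208 (df 5), p = 2.242e-06, mean diff +0.4948 (significant)
```

Each of the six simulated subjects contributes 40 stimulus windows and 40
preceding baseline windows. Distinguishing baseline from the strongest
stimulus is essentially solved (100% LOSO accuracy under the clean-effect
preset), while baseline vs the non-painful level sits at chance (50.5%):
the non-painful stimulus evokes no electrodermal response, so there is
nothing to find — the paired test confirms the two tasks differ. Swapping
`extractor = "hcf"` for `"mlp"`, `"cnn"`, `"convlstm"` or `"cae"`
retrains that network inside every fold before classification;
`run_experiment(experiment_config(...))` scripts the whole grid and
writes tidy CSV results. A thin command-line front end is installed at
`inst/scripts/painfex.R` (subcommands `simulate`, `features`, `run-all`).

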
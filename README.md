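# semgbench

Benchmarking of segmentation, feature extraction, and classification for
surface-electromyography (sEMG) gesture recognition with an 8-channel
armband.

## The problem

Wearable armbands (8 dry electrodes, 200 samples/s, 8-bit) can recognize
manual-alphabet gestures — e.g. the 26 letters of a sign-language
alphabet (20 static, 6 dynamic) — from muscle activity alone. The
recognition accuracy, however, depends heavily on three processing
choices made before any model sees the data:

1. **Segmentation.** Activations are detected on the channel-summed
   energy with a double threshold (amplitude threshold = 10% of the
   per-trial maximum energy, duration threshold = 150 ms), then cut into
   windows of length *W* with step *k*. The overlap fraction

   *φ = k / W*

   controls window density: φ = 1 tiles the activation disjointly
   ("disruptive" windows), φ = 0.125 steps by an eighth of a window.
2. **Features.** A bank of 33 canonical sEMG features (24 time-domain:
   MAV, RMS, WL, ZC, SSC, WAMP, sample entropy, 4th-order AR and
   cepstral coefficients, 9-bin histogram, L-scale, maximum fractal
   length, ...; 9 frequency-domain on a 2000-point spectrum: MNF, MDF,
   PKF, MNP, TTP, SM1–3, frequency ratio), extracted per channel and
   concatenated.
3. **Classifier.** Nine standard models with fixed parameterizations
   (1-NN, LDA, QDA, Gaussian naive Bayes, a 30-unit MLP, a 30-tree
   random forest, a 1000-unit extreme learning machine, and linear/RBF
   SVMs), evaluated with 10-fold cross-validation under pooled,
   per-subject, and trial-grouped schemes.

`semgbench` implements this whole chain as composable R functions, plus
a four-stage pipeline that (1) ranks the 33 features individually and
selects the above-mean classifiers, (2) compares literature feature sets
G1–G5 with data-derived sets G6–G9 by a Friedman test with Tukey-style
post-hoc on ranks, (3) sweeps the (W, φ) grid and picks the smallest
parameters statistically tied with the best via Nemenyi
critical-distance analysis, and (4) validates per subject and per
acquisition trial with confusion-matrix reports.

Because no public dataset accompanies the protocol, the package ships a
synthetic generator that emulates the acquisition: cued trials at 45 bpm
(1.3 s gesture / 1.3 s rest), 26 classes x 20 trials x 12 subjects,
gesture-specific per-channel gain maps on band-limited Gaussian noise,
a 1% rest-noise floor, and dials for SNR, inter-subject variability, and
class separability.

## Worked example

```r
library(semgbench)

# a small protocol: 2 subjects, 6 trials, all 26 classes
recs <- generate_dataset(synth_config(n_subjects = 2, n_trials = 6, seed = 1))

# segment at W = 1 s with disjoint windows, extract the reduced set G9
segs <- combine_segments(lapply(recs, segment_recording,
                                W = 1, phi = 1, cfg = run_config()))
tab  <- extract_table(segs, resolve_set("G9")$members)

# 10-fold pooled cross-validation of the 30-tree random forest
ev <- evaluate_cv(tab, "RF", folds = 10, seed = 1)
ev
#> <semg_eval> RF, pooled 10-fold: overall accuracy 0.9968 (26 classes, 312 predictions)

# how much does window overlap help at short windows?
segs8 <- combine_segments(lapply(recs, segment_recording,
                                 W = 0.25, phi = 0.125, cfg = run_config()))
tab8  <- extract_table(segs8, resolve_set("G9")$members)
evaluate_cv(tab8, "ELM", folds = 5, seed = 1)$accuracy   # phi = 0.125
#> [1] 0.9977413
evaluate_cv(extract_table(combine_segments(lapply(recs, segment_recording,
    W = 0.25, phi = 1, cfg = run_config())), resolve_set("G9")$members),
    "ELM", folds = 5, seed = 1)$accuracy                 # phi = 1
#> [1] 0.5977564
```

The first run shows the near-ceiling accuracy of the reduced
4-feature set (MFL, MNP, TTP, RMS) with a random forest on separable
synthetic data. The second pair isolates the overlap effect: at a
0.25 s window, stepping by an eighth of a window multiplies the
training instances roughly sevenfold and lifts the extreme learning
machine from 60% to 99.8%.

The full four-stage methodology runs as one call:

```r
res <- run_pipeline(recs, run_config(cv_folds = 5,
                    classifiers = c("KNN", "LDA", "RF")), out_dir = "artifacts")
res$summary
```

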
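---
title: "Methods: segmentation, features, and classifiers for armband sEMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, features, and classifiers for armband sEMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`semgbench` studies how the early processing choices of an sEMG gesture
recognizer — onset detection, window length, window overlap, feature
bank, feature-set reduction, classifier — shape recognition accuracy.
This vignette documents the models and conventions behind each stage,
the tunable parameters, the design decisions taken where the design was
genuinely open, and what the synthetic benchmark can and cannot show.

## The signal model

All amplitudes live on a normalized full scale of $[-1, 1]$; an 8-bit
armband sample is mapped to this range at ingest. This convention is a
package decision, not a device fact: the amplitude thresholds of the
feature bank ($10^{-2}$ for zero crossing, Willison amplitude, and
myopulse rate; $10^{-4}$ for slope-sign change) are only meaningful on
a fixed scale. Time is in seconds, intervals are half-open
$[t_\mathrm{start}, t_\mathrm{end})$, and sample index
$= \lfloor t \cdot f_s \rfloor$ with $f_s = 200$ samples/s by default.

## The synthetic acquisition protocol

`synth_config()` / `generate_dataset()` emulate a cued acquisition: in
each trial the subject performs every one of 26 alphabet gestures at a
45 bpm cadence — 1.3 s of gesture alternating with 1.3 s of rest — so a
trial lasts $26 \times 2 \times 1.3 = 67.6$ s and carries 52
annotations. Twelve subjects repeat the sequence 20 times. Defaults
follow that protocol; every count and level is a parameter.

The activation model is amplitude-modulated band-limited Gaussian noise,
the standard stochastic surrogate for interference-pattern sEMG (no
motor-unit simulation):

* each class has an 8-channel **gain map** drawn uniformly from
  $[0.2, 1]$ and resampled until all pairwise Euclidean distances exceed
  `min_separation` (default 0.3 — large enough that the default
  benchmark is clearly separable, small enough that short windows leave
  visible confusion);
* six classes are **dynamic**: their gain map drifts toward a
  channel-rotated copy across the gesture, mimicking movement;
* the per-gesture **envelope** rises over 10% of the cue, holds for
  80%, falls over 10%. The fast rise mirrors ballistic gesture onsets
  and keeps the energy detector's latency small relative to the cue, so
  detected activations cover $\ge$ 80% of their annotation and the
  detector is testable against known ground truth;
* the carrier noise is Butterworth band-passed to 20–90 Hz (4th order,
  zero-phase), inside the 100 Hz Nyquist limit of the device rate;
* a white **rest floor** of 1% full scale underlies everything, so the
  10% energy threshold separates activations cleanly;
* `snr_db` fixes the ratio of total mean power inside active intervals
  to the floor power (default 20 dB). At 0 dB the activation component
  vanishes by construction — active intervals equal the floor;
* `subject_jitter` perturbs each subject's channel gains once,
  multiplicatively (default 0: identical subjects).

What this generator does **not** emulate: electrode shift, fatigue,
crosstalk structure, non-stationary rest noise, and the heavy-tailed
amplitude statistics of real sEMG. Passing benchmarks here demonstrates
that the pipeline's machinery is correct and that its comparative
statements (overlap helps, amplitude features dominate, reduction keeps
accuracy) hold on controlled data — not that any accuracy level will
transfer to real recordings.

## Segmentation

`compute_energy()` sums squared amplitudes over channels and smooths
with a centered 50 ms moving average (edge-truncated). The smoothing
length is a package default: some smoothing is required for stable
threshold crossings on stochastic signals, and 10 samples is short
relative to the 150 ms duration threshold.

`detect_activations()` realizes the double threshold as one amplitude
threshold plus one duration threshold: the amplitude threshold is 10%
of the trial's maximum smoothed energy; a candidate onset is confirmed
only after the energy holds above threshold for 150 ms, an offset only
after it holds below for 150 ms (shorter dips are bridged), and bursts
shorter than 150 ms are rejected as false triggers.

`slide_windows()` anchors windows at the detected onset — the
real-time-relevant choice, since an online recognizer sees data only
from the onset forward — and steps by $k = \varphi W$ samples
($\varphi$ = overlap fraction; $\varphi = 1$ is the disjoint
"disruptive" window). Activations shorter than $W$ are **discarded,
not padded** (padding would fabricate signal); the discard log makes
the window-length-versus-data-loss trade-off measurable. Each
activation is labeled by the annotation with the largest temporal
overlap, earliest annotation winning ties (to within $10^{-9}$ s, so
floating-point jitter in cue times cannot flip the tie-break).

## The feature bank

The 33 features follow the canonical sEMG definitions; the exact
formula ledger is in `?extract_time` and the source. Non-obvious
conventions, all exposed as parameters:

* **MAV1/MAV2** use the standard piecewise weights (0.5 outside the
  central 50%; a continuous $4i/n$ ramp for MAV2).
* **LOGDEC** floors $|x_i|$ at $10^{-12}$ before the log.
* **HIST** uses 9 equal bins over $[\min x, \max x]$; a degenerate
  range puts all counts in the first bin.
* **L-scale** is the second sample L-moment via the order-statistics
  estimator $2b_1 - b_0$ (tested against half the Gini mean
  difference).
* **SSC** uses the slope threshold $10^{-4}$ (the per-feature table
  value), not the $10^{-2}$ amplitude threshold of the other three
  count features.
* **AR4** uses the Burg method (stable on short windows; Yule–Walker
  behind a flag); **CEPS** applies the standard AR-to-cepstrum
  recursion to the prediction-polynomial coefficients.
* **Sample entropy** ($m = 2$, $r = 0.2\,\sigma$, Chebyshev distance,
  self-matches excluded) is defined as 0 for constant windows and
  returns the largest attainable finite value $\ln\binom{n-m}{2}$ when
  no template pairs match, with a message, instead of failing.
* Spectra are one-sided periodograms of the 2000-point zero-padded
  transform — no detrending, no taper. Band sums (frequency ratio:
  10–50 Hz over 51–100 Hz) use inclusive grid membership.

Features are extracted per channel and concatenated (the standard
armband treatment), giving $47 \times 8 = 376$ columns for the full
bank (30 scalar features, plus 9 histogram, 4 AR, and 4 cepstral
components). Column order is fixed: registry order, channels contiguous
per component.

## Classifiers and validation

The nine specifications are fixed: 1-NN; LDA; QDA; Gaussian naive
Bayes; MLP with 30 hidden units; random forest with 30 trees; ELM with
1000 random tanh units and a ridge-regularized least-squares readout
(ridge $10^{-6}$, a package choice for numerical stability); linear SVM
with $C = 100$; RBF SVM with $C = 10$ and kernel scale $s = 1$ read as
$\exp(-\lVert u - v\rVert^2 / 2s^2)$, i.e. $\gamma = 0.5$. The ELM is
implemented directly (it is not a standard library model); the MLP
stands on `nnet` and therefore uses a logistic rather than hyperbolic
hidden activation — the same representational class, and a deliberate
trade against hand-rolling a network trainer.

Feature columns are z-scored with statistics fitted on the training
rows of each fold only — required for the distance- and kernel-based
models, and never allowed to leak test statistics.

Three validation schemes coexist because they answer different
questions. **Pooled** stratified k-fold ignores subject and trial
structure; with overlapping windows it is optimistic, since windows of
one activation can straddle the train/test split — this is kept
deliberately, as the optimistic pooled setting is part of what the
benchmark studies. **Per-subject** runs an independent k-fold inside
each subject (the calibration scenario). **Trial-grouped** assigns
whole acquisition trials to folds (trial $j$ to fold
$(j-1) \bmod k + 1$), so no trial is ever split — the leakage-safe
scheme; accuracies are reported per subject. A training fold that
degenerates to a single class yields a constant classifier with a
warning rather than an error.

## Feature-set construction and reduction

G1–G5 are literature sets (the Hudgins quartet; AR4 + histogram; the
two most-repeated features; TD4; TD9 — whose "MSF" and "IAV" members
are read as MSR and IEMG, the only consistent reading of that lineage).
G6 collects the features whose individual mean accuracy exceeds the
grand mean of the feature-by-classifier table; G7/G8 are its time- and
frequency-domain subsets; G9 is the greedy reduction of G6: add
features in rank order and stop at the smallest prefix whose per-fold
accuracy distribution is statistically indistinguishable (Friedman plus
Tukey HSD on within-block ranks, $\alpha = 0.05$) from every larger
prefix. The registry stores the reference defaults
(G9 = MFL, MNP, TTP, RMS); pipeline runs rebuild all four from data.
The "best classifiers" filter is likewise derived — classifiers above
the grand mean — never hard-coded.

## The statistical layer

The Friedman statistic is computed by direct rank arithmetic with
mid-ranks and the standard tie correction (fully tied blocks give
statistic 0, $p = 1$, by convention), and is cross-checked in the tests
against `stats::friedman.test`. Two post-hoc routes are exposed:
Tukey HSD applied to within-block ranks (a two-way rank ANOVA — the
common statistics-toolbox behavior), and the Nemenyi critical distance
$CD = q_\alpha \sqrt{g(g+1)/6b}$ for critical-distance diagrams, whose
connector lines are the maximal cliques of mutually non-significant
groups (ranks use 1 = best). Wilcoxon signed-rank and rank-sum tests
handle two-group comparisons; the degenerate all-differences-zero case
returns $p = 1$ flagged rather than erroring. $\alpha = 0.05$
throughout.

## Pipeline stage decisions

Stage 3 must turn "statistically tied with the best" into a single
$(W, \varphi)$. The rule codified here: choose the **smallest window**
in the clique containing the best-ranked window (shorter windows mean
lower recognition latency at equal evidence), then the **smallest
overlap fraction** in the clique containing the best-ranked fraction
(denser overlap is preferred when distributions tie, since it maximizes
training material; the cost is computation, not accuracy). Stage 2
prunes its top clique by dropping any set that is a strict superset of
another clique member — at equal evidence the smaller set wins, the
cheaper choice for embedded extraction. All stage randomness derives
from fixed offsets of one root seed.

## Problem sizes and numerical choices

The shipped tests and the acceptance script size their simulations for
a single CPU: the full default protocol (12 subjects x 20 trials x 26
classes, about 6,200 one-per-activation windows) backs the pooled
G9 + random-forest and label-permutation checks; the overlap-effect
comparison runs at a 0.25 s window on 2 subjects x 6 trials with
5-fold CV — the short-window regime is where overlap multiplies the
training set (roughly 28 versus 4 windows per activation) and where its
effect is visible, whereas at 1 s windows the default benchmark
saturates near 100% for all candidate classifiers and the comparison
degenerates to ties; the Friedman type-I calibration uses 1,000 null
matrices of 5 groups x 20 blocks. Brute-force oracles (direct DFT,
$O(n^2)$ sample entropy, exhaustive window enumeration, exhaustive
rank-sum permutation) verify every numerical kernel at small sizes.

## Known limitations

* Onset-anchored windows cannot reproduce protocols in which windows
  extended past the cue into rest; how the original acquisition handled
  windows longer than the 1.3 s cue is unspecified, and windows longer
  than a detected activation are discarded here.
* The exact energy formula behind the onset reference and the second
  threshold of the named "double threshold" technique are not printed
  anywhere authoritative; the 10%-of-maximum amplitude threshold plus
  150 ms duration threshold is the most common reading.
* Accuracy levels on the synthetic benchmark are not predictions for
  real sEMG; only the comparative structure is expected to transfer.
* Wall-clock feature-cost claims (e.g. a reduced set being faster) are
  hardware-dependent and are not asserted numerically anywhere.
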
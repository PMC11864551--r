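---
title: "Classifying behaviour from 1 Hz ear-tag accelerometers: methods and design"
author: "ethoaccel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying behaviour from 1 Hz ear-tag accelerometers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Commercial wildlife ear tags record triaxial acceleration at very low
sampling rates -- typically 1 Hz -- because battery life scales almost
linearly with sampling frequency, and recapturing wild animals to change
batteries is stressful and occasionally fatal. At 1 Hz the Nyquist limit is
0.5 Hz: the waveform of gaits and other rhythmic movements is invisible.
The question this package operationalises is whether behaviour can
nevertheless be classified from such data, and the answer it implements is
the window-statistics approach: the discriminative information at low
sampling rates lives in *static* distributional properties of the signal
(dispersion above all), not in its spectrum.

`ethoaccel` provides the full pipeline as a tested library plus a thin
command-line wrapper (`inst/cli/ethoaccel.R`): signal transforms →
overlapping windows with majority labels → moment and periodogram features
→ random-forest classification → per-class evaluation → window-size sweep,
together with a behaviour-labelled simulator so that every stage can be
exercised and audited without access to animal data.

## Signal model and transforms

A record is one sample per axis per second, in opaque sensor units (the
magnitudes behave like milli-*g*; nothing in the pipeline depends on the
unit). Timestamps are integer seconds; sub-second timestamps are truncated,
because both the acceleration stream and the behaviour labels are coded at
1 Hz and behaviours shorter than a second are unrepresentable. A
*contiguous segment* is a maximal run whose inter-sample gaps equal the
sampling period; every downstream stage respects segment boundaries.

**Jerk filter.** For a freely rotating ear tag the orientation of the axes
is arbitrary, so total acceleration mixes gravity into every axis
unpredictably. The jerk filter -- the per-axis first difference, scaled by
the sampling rate -- removes both orientation and gravity. The angle
between consecutive 3-D acceleration vectors (`dtheta`, degrees, computed
with `atan2(|a×b|, a·b)` for numerical stability, and defined as 0 when a
vector has zero norm) summarises directional change. A segment's jerk
series is one sample shorter than the segment; when jerk channels are
windowed together with raw channels, the first sample of each segment is
dropped from all channels so that every window is a rectangular table.
Whether the first difference should be scaled by the sampling rate is
convention; at 1 Hz the two conventions coincide, and the choice is exposed
as `scale_by_rate`.

**ODBA.** Overall dynamic body acceleration estimates the static
(gravitational) component per axis as a centred moving average over a 3 s
window and sums the absolute residuals across axes. The centred (not
trailing) average is standard practice; at segment edges the window
shrinks symmetrically rather than padding, which keeps ODBA exactly
translation-invariant everywhere. ODBA is computed and reported as a
movement-intensity summary, but it is *not* part of the default feature
set: it adds nothing beyond the per-axis dispersion statistics the
classifier already sees, and including it does not improve classification.

## Windows, majority labels, purity

Labelled series are cut into windows of `window_s` seconds with 50%
overlap by default (overlap is configurable; the implied step must be a
whole number of samples). Windows tile each contiguous recording segment
from its start; the terminal remainder shorter than the window is
discarded. Windows are anchored to recording segments, not to behaviour
bouts -- mixed windows are intended behaviour of the method, since in
deployment behaviours are not known a priori. Each window receives the
behaviour occupying the most seconds as its label, with ties broken by
earliest first occurrence (deterministic and order-stable; the choice of
tie-break is this package's, as none is forced by the method). The
fraction of seconds carrying the majority label is recorded as
`label_purity`, so users can study the contamination effect directly: the
walking/foraging confusion discussed below is largely a purity phenomenon.

## Features

Per window and channel (defaults: `x`, `y`, `z` raw plus `xj`, `yj`, `zj`
jerk; `dtheta` available behind a flag) the package computes 11 summary
statistics -- mean, median, SD, variance, skewness, kurtosis, minimum,
maximum, range, interquartile range, RMS -- plus the raw periodogram
ordinate at every nonzero Fourier frequency `k/W` up to the Nyquist
frequency, after mean-centring (no ordinate can exist above half the
sampling rate; at `W = 30` s and 1 Hz that is 15 ordinates per channel).
Decisions worth stating:

* The exact membership of the "11 statistics" is configurable
  (`stats_fun`); the default set numbers exactly 11, includes the classical
  moment statistics, and includes the IQR, which turns out to be the single
  most informative statistic class on both real and simulated data.
* Kurtosis is the raw (non-excess) fourth standardised moment; skewness
  and kurtosis of a zero-variance window are imputed as 0 so every feature
  is finite. Quartiles use linear interpolation between order statistics
  (type 7), the common default, checked in the tests against an
  independent sort-and-interpolate implementation.
* The periodogram is reported in full rather than as a top-k selection of
  "main" frequencies: which frequencies are main is data-dependent, the
  classifier can ignore uninformative ordinates, and the normalisation is
  fixed by Parseval's identity (ordinates sum to the centred sum of
  squares). A smoothed spectral estimate would also be defensible; the
  finding that spectral features carry almost no importance is robust to
  this choice.

Column naming is `<stat>_<channel>` and `pow<k>_<channel>`, so importance
rankings read directly as "IQR of the jerk-filtered z axis" and the like.

## Classifier and evaluation protocol

Windows are split at random into 50% training, 25% validation and 25%
test, redrawing (with an incremented seed, bounded retries) until every
class is present in all three subsets. The default classifier is a
probability random forest of 100 trees -- the only departure from the
library defaults -- run single-threaded with a fixed seed so the whole
train-to-predict path is bit-reproducible. Class imbalance is deliberately
left untreated; performance is judged with per-class balanced accuracy
instead. The validation subset is used only for logged metrics (there is
no early stopping in a forest); a single-hidden-layer softmax network
(`train_ann`) is provided for family comparison with its own documented
defaults and no accuracy claim. Variable importance is the forest's mean
decrease in impurity scaled so the top feature is 1.0; it answers the
qualitative question (which channels and statistic families matter), which
is the question the pipeline needs answered.

Evaluation follows the one-vs-rest definitions: sensitivity
`100·TP/(TP+FN)`, specificity `100·TN/(TN+FP)`, balanced accuracy their
mean, overall accuracy `100·trace/total` with an exact Clopper-Pearson 95%
CI, plus unweighted Cohen's kappa for observer agreement. Rows of the
confusion matrix are actual classes and columns predicted -- some popular
metric packages transpose this, so the test suite pins every metric to a
brute-force oracle computed directly from label pairs. A class that never
occurs has undefined (missing) sensitivity and is excluded from the mean
balanced accuracy with a warning; a class that occurs but is never
predicted contributes exactly 50, never 0. Metrics are exact cell-count
ratios; rounding (half away from zero) happens only at presentation.

The window-size sweep re-runs featurize/train/evaluate across window
lengths (6-60 s by default). So that sizes are compared on identical test
material, subset membership is decided once per 120 s time block and
shared across sizes; a window belongs to the subset of the block holding
its start second. (Windows straddling a block boundary make exact
second-level identity impossible; block assignment is the closest
well-defined construction.) Sizes leaving any class under 10 training
windows are skipped with a warning.

## The simulator

`simulate_scenario()` generates per-animal label-plus-acceleration streams
from behaviour profiles: a characteristic tag orientation with slow
angular wobble (an AR(1)/Ornstein-Uhlenbeck process with ~20 s correlation
time, continuous across bouts within an animal -- tags move continuously;
only true posture changes jump), gravity of magnitude 1000 sensor units, a
dynamic component, and additive measurement noise. Bout behaviours are
drawn i.i.d. with probability proportional to `mix/bout_mean` and
exponential durations, so realised time shares converge to the requested
mix by renewal theory (consecutive draws of the same behaviour merge into
longer runs; per-class run lengths remain exponential). The dynamic
component is a sinusoid along a per-bout random direction when
`oscillation_freq_hz > 0` and broadband Gaussian noise of SD
`dynamic_amplitude` otherwise; each bout draws a log-normal amplitude
multiplier (`amplitude_cv`) so intensity varies between behavioural events.

`boar_benchmark()` is the canned study-condition scenario: 13 animals
with durations 0.2-9.5 h (mean ~3.1 h, 40.8 h total) at 1 Hz, and the
heavily imbalanced mix seen around a feeding pen (80.9% foraging, 5.9%
walking, 4.1% each sternal resting and standing, 1.5% lateral resting,
1.2% lactating, plus small scrubbing and "other" fractions). Default
profile amplitudes were calibrated once so the per-behaviour mean ODBA
ordering matches field ear-tag data (sternal resting ~50 < lateral resting
< lactating < standing < foraging < walking < scrubbing ~550 sensor
units). All default profiles are broadband (`oscillation_freq_hz = 0`):
at 1 Hz the observable band contains no reliable gait line, which is
precisely the regime the method targets, and it is what makes dispersion
statistics -- not spectral power -- the informative features. Three
structural choices define the benchmark's difficulty:

* **Walking vs foraging.** Walking shares the foraging tag orientation,
  has only ~14% higher dynamic amplitude (the ODBA ratio observed in the
  field), and occurs as very short draws (1.5 s mean, merging into ~6 s
  runs). Its seconds are therefore mostly swallowed by foraging-majority
  windows: walking holds ~6% of the time but only ~2% of windows, and the
  windows it does hold are impure. The classifier predicts nearly all of
  them as foraging: walking's balanced accuracy sits at chance (~50) and
  the false negatives land in the foraging column.
* **Foraging's ceiling.** Because foraging is 80%+ of windows, every rare
  misrouted class erodes its *specificity*: with walking at chance,
  foraging's balanced accuracy is structurally capped near 87 even though
  its sensitivity is ~99.6. The benchmark's four *well-separated* classes
  -- the ones expected above 90 balanced accuracy -- are therefore the two
  resting postures, lactating and standing.
* **Scrubbing** is present but too rare (~0.5% of time) to learn,
  mirroring a never-predicted rare class (balanced accuracy exactly 50).

Resting-class profiles use a smaller amplitude jitter
(`amplitude_cv = 0.1`) than active classes (0.2): resting and suckling
intensity is stereotyped, and this is what keeps lateral resting and
lactating (same posture, amplitudes 38 vs 69) separable, as they are in
real data where lactation roughly doubles resting ODBA.

**What the simulator does not model:** biomechanical gait structure,
behaviour-dependent transition grammar (draws are i.i.d.), per-animal tag
mounting differences, temperature, drift, or missing-data patterns other
than clean gaps. Passing the benchmark therefore demonstrates that the
pipeline recovers the *kind* of structure this method exploits --
amplitude and posture contrasts under extreme class imbalance -- not that
any particular field accuracy will be attained.

## Numerical and degenerate-input choices

* Windows require at least 4 samples; statistics of shorter inputs are an
  error, as is a window length that is not a whole number of samples.
* Zero-variance windows: skewness/kurtosis imputed as 0 (see above); the
  zero test uses a relative tolerance so constant windows with rounding
  residue are still treated as constant.
* A window longer than every segment yields an empty window set with a
  warning, not an error, so sweeps over aggressive sizes degrade
  gracefully.
* Duplicate timestamps, non-finite values, out-of-vocabulary labels and
  schema mismatches between a model and a feature table all fail loudly
  with the offending item named.
* Problem sizes in the test suite: the benchmark runs once at ~147k
  records / ~9.8k windows, model unit tests use 2-animal scenarios of a
  few thousand seconds, and the sweep is exercised at 6 s and 30 s (the
  informative endpoints of the size ladder); these sizes were chosen so
  the full pipeline is exercised end to end while the suite stays quick to
  run.

## Known limitations

* The split is by window, not by animal; overlapping windows on both sides
  of a split boundary share seconds, so accuracies are optimistic relative
  to a leave-animal-out protocol. This reproduces the established protocol
  faithfully and is flagged here as a known optimism source.
* Importance is impurity-based and scaled; it supports qualitative claims
  (dispersion ≫ spectral power) rather than calibrated effect sizes.
* Balanced accuracies of very rare classes rest on small test supports
  (tens of windows) and fluctuate by several points across simulation
  seeds; single-seed values for rare classes should be read with that
  sampling variability in mind.
* No clock-skew correction is applied when merging labels with
  acceleration; both streams are assumed to share one clock at 1 s
  resolution.
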
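---
title: "Simulating demyelinated-nerve CMAPs and inferring conduction-velocity distributions"
author: "cmapnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating demyelinated-nerve CMAPs and inferring conduction-velocity distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmapnet)
```

## The problem

A compound muscle action potential (CMAP) is the summed electrical
response of a muscle to supramaximal nerve stimulation: several hundred
motor axons each contribute one single motor unit potential (sMUP),
delayed by that axon's conduction time. In demyelinating neuropathies the
conduction velocities (CVs) of individual axons slow heterogeneously
(temporal dispersion) and some axons fail to conduct at all (conduction
block, CB). The per-axon CV distribution would be diagnostically
valuable, but it cannot be read off the summed waveform directly:
recovering it is an inverse problem. `cmapnet` implements both halves of
a simulation-based approach to that problem for the median nerve:

1. a **forward model** that synthesizes CMAP waveforms from an axon
   population with known CVs, under six modeled patterns of
   demyelination, with and without conduction block; and
2. an **inverse model** — recurrent neural networks (simple RNN, LSTM,
   GRU, unidirectional or bidirectional, one to three layers) — trained
   on simulated (waveform, histogram) pairs to regress the 28-bin
   axon-count histogram from a 251-sample CMAP.

Everything is simulated; the package makes no claims about real nerves.

## Forward model

### The sMUP template

Every conducting axon contributes the same unit waveform, sampled at
0.1 ms on the half-open grid [0, 15) ms — 150 points at t = 0.0, 0.1,
..., 14.9 ms. (A closed interval would hold 151 points; the half-open
convention keeps the stated 150-sample count and composes cleanly with
the 251-sample CMAP window.) Amplitudes are forced to exactly 0 mV
outside the gate window (default 3.5–12.1 ms, zero for t < 3.5 and
t ≥ 12.1 ms) so that stimulus artifact and baseline noise regions never
enter the superposition; no baseline-noise model is added back.

Templates can be loaded from a two-column CSV of digitized points
(`loadSMUP()`), which are smoothed with a **natural cubic spline**
(second derivative zero at the end knots, exact at the knots, no
extrapolation) and resampled onto the grid. Because published digitized
waveforms are generally not redistributable, `syntheticSMUP()` provides
a parametric surrogate: two opposed Gaussian lobes giving the
conventional biphasic negative-then-positive surface-recorded
morphology, parameterized by peak amplitude (mV) and onset (ms), with a
seed-controlled ±10% jitter of the lobe widths. The waveform scales
linearly with its peak amplitude; any smooth biphasic generator
satisfying the gate and grid invariants would serve equally well.

### Geometry and latency shifts

The simulated montage is median-nerve stimulation at the wrist and
elbow, recording from abductor pollicis brevis (APB): 70 mm from wrist
to APB (the distal segment, always conducting at the axon's normal CV)
and 200 mm from wrist to elbow (the forearm segment, where
demyelination acts). For an axon with normal CV $v_n$ and forearm CV
$v_f$ (m/s), the template copy is delayed by

$$\Delta\tau = \frac{70}{v_n} + \frac{200}{v_f} - \frac{270}{63}
\quad\text{(ms)},$$

i.e. relative to a reference axon conducting at 63 m/s — the fastest
bin — in both segments. The absolute latency of the original template
recording is unknowable, so the template's own onset plays the role of
the fastest axon's physiological latency; any other reference would
only shift every waveform by a common offset. Shifts are rounded to the
nearest 0.1 ms grid step (no sub-sample interpolation; the whole
pipeline lives on a 0.1 ms grid), the copies are summed over the closed
[0, 25] ms window (251 samples), and contributions falling beyond 25 ms
— the tails of the slowest axons — are truncated. Blocked axons
contribute exactly zero; an all-blocked population yields the zero
waveform.

### The normal population and demyelination patterns

The healthy-nerve CV histogram (in `normalHistogram()`) places 200
axons — a motor unit number estimate — on the odd 2 m/s bins 37–63 m/s
with counts 1, 2, 2, 6, 18, 30, 42, 39, 27, 17, 9, 4, 2, 1 at 63 down
to 37 m/s. Demyelination redraws each axon's forearm CV uniformly at
random from a pattern-specific allowed set (`allowedCVs()`):

| pattern | name            | allowed forearm CVs                        |
|--------:|-----------------|--------------------------------------------|
| 1       | entire range    | unchanged down to 11 m/s                   |
| 2       | severe          | 11–19 m/s                                  |
| 3       | moderate        | 21–35 m/s                                  |
| 4       | mild            | up to 8 m/s slower                         |
| 5       | moderate 2      | up to 20 m/s slower                        |
| 6       | two distributions | pattern-4 set plus 11–19 m/s             |

The uniform draw is the minimal reading of "randomly assigned"; a
per-pattern weight vector over the allowed set is exposed for
weighted randomization but defaults to uniform. Conduction block is
applied **after** slowing: each axon is independently blocked with
probability 0.4. Blocked axons keep their CVs but are counted in the
0 m/s bin of the 28-bin label (0, 11, 13, ..., 63 m/s); this keeps
every label summing to the population size and makes the block
frequency itself inferable from the label.

### Corpus

`buildCorpus()` crosses the six patterns with block absent/present
(12 groups) and draws 1,000 sets per group by default — 12,000 labeled
sets of (251-sample waveform, 28-bin count label, group id) — then
`splitCorpus()` partitions them 80/20 (9,600/2,400) uniformly at
random without stratification. A normal (pattern-0) population can be
generated but is not part of the default 12-group corpus. Everything
is deterministic given the seeds.

```{r corpus-demo}
tpl <- syntheticSMUP(1.0, onset = 4.0, seed = 0)
cfg <- simConfig(nPerGroup = 5L)   # 60 sets for illustration
corpus <- buildCorpus(tpl, cfg, seed = 1)
corpus
range(rowSums(labelMatrix(corpus)))
```

## Inverse model

### Architectures

`buildModel()` constructs a sequence-to-vector regressor: the waveform
enters as a length-251 sequence of univariate steps, passes through a
stack of one to three recurrent layers (LSTM, GRU, or a single-layer
simple RNN; each layer optionally bidirectional, with intermediate
layers returning full sequences), and a final dense layer projects to
28 unconstrained outputs. The 13-architecture comparison grid
(`standardGrid()`) covers the simple RNN plus {LSTM, GRU} ×
{unidirectional, bidirectional} × {1, 2, 3} layers. Input kernels use
Glorot-uniform initialization, recurrent kernels orthogonal blocks, the
LSTM forget-gate bias starts at 1, and all initialization is controlled
by the seed. The GRU uses the reset-after-candidate variant
$n = \tanh(W_x x + b + r \odot (W_h h))$.

**Readout.** The final recurrent layer's output sequence is summarized
by its temporal mean (both directions concatenated for bidirectional
layers) before the dense projection. A last-hidden-state readout was
evaluated first and discarded: the gated template leaves both ends of
the 251-sample window silent, so at moderate widths the final hidden
states relax toward an input-independent fixed point during the silent
tail and carry almost no waveform information — training then stalls at
the label variance, i.e. at predicting the mean histogram. Mean pooling
gives every timestep a direct gradient path to the loss and removes
that failure mode without changing the recurrent stack.

### Training recipe

`trainModel()` minimizes mean squared error over the 28 outputs with
Adam (default rate 0.001), dropout 0.5 on each recurrent layer's
output, batch size 2,048, for up to 1,000 epochs, with early stopping
that monitors the **training** loss with patience 2 (stop after two
consecutive epochs without improvement). The held-out 20% serves as the
validation set during training — there is no third split. Epoch
training metrics are averaged over the minibatches (dropout active);
validation metrics are computed in evaluation mode.

Two numerical-conditioning choices, both invisible in the reported
units:

* **Output scaling.** The network is always fitted in standardized
  label units (counts divided by the standard deviation of the training
  labels) and predictions are rescaled to counts; reported losses are
  converted back to squared-count units. Without this, the dense-layer
  weights must grow two orders of magnitude to bridge the
  O(0.1)-feature / O(10–80)-count scale gap, which costs Adam tens of
  thousands of steps at narrow widths.
* **Input scaling.** `trainConfig(standardize = TRUE)` divides the
  waveforms by the global standard deviation of the training waveforms,
  keeping the recurrent nonlinearities out of saturation. It defaults
  to off, matching a pipeline with no input normalization; the examples
  and tests in this package switch it on.

### Metrics and prediction

The accuracy reported alongside the MSE loss is **dominant-bin
accuracy** (`dominantBinAccuracy()`): the fraction of cases where the
predicted histogram's largest bin coincides with the true histogram's
largest bin, ties broken toward the first index. This is how a generic
"accuracy" metric resolves for a multi-output regression against
integer-count targets; chance level is about 1/28 ≈ 0.036 for labels
with uniformly distributed dominant bins. The stricter
`exactMatchRate()` — all 28 rounded bins equal — is exposed as a
companion. For histogram predictions (`predictHistogram()`), raw
outputs are rounded half-away-from-zero and clipped below at zero;
the rounded prediction is deliberately not forced to sum to 200.

### Evaluation surfaces

`runNetworkGrid()` trains each architecture on the same split and
tabulates final training/validation loss and accuracy; the best row
maximizes validation accuracy, breaking ties by minimal validation
loss; a failing spec annotates its row rather than aborting the grid.
`evaluateByGroup()` computes loss and accuracy separately for the 12
(pattern × block) groups from **one** globally trained model — the
default reading of per-dataset results; the command-line interface also
offers `--per-group-train`, which trains 12 separate models, one per
group, for the alternative reading.
`exportPredictionPairs()` writes per-set true-versus-predicted
histogram CSVs plus the waveform, for plotting.

## What the simulation does and does not emulate

The generator reproduces the study conditions: a single shared sMUP
morphology for all 200 motor units, uniform per-segment conduction, a
two-straight-segment geometry, latency-shift-and-sum superposition,
and noiseless waveforms. Real recordings violate all of these to some
degree — motor unit potentials vary in size (a few percent of units
can dominate the CMAP), conduction can slow focally, volume conduction
and phase cancellation shape the waveform, and noise is never absent.
Passing tests therefore demonstrate the internal consistency of the
simulation and the learnability of its inverse map, not performance on
clinical data.

An intrinsic source of label noise is worth noting: the waveform
determines (up to deconvolution) the histogram of total latency
*shifts*, but the label bins the *forearm* CV, and the same shift can
arise from different (normal CV, forearm CV) pairs. Patterns whose
allowed sets are narrow relative to that ambiguity (notably pattern 4,
"mild slowing") are therefore intrinsically the hardest, and show the
lowest accuracy in per-group reports.

## Problem sizes used by the test suite

The package's tests exercise the full 12,000-set corpus generation and
split exactly once, and train networks at reduced size: the learning
check uses a 1,200-set corpus (100 per group), a two-layer
bidirectional LSTM with 64 hidden units per direction, dropout 0.5,
batch 128, input standardization, and at most 30 epochs — enough for
held-out dominant-bin accuracy well above 0.5 and rounded-prediction
error below the mean-histogram baseline, while keeping the suite
desk-sized. The full-scale recipe (1,000 units, batch 2,048, up to
1,000 epochs on 12,000 sets) is expressed by the defaults of
`modelSpec()` and `trainConfig()` and runs for hours on a single CPU;
it is not part of the test suite.

## Known limitations

* The sMUP surrogate is generic; no attempt is made to reproduce any
  specific published waveform.
* Only the elbow-stimulation waveform is simulated; the wrist response
  is not modeled, and the 25 ms window silently truncates the slowest
  tails.
* The per-pattern randomization weights behind "weighted" variants of
  the slowing draw are unspecified upstream and default to uniform
  here.
* Inference on recorded clinical CMAPs is out of scope: the models are
  trained and evaluated purely within the simulation.
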
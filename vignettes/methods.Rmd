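---
title: "Predicting intrinsic DNA cyclizability: model, training and design choices"
author: "DNAbendR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting intrinsic DNA cyclizability: model, training and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

DNAbendR predicts the intrinsic cyclizability (C-score) of 50-bp DNA from
sequence, trains that predictor from libraries of (sequence, score) pairs,
and provides the simulation and profiling machinery used to interrogate
what the score responds to. This vignette records the scientific model,
the conventions, and the choices made where the design was genuinely open.

## The prediction model

A 50-bp sequence is one-hot encoded as a 50×4 matrix in the fixed channel
order (A, C, G, T). The order is a convention, not physics; it is recorded
in the model archive so weights can never be silently combined with a
different encoding. An N encodes as the uniform row (0.25, 0.25, 0.25,
0.25) in single-sequence mode; in track mode windows containing N are
skipped outright, because inventing a score for unsequenced bases would
poison downstream profile averages.

The network:

1. **Stem.** A 3×4 two-dimensional convolution collapses the base axis
   (valid across the 4 channels, length-preserving zero padding along the
   position axis), producing a 1-D feature sequence; ReLU,
   batch-normalization, dropout 0.2.
2. **Inception module.** Two parallel branches of two serial
   convolutions: kernels 3×1 then 3×1; and 11×1 then 21×1. Each
   convolution carries ReLU; the *second* convolution of each branch also
   max-pools 2×1 before its batch-normalization and dropout (the block
   order within a layer is ReLU → pool → BN → dropout throughout). The
   small kernels see local dinucleotide steps; the 11- and 21-bp kernels
   span one and two helical turns, the natural scales of bendability
   signals.
3. **Residual shortcut.** The branch outputs are concatenated channelwise
   and added elementwise onto the inception input. Two shape choices make
   this addition well-typed and are our decisions, kept configurable:
   the stem emits 64 channels and each branch 32, the smallest symmetric
   choice whose concatenation matches the shortcut; and since branch
   pooling halves the length, the shortcut path is max-pooled 2×1 —
   parameter-free — rather than projected through a learned 1×1
   convolution.
4. **Head.** Max-pool 2×1, BN, dropout; an LSTM with 20 hidden units over
   the remaining 12-step feature sequence; the *final* hidden state (not
   the full state sequence) feeds a linear dense unit, because the target
   is a single scalar per fragment.

Weights are initialized by seeded variance-scaling (Glorot) uniform draws
from R's RNG; the seed is stored in the model. All forward and backward
passes are implemented in RcppArmadillo and are verified against central
finite differences in the test suite (absolute agreement ~1e-10 on a small
configuration).

### Reverse-complement averaging and detrending

Bendability is a property of the duplex, so the model scores each
sequence and its reverse complement independently and averages the two
raw outputs; the resulting invariance `C(s) = C(rc(s))` holds by
construction and is asserted to 1e-6 over random 50-mers. The averaged
raw output is then linearly recalibrated,

    C = a + b · raw,

because raw deep-regression outputs show a reproducible mean drift and
variance shrinkage relative to the labels. Two open choices:

* **Regression direction.** `(a, b)` are the least-squares coefficients of
  *labels on raw outputs* (recalibration direction), so applying them
  directly corrects the drift and shrinkage; on the calibration set the
  corrected mean equals the label mean and the OLS slope of labels on
  corrected predictions is exactly 1 (least-squares identities, asserted
  to 1e-8).
* **Calibration data.** The internal validation split, not the training
  split: raw outputs on training data are optimistically fitted, so
  calibrating there would under-correct the shrinkage.

## Training protocol

Labels are standardized to sample mean 0 and unit variance before
training; the constants are stored in the model so scores read as
z-scores (1.96 ≈ the 97.5% quantile of the training-genome distribution).
Optimization is stochastic gradient descent with rmsprop (lr 1e-3, decay
0.9, epsilon 1e-7 — standard defaults, exposed in `trainHyper()`) on MSE.
After each epoch the validation MSE is computed in evaluation mode; the
weights with the lowest validation MSE seen so far are checkpointed and
are what `trainModel()` returns — never the final epoch. Early stopping
halts training once validation MSE has failed to improve for more than
`patience` consecutive epochs. Batch size 128, maximum epochs 100 and
patience 5 are defaults chosen where the protocol left them open.

`crossValidate()` runs the 10-fold scheme: per fold, train on the other
nine (carving a seeded 10% internal validation split out of them for
early stopping and detrend calibration), evaluate Pearson correlation on
the held-out fold — correlation because measured cyclizability is only
comparable across libraries up to an additive constant — and flag the
best fold, ties broken by the lowest index.

Batch-normalization uses epsilon 1e-3 and running-average momentum 0.9;
the comparatively fast momentum lets the running statistics settle within
the short training schedules used at desk scale.

## Coordinates and track semantics

All internal coordinates are 1-based inclusive. A 50-bp window starting
at position `w` is anchored at its 25th base, `w + 24`: the score at
position 25 belongs to the fragment [1, 50], and an N-free sequence of
length L yields L − 49 scores at centers 25 .. L − 25. For an even window
width the center is inherently asymmetric; the left-of-center base is the
anchor everywhere in the package (windows, poly(dA:dT) tracts, PWM hits).
Mirror symmetry then maps a center p to L − p on the reverse complement,
which the track tests assert. Exported interval formats convert at the
boundary: bedGraph intervals are `[p−1, p)` 0-based half-open; WIG is
written as fixedStep step-1 blocks, broken at every gap left by skipped
N windows. Long sequences are scored in window batches whose size is a
performance knob only — batching must not, and does not, change values.

## Time-dependent Markov chains

`fitTDMC()` estimates, at every alignment position t, the conditional
distribution of the base given the previous min(t−1, k) bases, k ≤ 3.
Pseudocount 0 is the default because the un-smoothed estimator is what
makes the capture law exact: the expected position-specific (k+1)-mer
distribution of simulations equals the training distribution. Contexts
never observed fall back to the uniform distribution. `tdmcKmerDist()`
computes the expected k-mer law analytically by forward propagation, so
capture and the order-1 → 2 → 3 improvement can be checked without
simulation noise; simulated frequencies at n = 10,000 agree with training
within total-variation 0.05 at every position.

The 90th-percentile selection used to build training alignments follows
the linear-interpolation quantile (R type 7) with *strict* inequality —
fully tied score sets therefore select nothing; the threshold is recorded
on the output. PWM motif simulation draws the motif column-wise and pads
both ends with equal-length random sequence (uniform composition by
default, configurable), e.g. 91 bp on each side of a 19-bp motif for a
201-bp total; an odd remainder is an error naming the nearest valid
total.

## Profile analytics

Feature-anchored profiles average a per-bp signal at offsets −F..F from
width-1 anchors, reading offsets in anchor orientation (position − d on
the minus strand). Positions missing from the signal — track gaps,
chromosome edges — are excluded from both the mean and the reported
count rather than zero-filled, so edge attrition is visible. Quartile
stratification cuts at the 25/50/75 type-7 percentiles with boundary ties
assigned to the lower quartile. Poly(dA:dT) tracts are *maximal* runs of
a single base (pure A or pure T; "ATATAT" contains none) of exactly the
requested length — a 6-run contains no 5-tract. PWM scanning scores
log2((p + 1e-3)/(0.25 + 1e-3)) against a uniform background on both
strands; ties resolve to the leftmost position, then to the plus strand.

## The synthetic data generator

No public loop-seq download fits in a desk-scale test budget, so the
package carries a generator whose ground truth encodes the two sequence
determinants the field reports for bendability: phase-coherent ~10-bp
periodic AA/AT/TA/TT (W-W) occupancy, and poly(dA:dT) stiffness. The
noiseless oracle for a sequence of length L is

    score = w_per · A(s) + w_ww · f_WW(s) − w_polyA · P(s)

with `f_WW` the fraction of dinucleotide positions carrying a W-W 2-mer,
`A(s) = (2/L) |Σ_t I_WW(t) e^{2πi t / period}|` the phase-coherent
periodicity amplitude, and `P(s)` the sum of max(0, runLength − 4) over
maximal pure A- and T-runs. Defaults: w_per 1.0, w_ww 0.5, w_polyA 0.3,
period 10.0 (10.5 is equally meaningful; 10.0 keeps the phase arithmetic
simple and is configurable), noise sd 0.3. The oracle is a test scaffold,
not a claim about DNA mechanics; its formula is frozen so recovery
thresholds stay stable. `f_WW` and `P` are exactly reverse-complement
invariant; `A` is invariant up to the phase term, and near-invariant
empirically.

`makeLibrary()` mixes three classes (default 34/33/33): unstructured
random sequences; a periodic class planting 6-bp A/T patterns at
period-spaced offsets from a random per-sequence global phase (so peak
positions vary across the library, as they do in real highly bendable
fragments) — patterns contain no pure run longer than 2, and a G/C guard
base follows each plant because a background A/T there would sit half a
period out of phase and cancel amplitude; and a poly(dA:dT) class
planting one or two pure tracts of length 5–9. Labels are oracle +
Gaussian noise, standardized. The planting strengths were chosen so the
class structure is unambiguous (periodic exceeds random by more than half
a label sd at n = 5,000) and the sequence-determined signal dominates the
noise, comparable to real tiling-library training data; with the
defaults, the noise ceiling of held-out correlation is ≈ 0.95.

What the generator does **not** emulate: assay chemistry (tether effects,
ligation biases, read-count noise), genomic base composition and repeat
structure, GC-periodicity in anti-phase, or any coupling between classes.
Passing the recovery experiment therefore shows that the architecture and
training stack can extract planted periodicity/stiffness signal from
50-mers at realistic noise — not that the shipped untrained architecture
reproduces published genome-scale correlations, which require the
original training libraries as user-supplied inputs.

`makeSyntheticGenome()` plants nucleosome-like periodic elements (101-bp
footprints with W dinucleotides every period, phase-aligned at the
center), poly(dA:dT) tracts of stated exact lengths (flanked by G/C so
the planted length is also the maximal run length), and PWM instances on
random strands, greedily at non-overlapping random positions (an
impossible plan is an error), and returns truth anchor tables for
profile and refinement tests.

## Problem sizes and numerical tolerances

The test suite trains reduced architectures (16/8 filters, 8 LSTM units)
on libraries of a few hundred to a few thousand sequences for the
training-contract tests, and runs one full-size recovery experiment:
18,000 training / 2,000 validation / 2,000 held-out sequences, batch 128,
up to 6 epochs — sizes chosen to make the recovery statistically
unambiguous (threshold r ≥ 0.85 against a ≈ 0.95 noise ceiling) at
single-CPU cost. Equality tolerances: RC invariance and track-vs-window
agreement 1e-6 (accumulated float error across two evaluation orders);
least-squares identities 1e-8; standardization 1e-12; serialization is
bit-exact. The 2×1 max-pool drops a trailing odd position; batch
normalization clamps negative variances arising from cancellation at 0.

## Known limitations

* Training beyond a few epochs at full scale is CPU-bound in the GEMM of
  the 11- and 21-wide convolutions; there is no GPU path.
* Methylation-aware prediction and uncertainty quantification are out of
  scope.
* `predictTrack()` holds one chromosome's encoding in memory (~32 bytes
  per bp); chunk very large chromosomes at the caller if memory is tight
  — chunked and whole-sequence evaluation agree exactly.
* The detrend is calibrated on the training library's scale; applying a
  model across species preserves correlation but the additive scale is
  only as transferable as the training library's baseline.
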
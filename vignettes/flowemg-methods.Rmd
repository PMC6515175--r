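---
title: "Methods: invertible flow modelling of sEMG envelopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: invertible flow modelling of sEMG envelopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(flowemg)
```

This vignette is the package's account of its model, its parameter choices,
and the design decisions that were genuinely open — with the reasoning, so a
maintainer can revisit them.

## 1. Signal model and preprocessing

Raw sEMG is an interference pattern: approximately zero-mean broadband noise
whose *amplitude* carries the muscle-activation information. The linear
envelope extracts that amplitude:

1. **High-pass, 10 Hz** — removes movement artefacts and baseline drift.
2. **Full-wave rectification** — `abs()`.
3. **Moving average, 10 samples** (50 ms at 200 Hz) — local smoothing.
4. **Low-pass, 30 Hz** — the final envelope band.

Both filters are 4th-order Butterworth applied forward–backward
(zero-phase), the standard offline sEMG practice; the filter family and
order are our choice, as is the moving-average alignment (centered window
with edge replication, keeping the envelope time-aligned with the raw
signal). Because `signal::filtfilt` starts both passes from zero initial
conditions, we pad each channel with an odd reflection of up to 200 samples
before filtering and trim afterwards; the start-up transient decays below
1e-8 within ~150 samples for these designs, so DC rejection and edge
behavior are clean. The final low-pass can overshoot slightly below zero;
we clip to 0 so envelopes are nonnegative by construction.

Envelopes are cut into non-overlapping 64-sample windows (stride
configurable; the default stride equals the window because the comparison
protocols in the literature disagree and no overlap is the neutral choice).
Each window takes the *majority* per-sample label; exact ties would be
ambiguous training targets and the window is discarded. Rest (label 0)
vastly outnumbers movements in protocols that interleave rest between
movement repetitions, so `balance_rest_class()` subsamples rest down to the
median non-rest class count — a scale-free, reproducible (seeded) target.

## 2. The invertible transform

A window is a `64 x 16` matrix (time x electrode channels). The transform
must (a) have an exact, cheap log-determinant, (b) be exactly invertible,
and (c) end in a retained latent of `32 x 8`. We use three flow steps, each

* **actnorm** — per-channel affine `y = exp(s) * x + b` (this scale-then-shift
  convention is fixed and its inverse derived accordingly), log-determinant
  `T * sum(s)`. `s, b` are initialized from the first training batch so the
  post-layer activations have per-channel mean 0 / variance 1 (population
  moments), which stabilizes the early optimization.
* **invertible 1x1 channel mixing** — one learned nonsingular `C x C`
  matrix applied at every row; log-determinant `T * log|det W|`. At `C <= 32`
  we compute the determinant directly (an LU parameterization buys nothing
  at this size). Initialized to a random rotation (`log|det| = 0`).
* **affine coupling** — channels split in half; the first half passes
  through and feeds a two-layer tanh network (hidden width 64, final layer
  zero-initialized) producing per-element log-scales and shifts for the
  second half. The log-scale is squashed to `(-2, 2)` by `2 * tanh(.)`, so
  the layer is invertible for any parameter value, and the zero-initialized
  final layer makes each coupling exactly the identity at the start of
  training — the whole flow begins as (actnorm o rotation), which keeps
  early likelihoods finite.

**Multi-scale structure.** Before step 1 the window is squeezed along time:
adjacent time pairs move into the channel axis, `64 x 16 -> 32 x 32`. Steps
1 and 2 each end by routing the second half of the channels to the Gaussian
prior (`32 x 32 -> 32 x 16 -> 32 x 8`); step 3 has no split. Element count
is conserved exactly (retained 32x8 + splits 32x16 + 32x8 = 1024 = 64x16).

The squeeze is the one place we departed from the obvious reading (split
the time axis even/odd at step 1). That reading fails structurally: with
actnorm, mixing and coupling all acting row-wise on channels, *no layer
couples distinct time points*, so the even-time half can never be
Gaussianized conditionally on the retained half — the flow is exactly
time-factorized. Reverse-flow generation with split parts at their prior
mean then interleaves the fixed row `f1^{-1}(0)` into every generated
envelope; in our experiments the decoded rest-gesture center plateaued at
~0.35-0.45 of the movement centers' amplitude no matter how long we
trained. With the time squeeze, couplings see both elements of each time
pair, the splits become conditionally adjustable, and the decoded rest
center drops to ~0.1 of the movement amplitude while all printed shapes
(`64 x 16` in, `32 x 8` retained, halving per split) are unchanged.

Numerical guards: any non-finite intermediate raises an error naming the
stage (no silent clamping); a singular mixing matrix is an error; forward
passes require initialized actnorm layers.

## 3. Likelihood, classifier and joint training

The exact log-likelihood of a window is the standard-normal log-density of
*all* latent parts (retained and both splits — 1024 terms) plus the
accumulated log-determinant. The classifier is deliberately linear: SoftMax
on the flattened (column-major) retained latent, `53 x 256` weights for the
full gesture set. Zero initialization makes it the uniform classifier
(cross-entropy exactly `ln K` at the start).

The compound objective is

```
loss = mean_i [ -log p_x(x_i) ] + ce_weight * mean_i CE(y_hat_i, y_i)
```

Both terms are per-example means (a summed-NLL reading differs by a factor
of the batch size but has the same minimizers for fixed batches);
`ce_weight` defaults to 1, the unweighted reading. Gradients through all
layers are derived analytically and verified against central differences
(relative error < 1e-7 on a reduced model). The optimizer is Adam at
learning rate 1e-3 (flows train poorly with plain SGD; the source protocol
does not name an optimizer), batch 24, 15 epochs. Training is deterministic
given the seed on a fixed platform: per-epoch shuffles use bounded
sub-seeds drawn once from the master seed, and the RNG state is always
restored around seeded internals.

Two split protocols are provided: `split_random()` (70/30 at the example
level; train size `0.7 N` rounded half away from zero) and
`split_by_subject()` (all examples of 7 randomly chosen subjects train, the
remaining subjects test). `repeat_experiment()` re-draws the split *and*
re-initializes on seeds `seed + 0..repeats-1` (default 5 repeats); whether
the original protocol re-drew splits is unstated, and re-drawing gives the
more conservative variance estimate.

**What joint training buys.** On the synthetic benchmark the
generative-only flow already yields linearly separable latents, so joint
training and generative-then-head classification reach statistically
indistinguishable accuracy (the sign of the difference flips with the RNG
stream). The interaction is nevertheless real and measurable in latent
geometry: the between-class/within-class separation of held-out retained
latents is consistently higher under joint training. The test suite asserts
that separation property rather than an accuracy ordering; expect the
accuracy benefit to matter only on data where classes are not linearly
separable from generative features alone.

## 4. Latent interpretation

* **Gesture centers** — per-class arithmetic means of retained latents
  (splits excluded, consistent with the classifier seeing only the retained
  part).
* **Correlation matrix** — cosine of the angle between flattened centers;
  scale-invariant, symmetric, unit diagonal; zero-norm centers produce `NA`
  with a warning rather than a fabricated value.
* **Reverse-flow generation** — `flow_inverse` from a retained latent with
  split parts at their prior mean (zeros) unless supplied. Zeros are the
  least-informative choice; class-conditional mean splits would decode
  slightly more faithfully but leak information the latent is supposed to
  carry alone.
* **Dimension sweep** — decode the one-hot latent `z[a, b] = v` for all 256
  positions. `|v|` is bounded at 75 by default — the min/max latent value
  observed in full-scale training on the real database — with a `force`
  flag for exploration; on our synthetic models the trained latent range is
  only about ±6, so sweeps at large `v` extrapolate (they remain
  well-behaved because each inverse layer is globally Lipschitz given the
  bounded coupling log-scales).
* **Envelope strength** — "strength" is not formally defined in the source
  protocol; we use mean absolute amplitude (RMS behind a flag). Strength is
  positively homogeneous, which is what the monotonicity-in-`v` analysis
  needs.

## 5. The synthetic generator

`synthetic_spec()` + `make_synthetic_dataset()` emulate the structure of
the NinaPro DB5 protocol: 10 subjects, 6 repetitions per movement class,
16 channels at 200 Hz, movement bouts interleaved with rest, per-sample
labels with rest = 0. The carrier is band-limited (20–95 Hz) unit-variance
Gaussian noise, amplitude-modulated per channel by a class-specific
nonnegative combination of muscle-synergy patterns (each pattern dominated
by a distinct channel, pairwise cosine < 0.5) under a trapezoidal
ramp–hold–ramp bout profile, times a log-normal per-subject channel gain.
Defaults: 3 movement classes, 3 synergies, 192-sample bouts (three windows),
activation amplitude 2 against rest baseline `noise_sd = 0.02` — i.e. rest
is ~1% of the peak movement envelope on dominant channels, emulating clean
recordings in which rest is essentially a zero envelope; `subject_gain_jitter
= 0.1`.

What the generator does **not** model: motor-unit physiology, electrode
shift, powerline interference, fatigue, label noise, within-class movement
variability beyond the subject gain. Passing the end-to-end tests therefore
demonstrates that the pipeline, the flow, the training loop and the
analyses are correct and well-conditioned — not that real-database accuracy
is reproduced. The real-data workflow (NinaPro DB5 `.mat` files through
`flowemg preprocess` / `train --split subject`) is supported but requires
the database download and full-scale training; its headline accuracies are
outside the test suite by design.

## 6. Problem sizes and budgets

The shipped tests and the acceptance script run the full pipeline at desk
scale, chosen as the smallest sizes that exercise every component
meaningfully: the default synthetic dataset is 720 windows (10 subjects x 6
repetitions x 3 classes x 3 windows, plus balanced rest), trained for 15
epochs at batch 24 (~10 s per run); log-determinant oracles use the reduced
`8 x 4` architecture where the 32x32 Jacobian is cheap; the Monte-Carlo
change-of-variables check uses 10,000 windows. Checkpoints are JSON with
doubles at 17 significant digits (bit-exact round-trip); datasets are `.rds`
at run time; analysis outputs are CSV.

## 7. Known limitations

* One coupling per flow step and one time squeeze mean only *adjacent* time
  pairs are directly coupled; long-range temporal structure is captured
  only through the splits' marginal Gaussianization. More steps or deeper
  squeezing would model it better at the cost of the fixed `32 x 8` shape.
* The `[-75, 75]` sweep bound is inherited from full-scale training and is
  far outside the latent range of small synthetic models; sweeps there are
  extrapolations.
* The MAT reader supports little-endian v5 numeric matrices (long, short
  and zlib-compressed elements) — enough for DB5 — not structs, cells or
  v7.3/HDF5 files.
* `evaluate_accuracy` breaks logit ties toward the first class, which only
  matters for the untrained zero-weight classifier.
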
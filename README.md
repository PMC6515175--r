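# flowemg

Generative flow models for surface EMG hand-gesture classification, in R.

## The problem

Surface electromyography (sEMG) based gesture recognition usually relies on
deep discriminative models whose learned features are opaque — a real
obstacle in clinical use (prosthesis control), where understanding *why* a
model works for one user and fails for another matters. `flowemg`
implements the alternative: an **invertible generative flow** maps each
multi-channel sEMG linear-envelope window to a factorized latent feature
with an exact likelihood, and a **linear SoftMax classifier** on that
latent does the discrimination. Because the transform is invertible, every
latent dimension can be decoded back into an sEMG envelope and inspected —
the features stay physically interpretable, and empirically they resemble
muscle-synergy activation patterns.

## The model

A window $x \in \mathbb{R}^{64 \times 16}$ (64 time points, 16 electrode
channels at 200 Hz) is mapped by an invertible transform
$f_\theta : x \mapsto z$ with exact log-likelihood from the change of
variables:

$$\log p_x(x) = \log p_z(f_\theta(x)) + \log\left|\det \frac{\partial f_\theta(x)}{\partial x}\right|,
\qquad p_z = \mathcal{N}(0, I).$$

$f_\theta$ is built from three flow steps, each an **actnorm** (per-channel
affine, data-dependent init), an **invertible 1×1 channel mixing** and an
**affine coupling layer**; a multi-scale architecture Gaussianizes half of
the variables after steps 1 and 2, so the retained latent is
$z \in \mathbb{R}^{32 \times 8}$. Flow and classifier
$\hat{y} = c_\phi(f_\theta(x))$ are trained *jointly* on the compound
objective

$$\min_{\theta,\phi}\; \mathbb{E}\big[-\log p_x(x)\big] + \lambda\,\mathrm{CE}(\hat{y}, y),$$

so the label information regularizes the learned distribution. The
preprocessing chain (10 Hz high-pass, rectification, 10-point moving
average, 30 Hz low-pass, 64-sample windows, rest-class balancing), the
interpretation tools (gesture centers, cosine correlation matrix,
reverse-flow generation, per-dimension latent sweeps) and a muscle-synergy
synthetic sEMG simulator are all included, along with a reader for NinaPro
Database 5 style MATLAB files.

## Worked example

```r
library(flowemg)

# synthetic 3-gesture dataset with synergy structure (plus rest), 10 subjects
ds    <- make_synthetic_dataset(synthetic_spec(seed = 1))
parts <- split_random(ds$examples, seed = 1)        # 70/30 protocol
fit   <- train_model(parts$train, training_config(seed = 1))

glance(fit)
#> # A tibble: 1 × 7
#>   epochs    nll     ce  total train_acc n_classes n_parameters
#> 1     15 -2432. 0.0126 -2432.         1         4         8108

evaluate_accuracy(fit, parts$test)
#> [1] 1
```

`nll` is the per-window negative log-likelihood of the flow (lower = better
generative fit), `ce` the classifier cross-entropy. Interpretation:

```r
centers <- gesture_centers(compute_latents(fit, parts$train))
round(unclass(correlation_matrix(centers)), 2)
#>       0     1     2     3
#> 0  1.00 -0.20 -0.13 -0.20
#> 1 -0.20  1.00 -0.28 -0.39
#> 2 -0.13 -0.28  1.00 -0.47
#> 3 -0.20 -0.39 -0.47  1.00
```

Off-diagonal cosines near 1 would flag gesture pairs the model cannot tell
apart; here all classes are well separated. Decoding each gesture center
through the reverse flow gives its typical envelope — the rest center
decodes to a near-zero envelope (mean amplitude 0.017 against ~0.20 for the
movement gestures), matching what rest looks like in the signal:

```r
sapply(centers$center, function(z)
  envelope_strength(generate_envelope_from_latent(fit, z)))
#> 0.0169 0.1969 0.1988 0.2068
```

`dimension_sweep_grid(fit, v = 35)` decodes every one-hot latent position
into an envelope (the 32 × 8 grid of basic sEMG patterns);
`autoplot()` methods visualize training curves, correlation matrices and
sweep grids.

## Command line

An installed `exec/flowemg` script exposes the pipeline:

```sh
flowemg simulate --out ds.rds --seed 1
flowemg train --data ds.rds --out run/ --split random --seed 1
flowemg analyze --checkpoint run/checkpoint.json --data ds.rds --out run/analysis
flowemg sweep --checkpoint run/checkpoint.json --v 35 --out sweep.rds
```

`flowemg preprocess --input S1_E1_A1.mat --out ex.rds` converts a NinaPro
DB5 recording into model-ready windows (labels remapped to the global 0–52
gesture scheme), so the full database workflow — train on DB5 with random or
subject-wise splits — is the same `train`/`evaluate` calls on that output.

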
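---
title: "Methods: graph-guided latent embedding of cognitive phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-guided latent embedding of cognitive phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcen)
```

## The model

`lcen` treats a battery of cognitive phenotypes `y_i` (6–15 numeric columns
per subject: reaction times, working-memory spans, planning scores, possibly
binarized outcomes) as driven by a low-dimensional latent state `z_i`
inferred from high-dimensional multimodal features `x_i` (standardized EEG
power-spectral-density summaries, imaging-derived variables, and the like).
Three structural assumptions shape the architecture:

1. **Variational encoding.** `q(z_i | x_i) = N(mu_i, diag(sigma_i^2))` comes
   from a fully connected trunk (default widths 512/256/128/64, GELU, batch
   normalization, dropout 0.3 after layers 2 and 3) with two linear heads for
   `mu` and `log sigma^2`; `z_i = mu_i + sigma_i * eps` with seeded noise. The
   prior is isotropic standard normal, giving the usual closed-form KL term.

2. **Graph-structured decoding.** Phenotype dimensions depend on one another
   through a zero-diagonal adjacency `A`: the decoder resolves the implicit
   system `y = W_d z + A y` as `y = (I - A)^{-1} W_d z`. `A` is either fixed
   (supplied as an undirected weighted edge list) or learned. A learned `A`
   is symmetric by construction (`(P + P')/2`, zeroed diagonal) so the
   symmetry penalty `||A - A'||_F^2` is exactly zero by design yet still
   computed and logged for fidelity to the stated objective; sparsity is an
   L1 penalty on the entries. An optional two-layer residual block `y + R(y)`
   (widths 64/128, zero-initialized output layer, hence the identity at
   initialization) adds nonlinearity.

3. **A three-level hierarchy.** Phenotype columns are grouped into
   sensorimotor, cognitive-control, and executive tiers. Level-specific
   projections `h_l = f(W_l z + b_l)` feed linear heads for each level's
   columns; a softmax over compatibility scores `u_l' h_l` yields weights
   `alpha_l` that mix the level predictions. By default the scores are
   averaged over the batch before the softmax (`shared_alpha`), matching the
   per-level (not per-subject) form of the weighting; a per-subject variant
   is a config switch.

The composite objectives — graph smoothness
`sum_(k,l) |A_kl| ||yhat^(k) - yhat^(l)||^2`, latent variance/proximity
control, the variational mutual-information bound, squared-covariance
disentanglement, hierarchy consistency between parent and child tasks,
gradient-norm adaptive multi-task weights, the heteroscedastic uncertainty
loss, and the pretraining losses (input reconstruction, auxiliary-prior KL,
InfoNCE contrastive) — are all built on a small reverse-mode tape, so each is
exactly differentiable and is verified against central finite differences in
the test suite.

## Parameters that matter

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `encoder$layer_widths` | 512/256/128/64 | trunk widths; the last entry is the latent dimension `d_z` |
| `encoder$dropout_rate` | 0.3 | after trunk layers 2 and 3 (training only) |
| `decoder$delta` | 0.05 | spectral margin: adjacencies are projected to radius ≤ 1 − δ so the Neumann series converges; the magnitude of `A` is otherwise unconstrained and the solve would be ill-posed |
| `decoder$unroll_steps` | 8 | fixed-point iterations of the unrolled solver; error decays like `rho^steps` |
| `lambdas$kl` | 0.1 | weight of the posterior-prior KL (dimensionless) |
| `lambdas$sparsity` | 0.01 | L1 pressure on the learned adjacency |
| `lambdas$beta`, `lambdas$mutual` | 1, 0.1 | latent proximity and mutual-information weights; the source material leaves both un-tuned, these are our defaults |
| `multi_task$ema_beta`, `epsilon` | 0.9, 1e-8 | smoothing and stabilizer of the adaptive weights `lambda_t = 1/(EMA_t + eps)`, rescaled to sum to the task count so the loss scale is stable |
| `training$*` | Adam, lr 0.001, batch 32, ≤100 epochs, patience 10 | reference optimizer settings; early stopping on validation loss restores the best parameters |
| `pretrain$tau` | 0.1 | contrastive temperature (no stated value; 0.1 is the common InfoNCE choice) |
| `latent_variance_sign` | +1 | the latent variance term is *penalized* as the formula is printed, although the surrounding prose speaks of ensuring diversity; `-1` implements the prose reading |

Every default is a named key of `lcen_config()`; unknown keys are rejected,
and `read_config()` loads the same structure from YAML.

## Identifiability and the learnable adjacency

Two readings of the generative model differ in where the phenotype noise
enters, and only one of them makes the adjacency estimable. If noise is added
*after* the solve, `y = (I - A)^{-1} W z + eps`, then the conditional mean of
`y` given the features is `(I - Ahat)^{-1} What R z` for the learned
quantities, and for any candidate `Ahat` the choice
`What = (I - Ahat)(I - A)^{-1} W` reproduces it exactly: the reconstruction
loss is flat along that manifold and the L1 penalty then drives `Ahat` to
zero. No regression objective can recover `A` in that world. If instead the
noise enters the structural equation, `y = (I - A)^{-1}(W z + eps)` — the
standard convention for structural-equation and network models, and the one
consistent with the phenotype covariance
`(I - A)^{-1}(W W' + sigma_y^2 I)(I - A)^{-T}` that the simulator is checked
against — then `(I - A) y = W z + eps` with white residuals, and `A` is
identified: any other adjacency inflates the residual variance by
`||(I - Ahat)(I - A)^{-1}||_F^2 > d`.

The generator therefore places the noise inside the solve, and when the
adjacency is learnable the trainer fits the structural residual
`||y - (W_d z + A y)||^2` (prediction for a new subject always goes through
the closed-form solve, which is the correct conditional mean under this
model). A config flag (`training$structural_residual`) switches the trainer
back to the solve-based reconstruction for users who want the fixed-graph
behavior everywhere. Recovery is identifiable only up to a rotation of the
latent factors: `z` can be replaced by `Rz` with `W_d R'` absorbing the
rotation, which is why the recovery checks compare column *spans* (principal
angles) rather than entries of `W_d`.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure the model assumes:
latent factors `z* ~ N(0, I_k)`; a symmetric adjacency with an exact number
of edges (`round(density * d_y(d_y-1)/2)`, weights uniform in ±[0.3, 1],
rescaled to spectral radius 0.6 by default); phenotypes through the
structural solve with noise SD 0.1; features as two linear modality blocks
("eeg_psd", "imaging") of the factors with noise SD 0.1; optional binary
columns by thresholding at zero; and a contiguous three-level hierarchy. The
defaults (n = 800, d_x = 40, d_y = 10, k = 5, density 0.2, seed 7) define the
scenario on which parameter recovery is scored. Noise SDs of 0.1 put the
per-dimension signal-to-noise near 10:1 — optimistic but appropriate for a
recovery study whose question is whether the *estimator* works, not whether
the data are kind.

What the generator does **not** emulate: raw EEG waveforms or images (only
precomputed per-modality feature blocks), nonlinear feature maps,
non-Gaussian noise, missing data, or batch effects. Passing recovery tests
therefore says the estimator identifies structure when its assumptions hold;
it says nothing about robustness to real-data violations of them.

`make_worked_example()` pins a hand-enterable instance (4 subjects, 1 latent
factor, 2 phenotypes, adjacency `[[0, .5], [.5, 0]]`), whose phenotypes equal
the 2×2 closed-form solve (`z = 1` gives `y = (4/3, 2/3)`); the gradient
checks of all six composite objectives run on it. Cohorts are bit-identical
across runs for a fixed seed, pinned by an md5 fingerprint of a canonical
fixed-precision text serialization (no binary serialization is involved).

## Numerical choices

- **Spectral projection.** `project_adjacency()` symmetrizes, zeroes the
  diagonal, and rescales to radius `1 - delta` only when needed, so it is
  idempotent on valid graphs.
- **Solver equivalence.** The unrolled solver's truncation error after `m`
  steps is bounded by `rho^(m+1)/(1 - rho) * ||W_d z||`. At 50 steps the
  1e-6 agreement with the closed form holds for radii up to about 0.73 and
  cannot hold near 0.9 (0.9^51/0.1 ≈ 0.05); the equivalence checks therefore
  sample radii in [0.1, 0.7] and a separate property verifies the geometric
  bound itself across the full projected range.
- **Posterior initialization.** The log-variance head starts at −4
  (sigma ≈ 0.14). Starting at 0 (sigma = 1) injects unit reparameterization
  noise into `z` before the encoder has learned anything, which visibly
  stalls optimization; near-deterministic starts are standard practice.
- **Clamps.** `log sigma^2` is clamped to [−20, 20] inside every loss so all
  objectives stay finite for inputs up to ±1e6 (the uncertainty loss clamps
  its per-task log-variances to [−10, 10]). Sampling itself does not clamp,
  so a degenerate posterior (`log_var = -40`) collapses onto its mean.
- **Reduction conventions.** Reconstruction losses are summed over phenotype
  dimensions and averaged over the batch (this fixes the 1/N ambiguity of
  the decoding objective); batch variances and covariances use the n−1
  denominator; graph smoothness counts each undirected edge once, weighted
  by `|A_kl|` so fixed and learned graphs share one code path.
- **Splits.** Largest-remainder apportionment with ties resolved in
  train/validation/test order reproduces the printed 70/15/15 counts
  (3,000 → 2,100/450/450; 10,300 → 7,210/1,545/1,545) and gives
  (7, 2, 1) at n = 10. Stratification by a binary column keeps the ratios
  within each stratum.
- **AUROC.** Computed by trapezoidal integration of the empirical ROC curve
  with tie groups; this equals the Mann–Whitney rank statistic exactly, which
  the tests assert to 1e−12.
- **The literal attention penalty.** `sum_l |alpha_l|` is identically 1 for
  softmax weights, so its gradient is zero; it is kept and logged as stated.
  `attention_entropy_weight` adds `-sum alpha log alpha` for users who want
  an effective sparsity pressure — the attention-concentration property test
  uses it (0.05), together with GELU level projections: with linear
  projections on centered latents the batch-averaged score gradient is
  numerically zero and the weights cannot move at all.

## Design points the source leaves open

- The latent-space and phenotype-space graph regularizers are both
  implemented (`lambdas$graph` acts on predictions; the latent variant is
  available through `domain_regularizer()` on `z`); which to use is config.
- Batch-wise (not dataset-wise) variances in the latent regularizer.
- Tasks for multi-task weighting default to the hierarchy levels; any column
  partition can be supplied via `task_spec()`.
- Parent/child tasks of different widths are compared through fixed
  column-group means (children split into as many contiguous groups as the
  parent has columns).
- The gradient statistic for adaptive weights is the squared gradient norm on
  the shared encoder trunk, per batch, EMA-smoothed. As printed, a larger
  statistic gives a *smaller* weight, and the property tests assert that
  printed relation.
- In the uncertainty loss the first argument is treated as the prediction and
  the hatted symbol as the target, matching every other objective's
  convention.
- Auxiliary pretraining priors default to a single standard normal (`J = 1`);
  user-supplied per-dimension (mean, log-variance) priors are accepted.
- Per-level predictions come from level-specific linear heads on `h_l`, not a
  shared decoder.
- Contrastive negatives are in-batch (the other subjects' augmented
  embeddings); `tau = 0.1`.

## Problem sizes in the checks

The test suite trains on deliberately small instances: recovery uses the
default 800-subject cohort with a linear two-layer encoder (32/5), learning
rate 0.01, 150 full-patience epochs, five training seeds; the noiseless-cohort
check uses 400 subjects and 200 epochs; the pretraining-benefit comparison
uses 300 subjects with feature noise SD 0.4 — the low-SNR regime in which a
denoising initialization matters — and exactly 10 fine-tuning epochs; the
attention-concentration check uses 300 subjects with signal confined to the
sensorimotor columns. These sizes keep the full suite under a minute while
leaving each property comfortably away from its threshold.

## Limitations

- Internals are plain R matrices on one CPU; the package is built for
  thousands of subjects and tens of phenotypes, not for raw-signal deep
  learning.
- Convolutional/transformer modality backbones are out of scope: features
  enter as precomputed blocks, with only linear per-modality projections.
- The learnable adjacency is undirected by construction; directed phenotype
  dependencies are not representable.
- With exterior observation noise (noise added after the solve) the adjacency
  is fundamentally unidentifiable from feature/phenotype pairs, as derived
  above; users fitting real data should interpret a learned `A` under the
  structural-noise reading.
- Binary phenotypes are handled by thresholded scores and classification
  metrics, but the decoder itself is a regression model; no link function is
  fitted.
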
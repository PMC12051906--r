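---
title: "Multi-space alignment for cross-domain EEG seizure detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-space alignment for cross-domain EEG seizure detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Seizure detectors are trained per recording setup: a montage of C
electrodes sampled at a fixed rate, for one population of subjects. Moving
a detector to a different setup — another species, intracranial vs scalp
electrodes, 16 channels instead of 6, 400 Hz instead of 256 Hz — breaks
every layer of the model at once: the input dimensionality, the feature
distribution and the output calibration. `seizalign` implements a transfer
pipeline that aligns all three spaces simultaneously, so a convolutional
seizure classifier trained on a labeled *source* domain can be applied to a
*target* domain with few or no target labels.

The unit of classification is the clip: a fixed-length `C x T` segment
labeled seizure / non-seizure, scored by the model's seizure-class
probability and evaluated by per-subject AUC (the normalized Mann-Whitney
rank statistic, half credit for ties).

## The three alignments

**Input space — Euclidean alignment (EA).** For each subject with clips
\(X_1, \dots, X_n\) (each \(C \times T\)), the mean trial covariance is

\[ \bar R = \frac{1}{n} \sum_{i=1}^n X_i X_i^\top , \]

and every clip is whitened as \(\tilde X_i = \bar R^{-1/2} X_i\). After
alignment each subject's mean covariance is the identity, which removes
per-subject amplitude scales, electrode-gain spreads and much of the mixing
geometry. The statistic uses no labels, so test subjects are aligned with
their own unlabeled clips. \(\bar R^{-1/2}\) is computed by symmetric
eigendecomposition with an eigenvalue floor; when the smallest eigenvalue
of \(\bar R\) falls below \(\varepsilon \cdot \mathrm{tr}(\bar R)/C\) (with
\(\varepsilon = 10^{-6}\)) a ridge of that size is added, guarding
rank-deficient pools of few short clips. Alignment is idempotent and
invariant to per-subject rescaling — both properties are tested.

**Input space — channel projection.** When the domains differ in channel
count, the higher-channel domain is projected down to the lower montage by
a learnable linear map \(W \in \mathbb{R}^{C_{lo} \times C_{hi}}\) applied
per time sample (a width-1 convolution across channels). It is initialized
to the channel-selection matrix, so training starts exactly at the
truncation baseline ("keep the first \(C_{lo}\) channels"), and is trained
end to end with the rest of the model. We deliberately keep the projection
linear and bias-free: it is the simplest map that unifies montages while
preserving the temporal structure the backbone consumes. Whether the
projection should be applied source-to-target or target-to-source is
resolved by always projecting the *higher*-channel side down — reducing to
a common lower-dimensional representation never fabricates channels.

**Feature space — domain adaptation.** The backbone is a compact
convolutional network in the EEGNet-8,2 configuration (8 temporal filters
of half-a-second length, depthwise spatial filters with depth multiplier 2,
a separable temporal stage with 16 filters, batch normalization, ELU,
average pooling 4 then 8, dropout 0.25), followed by a linear classifier.
Two feature-space losses are provided on its flattened features / logits:

* **MCC** (minimum class confusion, the default): target-batch class
  probabilities are softened at temperature \(\tau_{mcc} = 2.5\), examples
  are weighted by prediction certainty (entropy-based, normalized to sum to
  the batch size), and the loss is the mean off-diagonal mass of the
  row-normalized weighted class-correlation matrix \(Y^\top W Y\). It is
  bounded in \([0, (K-1)/K]\) and needs no source/target pairing.
* **MMD**: the biased multi-kernel maximum mean discrepancy between source
  and target feature batches, five Gaussian kernels at bandwidth
  multipliers \(\{0.25, 0.5, 1, 2, 4\}\) on the median-heuristic base
  bandwidth (treated as a constant in gradients).

MCC is the default because in our ablations (and in the method's own
motivation) it is the more reliable single feature-space term; MMD remains
selectable by configuration.

**Output space — knowledge distillation.** On the projected domain's
batches, the truncation branch (the same backbone fed the first
\(C_{lo}\) raw channels, gradient-blocked) acts as teacher and the
projection branch as student:

\[ \mathcal{L}_{KD} = \tau^2 \, \mathrm{KL}\!\left(
   \mathrm{softmax}(z_t/\tau) \,\|\, \mathrm{softmax}(z_s/\tau) \right), \]

averaged over the batch, with \(\tau_{kd} = 2\). The truncation branch is
the stable reference at initialization (the projection starts as exactly
that selection), which is why it teaches by default; `--kd-direction`
offers the reverse and mutual modes. A channel-wise variant (per-channel
softmax over time on the unified input representation, KL per channel,
averaged) is available behind the `kd = "channelwise"` option for users who
want distillation closer to the signal.

**The composite objective** is

\[ \mathcal{L} = \mathcal{L}_{CE} + \lambda \, \mathcal{L}_{KD}
   + \beta \, \mathcal{L}_{DA}, \qquad \lambda = \beta = 1 , \]

cross-entropy on all labeled clips plus the weighted alignment terms. Both
trade-off weights default to 1 and performance is robust over a wide range,
so they are rarely worth tuning.

## Transfer scenarios and the split protocol

Two scenarios are supported. *Unsupervised*: no target labels; target clips
participate only as unlabeled data for the adaptation terms (transductive
use — disable with `transductive = FALSE`, which also disables adaptation
for lack of unlabeled input). *Semi-supervised*: for each target subject and
each class, the chronologically first \(l\%\) of clips (ceiling rounding,
\(l \in \{5, 10, 15, 20\}\)) join the labeled pool; everything after them is
test data. Splitting per class and per subject chronologically guards
against temporal leakage: no test clip of a subject precedes a labeled clip
of the same subject and class. Evaluation averages AUC over subjects within
a repeat, then reports mean ± SD over three repeats with consecutive seeds
(subjects lacking a test class are skipped with a warning, not imputed).

## Training protocol and numerical choices

* Adam, learning rate 1e-3, no weight decay; batches of 64 per domain;
  50 epochs by default. The synthetic benchmark below uses 6 epochs — at
  its data sizes the objective has long converged, and the shorter budget
  keeps a full 15-model ablation affordable on one CPU.
* Each step draws a labeled batch (source, plus target-labeled clips in the
  semi-supervised scenario) and an independent unlabeled target batch; the
  teacher pass uses batch statistics and is excluded from running-statistic
  updates.
* Batch-norm backward differentiates through the batch statistics; all
  gradients (convolutions, batch norm, ELU, pooling, projection, all three
  losses) are verified against central finite differences in the test
  suite.
* With `deterministic = TRUE` every source of randomness (initialization,
  shuffling, batch sampling, dropout masks) comes from one seeded R RNG
  stream, so two runs with the same seed produce bit-identical parameters
  and evaluations.
* Domains with different sampling rates are resampled to the *lower* rate
  before modeling (never fabricating high-frequency content), by Fourier
  resampling with exact output length `round(T * to/from)`. Band-pass
  preprocessing is a zero-phase 4th-order Butterworth (0.5-70 Hz default)
  after per-channel DC removal; an optional mains notch is off by default.
* Clip segmentation uses half-open windows, 0-based sample indexing, drops
  the trailing remainder, and labels boundary clips by majority overlap
  with the seizure annotations — exact ties are labeled seizure, favoring
  sensitivity.

## The synthetic benchmark

Real cross-species corpora are large, access-controlled downloads, so the
package ships a generator that reproduces the *structure* of the transfer
problem at desk scale. Two domains share one latent seizure process:
`n_latent = 4` sources of unit-variance pink (1/f) noise; in seizure clips
(30% of clips) half the sources additionally carry a 15-25 Hz sinusoidal
burst with random frequency, phase and raised-cosine envelope. The
oscillation amplitude is `seizure_gain - 1` background-SDs and the carrier
sources are rescaled by `seizure_gain` (default 3), so ictal clips show
both the elevated amplitude and the band-power excess that make seizures
recognizable in time and frequency domain, and weaker gains grade smoothly
into the background (the latent band-power oracle's AUC rises strictly with
the gain). Each subject owns a fixed random lead field — standard-normal
mixing scaled by a log-normal per-subject recording gain (log-SD 0.8) and
per-channel electrode sensitivities (log-SD 0.5) — and sensor noise is
added at 10 dB SNR. The source domain records 16 channels at 400 Hz, the
target 6 channels at 256 Hz; 4 subjects x 200 one-second clips per domain.

The per-subject amplitude heterogeneity is what makes the benchmark
honest: without it, clip variance transfers across montages unchanged and
every baseline saturates. With it, the alignment-free source-only model
degrades measurably while EA removes the heterogeneity exactly — the same
mechanism that motivates per-subject alignment on real recordings.

What the generator does *not* emulate: spike-wave morphology, ictal
evolution and propagation, artifacts, electrode drift, inter-ictal
discharges, or any biophysical head geometry. Passing the benchmark
therefore shows that the pipeline's alignments compose and recover a
transferable signal under montage, rate and gain heterogeneity — not that
it reaches clinical performance on real iEEG. One further honesty note:
real ictal EEG shows *increased* approximate entropy during seizures; this
generator's sinusoidal bursts are more regular than its pink background, so
its ApEn contrast runs in the opposite direction. The generator guarantees
the amplitude/band-power contrast only, and the QC tooling reports ApEn
empirically rather than asserting a direction.

## The benchmark ladder

`run_transfer_benchmark()` regenerates the data per seed and trains five
variants with a shared budget: `none` (projection only), `ea` (+ Euclidean
alignment), `ea_da` (+ MCC), `msa` (+ distillation; the full model), and
`trunc_source_only` (truncation, no alignment at all). Three seeds, 6
epochs, ~5 minutes on one CPU. The package's acceptance checks assert the
orderings a working implementation must show: the full model's mean target
AUC, its paired advantage over the alignment-free baseline, and a ladder
that never falls by more than one standard deviation between rungs.

## Limitations

* The backbone is one fixed compact architecture; no deeper variants.
* The projection is linear; nonlinear channel mappings are out of scope.
* Only MCC and MMD adaptation losses and logit/channel-wise distillation
  are implemented; other DA/KD families are not.
* Training is CPU-only and sized for hundreds-of-clips problems; real
  multi-hour corpora need longer budgets than the defaults.
* EDF import handles single-rate recordings with an external annotation
  CSV; vendor-specific folder layouts need custom adapters.
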
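---
title: "Generative augmentation of 1-D Raman spectra: models and methods"
author: "RamanForge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative augmentation of 1-D Raman spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RamanForge)
```

## The problem

Detectors for hazardous compounds increasingly rely on machine-learning
classifiers over Raman spectra, but real spectra of such compounds are scarce:
acquisition is dangerous, expensive, and often restricted to a handful of
measurements per substance.  Training a classifier on a few spectra —
or on the same few spectra duplicated — yields brittle models.  RamanForge
implements a generative augmentation system that turns a handful of seed
spectra into an arbitrarily large, diverse, realistic library, and that can be
trained either centrally or across decentralized nodes that never exchange
raw data.

The system composes five stages, each of which exists to fix a concrete
failure mode of the stage before it:

1. **DA — random-transformation augmentation.**  A generative adversarial
   network trained on one or two spectra collapses onto them; its samples are
   near-duplicates.  Jittering (additive Gaussian noise whose standard
   deviation is itself drawn uniformly from $[0, \sigma_{\max}]$ per copy) and
   horizontal shifting (an integer displacement drawn uniformly from
   $[-s, s]$ channels, vacated channels set to zero) expand the seeds into
   hundreds of distinct training spectra.  These two transforms mimic the two
   dominant environmental perturbations of Raman measurements: detector noise
   and calibration drift of peak positions.
2. **ZP — zero padding.**  Spectra end discontinuously, and a convolutional
   generator produces soaring artifacts at the signal ends.  Padding each end
   with $P$ zero channels before training moves those artifacts into a
   disposable region.
3. **GAN — a 1-D Wasserstein GAN** mass-produces new spectra (below).
4. **DAE — a convolutional denoising autoencoder** removes the noise that the
   GAN amplifies from the jittered training data (below).
5. **RZP — padding removal** cuts $P$ channels from each end of every
   generated spectrum, discarding the endpoint artifacts unseen.

The full composition is written `DA-ZP-GAN-DAE-RZP`; `runAblation()` scores
any subset against reference data with the three indices described below, one
row per composition, the classical ablation layout.

## The Wasserstein GAN

The critic $D$ maps a length-$N$ spectrum (channels $\times$ 1) through five
bias-free 1-D convolutions with channel ladder
$1 \to b \to 2b \to 4b \to 8b \to 1$ ($b = 64$ canonically).  Layers 1–4 use
kernel 4, stride 2, padding 1, each halving the length exactly; layer 5 uses
kernel $N/16$ and collapses the remaining signal to a single unbounded score.
Batch normalization follows layers 2–4 and leaky rectifiers (slope 0.2, the
DCGAN convention) follow layers 1–4.  The generator $G$ mirrors this with
transposed convolutions: a noise code $z \in \mathbb{R}^{100}$ of length 1 is
expanded by a kernel-$N/16$ layer to $8b$ channels of length $N/16$, then four
stride-2 layers double the length back to $N$ while narrowing to one channel,
ending in a hyperbolic tangent.  Because the critic's first layer and the
generator's last layer are agnostic to $N$, the same architecture serves any
input length divisible by 16 — $N$ enters only through the two kernel-$N/16$
layers.

Training minimizes the Wasserstein objective: the critic's loss is
$-(\bar{D}(x_{\text{real}}) - \bar{D}(G(z)))$ and the generator's is
$-\bar{D}(G(z))$, with five critic updates per generator update, RMSprop at
learning rate $10^{-4}$, batch size 8, and every critic parameter clipped into
$[-0.01, 0.01]$ after each update — the weight-clipping scheme that keeps the
critic approximately 1-Lipschitz so its score gap estimates an earth-mover
distance.  Spectra are min-max normalized to $[0,1]$ at generation and
linearly mapped to $[-1,1]$ for training to match the tanh output; samples are
mapped back to $[0,1]$.

Two counting conventions matter when comparing layer parameter tables:
convolutions in the GAN are bias-free (their printed counts equal
$C_{in} C_{out} K$ exactly), and batch-norm layers contribute only their
scale/offset pairs ($2C$); running statistics are buffers, not trainable
scalars.  `layerParameters()` exposes the per-layer breakdown:

```{r}
cfg <- ganConfig(datasize = 2688, noise_size = 100, epochs = 1)
layerParameters(buildCritic(cfg))
```

## The denoising autoencoder

The DAE is deliberately small: encoder convolutions $1\to4\to16\to32$ and
decoder transposed convolutions $32\to16\to4\to1$, all kernel 4, stride 1,
*with* bias, rectifiers between layers and a linear output (so denoised
intensities are not clipped).  Each encoder layer shortens the signal by 3
channels and each decoder layer restores 3, so output length equals input
length for any input longer than 9 channels.  Training corrupts clean spectra
with additive Gaussian noise ($\tilde{x} = x + \varepsilon$,
$\varepsilon \sim \mathcal{N}(0, \sigma^2 I)$) and minimizes the mean squared
reconstruction error against the clean original with Adam at $10^{-3}$, batch
size 10.  The corruption level defaults to the jitter bound
$\sigma_{\max} = 0.01$ because the jitter noise — amplified by the GAN — is
precisely what the DAE must remove.  The DAE is trained on clean seed spectra
with synthetic corruption (not on GAN outputs, for which no clean target
exists), cycled to the augmentation count and padded to whatever length it
will see at generation time.

## Federated training

`runFederatedTraining()` simulates federated averaging: one global model is
broadcast to $n$ nodes ("troops"), each runs its model's own local training
loop (the GAN's or DAE's, unchanged) on its private spectra for one epoch per
round, and the server aggregates parameters by the sample-count-weighted mean
$\theta_G = \sum_i (s_i / s)\, \theta_{L_i}$, generator and critic averaged
separately.  The aggregation is computed as
$\theta_1 + \sum_i w_i (\theta_i - \theta_1)$ — algebraically identical, but
exactly the identity when all locals agree, so the fixed-point property holds
to the last bit.  Three deliberate choices:

* **Local optimizer state persists** across rounds at each troop.  RMSprop
  and Adam moments are statistics of the local gradient stream; resetting or
  averaging them each round would change single-node training, and keeping
  them local makes a one-troop federation *bitwise identical* to centralized
  training — a property the test suite asserts.
* **Batch-norm running statistics** are aggregated with the same weights as
  trainable parameters (they are needed to sample from the global model) but
  are never counted as parameters.
* **One round = one local epoch**, making round counts directly comparable to
  centralized epoch counts.
* The server-side function accepts only parameter containers and sample
  counts; handing it anything else (for example a `SpectrumSet`) is an error.
  Spectra never leave the troop objects — the no-raw-data contract, enforced
  by the interface.

## Evaluation indices

`evaluateGeneration()` reports three complementary indices.  The squared
Fréchet distance between Gaussians fitted to the real and generated sets,
$d^2 = \lVert m - m_w \rVert^2 + \mathrm{Tr}(C + C_w - 2(C C_w)^{1/2})$, is
computed directly on spectrum vectors — no embedding network — with a ridge
$10^{-6} I$ on both covariances so the matrix square root stays well-posed
when channels outnumber samples; an optional principal-component projection
(`fid_dims`) is available for extreme cases.  The square root uses the
symmetric form $\sqrt{C}\, C_w \sqrt{C}$ via eigendecompositions, with tiny
negative eigenvalues from round-off clipped to zero, making the result
non-negative and symmetric in its arguments; the squared distance is reported
as is, without taking a root.  Pearson correlation and Euclidean distance are
averaged over generated spectra, each compared against the *mean* real
spectrum — a pairing-free convention that needs no assignment between the two
sets.

## The synthetic spectrum generator

Real chemical-agent spectra cannot be shipped with a package, so every
experiment runs on synthetic stand-ins: sparse sets of Lorentzian peaks (the
natural Raman lineshape; Gaussian kernels optional) with randomized centers,
amplitudes, and half-widths at half-maximum, on a smooth three-term
random-coefficient cosine baseline, plus iid Gaussian channel noise, min-max
normalized to $[0,1]$.  Classes drawn by `makeClassLibrary()` are re-sampled
until no two classes share more than half of their peak centers to within
±2 channels, keeping them as distinguishable as chemically distinct compounds.
`makeDataset()` freezes one template per class (peaks + baseline) and adds
fresh noise per replicate, so noiseless replicates are identical by
construction.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: fluorescence baseline drift, instrument
response functions, cosmic-ray spikes, wavelength-dependent noise, and any
compound-specific lineshape detail.  The tests establish that the *system*
behaves as designed (diversity from augmentation, denoising gain, artifact
removal, federated speed-up), not that any specific chemical is modeled.

## Canonical sizes and the scaled-down study conditions

The canonical spectrum length is $L = 2688$ channels: it is the unique length
consistent with the fixed architecture's two length-dependent layer sizes
($512 \cdot L/16 = 86{,}016$ and $100 \cdot 512 \cdot L/16 = 8{,}601{,}600$),
and with $P = 64$ padded channels per end the training length becomes
$2816 = 2688 + 128$, divisible by 16 as the four halvings require.  $P$ itself
is a free choice; 64 channels comfortably covers the few-channel endpoint
artifacts while sacrificing under 5% of the grid.

The behavioral experiments (in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) run at a reduced problem size chosen once for
single-CPU practicality: spectrum length $L = 256$, padding $P = 16$ where
used, network width $b = 16$ (the same $1\!-\!b\!-\!2b\!-\!4b\!-\!8b\!-\!1$
ladder), 100 training spectra, and epoch budgets given in each experiment.
Two findings from sizing runs shaped those experiments:

* **Diversity comparisons must match gradient steps, not epochs.**  One epoch
  over a single seed spectrum is one optimizer step; one epoch over 100
  augmented spectra is 13.  At equal steps the single-seed model converges
  onto its one spectrum and its sample diversity collapses, which is the
  overfitting phenomenon the augmentation stage exists to fix.
* **Held-out test spectra must carry the variation the system targets.**
  The classifier comparison (duplicated seeds vs generated spectra) uses
  test spectra with fresh noise *and* random peak drift within ±10 channels
  — the real-world variation the augmentation emulates.  On drift-free test
  data the duplicated arm's memorization is optimal by construction and the
  comparison degenerates.  Even with drift, these synthetic classes are
  separable enough that a classifier trained on two duplicated seeds can
  sit at the accuracy ceiling; the comparison is therefore reported
  alongside the diversity mechanism itself (zero within-class training
  variance in the duplicated arm, strictly positive in the generated arm).
* **Shift augmentation caps template correlation.**  Shifting smears peaks
  over ±10 channels, so a generator trained on shifted data converges to a
  smeared mean whose correlation with the sharp template plateaus well below
  what jitter-only training reaches.  The federated-vs-centralized
  convergence race therefore uses jitter-only augmentation, where a 0.9
  correlation threshold is attainable by both arms and the comparison
  measures training speed rather than the smearing confound.

## Numerical choices

* Weight initialization: $\mathcal{N}(0, 0.02)$ for GAN convolutions and
  $\mathcal{N}(1, 0.02)/0$ for batch-norm scale/offset (DCGAN convention);
  uniform $\pm 1/\sqrt{\text{fan-in}}$ for the biased DAE/classifier layers.
* Batch-norm: $\varepsilon = 10^{-5}$, momentum 0.1, biased variance for
  normalization, unbiased for the running estimate; evaluation mode (used by
  `sampleGenerator()` and `denoise()`) applies running statistics, so
  sampling is batch-size-invariant and deterministic.
* Every training entry point consumes one integer seed and restores the
  caller's RNG state; training states carry their own RNG stream so resumed
  training continues the exact stream — the basis of the federated
  equivalence guarantee.
* Convolution forward/backward passes, batch normalization and the two
  optimizers are implemented as compiled kernels (`src/conv1d.cpp`) beneath
  hand-derived backpropagation; the test suite checks every layer type
  against central-difference numerical gradients at $10^{-6}$ absolute
  tolerance.
* The epoch is one pass of $\lceil n / \text{batch} \rceil$ outer steps;
  critic batches are drawn uniformly with replacement only when the dataset
  is smaller than the batch.

## Known limitations

* Weight clipping is the original Lipschitz device and is kept for fidelity;
  gradient-penalty or spectral-norm critics generally train more stably and
  would be the first upgrade.
* The federation is simulated in-process: no transport, encryption,
  stragglers, or client sampling.
* Raw-vector Fréchet distances on $L \times L$ covariances are only as
  meaningful as the ridge makes them when samples are few; report them for
  comparisons under a fixed protocol, not as absolute quality numbers.
* The classifier study demonstrates a qualitative ordering (generated-data
  training is at least as good as duplicated-seed training) on synthetic
  classes; it makes no claim about real chemical-agent classification.
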
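---
title: "WaveFusion methods: subject-aware contrastive fusion for multi-lead EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{WaveFusion methods: subject-aware contrastive fusion for multi-lead EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavefusion)
```

## The problem and the model

Binary cognitive conditions (for instance low versus high decision
confidence) leave weak, spatially structured traces in the EEG
time–frequency plane — most prominently in posterior alpha-band (8–13 Hz)
power. `wavefusion` classifies such conditions from multi-lead epochs with a
late-fusion architecture:

1. **Per-lead spectrograms.** Each 1-second epoch, resampled to 100 Hz, is
   transformed into a 39 × 11 magnitude spectrogram per lead (short-time
   Fourier transform, details below). Only the 17 posterior leads (parietal,
   parieto-occipital, occipital) enter the model, giving a 17 × 39 × 11
   input tensor.
2. **Lightweight per-lead CNNs (LWCNNs).** Each lead owns a three-stage
   convolutional branch (16, 16, 32 channels; kernels 5×4, 4×2, 2×2; strides
   2×1, 2×1, 1×1; zero padding 2×1 on stage 1 only; 2×2 max-pooling after
   stages 1–2; 10% dropout after each stage; batch normalisation after
   stages 2–3). The stage order inside a branch is convolution → ReLU →
   pool → dropout → batch-norm, and the shape chain is
   39×11 → 16×20×10 → 16×10×5 → 16×4×4 → 16×2×2 → 32×1×1, so every lead
   yields a 32-vector. Padding on stages 2–3 is zero because that is the
   unique setting under which this chain closes.
3. **Squeeze-and-excite attention (SEN).** The 17 × 32 feature matrix is
   globally averaged per lead, squeezed through a 17 → 5 dense bottleneck
   (ReLU) and expanded back 5 → 17. The expansion pre-activations $a_i$ pass
   through a *temperature-flattened sigmoid*
   $$\pi_i = \frac{e^{a_i/\tau}}{e^{a_i/\tau} + 1},$$
   so $\pi_i \in (0,1)$ and, as $\tau \to \infty$, every weight approaches
   0.5. The flattening prevents the attention module from collapsing onto a
   few leads early in training; because the weights live on a common (0,1)
   scale they double as an interpretable measure of per-lead influence.
4. **Fusion encoder.** Each lead's 32-vector is scaled by its attention
   weight, the 17 scaled vectors are flattened to a 544-vector (lead index
   fastest — a fixed documented order; any fixed order is equivalent up to a
   permutation of the dense weights) and mapped by one dense layer to a
   128-d representation $r$. No nonlinearity follows this layer (a
   deliberate choice; the contrastive geometry lives on the projection
   sphere, and a linear read-out keeps the classifier head's job simple).
5. **Heads.** During pretraining a projection head maps $r$ to a 32-vector
   normalised onto the unit sphere, so dot products are cosine
   similarities. For classification the projection head is dropped and a
   2-node dense layer produces softmax logits.

## Subject-aware contrastive pretraining

A batch of $N$ samples yields $2N$ augmented views (two per sample, labels
inherited). For an anchor view $i$ with condition $y_1$ and subject $y_2$:

* **positives** $Q(i)$: other views with the *same subject and the same
  condition*;
* **intra-subject negatives** $N_a(i)$: same subject, opposite condition;
* **inter-subject negatives** $N_r(i)$: different subject, opposite
  condition.

The subject-aware contrastive (SAC) loss is
$$\mathcal{L} = -\sum_i \log\!\left(\frac{1}{|Q(i)|}\sum_{q \in Q(i)}
\frac{e^{z_i \cdot z_q/\tau}}{\sum_{s \in S(i)} e^{z_i \cdot z_s/\tau}}\right),
\qquad S(i) = N_a(i) \cup N_r(i).$$

Two properties of this form deserve emphasis, because they differ from the
standard supervised-contrastive (SupCon) loss that the package also
implements as a baseline:

* the **denominator contains negatives only** (SupCon sums over all
  non-anchor views), so the loss is not bounded below by zero — with a
  perfect positive and distant negatives the per-anchor term goes negative;
* the **mean over positives sits inside the logarithm** (SupCon's reference
  form puts it outside).

We implement the SAC form exactly as defined and keep the conventional
definition for the SupCon baseline. Same-condition views from *other*
subjects fall in neither set: they are simply absent from an anchor's term,
which is the mechanism by which subject heterogeneity is prevented from
polluting the condition contrast. Anchors with an empty positive or
negative set are skipped with a warning and excluded from the averaging
denominator; a batch in which every anchor is skipped raises a training
error. For optimisation we use the mean over valid anchors (the sum form is
reported by `sac_loss(..., reduce = "sum")`), which keeps the learning rate
meaningful across batch sizes. Exponentials are evaluated with per-anchor
max-subtraction.

**Batch composition.** Batches are keyed to one (subject, condition) pair.
The composition — fractions of positives, intra-subject negatives and
inter-subject negatives — is configurable, with presets named after their
percentage triples; the best-performing scheme is `"50/0/50"` (half
positives, half intra-subject negatives, none inter-subject) and the default
batch size is 500 at protocol scale. Fractions must produce integer counts
at the configured batch size; the validator rejects the 12.5%/37.5% presets
at size 500 for that reason (they are integral at 496 or 1000). One epoch
cycles every (subject, condition) key and partitions that key's samples into
positive blocks, so each training sample serves in the positive/anchor role
exactly once per epoch; a final short block is topped up by re-drawing from
the same key.

**Augmentation.** Views are built on the spectrogram tensors (not the raw
signals): additive 1/f-shaped "pink" noise along the frequency axis,
additive white Gaussian noise, and multiplicative input dropout. The two
noise amplitudes are expressed relative to the tensor RMS (defaults 0.1 and
0.05) and the dropout rate defaults to 0.1. The defaults are calibration
choices — mild enough to preserve the band-power structure, strong enough
that the two views of a sample differ.

**Training protocol.** Pretraining runs plain SGD for 25 epochs at a fixed
learning rate of 0.05 with loss temperature τ = 0.25. The pretrained
backbone (CNNs, attention, encoder, batch-norm statistics) is transferred
bit-exactly to a classifier model whose 2-node head is freshly initialised;
fine-tuning uses Adam at learning rate 1e-4 for 150 epochs with weight
decay (default 7e-3, grid-searchable with ties broken toward the smallest
value) and *no augmentation*. The attention temperature τ_attn defaults to
1.0 and is exposed for sweeps. Initialisation is Kaiming-uniform with zero
biases, seeded; all stochastic steps (initialisation, batching, dropout,
augmentation) derive per-stream seeds from one master seed, so every run is
bit-reproducible on CPU.

## The synthetic-data generator

No public recording set accompanies the method, so the package ships a
generator that emulates the statistical structure the model assumes — it is
first-class, tested code, and it doubles as the calibration instrument for
every downstream claim. Per subject, each trial is the sum of

* sinusoids at a fixed frequency grid (2–30 Hz by 2) with random phases and
  per-subject log-normal amplitude fingerprints (the heterogeneity the
  subject-aware loss exploits),
* a class-dependent multiplicative *power* modulation (`class_effect`,
  applied to the amplitude as its square root) confined to a configurable
  band (default 8–13 Hz) and lead subset (default: the posterior montage),
* broadband 1/f Gaussian noise of configurable scale.

A sum-of-sinusoids model was chosen over autoregressive alternatives
because its band powers are analytically controllable: `class_effect = 1`
makes the two conditions identically distributed (verified by permutation
and type-I-rate tests), and `class_effect = 3` with small noise gives a
band-power two-sample test power above 0.9 at 100 trials per class
(verified by Monte-Carlo). Seeding derives one stream per subject, so
adding a subject never perturbs the others.

What the generator does **not** emulate: volume conduction and realistic
lead-field mixing, event-related potential morphology, artifacts (blinks,
muscle), non-stationarity within an epoch, and realistic inter-subject
variability structure (the fingerprints are i.i.d. log-normal draws, a
calibration choice — the method's source material gives no quantitative
heterogeneity description). Tests passing on this generator therefore
certify the *mechanics* of the pipeline and the *direction* of its effects,
not clinical-grade performance on real EEG.

The `easy_dataset()` benchmark (10 subjects × 40 trials) confines the class
effect to five focal leads (P7, P6, PO7, PO8, Oz) out of the 17 in the
tensor; without null leads inside the tensor the attention-localisation
claim would be untestable.

## Preprocessing choices

* **Bootstrap averaging.** Weak single-trial effects are amplified by
  averaging 25 randomly chosen same-condition trials per draw (without
  replacement within a draw, with replacement across draws), emitting 500
  averaged trials per condition — 1000 per subject at protocol scale.
* **Truncation/resampling.** Epochs are cut to a 1-second window and
  resampled to 100 Hz through an anti-aliasing FIR decimator
  (`signal::decimate`; polyphase resampling for non-integer ratios).
* **STFT dialect.** The target 39 × 11 spectrogram cannot be produced from
  a 100-sample signal under textbook window/overlap conventions, so the
  default is pinned explicitly: Hann window of 80 samples, hop 10,
  symmetric zero padding of 40 samples at each end, keeping DFT bins 1–39
  (1.25–48.75 Hz; DC and Nyquist dropped). Every element is configurable
  through `stft_config()`. Magnitude (not power, not dB) is used — the
  fixed convolutional front-end is scale-sensitive, and magnitude keeps the
  dynamic range moderate without an extra calibration constant.
* **Posterior lead set.** The 17 default leads are the standard 10-10
  parietal/parieto-occipital/occipital labels (shipped as an editable
  montage CSV); tensor assembly stacks exactly these leads in their
  documented order regardless of input order.
* **Normalisation.** None by default; optional per-tensor z-scoring sits
  behind `normalize = TRUE`.

## Interpretability

`extract_attention()` returns the 17 inference-time attention weights;
`interpolate_topomap()` spreads them over the unit-disk scalp. The default
interpolant is a thin-plate spline (node-exact) with the surface clipped to
the observed value range — raw thin-plate surfaces overshoot, and a
topographic display of weights bounded in (0,1) should stay within the data
range; inverse-distance weighting is available as a strictly
range-respecting alternative (and reproduces the two-electrode midpoint
mean exactly).

Class activation maps: the final convolution output of a branch is
32 × 1 × 1, which makes the classic CAM construction degenerate (no spatial
extent). Maps are therefore gradient-weighted CAMs at the last spatially
extended layer — the 4 × 4 stage-2 activation — rectified, bilinearly
upsampled to 39 × 11 and max-normalised. An identically zero rectified map
is returned as all-zeros with a note rather than an error.

## Numerical and engineering choices

All forward and backward passes are hand-written vectorised R (im2col
convolutions; the whole default model has ~152k parameters, orders of
magnitude below contemporary CNN backbones). Gradients of every layer are
verified against central finite differences at 64-bit precision in the test
suite, and the SAC/SupCon losses against brute-force nested-loop oracles.
Max-pooling breaks ties by first match in a fixed scan order; batch
normalisation uses momentum 0.1, ε = 1e-5, biased batch variance, and
running statistics in inference mode; projection normalisation guards a
zero-norm embedding with an error at 1e-12.

Scales used by the shipped tests are deliberate package choices: the
directional pretraining-benefit experiment runs 5 seeds of the easy
10-subject × 40-trial benchmark with 3 pretraining and 15 fine-tuning
epochs, batch 20 — enough for both arms to reach high accuracy while
keeping the full suite desk-sized. The `"tiny"` pipeline preset (2 subjects
× 20 trials) exists purely as an end-to-end smoke configuration, and the
`"paper"` preset reproduces the protocol scale (bootstrap averaging to 1000
samples per subject, batch 500, 25 + 150 epochs).

## Known limitations

* Per-class "accuracy" is reported as per-class recall — the only reading
  under which the two classes can differ on a shared test set.
* The pretraining scheduler's exact batch-keying is one defensible reading
  of "each sample serves as the anchor"; alternatives (anchor-only batches,
  forced inclusion of both views of the anchor's source) exist and are not
  implemented.
* Attention weights localise *influence on the model*, not neural sources;
  no inverse modelling is attempted, and the scalp rendering is 2-D only.
* Training is CPU-bound R; protocol-scale runs (batch 500, 175 total
  epochs) are hours-long. The architecture is small enough that this is a
  practical ceiling rather than a correctness one.
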
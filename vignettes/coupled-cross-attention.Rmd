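---
title: "Decoding speech classes from EEG with hierarchical coupled cross-attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding speech classes from EEG with hierarchical coupled cross-attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The decoding problem

An imagined-speech brain-computer interface records a multichannel EEG trial
$x \in \mathbb{R}^{ch \times t}$ while a subject silently produces one of $m$
words, and must recover the word from the trial. The discriminative
information is weak, distributed over electrodes (spatial topography) and
over time (oscillatory dynamics), and — critically — the two views are
coupled: which electrodes matter depends on when you look, and vice versa.
Classical convolutional decoders extract spatial and temporal features
separately and merge them by summation or concatenation, which cannot
represent this coupling.

`eegcca` implements a hierarchical network that addresses this directly,
together with the complete experimental harness (synthetic data,
preprocessing, cross-validated training, ablations, robustness probes)
needed to study it end to end.

## The model

The network has three stages, each exposed as ordinary R functions so every
piece can be inspected and tested in isolation.

**Local feature extraction (LFEM).** Two parallel convolutional pathways
process the raw trial plane. The temporal-first pathway applies a
$1 \times \lfloor fs/10 \rfloor$ convolution along time and then a
$\lfloor ch/2 \rfloor \times 1$ convolution across electrodes; the
spatial-first pathway applies the same two kernels in the opposite order.
Each pathway is, literally,

$$f_t = \mathrm{AvgPool}_{4\times4}\!\big(\mathrm{ELU}(\mathrm{BN}(\mathrm{Conv}_2(\mathrm{Conv}_1(x))))\big),$$

with one batch-norm after the second convolution (the composition is applied
in exactly this nesting, not one batch-norm per convolution), valid
convolutions with stride 1 and no bias (batch norm absorbs it), and
average pooling with a $(4,4)$ window and stride equal to the window. The
pooled map is flattened row-major and resampled along the position axis to a
fixed-length sequence of 512 positions $\times$ $k$ features (see *Numerical
choices* for the resampling operator). Both pathways give identically shaped
sequences for every supported input geometry.

**Coupled cross-attention (CCA).** Scaled dot-product attention
$\mathrm{Atten}(Q,K,V) = \mathrm{softmax}(QK^\top/\sqrt{d_k})\,V$ is applied
in both directions between the temporal sequence $f_t$ and the spatial
sequence $f_s$, each direction with its own query/key/value projections
($k \to k$ affine maps, biases enabled):

$$f_{ts} = \mathrm{Atten}(f_t, f_s, f_s), \qquad
  f_{st} = \mathrm{Atten}(f_s, f_t, f_t),$$

and the two results are combined with learnable unconstrained scalar weights
followed by layer normalisation over the feature axis:
$f_{fusion} = \mathrm{LN}(\alpha f_{ts} + \beta f_{st})$. Both scalars start
at 1 (a symmetric start; nothing in the architecture breaks the symmetry
except the data). No positional encoding is used anywhere, so attention is
invariant to permuting key/value positions — a property the test suite
checks explicitly.

**Global feature extraction (GFEM) and classification.** Multi-head
self-attention over the fused sequence: the feature axis is split into $h$
heads of width $k/h$, each head runs scaled dot-product attention with its
own slice of the $k \to k$ query/key/value projections, head outputs are
concatenated and passed through a $k \to k$ output projection (standard
multi-head practice; the concatenation-only reading is recovered by setting
that projection to the identity). The classifier flattens the
$512 \times k$ result, applies dropout, a hidden affine layer
(width `fc_hidden`) with ELU, dropout again, and a final affine map to $m$
logits; the prediction is the argmax, lowest index on ties.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `k` | feature width of every stage | 32 | reference architecture width; acceptance runs use 16 to cut compute |
| `h` | self-attention heads | 4 | must divide `k` |
| `seq_len` | internal sequence length | 512 | fixed sequence-length contract between stages |
| `fc_hidden` | classifier hidden width | 256 | the head is otherwise unspecified; exposed in config |
| `dropout` | classifier dropout | 0.3 | active during training only |
| `epochs` | training epochs | 200 | reference protocol; separable synthetic data converges within ~10 |
| `learning_rate` | Adam base rate | 1e-3 | Adam convention; unreported in the reference protocol |
| `lr_step`, `lr_gamma` | schedule | 50, 0.5 | rate halves every 50 epochs: $lr(e)=lr_0 \cdot 0.5^{\lfloor e/50\rfloor}$ |
| `batch_size` | mini-batch size | 32 | unreported; conventional default |

Kernel sizes are derived, not configured: `fs/10` and `ch/2` are read as
floor divisions (all reference geometries divide evenly or nearly so).

## The synthetic generator: what it emulates and what it does not

Real imagined-speech EEG is unavailable offline, and no generative model of
these signals exists, so the package ships a class-conditioned simulator
whose distributional choices are deliberate stand-ins. Each class owns a
unit-norm spatial mixing vector over channels and a Hann-windowed sinusoidal
burst (class-specific frequency, spaced $\ge 2$ Hz apart inside 4–30 Hz, and
class-specific latency, ~10 µV peak); a trial is the rank-one outer product
of the two, scaled by a global gain, plus 1/f ("pink") background noise per
channel with a channel-correlated common-mode component. The gain is solved
so the realised mean per-trial SNR equals the configured value exactly.

The `coupling` knob controls where class information lives. At
`coupling = 0` each class has a unique topography and a unique waveform, so
either marginal view decodes. At `coupling = 1` topographies are shared
across one pairing of the classes and waveforms across the complementary
pairing — each view alone resolves only a pair, and only their combination
identifies the class. This is precisely the regime where a coupled fusion
mechanism should earn its keep, and it is the benchmark condition for the
end-to-end acceptance checks (SNR 10, coupling 1, 4 classes).

What the simulator does **not** emulate: volume-conduction forward models,
ocular/muscle artifacts, non-stationarity across a session, inter-subject
variability of topographies, and the tiny effect sizes of real inner speech
(real decoding sits near 25–45% for 4 classes; the synthetic benchmark is
deliberately separable). Passing the synthetic recovery test therefore
demonstrates that the implementation can learn coupled spatial-temporal
structure — it says nothing about real-data accuracy.

## Preprocessing

The conditioning chain mirrors standard EEG practice: optional
re-referencing (mean of a reference channel set subtracted everywhere),
zero-phase 4th-order Butterworth band-pass (default 0.5–100 Hz), zero-phase
biquad notch at 50 Hz with quality factor 30, and polyphase rational
resampling to the target rate with the new length `round(t * target/fs)`.
Zero-phase (forward-backward) filtering is used so class-informative
waveform latencies are not shifted; signals are mirror-padded before
filtering because high-Q notches ring far beyond the usual 3-order pad.
ICA-based artifact removal is deliberately out of scope — the pipeline
assumes pre-cleaned input, as artifact correction is a solved problem in
dedicated EEG toolchains.

Z-scoring is **not** part of `preprocess()`: its statistics (per-channel
mean and population standard deviation pooled over trials × time) depend on
the training split and are fitted inside the cross-validation loop only. A
leakage guard refuses to fit statistics on indices that overlap the test
set, and a perturbation test verifies the statistics are a pure function of
the training split.

## Training and implementation

Training minimises mean cross-entropy with Adam (β = 0.9/0.999) under the
stepped schedule, with seeded shuffling and dropout so a fixed seed
reproduces training bit-identically. Weights initialise from
$U(\pm 1/\sqrt{\mathrm{fan_in}})$; batch-norm tracks running statistics
(momentum 0.1) used at evaluation time.

There are deliberately two implementations of the forward pass. The R
functions (`temporal_pathway()`, `cross_attention_ts()`,
`multi_head_self_attention()`, `classify()`, …) are the readable reference:
plain matrix algebra, evaluation mode only. The compiled core
(RcppArmadillo) implements the batched forward pass and manual
backpropagation for all twelve variant × fusion combinations. The test
suite pins the two together — compiled evaluation logits match the composed
R forward pass to $10^{-10}$ for every combination — and checks the
analytic gradients against central finite differences. The training loop
runs the same templated code in single precision: the $512 \times 512$
attention matrices make the workload memory-bandwidth-bound, and halving
the element width roughly doubles throughput at a precision far below SGD
noise; prediction and the gradient interface stay in double precision.

## Numerical choices

* **Sequence resampling.** The mechanism that turns an $H \times W$ pooled
  map into exactly 512 positions is genuinely open; a learned projection
  would change the parameter count, so a parameter-free operator was chosen:
  the flattened positions are treated as a piecewise-constant function on
  $[0,1]$ and each output position takes its average over one of 512 equal
  intervals. This box-average is linear, reduces to the identity when
  $H\cdot W = 512$, and preserves the mean over positions exactly — unlike
  adaptive average pooling, whose overlapping windows distort the mean when
  upsampling.
* **Softmax** is computed with max-subtraction (shift-invariant within each
  row); layer/batch norm use $\epsilon = 10^{-5}$; the z-score floor is
  $10^{-8}$ so constant channels stay finite.
* **Ties** in the argmax resolve to the lowest class index; midrank ties in
  the signed-rank test are handled exactly by dynamic programming over
  doubled ranks (exact null for $n \le 25$, tie-corrected normal
  approximation with continuity correction beyond).
* **Fold assignment** deals shuffled class members round-robin, so per-class
  test counts across folds differ by at most one; the accuracy summary uses
  the population divisor over folds (mean ± σ with $1/n_{folds}$ inside the
  root).
* **Channel dropout** zero-fills `round(fraction * ch)` channels
  (round-half-even, at least one when the fraction is positive) rather than
  removing them, because the spatial kernel height $\lfloor ch/2 \rfloor$ is
  fixed at build time.

## Ablation machinery

`build_model()` accepts `variant` and `fusion` switches. `no_lfem` replaces
the convolutional front end by fixed box-resampling of the raw trial to 512
positions (time-major walk for the temporal stream, channel-major for the
spatial stream) plus a learned 1 → k width projection per stream — the
cheapest replacement that keeps the fusion stage's input contract intact, so
the ablation isolates the convolutions. `no_gfem` feeds the fused sequence
straight to the classifier. The fusion baselines are summation,
concatenation with a $2k \to k$ re-projection (keeping downstream shapes
fixed), and "standard attention": two softmax-normalised scalar weights from
a linear map of the position-pooled pair, applied as a convex combination.
The baselines skip the layer normalisation, which belongs to the coupled
fusion definition.

## Problem sizes used in the shipped checks

The acceptance runs use the coupled benchmark (4 classes × 50 trials, 8
channels, 256 samples at 256 Hz, SNR 10, coupling 1) with `k = 16` and 12
epochs under stratified five-fold cross-validation — separable data
converges well within that budget, and the permuted-label control is run
under the identical protocol. When the epoch budget is scaled down, the
schedule's *shape* is preserved rather than its absolute step length: the
reference protocol halves the learning rate at each quarter of the run, so
12 epochs use `lr_step = 3`. (Dropping the epoch count while leaving
`lr_step` at 50 silently removes the schedule, and the higher-capacity
attention fusion then converges more slowly than its parameter-free
baselines.) The fusion comparison uses the same benchmark with two folds,
three seeds and 16 epochs (`lr_step = 4`) — enough for every fusion
strategy to converge fully, so the comparison reflects the models rather
than the optimiser; on this deliberately separable generator the expected
outcome is a tie at ceiling, and the claim checked is directional
(coupled fusion is not beaten), not a magnitude. These sizes are the
package's choice of a desk-scale
experiment; the full reference protocol (k = 32, 200 epochs, `lr_step`
= 50) is available through the same configuration objects.

## Known limitations

* The classifier head width (`fc_hidden = 256`) is one defensible reading of
  "fully connected layers"; published parameter totals for this family of
  models are not recoverable from their descriptions and are not matched.
* The multiply-accumulate counter (`count_macs()`) is a rough orientation;
  FLOP conventions differ across papers and no comparison is attempted.
* Single-threaded CPU training only; at reference scale (128 channels,
  k = 32, 200 epochs) a GPU implementation is the right tool.
* EDF/BDF import is not included; trial sets enter through the plain-text
  container or the synthetic generator.
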
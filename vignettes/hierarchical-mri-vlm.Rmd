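---
title: "Hierarchical vision-language modeling of multi-sequence MRI studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical vision-language modeling of multi-sequence MRI studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

radclip models a radiology MRI *study* — a set of 3D acquisitions
("sequences", e.g. T1-weighted, FLAIR, DWI) plus its report — as a single
embedding vector, learned by aligning studies with their itemized report
text through a contrastive objective. This vignette records the model, its
assumptions, the tunable parameters and their defaults, the design choices
made where the design was genuinely open, and what the synthetic phantom
generator does and does not emulate.

## The model

The pipeline has three trained stages.

**1. Volume tokenization.** Each sequence is tiled into fixed-shape
subvolumes ("volume tokens"), zero-padded at the boundary, and each patch is
compressed by a vector-quantized autoencoder (VQ-VAE): a strided 3D
convolutional encoder maps the patch to a small latent grid, each latent
position is snapped to its nearest codebook vector in Euclidean norm (ties
to the lowest index), and a mirrored decoder reconstructs the patch. The
codec trains on an L1 reconstruction objective plus the standard
vector-quantization terms — a codebook term `||sg(z_e) - e||^2` and a
commitment term weighted 0.25 — with straight-through gradients. At full
scale patches are 32x32x4 voxels and latents 8x8x2 with 2 channels, a 16x
compression to a 256-dimensional token; the codebook holds 8192 vectors.
Background patches (fewer than 5% foreground voxels, where "foreground"
means above 5% of the volume's maximum intensity; both fractions
configurable) are removed before encoding. During codec training the image
axes of each batch are randomly permuted (one of the six orders per shape
bucket, uniformly) so the encoder is robust to acquisition plane and
orientation.

**2. Hierarchical encoding.** A sequence transformer attends over
`[register tokens | encoded sequence name | volume tokens]`, where each
token feature is its quantized latent concatenated with a 30-dim sinusoidal
encoding of its 3D grid coordinate (5 geometric frequency pairs per axis
over 0-based indices) and a 3-dim plane one-hot. The register outputs are
concatenated and linearly projected to the sequence representation `r_i`.
A study transformer then attends over `[study registers | encoded study
name | projected r_i]`; its register outputs concatenate into the study
vector. Position information enters only through explicit features, so both
levels are invariant to input order; one parameter set serves every
sequence. At full scale the sequence transformer has 15 layers with 16
64-dim heads (width 1024, 20 registers, `r_i` of length 1024) and the study
transformer 4 layers with 8 64-dim heads and 10 registers, giving a
10240-dim study vector. The printed head counts imply a 512-wide study
transformer; we bridge it to the 1024-wide representations with an input
projection and a per-register output projection, preserving both printed
facts. Sequence and study names pass through character-level transformer
encoders (case-folded, unknown characters to a reserved symbol); the
sequence-name encoder can be pre-trained contrastively against mean-pooled
token embeddings, the study-name encoder starts fresh.

**3. Joint training objective.** Study vectors and report embeddings (the
final-position hidden state of an autoregressive word-level language model
pre-trained on the report corpus) are projected to a shared space (128-dim
at full scale) and aligned with a symmetric CLIP loss: cosine-similarity
logits scaled by `exp(tau)` (`tau` trainable, initialized 0.07),
cross-entropy toward the diagonal in both retrieval directions, summed. A
patient sequence-discrimination loss additionally pulls the projected
`r_i` of the same study together: cosine logits between all sequence pairs
divided by a trainable temperature `tau_p` (init 0.1), self-logits set to
-10 with self pairs kept inside the positive mask (the executable
convention; the strict textbook variant is available via
`convention = "equation"`), each row contributing `-log` of its same-study
softmax mass weighted by `1/(k n_i)`. The combined loss is
`L = L_clip + lambda * L_patdis` with `lambda = 0.03`. Training augments
each drawn pair (finding-order shuffling 0.5, per-token drop 0.1, name
replacement with "unk" 0.1, per-sequence drop 0.1, background-threshold
jitter +-50%; all configurable) and upsamples abnormal studies fourfold per
epoch stream.

**Transfer.** With the encoder frozen, 3-layer MLP heads predict multi-hot
diagnoses and referrals (positive-weighted binary cross-entropy, weights =
exact negative/positive count ratios per label), three-tier acuity
(categorical cross-entropy) and age (L2). A 2-layer single-logit probe with
stratified 5-fold cross-validation serves as the generic transfer protocol.
Head inputs are standardized with training-split statistics and age targets
are standardized and de-standardized around the head; hidden width follows
`max(out_dim, in_dim/4)` with a floor of 16 so very low-dimensional
embeddings remain trainable. The checkpoint with the best validation metric
is returned (ties to the earliest epoch).

## Evaluation and audit components

Retrieval accuracy is the fraction of studies whose matched report ranks in
the top k of the similarity row (ties to the lowest index); the grouped
variant averages Top-1 within random disjoint groups of 100. Multi-label
AUROC is rank-based with midranks; single-class labels are excluded from
the mean with a warning. The normalized positive rate (NPR) of a query is
the positive rate among its 20 nearest reference neighbors divided by the
reference base rate; we use cosine distance in the study embedding space
and drop the query itself when the query set is the reference set. Under
random labels its expectation is 1. Priority scores are the
softmax-expected acuity class index rescaled to [0,1]; their agreement with
the three-tier truth is summarized by a Pearson correlation with a Fisher-z
interval (Spearman behind a flag).

LIME token attribution perturbs a single sequence by token *removal*
(dropped from the transformer input, not zeroed), evaluates the target
diagnosis logit for each of the sampled Bernoulli(0.5) masks (all-zero
masks resampled; the all-ones mask always included), and fits a
locality-weighted least-squares surrogate with the exponential kernel
`exp(-(1-s)^2 / 0.25^2)` on the cosine similarity `s` between mask and the
all-ones mask — the canonical kernel for binary masks; ridge is optional
and off by default. For any model affine in the mask the coefficients are
recovered exactly. Ranking ties break by lexicographic grid coordinate.

The fairness suite implements the equalized-opportunity criterion: subgroup
true-positive rate minus population TPR, in [-1, 1]. The bootstrap test
resamples `n` patients with replacement from the subgroup and `n`
diagnosis-matched patients from the population (population draws stratified
to reproduce the subgroup draw's label-pattern frequencies — the matching
algorithm is unspecified upstream, so pattern-frequency matching was
chosen), compares the two TPR distributions with a one-sided Mann-Whitney U
test, and repeats for 20 iterations. This procedure is well calibrated in
the regime it is meant for — bootstrap draws much smaller than the
subgroup, as in a health-system-scale cohort — and becomes anticonservative
when the draw size approaches the subgroup size, because the subgroup's own
sampling noise then exceeds the bootstrap spread; the test suite calibrates
it at cohort size 8000 with subgroups of 2500. Turnaround-time odds ratios
use the sample `(ad)/(bc)` with the Haldane-Anscombe 0.5 correction on zero
cells, a Woolf log-OR confidence interval and the exact conditional
two-sided Fisher p-value; family-wise correction across an attribute's
levels is Holm by default (Bonferroni available). The superiority-trial
sample-size calculator uses the standard two-group normal-approximation
formula with one-sided alpha.

## The synthetic phantom generator

Real training corpora for this kind of model are private, so every
component is exercised against a generator whose ground truth is known
exactly. A phantom "head" is an ellipsoid of tissue-like intensity with
paired ventricles whose CSF contrast depends on the sequence family
(bright on T2, dark on T1); four diagnosis classes plant distinct geometric
signatures, each visible only in a class-specific subset of contrast
families and at family-specific intensity levels:

| class | geometry | T1 | T2 | DWI |
|---|---|---|---|---|
| tumor | solid sphere | 0.85 | 1.3 | — |
| abscess | ring + core | rim 1.05, core 0.15 | — | rim 0.5, core 1.2 |
| ventriculomegaly | paired ellipsoid enlargement (x2.2) | CSF contrast | CSF contrast | CSF contrast |
| infarct | wedge | — | 0.7 | 0.95 |

Lesions are deliberately large (relative radius 0.18-0.28) and their levels
well separated: the generator makes no attempt at radiological realism —
the point is that class evidence is unambiguous and localized, so that
token attribution and transfer learning have a known target. Magnitude
noise is the absolute value of a complex Gaussian (Rician-approximating,
matching MRI magnitude statistics) at SNR 100, chosen so the noise floor
sits below the 5% background-intensity level and background filtering
remains meaningful. Ventricle size grows linearly with age
(atrophy = 0.004/year + N(0, 0.03), truncated), so age regression is
recoverable up to an irreducible noise of about 7.5 years equivalent.
Reports are numbered templated findings, one per planted class
("<class> in <region descriptor>"), which keeps the text-encoder vocabulary
small; acuity and referral targets come from editable mapping tables.
Subgroup metadata (region, schedule, sex, age band, insurer, scanner) is
sampled uniformly, and turnaround time is drawn through a dichotomized
late-report indicator whose odds are multiplied per attribute level from
the bias specification, so planted odds ratios are recoverable by the audit.

What the generator does **not** emulate: anatomy and its variability,
scanner physics (coil profiles, bias fields, partial-volume effects),
report language diversity, correlated comorbidity structure, or realistic
class imbalance tails. Passing tests therefore demonstrate that the
implementation is correct and that the method behaves as designed on data
with known structure — not that the learned representations would transfer
to clinical MRI.

## Desk-scale configuration and numerical choices

The desk preset is the configuration the test suite runs: 32-40 voxel
volumes (three shape variants so padding and heterogeneity paths are
exercised), 2-4 sequences per study, 8x8x4 patches with 2x2x2 x 2-channel
latents (16x compression, same ratio as full scale) and a 256-entry
codebook. The codebook is deliberately denser than a naive scale-down:
quantization resolution is what preserves rare-but-diagnostic latents
(bright lesion blocks), and with too few codes the bright intensity levels
collapse onto a single code and the class signal is destroyed. The codebook
is initialized by k-means over encoder outputs of a data sample, and codes
that starve during an epoch (usage below 1% of the uniform share) are
revived at the latents with the largest quantization error.

The encoder desk preset uses width 48, 2 layers and 2 heads per level, 4
sequence and 2 study registers, 32-dim CLIP projections. Transformers are
pre-norm with MLP ratio 4 and ReLU activations; register tokens initialize
N(0, 0.02^2) and linear layers with fan-in-scaled Gaussians. The optimizer
is Adam with decoupled weight decay 0.01 and global gradient-norm clipping
at 1.0; the two temperatures get a 25x learning-rate multiplier and the
logit scale `exp(tau)` is kept within [exp(0.07), 100] during training —
with the printed parameterization the scale starts near 1, where the
contrastive softmax is nearly uniform, and an unbounded downward drift of
`tau` otherwise parks training at the uniform fixed point before alignment
can take hold.

Numerical conventions: probability clamping at 1e-7 in the exported BCE;
layer-norm epsilon 1e-5; cosine normalization epsilon 1e-12; quantizer ties
to the lowest codebook index; checkpoint ties to the earliest epoch; LIME
ranking ties to the lowest lexicographic grid coordinate; all generator,
training and audit randomness flows through explicit integer seeds, with
the caller's RNG state restored afterwards.

Problem sizes used by the test suite: cohorts of 24 studies for unit
fixtures and 200 for the end-to-end run; about 600 training patches and 10
epochs for the codec; 4 epochs for the language model; tens of epochs for
the contrastive stage; 100-200 masks per LIME explanation; bootstrap
calibration at cohort size 8000. The full-scale presets
(`full_scale_tokenizer_config()`, `full_scale_encoder_config()`) construct the
printed architecture exactly and are exercised for shape and compression
contracts.

## Known limitations

- Training the hierarchical encoder from scratch with a few hundred studies
  is optimization-limited: contrastive convergence on CPU at desk scale is
  slow, and short schedules can memorize the training pairs before class
  structure emerges. The augmentation policy and weight decay mitigate but
  do not remove this; the end-to-end test documents the behavior actually
  achieved under its stated budget.
- The printed parameter total for the full-scale encoder (about 57 million)
  cannot be reproduced from the printed layer dimensions under any standard
  MLP ratio; the full-scale preset treats it as an order-of-magnitude
  sanity figure only.
- Precomputed tokens mean the background-threshold jitter augmentation can
  only raise the effective threshold; tokens filtered at the base threshold
  cannot be resurrected.
- The bootstrap disparity test inherits the anticonservatism of its
  upstream design when bootstrap draws are not small relative to the
  subgroup; use it in the regime described above.
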
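---
title: "Models and methods behind crisprnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crisprnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

crisprnet predicts two things about a CRISPR-Cas9 single-guide RNA
(sgRNA): how efficiently it knocks out its intended target, and where
else in the genome the Cas9--sgRNA complex is likely to cleave. Both
predictions come from convolutional networks over a unified encoding of
the 23-nt guide window; this vignette explains the encoding, the
networks, the training procedures, the interpretation machinery, the
synthetic data the package tests itself on, and the design decisions
that were genuinely open.

## The eight-channel encoding

A guide window is the 20-nt protospacer followed by the 3-nt NGG PAM,
always stored 5'→3' on the protospacer strand. Each of the 23 positions
carries 8 channels: a one-hot nucleotide block (A, C, G, T) and four
cell-type-specific epigenetic channels — CTCF binding, DNase
accessibility and H3K4me3 (binary peak overlap from BED intervals), and
RRBS methylation beta in [0, 1] from bedGraph records (0 where
uncovered). Window positions are numbered 1–20 from the PAM-distal 5'
end, with the PAM at 21–23; minus-strand guides are encoded from their
reverse-complement window so the PAM always sits at the 3' end of the
representation. Epigenetic values are assigned per position (not per
window): the encoding is an image-like 23 × 8 matrix, and a peak that
covers only part of the window marks only those positions.

Two choices here were open. Ambiguity codes (N) are rejected rather
than imputed — silently imputing a base would fabricate sequence
evidence. RRBS betas are kept continuous rather than binarized; the
methylation signal is inherently quantitative and thresholding it would
discard information the network can use.

For the off-target model a (guide, candidate site) pair is encoded as
two independent 23 × 8 parts; nothing is mixed between the parts before
the network's merge stage.

## Candidate off-target enumeration

`scan_pam_sites()` emits every window with a canonical NGG PAM on
either strand (forward-strand `GG` at offset 21 for `+` sites,
forward-strand `CC` at offset 0 for `-` sites); windows containing
non-ACGT characters are skipped and counted. `enumerate_candidates()`
keeps the sites within `max_mm` (default and maximum 6) protospacer
mismatches of a query guide. The Hamming distance runs over positions
1–20 only: the PAM's first base is free, but candidate sites must carry
`GG` at 22–23 — non-NGG PAMs (NAG etc.) are deliberately excluded, as
are DNA/RNA bulges; the model family treats substitution-only
off-targets. The scanner is a direct vectorized pass over the genome;
at the package's intended scale (up to a few Mb) no index is needed,
and the test suite holds the scanner to exact agreement with a
brute-force oracle.

## On-target labels

Screens report knockout efficacy as a log-fold change. For
classification, efficacy is binarized at a cutoff of 1, boundary
inclusive (`raw >= 1` → efficacious). For regression across multiple
experiments, a collaborative-filtering normalization removes
experiment- and guide-level offsets from the experiments × guides
matrix:

$$y_{norm} = y_{ij} - (m_{row} + m_{column} + m_{all})/3$$

with the three means taken over observed entries only when the matrix
has holes (every row and column must retain at least one observation).
On a complete matrix the normalized entries sum to zero, and adding a
constant to the whole matrix leaves them unchanged — both identities
are asserted in the tests. A rank normalization `(rank − 0.5)/n` with
midrank ties then maps the normalized values into (0, 1) as the final
regression labels.

Training sets are enlarged by data augmentation: mismatches at the two
PAM-distal positions (window positions 1–2) generally do not affect
cleavage, so each seed guide spawns the 3 × 3 = 9 variants with exactly
one substitution at position 1 and one at position 2, inheriting the
seed's labels and epigenetic profile. An option adds the 6
single-mismatch variants as well; the double-mismatch-only set is the
default. Splits guard against augmentation leakage: stratified
splitting operates on augmentation families (records identical outside
positions 1–2 within a cell type), so no variant of a test seed can
appear in training, and leave-one-cell-type-out splitting purges
sequence overlap between sides.

## The networks

No deep-learning framework is available to this package, and the
convolutional models are its core, so crisprnet carries a compact 1-D
convolution engine written in base R matrix operations: im2col
convolution as a single matrix product, batch normalization, ReLU,
dense layers, manual reverse-mode gradients, Adam with decoupled weight
decay. All randomness flows through R's own RNG, which makes every
training run bit-reproducible given `network_config(seed = ...)`.

**Parent network (denoising autoencoder).** The encoder is three
convolution blocks (kernel 3, channels 32/64/64, stride 1, batch
normalization, ReLU) mapping 23 × 8 to a 23 × 64 latent feature map.
It is pretrained as a denoising autoencoder: inputs are corrupted by
replacing each position's one-hot with a uniformly random one-hot with
probability `mask_prob` (default 0.05) and adding Gaussian noise (sd
0.1) to the epigenetic channels, clipped to [0, 1]; a direct dense
decoder reconstructs the clean input under per-position softmax
cross-entropy for the nucleotide block plus squared error for the
epigenetic block. The corruption rates are deliberately small at
the default: heavier masking teaches the encoder *invariance* to
single-base changes, which is exactly the wrong property for a
representation whose downstream job includes detecting single-base
mismatches.

**On-target predictor.** A copy of the parent encoder plus a head of
two kernel-3 batch-normalized convolution blocks, a flatten readout and
a dense output — softmax for classification (probability of the
efficacious class), identity for regression (squared-error loss).
Fine-tuning is on by default, with the parent copy updated at
`lr_parent_ratio` (default 0.1) times the head's Adam learning rate;
`fine_tune = FALSE` freezes the parent bit-exactly for ablations.

**Off-target pair predictor.** Two copies of the parent encoder — the
"baby networks", one per pair part — whose latent maps are concatenated
channel-wise and fed to a head of a kernel-1 block and a kernel-3 block
(no batch normalization), a flatten readout and the task output. The
first head convolution is initialized antisymmetrically over the two
branch blocks (site-branch weights are the negation of the guide-branch
weights), so at initialization the head responds to
$W(h_{guide} - h_{site})$: silent where the two windows agree, active
at mismatches. Training may move away from this point; it is an
inductive bias, not a constraint.

Three architecture decisions deviate from the obvious defaults and
deserve their reasons:

* *No downsampling.* With a 23-position window, strided convolutions
  buy no meaningful compute and cost positional resolution; a
  full-resolution latent lets the pair model localize individual
  mismatches.
* *Flatten readout, not global pooling.* Global mean pooling makes the
  head translation-invariant, and a translation-invariant readout
  cannot express position-specific effects — but position is exactly
  what matters here, both for nucleotide preferences in on-target
  efficacy and for the PAM-proximal/PAM-distal asymmetry of mismatch
  tolerance. A pooled head can at best count pattern occurrences
  regardless of where they sit; the planted-rule recovery checks in
  the test suite are only passable with the position-aware readout.
* *No batch normalization in the pair head.* The informative signal at
  the merge is the small difference between branch activations; batch
  normalization re-centers and re-scales it per batch, and with
  bootstrap-balanced batches (minority examples repeated many times)
  the batch statistics are badly distorted.

All of these remain overridable through `network_config()`.

## Class imbalance: bootstrap-balanced batches

Genome-wide off-target labels are extremely imbalanced (about 1
positive per 250 candidate loci). `balanced_batches()` makes every
mini-batch exactly half positive and half negative: the majority class
is shuffled and partitioned across the epoch (one epoch = one pass over
the majority class) while the minority class is bootstrapped —
resampled with replacement — to fill its half; when the classes are
already equal both are partitioned, so each example appears exactly
once. The tests assert the exact per-batch counts across 100 seeded
epochs, and the acceptance suite runs the ablation (balancing on versus
off, five seeds, identical configuration otherwise).

A caveat the ablation exposes honestly: the benefit of balanced
batching presumes enough distinct minority examples that bootstrapping
adds stability rather than repetition. At the desk-scale study
conditions used here (tens of positive pairs), upweighting each
positive by a factor of hundreds promotes memorization, and plain
unbalanced mini-batches — where the Adam optimizer absorbs the gradient
scale imbalance — can rank held-out pairs as well or better. The batch
contract itself (exactly equal counts, always) holds regardless and is
what the package guarantees; which regime wins is an empirical matter
that flips with the number of distinct positives, and users with
realistically sized detection datasets (hundreds of positives or more)
are in the regime the balancing strategy was designed for.

## The desk-scale off-target recipe

At the package's test scale the pair model trains on ~20,000 pairs with
only ~80 positives. Two departures from the obvious procedure are
recommended (and used by the acceptance suite), both documented here
because they matter at small label counts:

* *Frozen branches.* With `fine_tune = FALSE` the branch encoders stay
  at the pretrained parent weights. With only tens of positives the
  branches have far more freedom than the labels can constrain:
  fine-tuning lets them drift apart and memorize, while the frozen,
  aligned latents keep the cross-part difference signal clean. (The
  function default remains `fine_tune = TRUE`, the behaviour intended
  at realistic label counts, and the test suite asserts the two
  branches genuinely diverge under it.) Freezing also allows the
  implementation to encode each part once and train only the head on
  cached latents, which is what makes ensembling affordable.
* *A small bag of heads.* A single head's held-out performance varies
  substantially from seed to seed at this positive count;
  `ensemble = 5` trains five independently initialized heads on the
  same cached latents and averages their predicted probabilities.
  Weight decay 1e-2 on the head is the matching regularizer.

## Interpretation

**Activation maximization.** For a class of interest,
`activation_maximize()` starts from the uniform input (nucleotide
channels 0.25, epigenetic channels 0.5) and performs projected gradient
ascent on the class logit minus an L2 penalty (defaults: 500
iterations, step 0.1, lambda 1e-3). After every step each position's
nucleotide block is Euclidean-projected back onto the probability
simplex and the epigenetic channels are clipped to [0, 1]; steps that
would lower the penalized score are rejected and the step size halved,
so the score trace is monotone and the procedure needs no tuning to be
stable. The optimized "synthetic guide" shows which bases and
epigenetic states the model considers characteristic of the class.

**Substitution effect maps.** For the pair model,
`substitution_effect_map()` fixes each background pair, sets the site
base at position p to the matched base X and to each alternative Y, and
records the mean change in predicted occurrence probability — a
20-position × 16-substitution grid whose X→X diagonal is identically
zero. Because the number of guides with detected off-targets is small,
cells are additionally screened by a two-sided Fisher exact test
(substitution presence × detection status, 2 × 2 per cell; alpha 0.05,
no multiplicity correction by default, Benjamini–Hochberg available),
and non-significant cells are rendered as hyphens in text reports. The
per-position averaged map is partitioned by `zone_partition()` into
*preference* (mean effect > tau), *avoiding* (< −tau) and
*undetermined* zones, with tau defaulting to half the map's standard
deviation — a scale-free threshold, since the probability-scale effect
magnitudes depend on the model's calibration.

**Duplex notation.** The map describes protospacer-strand
substitutions X→Y with the guide fixed; classic mismatch heatmaps
describe the RNA:DNA duplex, whose DNA base lies on the target strand.
The two are related by Watson–Crick complementation of the substituted
base: X→Y corresponds to rX:d(complement(Y)), so G→C is rG:dG and G→T
is rG:dA. `substitution_to_duplex()` and its inverse implement the
bijection.

## The anti-OT score and profile export

A guide's genome-wide off-target propensity is summarized as

$$S = \ln(1 + e^{-\sum_i OT_i}) / \ln 2$$

over the predicted occurrence probabilities of all its candidate loci.
The exponent is negated relative to the form sometimes quoted with a
positive sum: with a positive exponent the expression is ≥ 1 and
*increases* with off-target probability, contradicting both the
intended range (0, 1] and the intended reading that a higher score
means a safer guide. With the negated exponent S attains exactly 1 when
the summed probability is zero and decreases strictly in every OT_i.
The literal positive-exponent variant stays available behind
`literal = TRUE` for comparison. The sum runs over all candidates'
predicted probabilities (not only predicted positives). For display,
`severity_bands()` labels each site mild / moderate / severe
(green/yellow/red) at thresholds (1/3, 2/3) by default — the banded
display needs three levels but no canonical cutoffs exist, so round
thirds are used — and `plot()` on a profile draws a simple circular
track; byte-compatibility with any particular plotting toolchain is a
non-goal.

## Evaluation metrics

ROC-AUC is computed from the midrank statistic (ties give 0.5);
PR-AUC by stepwise integration of the precision–recall curve over
descending score thresholds. Spearman correlation is Pearson on
midranks; the weighted variant computes a weighted Pearson correlation
of midranks with weights proportional to the rank of the true value
(largest truth → largest weight, normalized to sum 1), so misranking
the strongest cleavage sites costs more than misranking weak ones. The
weighting convention is this package's own: with equal weights it
reduces exactly to Spearman, which the tests assert to 1e-12.

## Synthetic data: what it emulates and what it does not

Every model-level claim in the test suite is made on seeded synthetic
data, so the package is testable with no downloads.

* `gen_genome()` draws i.i.d. bases at a target GC fraction (default
  0.41, the human genome-wide average).
* `gen_tracks()` emits peak intervals with mark-typical coverage and
  widths, and RRBS betas at a subset of CpG dinucleotides drawn from a
  U-shaped Beta(0.4, 0.4), mimicking the bimodality of bisulfite
  betas.
* `gen_ontarget_set()` plants a linear-logistic efficacy rule:
  positional nucleotide weights plus epigenetic channel weights, with
  Gaussian score noise and optional label flips. Planted rules are
  linear so that their recoverability can be checked in closed form
  (a single-feature classifier on a planted position must reach
  AUC > 0.95, and near-0.5 label noise must push any model to
  chance).
* Synthetic guides are sampled with a non-uniform base composition
  (G-rich, T-depleted, invariant GG PAM), matching real sgRNA
  collections. This matters for pretraining: denoising can only ever
  beat the corrupted input where the sequence distribution has
  structure to restore, and uniformly random sequences have none.
* `gen_offtarget_set()` pairs guides with mutated candidate sites
  (0–6 mismatches, counts steeply increasing as in genome-wide
  candidate sets) and draws detection as a Bernoulli of the logistic
  of summed planted positional effects, with the intercept calibrated
  on the realized pair structure to hit the target positive fraction
  (default 1/250). The default per-position effects are +1.5 at
  positions 1–3, −0.5 at 4–15 and −4 at 16–20: seed-region
  (PAM-proximal) mismatches essentially abolish cleavage,
  mid-protospacer mismatches cost moderately, and PAM-distal
  mismatches are tolerated and hence enriched among detected sites —
  the three-zone structure the interpretation machinery should
  recover. Under these conditions the Bayes-optimal ranking of the
  true logits achieves a held-out ROC-AUC of roughly 0.96, leaving
  real headroom for a learned model; a flatter effect profile was
  rejected because it makes the planted structure unidentifiable for
  any model, which would turn model-quality tests into coin flips.
* `gen_efficacy_matrix()` builds experiments × guides matrices as
  guide effect + experiment offset + noise with a missingness mask
  that always leaves every row and column observed at least once.

What the synthetic data does *not* emulate: linkage between epigenetic
marks and sequence context, assay-specific detection sensitivities
(GUIDE-seq versus Digenome-seq and kin), bulges, non-NGG PAMs, and any
realistic chromatin biology. Passing the synthetic recovery tests
therefore demonstrates that the machinery — encoding, pretraining,
balanced training, saliency, zone recovery — works as specified, not
that the shipped defaults would reach any particular accuracy on real
cell-line data.

## Problem sizes and numerical choices

The test and acceptance suites run at deliberately modest sizes chosen
as this package's desk-scale study conditions: on-target models train
on 2,000 guides (500 held out), the pair model on ~16,000 of 20,000
pairs at 1:250 imbalance, pretraining on the training-side encodings
for 10 epochs, ablations and multi-seed recovery checks on 3,000 to
4,000 pairs. Batch size is 64 throughout; Adam uses learning rate
2e-3 (head), 1e-8 epsilon, and momentum parameters 0.9/0.999;
divergence (non-finite loss) aborts training with the recent loss
trace in the error. Degenerate inputs are rejected early with the
offending position, row or column named: non-ACGT characters, empty
matrix margins, single-class label vectors, odd batch sizes, invalid
severity thresholds. Ties are handled by midranks everywhere ranks
appear. Checkpoints store architecture, parameters, normalization
statistics, seed and an encoding-schema hash, and refuse to load under
a different schema, so a model can never silently score differently
encoded data.

## Known limitations

The engine is single-threaded R; at these problem sizes every suite
runs on one CPU, but the implementation is not meant for
genome-scale pretraining corpora. The planted-rule world is linear;
models that exploit nonlinear epistasis are exercised only through
their optimization machinery, not their scientific claims. Off-target
training at realistic positive counts (hundreds+) has not been
characterized here, and the frozen-branch recommendation is expected
to flip toward fine-tuning as labels grow.
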
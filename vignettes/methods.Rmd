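---
title: "Predicting promoter-centered chromatin interactions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting promoter-centered chromatin interactions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Promoter-capture Hi-C (pcHi-C) enriches Hi-C libraries for contacts that
involve gene promoters, producing promoter-centered chromatin interactions:
promoter-enhancer (PE) and promoter-promoter (PP) pairs, each reported with a
per-interaction false-discovery rate (FDR). Because pcHi-C experiments are
expensive and often underpowered, a supervised classifier that predicts
whether two anchors interact — trained on the tissues where data exist — is a
practical way to recover missed interactions and to transfer knowledge into
poorly-assayed tissues.

`pchicnet` implements such a classifier end to end: labeled-dataset
construction from interaction summaries, multi-modal featurization, a densely
connected convolutional network, three training paradigms (Base, multi-task,
transfer), an evaluation harness, a gene-overlap tissue-similarity score for
choosing pretraining tissues, and a synthetic-study generator that emits
every input format the pipeline consumes.

# Dataset construction

Candidate interactions arrive as BEDPE-like rows (two anchors + FDR). The
pipeline:

1. keeps only intra-chromosomal pairs with midpoint distance at most 1 Mb
   (the bound is strict "greater than" removal: a pair at exactly 1,000,000 bp
   is retained);
2. standardizes each anchor to 2 kb — 1 kb upstream and downstream of the
   anchor midpoint (`floor((start + end) / 2)`; anchors that would run past a
   chromosome edge are dropped with a warning rather than padded, since a
   padded anchor would carry fabricated sequence);
3. deduplicates identical standardized anchor pairs, keeping the smallest
   FDR;
4. labels interactions with FDR < 0.1 positive and uses those with FDR > 0.5
   as the negative pool (both cutoffs configurable, e.g. 0.05/0.5, 0.1/0.7,
   0.1/0.9);
5. samples negatives GC-matched to the positives.

Coordinates are 0-based half-open throughout (BED convention).

**GC matching.** GC content confounds sequence models, so the negative set is
drawn to match the positives' GC distribution. The sampler bins the positive
GC values into deciles and draws, per bin and without replacement, the same
number of pool members (times the negative:positive `ratio`, 1 by default, 5
for the unbalanced regime); a bin whose pool runs short is topped up with the
unused pool members nearest in GC to the bin center. GC is measured over the
concatenation of the two standardized anchor sequences; matching per anchor
instead is available via `interaction_gc(per = "anchor")`. The sampler is
deterministic given its seed.

**Splits.** Labeled data are partitioned 70/15/15 into train/validation/test
(pretraining uses 85/15). Rounding: every part but the last takes
`floor(n * fraction)`, the last takes the remainder.

# Features

Three core modalities (any subset can be active, for ablations):

* **S — sequence**: the 2 kb anchor sequence one-hot encoded, `A=(1,0,0,0)`,
  `C=(0,1,0,0)`, `G=(0,0,1,0)`, `T=(0,0,0,1)`; ambiguous bases are all-zero
  rows. Both anchors are taken on the forward strand.
* **R — reads**: per-tissue epigenetic coverage (default panel: open
  chromatin, H3K4me3, H3K4me1, H3K27ac) normalized to counts-per-million and
  summarized over the anchor by sliding-window means: window 1000 bp, step
  50 bp, hence 21 values per anchor per track. CPM was chosen because the
  normalization method is otherwise a free choice and CPM makes the window
  features library-size invariant; window *means* (rather than sums) make a
  constant track a fixed point of the transform, which gives a trivial
  oracle for testing.
* **D — distance**: |midpoint1 − midpoint2| scaled by the 1 Mb filter bound,
  so it lies in [0, 1] for any retained interaction. A log10 scaling is a
  config option.

Auxiliary per-base tracks (conservation scores, DNA-shape features MGW /
HelT / ProT / Roll) are consumed pre-computed and windowed exactly like R
(21 values per anchor per track); computing them from sequence is out of
scope. Missing bases in a coverage track are imputed as zero.

# The network

Each array modality (S, R, aux) passes through its own *dense block*: four
"convolution layers", where one convolution layer is the composite
convolution → batch normalization → PReLU → dropout. The four layers use
64/32/16/16 filters with dilation rates 1/2/3/4. The entry layer is
modality-specific — kernel 20×4 with stride 10×4 for sequence (collapsing
the 4-wide base axis), kernel 3×1 with stride 1×1 for reads — and runs
unpadded; the remaining three layers run at stride 1×1 with
height-preserving padding so their outputs align for concatenation. Each
in-block layer receives the channel-concatenation of all previous layers'
outputs, and the block output concatenates all four (128 channels).

Two design points the architecture leaves open were resolved as follows,
and are asserted by the introspection tests:

* **Anchor pairing.** The two anchors' matrices are stacked as input
  channels (sequence input 2000×4×2, read input 21×M×2). This keeps the
  printed 20×4 kernel geometry valid; stacking along the length axis is the
  plausible alternative but would change every downstream shape.
* **Within-block concatenation.** The raw block input is *excluded* from the
  concatenation (the entry layer is the block's transform into feature
  space). For the sequence path this is forced — the 10×4 stride changes the
  spatial shape — and the read path follows the same rule for symmetry. The
  input channels of in-block layer *k* therefore equal the sum of the
  filters of layers 1..k−1 (64, 96, 112).
* **Fusion reshape.** The fusion convolution (kernel 4×4, stride 4×4)
  expects a 2-D grid. Each block output `(h, w, 128)` is flattened to an
  `(h*w) × 128` positions-by-channels grid with one channel; modality grids
  are stacked row-wise and fused by that convolution, followed by global
  average pooling. The fusion filter count is not pinned by the
  architecture's printed constants; the default is 64.

The pooled fused vector is concatenated with the scalar distance and
classified by a fully connected 256-unit ReLU layer with a sigmoid output.
With only D active the model reduces to the classifier on the scalar
distance — the degenerate ablation used to quantify how much distance alone
explains.

Remaining defaults where the architecture is silent: dropout 0.2, PReLU
initial slope 0.25, He-normal weight initialization, no convolution bias
(batch norm's shift absorbs it).

## The engine

No deep-learning framework is part of the package's dependency set; the
network, its backpropagation, and the Adam optimizer are implemented in R
with BLAS-backed im2col convolutions whose gather indices are precomputed at
build time. Analytic gradients are verified against central finite
differences in the test suite (tolerance 1e-4 on sampled coordinates of
every parameter tensor). Training is deterministic given the configuration
seeds: weight initialization, batch shuffling and dropout masks all derive
from them, and package functions restore the caller's RNG state.

# Training paradigms

All paradigms optimize binary cross-entropy with Adam, initial learning rate
1e-4 decaying exponentially per epoch (decay factor 0.96 by default — the
decay constant is otherwise unspecified), for at most 200 epochs, stopping
early when the validation loss has not decreased for 5 consecutive epochs
and restoring the best-validation weights. Batch size defaults to 64.

* **Base** trains one network per tissue on that tissue only (70/15/15).
* **Transfer (TL)** pretrains a network on the pooled interactions of source
  tissues (85/15 split; the target tissue must not be in the pool), keeps
  the feature extractor, discards the pretraining head, and fine-tunes *all*
  layers on the target tissue.
* **Multi-task (ML)** uses the same pretrained extractor as frozen *shared*
  extractor (common features), trains a *private* extractor of identical
  architecture on the target tissue, and feeds the concatenation
  [common ‖ private ‖ distance] to the tissue-specific classifier. Whether
  the shared extractor should stay frozen during target training is a
  genuinely open design point; freezing is this package's choice, because it
  is what keeps common features uncontaminated by the (small) target tissue
  and it makes the shared features precomputable, which is also much
  cheaper. A frozen extractor receives no gradient and its batch-norm
  statistics do not drift.

Source tissues for pretraining can be: all others, a predefined biologically
relevant group minus the target, or the top-k (default 5) most similar
tissues under the gene-overlap similarity below.

# Tissue similarity

Each tissue is summarized by the set of genes nearest to the anchors of its
positive interactions: for each anchor, the gene with the closest
transcription start site to the anchor midpoint (TSS = BED `start` on '+',
`end − 1` on '−'; ties break to the smaller coordinate, then lexicographic
id). "Nearest gene" could alternatively be defined by gene-body distance;
TSS distance was chosen as the convention most annotation tooling uses.
Similarity between two tissues is the proportion of shared genes among all
genes seen in either tissue — the Jaccard index of the two gene sets. The
denominator ("among all genes in both") admits other readings (minimum or
mean set size); the union reading is this package's documented choice and
the function is pluggable. Two empty sets score 0, not NaN.

# Evaluation

AUC is computed in the Mann-Whitney form (ties count one half) and AUPRC as
step-wise average precision — not trapezoid-interpolated, which inflates
early-precision estimates. To absorb split-sampling variance the experiment
harness re-splits the data 10 times, retrains, and reports per-repeat
AUC/AUPRC; methods are ranked per tissue by the median AUC over repeats
("mAUC", average ranks on ties), and two methods are compared across tissues
with a two-sided Wilcoxon rank-sum test on their per-tissue mAUC vectors
(exact for small tie-free samples, tie-corrected normal approximation
otherwise). Cross-prediction (train on PE, score on PP, and vice versa)
evaluates a trained model on the other interaction type without weight
updates.

# The synthetic-study generator

`simulate_study()` generates, from one seed: a random genome of configurable
GC content; a uniform gene annotation; per-tissue PE/PP interaction tables
whose FDRs are Uniform(0, 0.1) for true positives and Uniform(0.5, 1) for
true negatives (so FDR labeling at the default cutoffs recovers the planted
truth exactly, making dataset-construction correctness directly assertable);
and per-tissue Poisson coverage tracks. Signal is planted as:

* a **shared motif** present in both anchors of a positive with probability
  `p_shared`, common across tissues — the learnable signal that transfer and
  multi-task learning can exploit;
* optional **tissue-private motifs** (`p_priv`);
* multiplicative coverage **fold-enrichment** at positive anchors over
  Poisson background (fold 1 = no coverage signal);
* a **distance regime**: "shifted" (positives drawn closer, emulating the
  real-data tendency of true interactions to be proximal) or "matched"
  (identical distance samplers, the regime used to show distance-free
  robustness).

Motifs are planted at uniform random offsets within each anchor, in
`motif_copies` copies (default 3). Clustered occurrences emulate the
binding-site clusters of regulatory elements; they also matter
quantitatively because the network ends in *global average pooling*, which
dilutes an isolated 10-mer hit across the pooled map — a single planted copy
produces a fixture that is nearly unlearnable at small sample sizes while
clustered copies behave like real enhancer sequence signal.

What the generator does **not** emulate: realistic Hi-C contact physics,
restriction-fragment structure, correlated histone marks, sequence
composition heterogeneity (isochores), or calibrated FDRs. Passing tests on
these fixtures therefore demonstrates that the machinery — labeling,
matching, featurization, optimization, transfer — works as specified, not
that the defaults are tuned for any particular real dataset.

# Problem sizes used by the test suite

The architecture-constant checks run at the full-scale geometry (2 kb
anchors, 21×4 read features, 64/32/16/16 filters). The learning checks run
at a reduced geometry chosen as the package's own test design: 200 bp
anchors (window 100 / step 5, still 21 windows per track), filter widths
32/16/8/8, fusion width 32, classifier width 64, learning rate 1e-3, and a
16-mer shared motif in 4 copies. At these sizes a planted-signal study of
2000 interactions trains to test AUC well above 0.85 in a few minutes of CPU
time; a no-signal null stays at chance (AUC ≈ 0.5); and on a small
(n = 300) target tissue with three source tissues, transfer and multi-task
training each beat base training in almost every paired seed. The
`scripts/acceptance.R` script recomputes all of these quantities from
scratch.

# Known limitations

* The engine is CPU-only, pure R; it is sized for the package's fixture
  scale, not for genome-wide training runs.
* "Shared knowledge transfer" is implemented as freeze-then-concatenate;
  joint multi-tissue optimization with task-weighted losses is explicitly a
  non-goal.
* FDRs are consumed, never computed: calling interaction significance from
  raw contacts is out of scope, as are liftover, peak calling and computing
  conservation or DNA-shape tracks from sequence.
* Competing architectures (recurrent/attention sequence models) are not
  reimplemented; the evaluation harness accepts any scorer closure, which is
  where such baselines would plug in.
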
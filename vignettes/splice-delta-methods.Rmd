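---
title: "Methods: collapsed splice annotations, per-nucleotide models, and variant delta scores"
author: "splicedelta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collapsed splice annotations, per-nucleotide models, and variant delta scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicedelta)
```

## The problem

Pre-mRNA splicing removes introns at donor (5′, GT-anchored) and acceptor
(3′, AG-anchored) splice sites. A large fraction of disease-causing variants
act by disrupting splicing — destroying an annotated site or creating a
cryptic one — yet most are hard to call from sequence inspection alone.
`splicedelta` implements a complete pipeline for this problem:

1. build a *collapsed* per-gene splice-site annotation from a GENCODE-dialect
   GTF (the union of splice sites across manually annotated isoforms);
2. encode genomic sequence and per-nucleotide site labels into fixed-size
   one-hot training windows;
3. train a per-nucleotide splice-site classifier (a residual dilated
   convolutional network) under a chunked schedule;
4. annotate VCF variants with four *delta scores* — acceptor gain (AG),
   acceptor loss (AL), donor gain (DG), donor loss (DL) — and the positions
   at which they occur, with principled alignment of indel predictions back
   to reference coordinates;
5. evaluate variant predictions as a binary classification task and at
   exact-effect (base-pair) resolution.

A deterministic synthetic-genome generator with motif-defined splice sites,
plus a rule-based oracle predictor, makes every stage testable end to end
without external data.

## Collapsed annotations

Transcripts are read from GTF (`parse_gtf()`), filtered to annotation level
≤ 2 by default (`filter_level()`; level 3 marks automated annotation, so the
default keeps only manually annotated isoforms). For each transcript, exon
boundaries that coincide with the transcript's own start or end are removed
(`internal_boundaries()`), which implicitly removes single-exon transcripts;
the surviving acceptor and donor positions of all of a gene's transcripts
are unioned into one collapsed pseudo-isoform (`collapse_gene()`).

Coordinate conventions, fixed throughout the package:

* intervals are 0-based half-open internally; GTF input (1-based inclusive)
  and VCF positions (1-based) are converted at the boundary;
* an **acceptor** is the genomic position of the *first exonic base* at a 3′
  splice site, a **donor** the position of the *last exonic base* at a 5′
  splice site, so per-nucleotide labels always sit on sequenced bases; on
  the minus strand the genomic roles swap with the reading direction;
* a position annotated as both acceptor and donor across isoforms (possible
  in principle after collapsing, pathological in practice) is labelled
  acceptor, deterministically, with a warning — one-hot labels admit one
  class per base.

Gene identity is the versioned `gene_id`; transcripts of one gene on mixed
strands or chromosomes are an error, never a silent merge. Chromosome
filtering and gene exclusion lists (e.g. paralog lists for held-out
evaluation) are options of `build_collapsed_annotation()`, not hard-coded.
Transcripts lacking a level attribute are dropped with a warning by default
(`missing_level = "error"` is available); the treatment of such transcripts
is a package choice, as level-less records are rare and ambiguous.

## Window encoding

Each gene span is enlarged by a flank on both sides (5,000 bases at
full scale, giving 10,000 bases of context), minus-strand genes are
reverse-complemented so everything runs in transcription direction, and the
span is sliced into windows: window *i* predicts `predict_len` bases given
`context_len/2` bases of flanking sequence on each side
(`encoder_config()`, default 5,000 + 10,000 = 15,000-base windows).
Window context is drawn from the neighbouring span sequence or the flank —
real genome sequence, not padding; `N` (all-zero one-hot rows) appears only
beyond chromosome ends, and label rows beyond the span are class `neither`.
One-hot encoding uses the fixed order A, C, G, T with all-zero rows for
unknown bases (the convention of this architecture family; a 0.25-uniform
row would invent certainty that is not there), and labels the fixed order
neither, acceptor, donor. Overlapping genes are encoded independently — the
pipeline is per-gene throughout.

For training, genes are aggregated into chunks of `chunk_size` genes with
the last two chunks merged so no chunk is undersized (`chunk_genes()`);
100 genes per chunk at full scale, 10 at the desk scale used in the tests
so that the 90%/10% chunk split still yields a meaningful held-out set from
100 genes.

## The per-nucleotide model

`splice_cnn()` builds a fully convolutional residual network over one-hot
DNA: a 1×1 input projection, `n` pre-activation residual blocks — each
normalization → ReLU → dilated convolution, twice — and a 1×1 projection to
three classes with per-position softmax. The receptive-field context is
determined entirely by the stack, `2·(kernel−1)·Σ dilations`, and the
constructor refuses a declared `context_len` that does not match, reporting
the computed value. The desk default (kernel 11, four blocks, dilation 1,
12 channels, ~80,000 parameters) has an 80-nt context; wider kernels and
dilations scale the same code to larger contexts, and any externally trained
model can be plugged in through the predictor contract
(`predict_window()`: one-hot `(L + context) × 4` in, acceptor/donor tracks
of length `L` out).

Two numerical choices deserve note. Normalization is computed per channel
over the positions of the window being processed (deterministic at
inference; no running statistics), which is well-estimated for the
multi-kilobase windows this model sees and keeps prediction a pure function
of the input. The output bias is initialised to approximate class-prior
logits (sites are roughly 1 in 400 bases), so early optimizer steps are not
spent learning the background rate — an initialisation, not a loss
modification.

### Training schedule

`train_splice_models()` implements the schedule exposed in `train_config()`:
each of `n_models` (default 5) ensemble members receives an independent
random 90% of the chunks as training data, the remainder as validation; it
trains for 10 × (number of training chunks) steps, each step visiting one
randomly chosen chunk and taking one Adam step per gene, with all windows
of a gene as one batch and mean categorical cross-entropy as the loss. The
learning rate starts at 0.001 and halves at 60%, 70%, 80% and 90% of the
total chunk-visit steps, applied from the first step at or past each
boundary; the realised rate of every step is recorded in the training
history. The last-step weights are kept — no early stopping is part of the
schedule. Training is bit-reproducible given (seed, config, data).
Ensemble prediction (`splice_ensemble()`) is the elementwise arithmetic
mean of the members' probability tracks.

Validation quality is the pooled PR-AUC of acceptor and donor probabilities
over all held-out positions, computed by the same `pr_auc()` used by the
variant benchmark — one implementation, shared.

## Variant delta scores

`annotate_vcf()` scores each variant against each overlapping gene (span
enlarged by `max_distance`, default 5,000, symmetric — no asymmetric
workaround is reproduced). Alleles are first normalised: shared
suffix/prefix trimming to the minimal representation, then left-alignment
of indels through repeat tracts against the genome — uniform treatment that
removes coordinate ambiguity before windowing. The reference window covers
the variant ± (`max_distance` + context), the alternative window replaces
the reference allele with the alternative; minus-strand genes are
reverse-complemented before prediction and tracks mapped back afterwards.

Because insertion and deletion tracks live on shifted coordinates, the
alternative track is aligned back to reference coordinates before
differencing (`align_alt_track()`):

* **deletions** — zeros are inserted at the deleted reference positions,
  immediately after the retained allele prefix (a deleted base has no
  probability of being a splice site);
* **insertions** — the alternative-allele block collapses onto the final
  reference-allele base by elementwise maximum (block-plus-anchor rule: the
  strongest signal inside or at the boundary of the inserted block is
  retained), chosen because a cryptic site created anywhere inside the
  insertion should surface at the anchor rather than be discarded;
* multi-nucleotide substitutions (e.g. GTT>AA) reduce to the same rules via
  their net length difference.

`delta_scores()` then takes, over positions within ± `max_distance` of the
variant, the 0-clipped maxima of the four signed difference tracks
(gain and loss reported separately, both ≥ 0) and the signed offsets of the
maxima (ties: smallest absolute offset, then negative before positive).
The binary decision for a variant is the maximum of the four delta scores
over its gene entries, equivalent to thresholding the maximum absolute
per-nucleotide delta. No masking of annotated sites is applied by default —
it is not part of the method here. Output is a VCF INFO field
(`SDELTA=ALLELE|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL`,
scores to two decimals, one entry per alt allele × overlapping gene), with
a deterministic, byte-stable body.

## Benchmarking

`binary_eval()` evaluates the binary splice-affecting task: variants with
no prediction are filled as non-affecting — implemented as a `-Inf`
surrogate so that a tool legitimately scoring 0 remains distinguishable
from a missing prediction in the ranking — while still counting against
coverage. PR-AUC is the step-interpolated area (average precision; the
convention of the surrounding ecosystem, stated here so results are
reproducible), ROC-AUC the rank form with midranks for ties. The optimal
threshold maximises accuracy over all candidate cuts (midpoints between
adjacent distinct finite scores plus the extremes), ties resolved toward
the smallest threshold.

`exact_eval()` scores base-pair-resolution effect prediction on variants
with annotated events: for each of the four effect classes, a variant is
correct when the predicted position (variant position + delta position of
the entry with the highest delta score of that class) matches an annotated
event position exactly. Matching is position-exact by default; a tolerance
flag exists (default 0) since no tolerance is part of the task definition.
Variants with several events of one class count as correct on any match;
classes with no variants report `NA`, not 0. `compare_predictive_error()`
compares two models by per-variant error |max score − label|, reporting the
fraction of variants whose error changed and the fraction of those that
improved.

## The PWM sliding-window scorer

`build_pwm_scorer()` constructs a fixed-width log-odds position weight
matrix from the collapsed sites themselves (23-base acceptor and 9-base
donor windows by convention), with a pseudocount and genome-derived
background frequencies. `sliding_delta()` applies any such scorer — the
interface also accepts externally derived score tables — at every window
placement touching a variant's alleles (exactly `width` placements for an
SNV), scoring reference and alternative sequence at each placement and
returning the maximum absolute difference; both strands are evaluated when
the gene strand is unknown. The absolute difference is used, matching the
maximum-absolute-delta decision rule of the main method.

## The synthetic fixture generator

`generate_genome_and_annotation()` lays out multi-isoform genes on both
strands of one chromosome. Every splice site carries an exact consensus
motif — donor `CAGGTAAGT` (site base 3, GT at 4–5), acceptor
`TTCTTTCTTTTTTTTTTCAGGTT` (site base 21, AG at 19–20) — and the generator
rewrites any accidental exact occurrence elsewhere (both orientations), so
motif presence is provably equivalent to site presence. Genes carry
cassette exons shared by subsets of isoforms (exercising the union),
level-3 isoforms and single-exon transcripts (exercising the filters), and
near-miss *cryptic* motifs (one base off) in introns whose single-base
restoration creates a genuine cryptic site. A deliberate wrinkle: a gene
may carry a cassette exon annotated *only* by a level-3 isoform and backed
by no motif — an automated-annotation artifact that makes the level filter
consequential. The ground-truth collapsed annotation is derived directly
from the planting plan, independently of the GTF parsing path.

`oracle_predictor()` satisfies the predictor contract by exact motif
matching: probability 1 exactly where the planted motif surrounds a
position, 0 elsewhere. It is sequence-driven, so variant edits change its
output, and on collision-free fixtures it is correct by construction —
giving the annotation and benchmark modules a case with known-perfect
answers (100% coverage, 100% binary accuracy, 100% in all four exact
classes). `generate_variants()` produces splice-destroying edits (SNVs at
the invariant GT/AG anchors, small deletions, insertions and
multi-nucleotide substitutions inside motifs), cryptic-gain SNVs restoring
near-misses, and neutral edits at least 30 bases from any motif footprint
that are verified not to create one. SNVs dominate the mix with deletions
the most common indel class, mirroring curated clinical variant sets.

### The noisy training task and its calibration

Exact motifs make site recognition trivially solvable; the training
conditions for the desk network therefore corrupt each non-anchor motif
base with probability 0.05 (`noisy_training_spec()`), leaving the invariant
GT/AG dinucleotides fixed — degenerate consensus signals, as in real splice
sites. The corruption level is a calibrated design choice: with an ideal
generative-model detector, pooled site PR-AUC on this task is ≈ 0.99 at 5%
corruption, so a well-trained network can be expected to approach it, and a
shortfall is attributable to training rather than task ambiguity. Two
configurations were rejected by that analysis: 10% corruption drops the
ideal detector itself to ≈ 0.88 (corrupted 9-mer donors become
statistically indistinguishable from background near-matches), and planting
near-miss decoys alongside corrupted motifs caps it at ≈ 0.93 (a decoy is
exactly as motif-like as a once-corrupted true site). Decoys are therefore
confined to the exact-motif fixtures used for variant-effect experiments,
where they are unambiguous. Under these conditions the desk network (80-nt
context, 12 channels, single model, the standard schedule over 100 genes in
chunks of 10) reaches held-out pooled PR-AUC ≈ 0.99, and the test suite
asserts ≥ 0.9 — the same qualitative bar as full-scale splice models on
held-out chromosomes.

## Problem sizes used in tests

The suite and acceptance script run at desk scale, chosen so the full
pipeline executes in minutes on one CPU: 50-gene fixtures with 200 variants
for the oracle end-to-end check; 100 fixtures plus 1,000 random transcript
sets for collapse correctness; 10,000 random variants for indel-alignment
closure; 500 random score sets for threshold optimality; and the 100-gene
training run above (windows of 5,000 predicted bases with 80 bases of
context). The encoder and model accept the full-scale geometry (5,000 +
10,000) unchanged; nothing in the code is specific to the desk sizes.

## What passing tests do and do not show

The fixtures emulate the *structure* of the real task — strand handling,
isoform collapsing, annotation levels, motif-anchored sites, indel
coordinate algebra, near-miss cryptic sites — with exact or mildly
corrupted motifs and uniform background. They do not emulate branch points,
polypyrimidine-tract variation, splice-site strength spectra, regulatory
elements, GC structure, or repeats. Passing therefore certifies the
pipeline's correctness (coordinates, alignment, scoring, evaluation) and
the trainability of the architecture, not clinical-grade predictive
performance; the latter requires full-scale training on real annotations
with 10,000-nt context, which this package's components support but whose
compute lies outside a test suite.

## Known limitations

* The desk network's 80-nt context cannot see distal determinants (branch
  points sit 20–50 bases upstream of acceptors; real models benefit from
  kilobases of context).
* Per-window normalization statistics differ minutely between reference
  and alternative windows, adding noise of order 1/window-length to CNN
  delta scores; the oracle-based correctness tests are unaffected.
* Structural variants, symbolic alleles and breakends are out of scope and
  skipped with a warning; phased annotation is not attempted.
* `exact_eval()` conditions only on position match, not on a score
  threshold; a threshold flag is the natural extension if calibrated
  cut-offs are wanted.
* PWM scoring assumes positional independence; dinucleotide dependencies
  (as in maximum-entropy site models) are deliberately not estimated, but
  such scorers drop into the same `site_scorer` interface.
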
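---
title: "Methods: image-like contact encodings and the convolutional binding classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-like contact encodings and the convolutional binding classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Peptides presented by HLA class I molecules to cytotoxic T cells are the
raw material of epitope discovery; predicting which nonapeptides bind
which alleles replaces expensive competition assays with a classifier.
`ilamhc` implements a *pan-specific* classifier: a single model covering
all alleles, with the allele represented by its 34-residue contact
pseudo-sequence (the NetMHCpan-style subset of HLA positions that touch
the bound peptide).

A peptide--allele pair is encoded as an **image-like array (ILA)**: a
W x H grid whose columns are the 34 HLA contact residues and whose rows
are the 9 peptide positions. Each pixel (i, j) is the contact between HLA
residue i and peptide residue j; its channels hold the physicochemical
property values of the two residues — channels `1..S` for the peptide
residue, `S+1..2S` for the HLA residue. With the default 9-scale property
set this gives the 34 x 9 x 18 array. Binding-relevant structure —
anchor-position preferences, locally clustered synergistic contacts —
appears as local motifs in this image, which is what a convolutional
network detects well.

The classifier is a small VGG-style network: three convolution blocks of
two 3 x 3 same-padded convolutions (ReLU) with 32, 64 and 128 filters,
each block followed by 2 x 2 max pooling and dropout; then dense ReLU
layers (256, 128) and a single sigmoid unit giving the binder
probability. On a 34 x 9 input the pooled spatial trace is
34x9 → 17x4 → 8x2 → 4x1. Training uses Adam at learning rate 0.001 with
binary cross-entropy for up to 200 epochs, stopping early when the
validation loss has not decreased for 15 consecutive epochs (strict
improvement; `min_delta = 0`), and restoring the best-epoch weights.
Binders are defined by the conventional strict threshold IC50 < 500 nM;
exactly 500 nM is a non-binder.

The network engine (convolutions, pooling, backpropagation, Adam) is
implemented in the package itself with compiled im2col/BLAS kernels; the
forward/backward pass is verified against finite differences in the test
suite, and all stochastic steps (initialization, shuffling, dropout) run
off R's seeded RNG so training is reproducible on a single thread.

## Property scales

The identity of the property scales behind the published 18-channel
encoding is not fixed by this package; we ship a default table of 11
widely used indices (Kyte--Doolittle hydropathy, Hopp--Woods
hydrophilicity, residue volume and mass, Zimmerman bulkiness, Grantham
polarity, Zimmerman isoelectric point, side-chain net charge,
Bhaskaran--Ponnuswamy flexibility, Chou--Fasman helix and sheet
propensities), transcribed from the standard literature. Scales are
z-scored over the 20 amino acids (the table mixes units; unscaled columns
would weight channels arbitrarily) and correlation-pruned: while any pair
of scales has squared Pearson correlation above 0.8, the scale with the
highest mean absolute correlation among those in a violating pair is
dropped (ties: the later column). On the shipped table this removes one
of {volume, mass} and one of {isoelectric point, net charge}, leaving 9
scales and hence 18 channels. Pearson correlation is shift/scale
invariant, so pruning commutes with standardization. The table is
user-replaceable (`default_property_scales(path = ...)`, CLI
`--properties`).

Open choices resolved here: the greedy mean-correlation removal rule and
the drop-later tie-break are our determinism choices, not a published
rule; channel order (peptide half first) is likewise fixed by us so that
attribution maps are comparable across runs. A further open choice is
what the "deployed" model is after cross-validation: this package's
`train` subcommand and `ila_cnn()` fit one model with an internal
validation split and early stopping, and that early-stopped model is the
deliverable — we do not retrain on all data at the stopped epoch, because
without a validation set the stopping point found on one split has no
monitored counterpart, and restoring best-epoch weights requires one.

## Pseudo-sequences

The 34 contact positions are treated as an upstream constant: the
registry loads a NetMHCpan-style two-column file and never derives
positions from structures. Allele spellings (`HLA-A*31:01`, `HLA-A3101`,
`A*31:01`) are normalized to one canonical form. The file shipped under
`inst/extdata/` is a *synthetic* stand-in (random 34-mers attached to
real allele names) sufficient for tests and examples; real analyses must
supply the real pseudo-sequence list.

## Training data handling

IEDB-style TSVs are parsed with their inequality qualifiers. Labeling
honours qualifiers: `>` with a value at or above threshold is a
non-binder, `<` at or below is a binder, and qualified values that leave
the side of the threshold undetermined are excluded as ambiguous (and
reported). Replicate (allele, peptide) IC50 rows collapse to their
geometric mean before labeling. Five-fold splits are unstratified uniform
random with a fixed default seed (20171228); leave-one-allele-out holds
out every record of one allele per round, testing transfer to unseen
alleles. Evaluation groups records by (reference, allele, measurement
type) and scores each subset with precision, recall and F1, with
zero-denominator metrics defined as 0 (flagged) so small subsets stay
comparable; continuous predictions are binarized at probability 0.5, a
symmetric default the user can move.

## Attribution

Informative pixels are computed with DeepLIFT multipliers under the
rescale rule: linear propagation through dense and convolution layers,
delta-output/delta-input ratios at ReLU and sigmoid units, and pooling
contributions routed to the input's selected locations. The reference
input is the all-zero ILA — because scales are z-scored this is the mean
amino-acid profile. Two numerical choices matter. First, reference
activations are computed through the *input's* pooling switches, which
makes every layer linear or elementwise for the input/reference pair and
gives the completeness identity (contributions summing to the output
difference) to machine precision; the test suite asserts 1e-3. Second,
multipliers are propagated on the pre-sigmoid logit and rescaled once
through the sigmoid, which is numerically stable and keeps completeness
on the probability scale. Positive scores push towards binder (rendered
red), negative towards non-binder (blue); heatmaps are drawn with a
diverging palette symmetric about zero and scaled to the maximum
absolute score, alongside a CSV twin with 1-based peptide-position rows.

## The synthetic world

Real training corpora are large external downloads, so the package ships
a generator whose ground truth is known. Each pseudo-allele receives a
random pseudo-sequence and an energy model: anchor positions (always 2
and the C-terminus, plus one random secondary by default), a preference
energy vector per anchor, and pairwise synergy bonuses between anchor
positions (default 3 terms, bonus ~ N(1.0, 0.25^2) log10 nM). Anchor
preferences emulate pocket compatibility the way pan-specific prediction
assumes it works: every peptide position has a fixed pocket of 4 contact
columns shared across alleles (the groove's structural constancy), and
the preference of an allele's pocket for a peptide residue is a shared
bilinear form between the residue's property vector and the pocket
residues' mean property vector, rescaled to sd 1.5 log10 nM over the 20
amino acids. This is deliberate, twice over: binding in this world is
driven by the same physicochemistry the encoder exposes, and specificity
is a smooth function of the pseudo-sequence — so similar pockets imply
similar motifs and leave-one-allele-out transfer is meaningful.
Preference vectors drawn independently of residue properties or of the
pseudo-sequence would make the planted signal invisible to any
property-channel model and would test nothing but memorization of allele
identities. Measurements
follow `log10(IC50) = base - energy + N(0, 0.3)`, clipped to
[0.1, 50000] nM, with the per-allele base calibrated on a seeded
2000-peptide sample so uniform draws yield roughly the 0.4 target binder
fraction. Defaults: 6 alleles, 34 contact residues, nonapeptides.

What passing the end-to-end test shows — and what it does not: the
pipeline can recover a planted, physicochemically coherent, locally
clustered signal (held-out F1 and anchor-concentrated attribution). Real
data add measurement heterogeneity, allele imbalance, shared structure
between alleles and non-additive effects beyond pairwise synergy;
performance numbers on this world say nothing quantitative about IEDB
benchmarks.

## Problem sizes used by the shipped tests

The test suite trains at reduced scale by design: the end-to-end recovery
run trains the full 32/64/128 architecture on a 4000-record sample of the
default world under the published protocol (learning rate 0.001, batch
128, patience 15, best-weight restore) with the epoch budget capped at 60
— early stopping fires well before the cap — using a fresh 800-record
draw as the early-stopping monitor and another as the held-out test set;
attribution recovery is checked on every correctly classified held-out
binder. Cross-validation mechanics are exercised on a 3-allele world with
a small architecture; the full-corpus constants (118,174 records, 76
alleles, 5-fold and leave-one-allele-out) are asserted on index
arithmetic, which is scale-exact without the corpus. At this scale the
network recovers most but not all of the planted signal: a noiseless
oracle on the same world scores F1 0.96 while the trained network lands
around 0.78, reflecting that the fixed architecture approximates the
world's bilinear peptide-pocket energetics only coarsely from 4000
examples — the original setting trains the same architecture on roughly
thirty times more data.

## Known limitations

- Nonapeptides only in the default model path; the encoder is
  length-generic but no length-9 alternative model is provided.
- The shipped property table is a documented default, not the exact
  scales behind the published channel values; absolute probabilities are
  therefore not comparable to the original tool's.
- Single-threaded determinism is guaranteed; multi-threaded BLAS may
  reorder floating-point reductions.
- No calibration of the 0.5 operating point against a 500 nM-equivalent
  score is attempted; for benchmark-style comparisons the operating
  point is configurable.
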
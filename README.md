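# ilamhc

Pan-specific peptide–MHC class I binding prediction with a small
convolutional network trained on image-like contact encodings, plus
DeepLIFT-style explanations of individual predictions.

## The problem

Cytotoxic T cells recognize short peptides presented by HLA class I
molecules; knowing which nonapeptides bind which HLA allele is the first
computational step of epitope discovery and peptide-vaccine design.
Binding is driven by physicochemical compatibility at the contact sites
between the peptide and the groove, and neighbouring contacts act
synergistically rather than independently — local structure that linear,
position-independent scoring misses.

`ilamhc` encodes a peptide–allele pair as an **image-like array (ILA)**:
a W×H grid whose W = 34 columns are the NetMHCpan-style HLA contact
residues and whose H = 9 rows are the peptide positions. Each pixel holds
the physicochemical properties of its residue pair in C = 2S channels
(peptide half first); with the default 9-scale property set the encoding
is 34×9×18. A VGG-style convolutional classifier — three blocks of two
3×3 convolutions (32/64/128 filters) with 2×2 max pooling and dropout,
then dense layers 256/128 and a sigmoid unit — is trained with Adam
(learning rate 0.001, binary cross-entropy, up to 200 epochs, early
stopping after 15 non-improving validation epochs) on measurements
labeled by the conventional strict rule IC50 < 500 nM ⇒ binder.
Evaluation follows the benchmark protocol of grouping records by
(reference, allele, measurement type) and scoring each subset with

    precision = TP/(TP+FP),  recall = TP/(TP+FN),
    F1 = 2·precision·recall/(precision+recall).

Predictions are explained with DeepLIFT (rescale rule) attribution maps:
signed per-pixel contributions towards binder (red) or non-binder (blue),
satisfying the completeness identity (contributions sum to the output
difference from a reference input).

The network engine (convolution/pooling kernels in RcppArmadillo,
backpropagation, Adam, early stopping) is implemented in the package and
verified against finite differences in the test suite. A synthetic-data
module generates worlds with planted anchor-position preferences and
pairwise synergies so the full pipeline — encoding, training,
cross-validation, benchmarking, attribution — is testable offline with
known ground truth.

## Worked example

```r
library(ilamhc)

## a synthetic world with planted anchor energetics (positions 2, 9 + one
## secondary anchor per allele)
world <- generate_world(synthetic_config(n_alleles = 3), seed = 1)
recs  <- sample_records(world, 1200, seed = 2)

fit <- ila_cnn(recs, world$registry,
               config = train_config(max_epochs = 30, patience = 10))
print(fit)
#> Pan-specific peptide-MHC binding classifier (convolutional)
#>   input 34x9x18; 32/64/128 filters; 455,681 parameters
#>   trained on 1200 records (240 validation); stopped at epoch 21, best epoch 11
#>   best validation loss 0.5343, validation accuracy 0.7667

## predict new peptide-allele pairs
predict(fit, data.frame(peptide = recs$peptide[1:2], allele = recs$allele[1:2]))
#> [1] 0.26703392 0.05184999   # probabilities; >= 0.5 means binder

## explain a correctly predicted binder: which pixels pushed it there?
ila <- encode_pair("YSPMNEFLW",
                   lookup_pseudosequence(world$registry, "SYN-A*02:01"),
                   fit$scales)
att <- deeplift_attribution(fit, ila)
print(att)
#> Attribution map for YSPMNEFLW / SYN-A*02:01 (34x9x18)
#>   output 0.8037 vs reference 0.5739; total contribution 0.2298
export_heatmap(att, "example")   # example.png + example.csv
```

The printed probabilities are the sigmoid outputs of the trained network.
The attribution map's total contribution equals the output minus the
reference output (DeepLIFT completeness); in the exported heatmap the
rows are peptide positions 1–9, the columns the 34 contact residues, and
red intensity marks contacts that pushed the call towards binder — for
this peptide the planted anchor positions (2, 3 and 9 for this allele)
carry a higher mean attribution (9.1e-4) than the non-planted rows
(6.7e-4).

There is also a command-line interface (`inst/scripts/ilamhc`) with
subcommands `encode`, `simulate`, `train`, `cv`, `predict`, `benchmark`
and `explain`; every run writes a resolved-config JSON next to its
outputs.

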
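# molattn

Interpretable masked-attention Transformer for molecular property
prediction in R.

## What problem this solves

Relating molecular structure to perceptual or biological properties — which
substructures make a molecule smell fruity, musky, fatty — needs models
that are both accurate on sparse multilabel data and *attributable*: a
prediction should point back to the atoms responsible. `molattn` implements
a graph Transformer built for exactly that, aimed at cheminformatics
practitioners studying structure–odor relationships and, more generally,
substructure-driven molecular properties.

## The model

A molecule with *n* heavy atoms is represented by one-hot atom features
(71 dims: identity, neighbor counts, aromaticity, ring membership,
hybridization, chirality, charge, valences), its covalent adjacency matrix
*A*, and the Euclidean distance matrix *D* of one embedded 3D conformer.
Encoder attention runs in two masked branches per head:

    Attn = (softmax(Q_adj K_adj' / sqrt(d_k)) ⊙ A) V_adj
         + (softmax(Q_dist K_dist' / sqrt(d_k)) ⊙ g(D)) V_dist,   g(d) = exp(-d)

so inner-product message passing only carries information between bonded or
spatially close atoms; the masks multiply *after* the softmax, with no
renormalization. Single-branch (`adj_only`, `dist_only`) and additive
(`mat_attn`, `(λ1 softmax(QK') + λ2 g(D) + λ3 A) V`) variants are included
for comparison, plus a `simplified_decoder` ablation (sum pooling).

Each prediction target owns a learnable query vector that cross-attends the
encoder output through decoder-like modules (Transformer decoder layers
without self-attention); the decoder's softmax rows over atoms sum to 1 and
serve directly as atom attributions. Training uses class-weighted binary
cross-entropy (positive weight `(N − P)/P` per target) plus an optional
supervised contrastive loss with temperature τ. Attention-localization
statistics, an ensemble top-k atom-annotation procedure, and an approximate
randomization test for paired model comparison complete the toolkit. A
seeded fragment-grafting generator produces valence-correct synthetic
molecules with controlled substructure prevalence, so the whole pipeline is
testable with no external data.

## Requirements and installation

R (with Rcpp/RcppArmadillo) and a Python interpreter with `rdkit` on the
PATH (or pointed to by `MOLATTN_PYTHON`); chemistry is delegated to a
bundled RDKit helper script.

```sh
R CMD INSTALL .
# run the test suite
Rscript -e 'testthat::test_dir("tests/testthat", package = "molattn", load_package = "installed")'
```

## Worked example

```r
library(molattn)

# 1. synthesize 2,000 molecules with four substructure targets at ~30% prevalence
smi <- generate_molecules(generator_config(2000, seed = 5))
targets <- list(target_spec("ester",    "C(=O)O"),
                target_spec("peroxide", "OO"),
                target_spec("benzene",  "c1ccccc1"),
                target_spec("tbu",      "CC(C)(C)C"))
data <- prepare_molecules(as.character(smi), targets)

# 2. split 5:1, train, evaluate
sp    <- split_dataset(seq_along(data$graphs), seed = 1)
train <- list(graphs = data$graphs[sp$train], labels = data$labels[sp$train, ])
test  <- list(graphs = data$graphs[sp$test],  labels = data$labels[sp$test, ])
fit   <- molattn(train, molattn_config(max_epochs = 14, seed = 1))
evaluate(fit, test)
```

```
metrics_report on 333 samples (threshold 0.5 )
   target  tp fp fn  tn precision recall     f1
    ester  95  0  0 238    1.0000      1 1.0000
 peroxide  92  1  0 240    0.9892      1 0.9946
  benzene 103  0  0 230    1.0000      1 1.0000
      tbu 102  0  0 231    1.0000      1 1.0000
macro F1 = 0.9986   micro F1 = 0.9987
```

Per-target F1 is `2TP/(2TP+FP+FN)`; macro F1 averages the four targets,
micro F1 pools their confusion counts. To see *where* the model looks,
extract decoder attention and compare the mass on the true substructure
atoms with the `|T|/N` chance baseline:

```r
full  <- predict(fit, test, type = "all")
atoms <- substructure_atoms(vapply(test$graphs, `[[`, "", "smiles"), data$targets)
i <- which(test$labels[, "ester"] == 1)[1]          # a true ester
localization_stats(full$attention[[i]]$ester, atoms[[i]]$ester)$normalized
#> e.g. 0.52 on a molecule where ester atoms are 0.28 of the atoms
render_attention(test$graphs[[i]]$smiles,
                 sum_attention(full$attention[[i]]$ester), "ester.svg")
```

In the run above, the mean normalized attention mass on target atoms over
true-positive test molecules exceeded the chance baseline for all four
targets (ratios 1.8, 2.0, 1.6, 1.5) — the attention localizes on the
substructures the model predicts.

A command-line interface wrapping the same functions (subcommands `synth`,
`train`, `eval`, `compare`, `attend`, `render`) ships at
`inst/cli/molattn.R`, and preset hyperparameter grids under `inst/configs/`.

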
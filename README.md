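# clonoreg

Clonality-supervised identification of malignant T cells in single-cell
transcriptomes of cutaneous T-cell lymphoma.

Skin lesions in mycosis fungoides contain malignant T cells — the progeny of
one expanded clone — interleaved with benign bystander T cells.  Because
every T cell carries a near-unique rearranged T-cell receptor, reconstructed
TCR sequences can serve as *natural clonality labels*: this package
partitions each donor's cells into a main clone, related-to-main-clone
cells, bystander groups and single bystanders from their TCR recombinants,
and uses the resulting malignant/bystander targets to supervise an
interpretable classifier on the expression matrix (all TCR variable-region
genes removed, so the receptor cannot leak into the labels).

The classifier, NN-log-reg, is an adaptive logistic regression whose
per-gene weights are produced for each cell by a hypernetwork:

    a(x) = softmax( sigmoid( b_C + W_C tanh( b_B + W_B tanh( b_A + W_A x ))))
    p    = sigmoid( b_D + w_D * a(x)' x )

The adaptive weights `a(x)` (positive, summing to 1 per cell) double as
per-cell gene attention: for every correctly classified cell the genes in
the top 0.5% of `a(x)` are "important" for it, and aggregating across cells
gives a per-gene percentage, significant-gene lists for the training and
test splits, and their overlap.  A standard SELU feed-forward network is
included as a baseline, evaluation is by ROC/AUC on donor-held-out splits,
and a seeded synthetic generator (TCR repertoires with planted clonal
structure, negative-binomial expression with planted 2-fold markers) makes
the whole workflow testable without any external data.

## Worked example

A complete synthetic study at desk scale (5 donors x 100 cells, 2,000 genes
plus TCR decoys, 10 planted markers at 2-fold; about two minutes on one
CPU):

```r
library(clonoreg)

cfg <- sim_config(seed = 1)
sim <- simulate_dataset(cfg)

labels <- assign_clonality(admit_cells(sim$cells))
round(clonality_fractions(labels), 3)
#>            MAIN_CLONE RELATED_TO_MAIN_CLONE       BYSTANDER_GROUP
#>                  0.60                  0.15                  0.10
#>      SINGLE_BYSTANDER
#>                  0.15

ds <- exclude_tcr_genes(sim$dataset)       # drops TRAV/TRAJ/TRBV/TRBJ genes
tc <- train_config(hidden = 64L, seed = 1)
sp <- split_by_donor(ds, tc)               # whole donors per split
model <- nn_logreg_train(sp$train, sp$validation, tc)
model
#> NN-log-reg model: G = 2000 genes, H = 64 | best epoch 231 of 281 (val loss 0.5327)

roc_curve(predict(model, sp$test), sp$test$targets)
#> ROC: AUC = 0.7899 over 101 thresholds

imp_tr <- gene_importance(model, sp$train, set_tag = "TRAIN")
imp_te <- gene_importance(model, sp$test, set_tag = "TEST")
overlap_genes(significant_genes(imp_tr, 0.5), significant_genes(imp_te, 0.5))
#> [1] "GENE0286" "GENE0371" "GENE0458" "GENE0508" "GENE0606" "GENE0614"
#> [7] "GENE0836" "GENE0849" "GENE1261" "GENE1326"
```

The clonality fractions recover the planted 0.60/0.15/0.10/0.15 mix exactly.
The train/test overlap of significant genes contains all five planted
*up*-shifted markers (here GENE0371, GENE0508, GENE0606, GENE0836,
GENE0849); down-shifted markers are used by the model through below-average
attention and by design do not surface in a top-attention list.  The methods
vignette (`vignettes/clonality-supervised-classification.Rmd`) explains the
clonality rules, the training scheme, and the known desk-scale AUC ceiling
of this architecture.

`run_pipeline()` chains all of the above (simulate → clonality → TCR-gene
exclusion → split → train → ROC → importance) into one reproducible run with
a JSON manifest, and `inst/scripts/clonoreg` exposes the same stages as a
command line (`simulate`, `clonality`, `train`, `evaluate`, `importance`,
`run`).

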
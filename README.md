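# hetfuse

Disease-gene prioritization by multi-head attention fusion of
heterogeneous network embeddings.

`hetfuse` scores candidate gene-disease associations for computational
biologists who have typed association tables — gene functional similarity,
disease semantic similarity, gene-disease, gene-miRNA, disease-miRNA,
gene-lncRNA and disease-lncRNA edges — and want a ranked list of candidate
genes per disease. It is aimed at link-prediction studies on heterogeneous
biological networks and at methodologists who want a fully seeded,
self-contained reimplementation of this model family to experiment with.

## The model

Three undirected weighted networks are assembled from the seven relations:
**GD** (gene-disease, with both similarity relations), **GMD**
(gene-miRNA-disease) and **GLD** (gene-lncRNA-disease); an edge exists
exactly when the association weight exceeds 0. Each network is embedded
with node2vec (second-order biased random walks with return parameter *p*
and in-out parameter *q*, fed to skip-gram with negative sampling) and
with LINE (first- plus second-order proximity), giving, for *n*
gene-disease pairs and embedding dimension *e*, three pair-feature
matrices in R^(n x 4e) (gene ⊕ disease per algorithm). The auxiliary
matrices query the GD features with multi-head scaled dot-product
attention (h = 8 heads),

    A_m = MultiHead(X_gmd, X_gd, X_gd),   A_l = MultiHead(X_gld, X_gd, X_gd),

the fused matrix is `linear(concat(A_m, A_l, X_gd))`, each row is
re-weighted element-wise by a self-attention score
`alpha = softmax(H tanh(W x + b))`, and a sigmoid MLP
(`Sigmoid(Linear(Relu(Linear(x))))`, dropout 0.2 after the hidden layer)
outputs an association score in [0, 1]. The whole stack trains end-to-end
under binary cross-entropy with Adam; backpropagation is hand-derived and
verified against finite differences in the test suite. Evaluation follows
balanced negative sampling with 5-fold cross-validation (AUC, AUPR,
accuracy, precision, recall, F1, mean ± sd), plus network-combination
ablations and per-disease candidate ranking. A seeded generator of
synthetic tripartite networks with planted gene-disease associations makes
every stage testable offline.

## Worked example

Simulate a planted-partition benchmark, hold out 20% of the positive
gene-disease edges before embedding, and run the pipeline for the full
fusion and the GD-only ablation:

```r
library(hetfuse)
cfg <- syntheticConfig(nGenes = 120, nDiseases = 20, nLncRNAs = 40,
                       nMiRNAs = 60, nModules = 5, seed = 1)
run <- runPipeline(simCfg = cfg, embedCfg = embedConfig(e = 16, seed = 1),
                   combos = c("GD+GMD+GLD", "GD"), seed = 42)
run$networks$GD
#> HeteroNetwork [GD]: 140 nodes, 7382 edges
#>   nodes: gene=120, disease=20
#>   edges: gene_gene=7140, disease_disease=190, gene_disease=52
for (cb in names(run$perCombo))
  cat(sprintf("%-11s test AUC %.3f  AUPR %.3f\n", cb,
      run$perCombo[[cb]]$metrics$auc, run$perCombo[[cb]]$metrics$aupr))
#> GD+GMD+GLD  test AUC 0.609  AUPR 0.653
#> GD          test AUC 0.859  AUPR 0.901
head(run$test[order(-run$scores), c("gene", "disease", "label")], 3)
#>    gene disease label
#> 2  g117    d014     1
#> 16 g032    d009     0
#> 1  g040    d020     1
```

The held-out test AUC of 0.86 for the GD-only model shows the pipeline
recovering the planted module signal from edges it never saw. On this
synthetic benchmark the auxiliary miRNA/lncRNA networks carry almost no
extra pair-level signal at the configured edge densities, so the full
fusion — whose pair-to-pair attention is transductive and can memorize
its training contexts — scores lower here; the methods vignette
(`vignettes/hetfuse-methods.Rmd`) quantifies both effects and describes
when fusion does help (the test suite includes a construction where the
auxiliary networks carry the signal and fusion wins by a wide margin).

A command-line interface wraps the same functions
(`inst/cli/hetfuse.R`): `simulate`, `build-net`, `embed`, `features`,
`train`, `predict`, `eval`, `ablate` and `rank` subcommands; see
`?hetfuseCLI`.

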
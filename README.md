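# gainet

Graph-based integration of miRNA and promoter CpG methylation effects on
mRNA expression, for multiclass molecular subtype analysis.

## The problem

Bulk transcriptome, miRNA and DNA-methylation profiles from the same
samples are usually integrated either by naive concatenation (which
ignores the biology connecting the layers) or by autoencoder-style
compression (which destroys interpretability). `gainet` takes a third
route: it encodes the known repressive relationships — miRNAs lower the
expression of their target mRNAs, promoter CpG methylation silences the
neighbouring gene — as two weighted bipartite graphs, and converts them
into per-gene, per-sample *modulating factors* that rescale the mRNA
matrix. The result is a single gene-level feature matrix that carries the
combined regulatory evidence, stays interpretable (every feature is still
a gene), and feeds any downstream classifier.

For a gene with $n$ interacting miRNAs and $m$ promoter CpGs
(0–1500 bp upstream of the TSS), per sample:

$$\delta_1 = \frac{1}{n}\sum_{i=1}^{n}
\frac{1}{IS_i \, e^{\alpha \log_2(e_i + 1)}},\qquad
\delta_2 = \frac{1}{m}\sum_{i=1}^{m} \frac{1}{e^{\beta \log_2 b_i}},\qquad
\delta = \frac{w_1\delta_1 + w_2\delta_2}{w_1 + w_2},$$

$$\mathrm{trans(mRNA)} = \delta \times \mathrm{expr(mRNA)},$$

with $e_i$ the partner miRNA's expression, $IS_i \in (0,1]$ its
normalised interaction score, $b_i \in (0,1]$ the CpG's methylation beta
value, and $\alpha = \beta = 1.5$, $w_1{:}w_2 = 1{:}1$ by default.

Around this core the package provides the full working pipeline:
missingness filtering (strict 20% zero/NA rule) and cross-omics sample
intersection, median-of-ratios count normalisation, beta imputation and
clamping, adaptive synthetic minority oversampling, four classifier
families with per-class precision/recall/F1 and macro one-vs-rest AUROC,
tree-path Shapley feature importance with a SIFT/PolyPhen/
haploinsufficiency filter cascade and subtype-unique set logic,
Kaplan–Meier log-rank screening of candidate prognostic genes, and a
seeded synthetic multi-omics generator so everything runs without any
external download.

## Worked example

Entirely self-contained — the bundle is synthetic, with class signal
planted only in the regulators of 16 genes:

```r
library(gainet)

b      <- generateBundle(syntheticConfig(seed = 1))
pre    <- preprocessOmics(b$mrna, b$mirna, b$meth)
ints   <- normalizeInteractionScores(b$interactions)
graphs <- buildGraphs(ints, restrictPromoterMap(b$promoterMap),
                      pre$mrna, pre$mirna, pre$meth)
res    <- transformMatrix(pre$mrna, pre$mirna, pre$meth, graphs)
graphs
#> RegulatoryGraphs: 60 genes with miRNA partners, 60 genes with CpG partners
#>   usable edges: 202 miRNA-gene, 203 CpG-gene (dropped: 0, 0)
res
#> DeltaResult: 60 genes x 150 samples
#>   genes with miRNA factor: 60, with CpG factor: 60

lab  <- b$labels[b$labels$sample_id %in% sampleIds(pre$mrna), ]
sp   <- stratifiedSplit(lab, 0.2, 2)
y    <- setNames(lab$class_label, lab$sample_id)
X    <- t(transformedMatrix(res))
pred <- fitPredict(modelSpec("logistic_ovr", seed = 3),
                   X[sp$train, ], y[sp$train], X[sp$test, ])
evaluateClassifier(y[sp$test], pred$labels, pred$scores)
#> EvalReport: accuracy 1.0000, macro one-vs-rest AUROC 1.0000
#>   class precision recall f1 auroc support
#> 1    C1         1      1  1     1      12
#> 2    C2         1      1  1     1       6
#> 3    C3         1      1  1     1       4
#> 4    C4         1      1  1     1       8

screenGenes(omicsValues(b$mrna), b$survival, b$truth$prognosticGene)
#>   gene statistic            p significant
#> 1 g001  25.02805 5.650239e-07        TRUE
```

The evaluation says the classifier separated all four synthetic subtypes
on the held-out fifth of the data using only the 60 transformed gene
features — even though the class signal was planted exclusively in the
regulator layers. The survival screen recovers the planted prognostic
gene (`g001`, hazard ratio 3) with a log-rank p-value far below the 0.05
threshold.

The same flow is scriptable from a shell through the thin wrapper in
`inst/exec/gainet` (`simulate`, `preprocess`, `transform`, `train`,
`explain`, `survival`, `run` subcommands), and `runPipeline()` executes
all stages with a JSON run manifest whose output digests make seeded runs
verifiably reproducible.

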
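# mirTally

Integrated miRNA–mRNA differential-expression analysis with the
**combinatorial target-count statistic**, for paired expression studies with
a two-factor (age × exposure) design — the setting of primate models of
prenatal alcohol exposure (PAE), where upregulated miRNAs and globally
downregulated mRNAs are observed together and the question is whether they
are functionally linked.

The package is aimed at transcriptomics analysts who have (a) a miRNA
expression matrix over an unbalanced 2×2 design, (b) a per-gene log2
fold-change table from a paired mRNA experiment, and (c) one or more
miRNA→gene target-prediction files (TargetScan-7.2-style, miRWalk-3.0-style,
or generic two-column).

## The statistic at the core

For a target map *T* (a deduplicated miRNA→gene relation) and a miRNA list
*L*, every gene *g* gets an **independent target count**

> c_L(g) = |{ m ∈ L : (m, g) ∈ T }|

— the number of *distinct* miRNAs from *L* predicted to target *g* (never
the number of binding sites). With *L* the list of differentially expressed
(DE) miRNAs (two-factor Type III ANOVA, p < 0.05 and |log2FC| > 1), the
analysis relates c(g) to the gene's mRNA log2 fold change: a negative
count–fold-change association is the signature of combinatorial repression.
Specificity is established against a matched control list — the 24 non-DE
miRNAs with main-effect p-values nearest 1 (strong interaction effects
excluded) — via the per-category **residual fold change**
mean_fc_DE(k) − mean_fc_control(k) and a Welch t-test between genes with
≥ 4 hits from either list. A replication pass with a second prediction
algorithm guards against artifacts of any one predictor.

Supporting stages: MAS5-style detection calls and the
expression/species/uniqueness probe filter, RMA-style summarization
(quantile normalization + median polish), Storey q-values, and a
first-principal-component-ordered co-expression view of the DE miRNAs with
genomic-cluster statistics.

## Worked example

The built-in generator plants known structure — 24 upregulated miRNAs
(+1.5 log2 under exposure, 5 of them a co-expressed cluster on chromosome
24), 3 downregulated, and gene-wise mRNA depression of 0.02 log2 units per
targeting DE miRNA — so every downstream number has a known truth.

```r
library(mirTally)

ds  <- simulatePairedData(synthConfig(seed = 1))
res <- fitTwoFactorAnova(ds$mirna)
de  <- selectDE(res)                  # p < 0.05 and |log2FC| > 1, strict
ctrl <- selectControlList(res)        # 24 non-DE miRNAs, p ~ 1

counts <- buildTargetCountTable(ds$maps$targetscan7, de$up, ctrl,
                                ds$mrnaFoldChange)
g  <- groupFoldChange(counts, "de")
rs <- residualFoldChange(g$summary, groupFoldChange(counts, "control")$summary)
tt <- compareFoldChangeTTest(counts, minHits = 4)

cat("DE miRNAs:", length(de$up), "up /", length(de$down), "down\n")
cat("expected sub-0.05 count under the null:",
    expectedNullCount(nrow(res), 0.05), "\n")
cat("count-FC slope:", round(g$test$estimate_slope, 4),
    " (planted: -0.02), p =", format(g$test$p, digits = 3), "\n")
cat("negative residual categories:", round(mean(rs$residual < 0), 2), "\n")
cat("mean FC, >=4 hits: DE", round(tt$mean_de, 3),
    "vs control", round(tt$mean_control, 3),
    ", Welch p =", format(tt$p, digits = 3), "\n")
cat("DE-vs-control count correlation r =",
    round(mapOverlapCorrelation(counts), 2), "\n")

cs <- clusterStats(ds$mirna, ds$annotation, chrom = "24", window = c(0, 2e6))
cat("chr24 cluster:", cs$n_members, "members, mean r =",
    round(cs$mean_r, 3), "\n")
```

Output:

```
DE miRNAs: 24 up / 3 down
expected sub-0.05 count under the null: 30
count-FC slope: -0.0205  (planted: -0.02), p = 0
negative residual categories: 0.86
mean FC, >=4 hits: DE -0.124 vs control -0.102 , Welch p = 4.07e-10
DE-vs-control count correlation r = 0.76
chr24 cluster: 5 members, mean r = 0.976
```

Reading it: all 24 planted upregulated miRNAs are recovered (and the 3
downregulated ones); the per-hit depression slope matches the planted
−0.02 (its correlation p-value underflows to 0 at this problem size); residuals are predominantly negative, and heavily targeted genes of
the DE list are more depressed than equally targeted genes of the control
list — even though the two lists' target counts correlate at r ≈ 0.76,
i.e. they largely share their frequent targets. The planted chromosome-24
cluster is recovered with its configured ~0.97 mean pairwise correlation.

`runPipeline(fixturePipelineConfig(dir))` executes the same chain on a
fixture directory written by `writeFixture()` (or on your own TSV files via
`pipelineConfig()`) and writes every intermediate table, a stats JSON and a
run log; identical configurations reproduce byte-identical output bundles.

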
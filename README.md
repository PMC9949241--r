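# MicrogliaStates

Microglia (MG) — the brain's resident immune cells — change
transcriptional state with age and after ischemic stroke. Two hallmark
readouts in single-cell RNA-seq of the post-stroke brain are the
expansion of *disease-associated microglia* (DAM; high `Lpl`, `Spp1`,
`Cst7`, `Itgax`) and the induction of the interferon-stimulated gene
`Ifi27l2a`, which rises with stroke, rises further with age, and
anti-correlates with the DAM program inside MG.

MicrogliaStates implements that analysis as a tested, reusable pipeline
for gene-by-cell count matrices over a 2×2 aging-by-stroke design,
aimed at analysts who want each stage reproducible and scoreable rather
than embedded in an interactive session:

* **I/O** — 10x-convention MatrixMarket triplets (`matrix.mtx`,
  `features.tsv`, `barcodes.tsv`) plus a per-cell condition table and
  two-column gene-signature files (`readTenx()`, `writeTenx()`,
  `readSignatures()`).
* **Normalization** — per-cell scaling to a fixed total and natural
  log1p: `v_gc = ln(1 + 10000 · c_gc / Σ_g c_gc)` (`logNormalizeCells()`).
* **Annotation** — marker-signature scoring (mean z-scored expression
  per signature) with deterministic argmax labels
  (`scoreSignatures()`, `assignTypes()`, `cellComposition()`).
* **Differential expression** — Wilcoxon rank-sum per gene with
  Benjamini–Hochberg correction in the FindMarkers-style table
  conventions: `avg_logfc = mean_b − mean_a` of log-normalized values,
  `fold_change = 2^avg_logfc`, percent-expressing by `count > 0`
  (`groupStats()`, `rankMarkers()`, `wilcoxRankSum()`, plus
  `ddctFold()` for the qPCR 2^−ΔΔCt convention).
* **DAM gate** — a compound count threshold: a cell is DAM when it is
  annotated MG and every gate gene (`Aif1`, `Spp1`, `Cst7`, `Lpl` by
  default) reaches its per-gene minimum raw count (`gateDAM()`,
  `damSummary()`).
* **Ifi27l2a stratification** — half-open expression bins
  ([0.3,1), [1,2), [2,3), [3,∞)), cell-level Spearman correlation
  against DAM / homeostatic / DAM-down gene programs, a high/low
  dichotomy at 1.0 normalized units, and per-subcluster induction as a
  plain ratio of group means (`binCells()`, `binProfile()`,
  `trendCorrelation()`, `splitHighLow()`, `subclusterFoldChange()`).
* **Simulator** — a seeded negative-binomial generator with planted
  ground truth (cell types, latent DAM identity, Ifi27l2a induction
  multipliers with an aging×stroke synergy term) emulating the study
  design: 5,706 / 12,866 / 5,174 / 8,226 cells across
  young-sham / young-stroke / aged-sham / aged-stroke and DAM fractions
  0 / 10.2 / 0.9 / 17.9 % of MG (`defaultSimConfig()`,
  `simulateCells()`, `truthTable()`).

Everything is orchestrated by `runPipeline()`, which writes plain TSV
tables plus a JSON manifest and is byte-reproducible under a fixed
seed. A thin CLI wrapper lives in `inst/scripts/run_pipeline.R`.

## Worked example

Simulate a 10%-scale study, run the stages, and summarize:

```r
library(MicrogliaStates)
library(SingleCellExperiment)

cfg  <- defaultSimConfig(seed = 1, cellScale = 0.1)
sce  <- logNormalizeCells(simulateCells(cfg))
ann  <- assignTypes(scoreSignatures(sce, defaultCellTypeSignatures()))
gate <- gateDAM(sce, ann, gateConfig())
damSummary(gate, colData(sce)$condition)
#>     condition n_MG n_DAM   pct_DAM
#>     aged_sham  212     3  1.415094
#>   aged_stroke  318    67 21.069182
#>    young_sham  229     0  0.000000
#>  young_stroke  387    51 13.178295
```

The gate percentages reproduce the planted ordering — no DAM in young
sham, a trace in aged sham, and a stroke-driven expansion that aging
amplifies (at this small scale the percentages are noisy; the full-scale
run in `scripts/acceptance.R` pins them down). Differential expression
within MG between the stroke conditions puts the interferon-stimulated
gene on top:

```r
cond <- colData(sce)$condition; mg <- ann$label == "MG"
groupStats(sce, mg & cond == "young_stroke", mg & cond == "aged_stroke",
           genes = c("Ifi27l2a", "Lpl", "Cst7", "Aif1"))
#>      gene mean_a mean_b pct_a pct_b avg_logfc fold_change        p    p_adj
#>  Ifi27l2a  1.123  1.605 0.822 0.912    0.4816       1.396 2.11e-15 8.44e-15
#>       Lpl  0.295  0.443 0.207 0.264    0.1483       1.108 3.56e-02 4.75e-02
#>      Cst7  0.284  0.453 0.209 0.280    0.1691       1.124 1.14e-02 2.28e-02
#>      Aif1  1.689  1.662 0.995 0.997   -0.0265       0.982 4.71e-01 4.71e-01
```

`Ifi27l2a` rises ~1.4-fold (log2 scale 0.48) with a jump in percent
expressing (82% → 91%), the DAM genes move with the larger DAM
compartment, and the pan-microglial `Aif1` stays flat. The one-call
version writes every table and prints a summary:

```r
dir <- tempfile()
runPipeline(dir, simConfig = cfg)
pipelineReport(dir)
#> # Pipeline report (MicrogliaStates 0.1.0, seed 1)
#> - dge_young_stroke_vs_aged_stroke: top induced gene Ifi27l2a (avg_logfc 0.48, fold 1.40)
#> - DAM: aged_sham 1.4%, aged_stroke 21.1%, young_sham 0.0%, young_stroke 13.2%
#> - Ifi27l2a vs DAM: 5/5 genes negatively correlated
#> - Ifi27l2a vs homeostatic: 2/4 genes negatively correlated
#> - Ifi27l2a vs DAM_down: 0/4 genes negatively correlated
```

All five DAM-program genes anti-correlate with `Ifi27l2a` inside aged
MG, while homeostatic genes do not — the planted structure, recovered
by the pipeline's own statistics.

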
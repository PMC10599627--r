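# csfShift

Quantifying how human cerebrospinal fluid (CSF) shifts patient-derived
glioblastoma (GBM) cells toward quiescent, mesenchymal-like,
therapy-resistant states.

GBM cells are usually studied in defined glioma medium (GM), but in the
brain they live in CSF. `csfShift` is an R/Bioconductor-style toolkit for
the full quantitative analysis of a GM-vs-CSF comparison, for
computational biologists analysing paired two-condition single-cell
experiments on patient-derived lines and the accompanying plate and
electrophysiology assays:

* **Single-cell QC** — 200-gene / 3-cell prefiltering to a fixed point,
  four-criterion outlier tagging (>55,000 reads, <2,000 detected genes,
  <70 of 98 housekeeping genes, >20% mitochondrial reads; per-line
  overrides) and per-line GM/CSF balancing.
* **Program scoring** — global-scaling log-normalization
  (`ln(1 + 10^4 · c/total)`), binned-dispersion HVG selection, and
  expression-bin-matched module scores: for each program gene, 100
  control genes are drawn from its expression bin (24 bins) and
  `score = mean(program) − mean(controls)`. Proliferation
  = (G1S + G2M)/2, Cycling iff ≥ 0; Quiescent iff quiescence score ≥ 0.
* **Cell states** — the four GBM meta-modules (AC/MES/NPC/OPC) on a
  two-axis projection with `D = max(OPC,NPC) − max(AC,MES)`,
  `y = sign(D)·log2(|D|+1)`, and quadrant assignment AC (x<0,y<0),
  MES (x>0,y<0), NPC (x>0,y>0), OPC (x<0,y>0); per-line composition.
* **Differential expression** — 700-cell-per-line-per-condition balanced
  downsampling (10 lines → 14,000 cells), per-gene Wilcoxon rank-sum
  (exact enumeration at group sizes ≤ 8), Bonferroni correction,
  top-20 markers, and GSEA rank scores
  `sign(log2FC)·−log10(p_adj)`.
* **Preranked GSEA** — the weighted enrichment statistic
  (hits add `|r|/N_R`, misses subtract `1/(N−N_H)`; ES = signed maximum
  deviation), 1,000 gene-set permutations, mean-division NES,
  permutation p and pooled FDR q; GMT/RNK file support.
* **Cytotoxicity assays** — paired-control viability, responsiveness
  stratification (<50% / 50–90% / >90% and the 50–75% variant),
  CSF-vs-GM resistance fold change, and bounded 4PL dose-response fits
  `v(d) = bottom + (top−bottom)/(1+(d/IC50)^hill)`; comparative-CT qPCR
  (`fold = 2^−ΔΔCt`).
* **MEA neurotoxicity** — 6-SD adaptive spike detection, >5 spikes/min
  active-neuron filtering, bursts (≥5 spikes, ISI ≤ 100 ms), network
  events (≥50 pooled spikes, ISI ≤ 80 ms), 500-ms population event
  vectors, phase AUC, and control-normalized percent-change matrices.
* **Synthetic data** — generators for all three data types with planted,
  recoverable condition effects (negative-binomial counts, 4PL plates,
  Poisson-plus-planted spike trains), so the whole pipeline runs and is
  tested without any external download.

## Worked example

```r
library(csfShift)

params <- ScSimParams(nPatients = 3, nCellsPerCondition = 300, seed = 7)
sce    <- simulateCells(params)                       # counts + ground truth
sce    <- runQC(sce, qcThresholds(minGenesOutlier = 500), seed = 8)
sce    <- logNormalize(sce)

gsc    <- defaultGeneSets(sce)                        # AC/MES/NPC/OPC/G1S/G2M/quiescence
scores <- scoreCells(sce, gsc, seed = 9)
csf    <- sce$condition == "CSF"
```

The planted CSF effects (MES +1 log2, quiescence +0.5, cycle −0.5) are
recovered by the scores:

```
mean MES score     GM -0.214   CSF  0.239
quiescent fraction GM  0.299   CSF  0.690
```

State classification shows the MES takeover in CSF:

```r
states <- projectStates(scores)                 # corrected-mode quadrants
prop.table(table(states$state, sce$condition), 2)
#>          GM   CSF
#>   AC  0.309 0.104
#>   MES 0.017 0.661
#>   NPC 0.316 0.085
#>   OPC 0.357 0.150
```

Balanced differential expression ranks the planted NUPR1-like
stress-response gene first, and GSEA calls the planted programs:

```r
down <- logNormalize(downsampleBalanced(sce, quota = 250, seed = 10))
de   <- wilcoxonDE(down)
head(de[order(-de$rank_score, de$gene), c("avg_log2FC", "p_adj", "rank_score")], 3)
#>       avg_log2FC         p_adj rank_score
#> NUPR1  1.3404907 1.325072e-108  107.87776
#> G0231  0.9387581  7.133056e-59   58.14672
#> G0251  0.9300247  9.681070e-56   55.01408

gseaPreranked(rankGenes(de),
              geneSets(gsc)[c("MES", "quiescence", "G1S", "G2M")],
              nPerm = 1000, seed = 11)[, c("set", "ES", "NES", "p_perm")]
#>          set     ES   NES  p_perm
#> 1        MES  0.990  1.36 0.00104
#> 2 quiescence  0.947  1.29 0.00104
#> 3        G1S -0.976 -1.50 0.03390
#> 4        G2M -0.975 -1.56 0.01042
```

Positive enrichment of the MES and quiescence programs in CSF and
negative enrichment of both cell-cycle programs — the full planted
phenotype — at permutation p < 0.05 throughout.

`runPipeline(defaultPipelineConfig(), "out/", seed = 1)` chains all of
the above at full scale (10 lines × 2 × 800 cells), writes every stage
product as plain text and a manifest with config, seeds and MD5
checksums; `inst/scripts/pipeline.R` wraps it for the shell.

## Acceptance script

`scripts/acceptance.R` re-runs the complete pipeline from scratch — the
full-scale simulation, QC, scoring, state classification, balanced
differential expression, 1,000-permutation GSEA, plus the 4PL
dose-response and MEA spike-train arms — deriving all randomness from
`--seed`, and writes its results JSON to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## The vignette

`vignettes/csfShift-methods.Rmd` documents the model and every numerical
choice: the QC rule interactions, the control-bin scoring construction,
the three state-projection modes (including the as-written audit mode and
its documented inconsistency), the exact/approximate Wilcoxon branches,
the GSEA estimator and its floor, 4PL initialization and reliability
flags, the MEA event definitions, and precisely what the synthetic world
does and does not emulate.
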
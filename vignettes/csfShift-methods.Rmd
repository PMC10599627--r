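---
title: "Methods: quantifying CSF-induced state shifts in glioblastoma cells"
author: "csfShift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying CSF-induced state shifts in glioblastoma cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfShift)
```

# The scientific problem

Patient-derived glioblastoma (GBM) cells are normally propagated in a
defined serum-free glioma medium (GM). In the tumor, however, infiltrating
cells are bathed in cerebrospinal fluid (CSF), and exposure to CSF pushes
GBM cells toward slow-cycling, quiescent, mesenchymal-like (MES)
transcriptional states associated with therapy resistance. `csfShift`
implements the complete quantitative toolkit needed to measure that shift:
single-cell QC and condition balancing, per-cell program scoring,
cell-state classification, differential expression, preranked gene-set
enrichment, plate-based cytotoxicity and dose-response analysis, and
multielectrode-array (MEA) neurotoxicity metrics — together with a
synthetic-data generator that plants known effects so every stage is
testable offline.

# Single-cell quality control

`qcThresholds()` carries the filtering rules as data, none hard-coded:

* **Prefilter** — cells expressing ≥ 200 genes, genes expressed in ≥ 3
  cells. The two rules interact, so `prefilterCells()` applies the cell
  pass, then the gene pass, and iterates to a fixed point; the output
  provably satisfies both rules simultaneously. The order (cells first)
  and the fixed-point iteration are our choice — the source text is
  silent — and make the contract checkable.
* **Outlier tagging** — a cell is an outlier iff it violates *any* of:
  more than 55,000 reads (per-line overrides, e.g. 80,000 for a deeply
  sequenced line), fewer than 2,000 detected genes (per-line overrides
  500/800/1,000 for shallow libraries), fewer than 70 of a 98-gene
  housekeeping panel, or more than 20% mitochondrial reads.
  `flagOutliers()` returns every violated criterion as a reason code.
  The original analysis "tags" outliers; since all downstream figures use
  filtered data we remove them, with `keepFlagged = TRUE` as an audit
  mode. The mitochondrial fraction denominator (total raw counts) is also
  unstated in the source and is our definition.
* **Condition balancing** — within each line both conditions are
  subsampled to `min(nGM, nCSF)` cells, uniformly without replacement,
  reproducibly from a seed.

Whether the original pipeline applied the outlier rules before or after
the prefilter is unknowable from the text; we prefilter first (the
outlier metrics are then computed on cells that are at least droplets),
and the audit mode preserves both populations for inspection.

# Normalization, variable genes, module scores

`logNormalize()` uses global scaling: each value becomes
`ln(1 + 10000 * count / cellTotal)`. Natural log is our reading of
"log-transformed"; it matches the default of the toolchain the analysis
names.

`selectHVG()` ranks genes by a mean-binned normalized dispersion
(variance/mean on the back-transformed scale, z-scored within 20
equal-frequency mean bins, ties broken by gene order). The source states
only "top 2000 genes"; the statistic is the classic dispersion flavor of
that toolchain.

`moduleScore()` is the expression-bin-matched program score: all genes are
cut into 24 equal-frequency bins by mean expression; for each program
gene, 100 control genes are sampled from its bin (with replacement when
the bin is smaller); the score is the mean expression of the program
genes minus the mean of the pooled controls. The defaults (24 bins, 100
controls) are the documented behavior of the scoring function the
analysis called, exposed as parameters. Program genes are sorted before
control sampling so the score depends only on the gene *set*. On null
data the score is centered at zero; the test suite verifies
`|mean| < 0.02` across random 50-gene sets.

Derived quantities: proliferation score = (G1S + G2M)/2; Cycling iff
proliferation ≥ 0 (the text says "positive (≥0)" — we follow the
inclusive operator, not the word); Quiescent iff quiescence score ≥ 0.
The source also contains a second, caption-level cycling definition
(G1S > 0 *or* G2M > 0); both are implemented (`cyclingMode = "average"`
default, `"max"` alternative) because the two disagree on cells with one
positive and one negative cycle score, and the text cannot adjudicate
which produced the published panels.

# Cell-state projection

Meta-module scores for the four GBM states (AC-like, MES-like with its
two 50-gene halves, NPC-like, OPC-like) feed a two-axis "butterfly"
projection with quadrant semantics AC (x<0, y<0), MES (x>0, y<0),
NPC (x>0, y>0), OPC (x<0, y>0). Three modes:

* **corrected** (default): `D = max(OPC, NPC) − max(AC, MES)`,
  `y = sign(D)·log2(|D|+1)`; `x = sign(NPC−OPC)·log2(|NPC−OPC|+1)` in the
  upper half, `x = sign(MES−AC)·log2(|MES−AC|+1)` in the lower half. A
  cell's dominant score then determines its quadrant, which is what the
  published quadrant rule requires.
* **as_written**: the printed formulas verbatim. They can take log2 of a
  non-positive argument (such cells are flagged undefined) and they
  strand dominant-NPC cells at x = 0 with y < 0 — an internal
  inconsistency we reproduce as a characterization, not a behavior we
  claim the authors ran. Boundary cells are left unclassified here so the
  inconsistency stays visible; in corrected mode boundary cells (x = 0 or
  y = 0, measure-zero in practice) fall back to the argmax state and are
  counted separately.
* **argmax**: state = largest score; used as the cross-check. On cells
  whose top score dominates by ≥ 0.3 the corrected quadrant agrees with
  argmax on ≥ 99% (it is deterministic algebra, verified on 5,000
  synthetic cells).

# Differential expression and GSEA

`downsampleBalanced()` subsamples every line to 700 cells per condition
(10 lines → 14,000 cells, 7,000 per condition) before the pooled CSF-vs-GM
comparison. `wilcoxonDE()` runs a two-sided rank-sum test per gene on the
log-normalized values: exact enumeration of the permutation distribution
for group sizes ≤ 8, the tie-corrected normal approximation above
(oracle-equivalence tests bound the approximation). All genes are tested
("default parameters": no min-pct or fold-change prefilter) and corrected
by Bonferroni over the tested universe. The fold change back-transforms
the normalized values with pseudocount 1 —
`log2(mean(expm1(x_CSF)) + 1) − log2(mean(expm1(x_GM)) + 1)` — the
documented default of the referenced toolchain. Genes are ranked for GSEA
by `sign(log2FC) · −log10(p_adj)`.

`gseaPreranked()` implements the weighted statistic: walking the ranked
list, hits add `|r|/NR`, misses subtract `1/(N−NH)`; the ES is the
running sum's signed maximum deviation. The null is 1,000 random
same-size gene sets; NES divides the ES by the mean |ES| of same-sign
nulls (mean-division normalization); the permutation p uses the add-one
estimator `(1 + #{same-sign |null| ≥ |ES|}) / (1 + #same-sign)`, which is
never exactly zero (the reference software reports 0 below its
resolution; the estimator is the statistically defensible choice and its
floor is `1/(1 + #same-sign nulls)`). FDR q across ≥ 2 sets uses the
pooled normalized-null procedure; a single-set run falls back to q = p.
A null permutation set landing entirely on zero-weight genes (possible
when many adjusted p-values saturate at 1) is assigned ES = 0, its
zero-weight limit. Ties in rank scores are broken by gene id before the
walk, for determinism. The leading-edge convention for negative ES
(set genes at or after the extremum) mirrors the positive case; the
reference software's exact convention is not restated in the text.

# Plate assays and qPCR

`plateViability()` normalizes nuclei counts to the mean of paired
vehicle-control wells (controls average 100% by construction).
`stratifyResponsiveness()` labels lines responsive (< 50% survival),
moderate, or unresponsive with configurable cutpoints; the printed
interval conventions differ between assays (50–90% for temozolomide in
the results text, 50–75% for irradiation/combination in the captions), so
both are presets and boundary values join the lower-resistance class
("<50" strict, the closed interval inclusive, ">75/90" strict).
`resistanceFoldChange()` normalizes each line's viability in both
conditions to the mean population survival in GM and reports the ratio.

`fit4PL()` fits `v(d) = bottom + (top−bottom)/(1+(d/IC50)^hill)` by
bounded least squares (top/bottom initialized from the extreme-dose
means, IC50 from the log-dose midpoint crossing, hill = 1; IC50 bounded
positive; Nelder–Mead fallback). Fits are flagged `reliable = FALSE`
when non-convergent, non-inhibitory, or with IC50 far outside the dose
range. At the simulation's stated noise (6 doses × 6 replicates, 5%
replicate CV) the IC50 estimate has a relative sampling SD near 5%, so
recovery is assessed as the aggregate accuracy of a multi-seed
experiment — a per-seed worst-case guarantee tighter than ~2 SD is not
achievable by any consistent estimator at that design, and the test
suite says so explicitly.

`ddct()` implements comparative-CT quantitation
(ΔΔCt, fold = 2^−ΔΔCt) against a stable reference gene; no efficiency
correction, since the source states the comparative-CT method only.

# MEA spike-train metrics

`detectSpikes()` thresholds a voltage trace at 6 SDs above the local mean
background noise. The rolling-noise window (10 ms) and refractory
hold-off (1 ms) are our parameters — the vendor values are not public —
and the noise statistics are computed on a spike-clipped copy of the
trace (clipped at median ± 4 robust SDs) so large deflections do not
inflate their own threshold; detection is invariant to rescaling the
trace. `filterActive()` keeps neurons firing strictly more than 5
spikes/min. `detectBursts()` finds maximal runs of ≥ 5 spikes with every
inter-spike interval ≤ 100 ms; `detectNetworkEvents()` applies the same
maximal-run rule to the pooled well train with ≥ 50 spikes and ≤ 80 ms.
Maximal greedy-left runs are the unique parameter-faithful reading of
"(minimum spikes, maximum ISI)" and match a brute-force sliding-scan
oracle on random trains; a 1-ns guard keeps an ISI exactly at the limit
inside a run despite floating-point timestamps.
`populationVector()` binarizes spikes per neuron per frame, sums across
neurons and smooths with a centered 500-ms rolling window.
`treatmentAUC()` integrates a metric over an annotated phase by the
trapezoid rule, optionally after a two-point moving average.
`normalizedPercentChange()` expresses each well's change from its
pretreatment baseline relative to vehicle-control wells; "normalized to
the percent change in the control" is ambiguous between a ratio and a
subtraction, so both modes ship (`ratio` default) and neither is claimed
to be the original computation.

# The synthetic world

`simulateCells()` states the cohort the pipeline targets: 10 patient
lines × 2 conditions × 800 cells, 2,000 genes. Each of eight programs
(AC, MES1, MES2, NPC, OPC, G1S, G2M, quiescence; sizes matching the gene
sets used downstream, e.g. 43/54/100 for G1S/G2M/quiescence and 50+50
for the MES halves) has per-patient baseline activity (SD 0.2 log2),
a CSF condition shift, and per-cell noise (SD 0.3 log2). Default planted
effects are the ones the pipeline must recover: MES +1 log2, quiescence
+0.5, G1S and G2M −0.5 each, plus one NUPR1-like stress-response gene up
1.5 log2 in CSF. Gene baseline weights are log-uniform over e^−2..e^2;
the 98-gene housekeeping panel and the 13-gene mitochondrial block are
drawn at the *top of that continuum* rather than as detached
high-expression islands — bin-matched control scoring presumes a
continuous expression distribution, and an island above the continuum
makes the top bins heterogeneous and biases null scores (we measured the
random-set score SD dropping threefold when the islands were embedded).
The cost is a modest baseline mitochondrial fraction (~2–3%, low-normal
for cultured lines); planted mito violators are still pushed past the
20% threshold. Counts are negative binomial (dispersion 0.4) with
lognormal library sizes (median ~12,000 reads). Since the simulated
transcriptome has 2,000 genes, pipeline runs on synthetic data use the
500-gene outlier threshold (one of the published per-line override
values) instead of the 2,000-gene default, which would flag every cell.

A configurable 2% of cells violate exactly one QC criterion each, in
rotation: library 75,000 (reads), library 450 (detected genes fall
between the 200-gene prefilter and the 500-gene outlier threshold), all
but 40 housekeeping genes zeroed, or the mitochondrial block rescaled to
~30% of reads. This makes the QC tests deterministic. Ground truth
(planted effects, violator list, program gene lists) travels with the
object and is serialized as JSON by the pipeline.

What the generator does **not** emulate: ambient RNA, doublets, batch
chemistry, patient-specific gene-level heterogeneity beyond program
activity, or raw reads. A green recovery test therefore establishes that
the statistics do what they claim on data with the assumed structure —
not that the published biological effect sizes are reproduced; the
original cohort (25 lines, fresh CSF, real 10x libraries) is not
reproducible at desk scale. The source gives no distributional
description of its data, so all generator choices are stand-ins, stated
once here and fixed.

`simulatePlate()` draws nuclei counts from a known 4PL curve with
multiplicative replicate noise; `simulateSpikeTrains()` overlays planted
bursts and network events on Poisson background firing. All three
generators are bit-reproducible from their seed.

# Orchestration and reproducibility

`runPipeline()` executes simulate → QC → normalize → HVG → score →
states → DE → GSEA, writing every stage product as plain text (MTX
triplet, TSV, GMT, RNK, JSON) plus a manifest with the full config,
seeds, and per-file MD5 checksums; stages communicate through files so
each is independently reproducible, and re-running with the same config
and seed reproduces identical checksums. Functions that sample take an
explicit seed and restore the caller's RNG state; the pipeline derives
per-stage child seeds from the master seed. Unknown configuration keys
are rejected rather than ignored.

# Known limitations

* The gene sets are synthetic stand-ins wired to the generator; the
  published signature lists (Tirosh cycle, Atkins quiescence, Neftel
  meta-modules) are not redistributed with the package, and
  `readGmt()` exists precisely so users can supply them.
* The exact-enumeration Wilcoxon branch is O(C(n1+n2, n1)) and capped at
  group sizes of 8 by default.
* `detectSpikes()` is a reference implementation of the 6-SD adaptive
  rule, not a reimplementation of the vendor's acquisition stack; spike
  sorting is out of scope (sorted trains are the expected input).
* The as-written projection mode is shipped for audit only; none of the
  three modes is claimed to be the authors' exact code.
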
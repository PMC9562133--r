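# tandemdup

Genome-wide analysis of **tandem duplicated genes (TDGs)** for plant
molecular-evolution studies — built around the question of how salt-tolerant
grasses accumulated stress-response genes through gene duplication.

Tandem duplication places a gene's copy at an adjacent chromosomal
position; arrays of such copies are a major source of stress-adaptation
genes. `tandemdup` provides the complete analysis chain as an R package:

* **Detection** — tandem pairs and clusters from gene order (GFF3) plus
  filtered all-vs-all protein homology (BLAST outfmt-6; `E < 1e-10`, top
  10 matches per query, rank gap ≤ 1), with chromosome-distribution
  summaries.
* **Ka/Ks** — Nei–Gojobori (1986) counting on protein-guided codon
  alignments: synonymous/nonsynonymous site counts, pathway-averaged
  differences, Jukes–Cantor correction, selection labels
  (Ka/Ks < 1 purifying, = 1 neutral, > 1 positive).
* **Dating** — the molecular clock `T = Ks / (2λ)` with
  λ = 1.5 × 10⁻⁸ synonymous substitutions · site⁻¹ · year⁻¹, and Ks
  histogram peak detection (bin width 0.1) per tissue-response class.
* **Enrichment** — hypergeometric over-representation with
  Benjamini–Hochberg q-values, the *rich factor* k/n, and shared/unique
  partitioning of term sets.
* **Salt-stress classification** — from per-contrast DE tables
  (FDR ≤ 0.05, log2FC ≥ 1, one-sided), genes are leaf-specific (≥ 4 up
  events in leaves, ≤ 1 in roots), root-specific (symmetric), co-expressed
  (≥ 7 events in total) or unclassified.
* **Synthetic data** — a generator for genomes with planted tandem arrays,
  codon pairs diverged at known Ka and Ks, planted enriched terms and a
  two-tissue × five-timepoint × three-replicate salt-stress design, plus a
  ground-truth manifest, so the whole pipeline is testable offline.

## Worked example

```r
library(tandemdup)
rep <- runPipeline(defaultSimConfig(rngSeed = 1), outDir = "tdg_run")

rep$tdgCount                  # 390
rep$tdgFraction               # 8.86   (% of the 4,400-gene synthetic genome)
rep$recovery$ari              # 1      (planted clusters recovered exactly)
rep$classSummary$counts       # leaf_specific 48, root_specific 116,
                              # co_expressed 138, unclassified 88
rep$classSummary$totalResponsive  # 302
subset(rep$peaks, class == "whole" & primary)
#   class  lo  hi midpoint count primary t_ma t_lo_ma t_hi_ma
#   whole 0.6 0.7     0.65    98    TRUE 21.7      20    23.3
```

The run writes plain-text intermediates (`genes.gff3`, `cds.fasta`,
`homology.tsv`, `de.tsv`, `kaks.tsv`, `enrichment.tsv`, …) under
`outDir`, so each stage can equally be driven by real data — a genuine
BLASTP table, a DESeq2 output table — in place of the simulated files.
The numbers above read: 390 of 4,400 genes sit in tandem arrays (8.86%),
all 126 planted arrays are recovered at homology-noise 0, 302 TDGs
respond to salt stress (48 leaf-specific / 116 root-specific / 138
co-expressed), and the genome-wide Ks distribution peaks in [0.6, 0.7),
dating the duplication burst to 20.0–23.3 Ma.

Individual stages are exported directly: `detectTandem()`,
`computeKaKs()`, `divergenceTime()`, `histogramPeaks()`,
`hypergeomEnrich()`, `classifyTissue()`, and the generators
`generateGenome()` / `generateExpression()` / `generateHomologyTable()`.
See the vignette (`vignettes/tandem-duplication-analysis.Rmd`) for the
model, parameter meanings and design decisions.

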
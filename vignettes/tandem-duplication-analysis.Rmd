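---
title: "Tandem duplication analysis: detection, Ka/Ks dating and salt-stress classification"
author: "tandemdup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tandem duplication analysis: detection, Ka/Ks dating and salt-stress classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemdup)
```

## Scope and model

`tandemdup` implements a genome-wide tandem-duplicated-gene (TDG) analysis
of the kind used to study stress adaptation in halophytic grasses. The
chain is:

1. **Tandem detection.** Genes are ranked by start coordinate within each
   chromosome. An all-vs-all protein homology table (BLAST outfmt-6 layout)
   is filtered to hits with `E < 1e-10`, at most 10 subjects per query;
   a homologous pair at rank distance `<= maxGap` (default 1, i.e.
   strictly consecutive genes) on one chromosome is a tandem pair, and
   clusters are the connected components of the tandem-pair graph.
2. **Ka/Ks.** For designated pairs (consecutive cluster members), protein
   sequences are globally aligned (Needleman–Wunsch, BLOSUM62, affine
   gaps), back-translated to codon alignments, and fed to the
   Nei–Gojobori (1986) counting method: per-position synonymous site
   fractions, difference counts averaged over all `k!` substitution
   pathways per codon pair, and Jukes–Cantor correction
   `d = -3/4 log(1 - 4/3 p)`. `Ka/Ks < 1` is purifying (negative)
   selection, `= 1` neutral, `> 1` positive.
3. **Dating.** Duplication events are dated with the molecular clock
   `T = Ks / (2 lambda)` with `lambda = 1.5e-8` synonymous substitutions
   per site per year (a grass-lineage rate; configurable). A Ks of 0.6–0.7
   dates to 20.0–23.3 Ma, a Ks of 2.5 to 83.3 Ma.
4. **Ks landscape.** Filtered Ks values (undefined and values above a cap
   of 3.5 removed) are binned at width 0.1; the modal bin is the primary
   peak and local maxima reaching 25% of the modal count, at least 3 bins
   away, are secondary peaks. Distributions are compared across
   tissue-response classes; a pair belongs to a class only when both
   members share it.
5. **Enrichment.** Hypergeometric upper-tail over-representation of a
   study set against term assignments, with Benjamini–Hochberg q-values
   and the *rich factor* `k/n` (study genes in a term over all genes in
   that term), plus Venn-style shared/unique partitioning of several
   enriched-term sets.
6. **Salt-stress classification.** From per-contrast differential
   expression (gene x tissue x timepoint), an up-regulation event requires
   `FDR <= 0.05` and `log2FC >= 1` (one-sided). A gene with `>= 4` events
   in one tissue and `<= 1` in the other is tissue-specific; otherwise
   `>= 7` events in total across both tissues makes it co-expressed;
   otherwise it is unclassified.

## A worked example

```{r example, eval = FALSE}
cfg <- defaultSimConfig(rngSeed = 1)
rep <- runPipeline(cfg, outDir = "tdg_run")
rep$tdgCount          # 390 TDGs (8.86% of 4,400 genes)
rep$recovery$ari      # 1 at noise 0
rep$classSummary      # 48 / 116 / 138, total 302
rep$peaks             # whole-set modal bin [0.6, 0.7) -> 20.0-23.3 Ma
```

Every intermediate is a plain-text file (GFF3, FASTA, outfmt-6 TSV,
headered TSV, JSON), so any stage can be re-driven from real data: a
genuine BLASTP table can replace `homology.tsv`, a DESeq2 result table can
replace `de.tsv`.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `evalueMax` | 1e-10 (strict `<`) | homology inclusion threshold |
| `topN` | 10 | best-scoring subjects kept per query |
| `maxGap` | 1 | maximum rank distance of a tandem pair |
| `lambda` | 1.5e-8 /site/year | synonymous clock rate for `T = Ks/2λ` |
| `binWidth` | 0.1 | Ks histogram bin width |
| `ksCap` | 3.5 | Ks retention cap (NG86 saturates beyond ~3) |
| `fdrMax`, `lfcMin` | 0.05, 1 | up-regulation event thresholds |
| `specMin`, `otherMax`, `coMin` | 4, 1, 7 | tissue-classification rule |
| `qMax` | 0.05 | enrichment significance threshold |

Design choices where the method family is genuinely open:

* **Tandem gap.** Duplicate classifiers in the MCScanX family do not fix a
  single published gap; we default to strictly consecutive ranks
  (`maxGap = 1`), the most conservative reading, and expose the parameter.
* **"First 10 matches."** Interpreted per query after a deterministic sort
  (bitscore, then E-value, then subject id), reproducing the intent of
  BLAST's `-max_target_seqs` without its tie ambiguity. Homology is then
  symmetric-closed: a pair survives if either direction does, since
  duplication is a symmetric relation.
* **Clock rate.** The rate is taken as `1.5e-8` substitutions/site/year;
  this is the only reading consistent with dating Ks 0.6–0.7 to 20.0–23.3
  Ma and Ks 2.5 to 83.3 Ma.
* **Which pairs get Ka/Ks.** Within a cluster of size *s* we compute the
  *s − 1* consecutive-rank pairs rather than all *s(s−1)/2* pairs; this
  keeps one divergence estimate per duplication edge and is recorded in
  the run's parameter log.
* **Co-expression rule.** "Up-regulated at least seven times in both
  tissues" is implemented as a *total* of 7 events across both tissues:
  with five timepoints per tissue, seven in each is impossible, so the sum
  is the only consistent reading. Specificity is tested before
  co-expression (they cannot both fire at the defaults, but the order
  matters for larger designs).
* **Enrichment background.** All annotated genes (standard ORA practice),
  and only terms with at least one study hit are tested — this defines the
  BH denominator.

## Numerical choices

* **Stop codons in NG86.** Site counting treats mutations to stop codons
  as nonsynonymous, so `S + N = 3 x` included codons. Pathways passing
  through a stop are dropped from the pathway average; a codon pair whose
  pathways all drop is excluded entirely. Alignment columns containing
  gaps, stops or ambiguous bases never enter the counts.
* **Saturation.** The Jukes–Cantor correction diverges at `p = 0.75`; at
  or beyond it the estimate is returned as `NA` ("undefined"), never
  clamped. The Ka/Ks ratio is undefined (not zero) when `Ks = 0`.
* **Rounding.** Report tables round half-up (2 decimals for percentages
  and ratios, 1 for times in Ma); full precision is kept internally.
  Peak-interval bounds are rounded at the 10th decimal to keep bin edges
  exactly representable.
* **Determinism.** One seed drives named substreams per stage; the same
  seed yields byte-identical output files. Rank ties (shared start
  coordinate) break by end then gene id; top-N ties by subject id;
  histogram modal-bin ties by the lower bin.

## What the synthetic data emulate — and what they do not

The generator (`generateGenome`, `generateHomologyTable`,
`generateExpression`, `generateTermAssignments`) produces every input the
pipeline consumes, with a ground-truth manifest. The default study
conditions (`defaultSimConfig()`) are a 10-chromosome genome of 4,400
genes with 126 planted tandem arrays (390 TDGs, 8.86% of the gene set;
sizes 2–9), a two-tissue x five-timepoint (8 h, 12 h, 24 h, 48 h, 5 d) x
three-replicate salt-stress design with planted classes of 48
leaf-specific, 116 root-specific and 138 co-expressed genes (302
responsive TDGs), and ten terms over-represented in the TDG set. Most
clusters are planted at Ks ≈ 0.65 (the recent duplication regime);
twelve leaf-specific clusters at Ks ≈ 2.45 carry the older regime. These
sizes keep a full run around a minute on one core while preserving the
structure of a real genome scan; they are a deliberate scale-down of a
~29,000-gene genome.

The codon simulator applies per-site uniform nucleotide proposals with
stop rejection, calibrated by expected synonymous/nonsynonymous site
counts, so it shares no difference-counting machinery with the estimator
it is used to validate. Expected recovery holds well below saturation
(within a few percent up to Ks ≈ 1); near Ks 2.5 estimates scatter widely
and about half are flagged saturated — visible in the pipeline's leaf
class, whose old-regime pairs spread across high-Ks bins instead of
forming the sharp interval a direct value-level histogram shows.

Not emulated: read-level sequencing (FASTQ), mapping, isoforms, codon
usage bias, transition/transversion bias, indel evolution, GO DAG
structure, and negative-binomial dispersion trends. Passing tests
therefore demonstrate correctness of the estimators and rules on data
satisfying their assumptions, not robustness to every artefact of real
RNA-seq or real annotation pipelines. The expression module's
`simpleDE()` is a transparent stand-in (normalised-mean log2FC plus a
pooled t-test with BH correction), not a replacement for a
negative-binomial GLM; DE tables from dedicated tools can be supplied
directly.

## Known limitations

* NG86 is a counting method: no transition/transversion weighting, no
  codon-frequency correction, no maximum-likelihood (GY94-style)
  alternative. Beyond Ks ≈ 2 its estimates are biased upward and
  increasingly often saturated; dates derived from such peaks inherit
  that uncertainty.
* Only the tandem duplicate class is detected — segmental, proximal and
  dispersed duplicates (and synteny blocks generally) are out of scope.
* Enrichment ignores term topology (GO DAG propagation, pathway
  structure).
* The tissue classifier counts up-regulation events only; down-regulation
  is not analysed.
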
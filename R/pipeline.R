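# End-to-end orchestration: simulate -> detect -> Ka/Ks -> classify ->
# date -> enrich -> report, with one seed, plain-text intermediates and a
# consolidated report. Every stage reads its inputs from the written files
# so any stage can be re-driven from external tools' outputs.

#' Consecutive-rank gene pairs within clusters
#'
#' The designated Ka/Ks pairs: for each cluster, members at adjacent ranks
#' form a pair. This choice (rather than all within-cluster pairs) is
#' recorded in the pipeline's parameter log.
#'
#' @param clusters a [TandemClusters-class].
#' @return data.frame `gene1`, `gene2`.
#' @export
adjacentClusterPairs <- function(clusters) {
  stopifnot(is(clusters, "TandemClusters"))
  rows <- lapply(clusters@members, function(mm) {
    if (length(mm) < 2L) return(NULL)
    data.frame(gene1 = mm[-length(mm)], gene2 = mm[-1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene1 = character(), gene2 = character())
  }
  rownames(out) <- NULL
  out
}

#' Adjusted Rand index between two cluster labelings
#'
#' @param a,b named vectors (or plain vectors of equal length) of cluster
#'   labels; names are matched when present.
#' @return the Hubert-Arabie adjusted Rand index.
#' @export
adjustedRand <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  }
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  maxIdx <- (ai + bj) / 2
  if (maxIdx == expected) return(1)
  (nij - expected) / (maxIdx - expected)
}

#' Compare detected clusters against the planted truth
#'
#' @param clusters detected [TandemClusters-class].
#' @param manifest truth manifest from [generateGenome()].
#' @return list: `ari` (adjusted Rand index over the union of planted and
#'   detected genes, singletons for genes missing from either side),
#'   `exactRecovered` (planted clusters whose member sets are detected
#'   exactly), `nPlanted`, `nDetected`, `recoveryRate`.
#' @export
clusterRecovery <- function(clusters, manifest) {
  planted <- lapply(manifest$clusters, `[[`, "members")
  detected <- clusters@members
  labelsOf <- function(sets, genes, prefix) {
    lab <- stats::setNames(paste0("s_", genes), genes)  # singletons
    for (i in seq_along(sets)) {
      lab[sets[[i]]] <- paste0(prefix, i)
    }
    lab
  }
  genes <- union(unlist(planted), unlist(detected))
  truth <- labelsOf(planted, genes, "p")
  found <- labelsOf(detected, genes, "d")
  key <- function(mm) paste(sort(mm), collapse = ",")
  exact <- sum(vapply(planted, key, "") %in%
                 vapply(detected, key, ""))
  list(ari = adjustedRand(truth, found),
       exactRecovered = exact,
       nPlanted = length(planted),
       nDetected = length(detected),
       recoveryRate = if (length(planted)) exact / length(planted) else NA)
}

#' Run the full synthetic tandem-duplication analysis
#'
#' Simulates a genome, homology, term and expression data from `config`,
#' writes all intermediates under `outDir` (GFF3, FASTA, outfmt-6 TSV,
#' manifest JSON, counts/design/DE TSV), then re-reads them to run tandem
#' detection, Ka/Ks estimation on consecutive within-cluster pairs,
#' tissue classification, per-class Ks dating, and term enrichment.
#' Deterministic given `config@rngSeed`: the same seed yields byte-identical
#' output tables.
#'
#' @param config a [SimConfig-class]; default [defaultSimConfig()].
#' @param outDir output directory (created if needed).
#' @param evalueMax,topN,maxGap tandem-detection parameters.
#' @param lambda clock rate for dating.
#' @param binWidth,ksCap Ks histogram parameters.
#' @param fdrMax,lfcMin up-regulation thresholds.
#' @param specMin,otherMax,coMin tissue-classification thresholds.
#' @param qMax enrichment significance threshold.
#' @return invisible report list: `tdgCount`, `tdgFraction`,
#'   `distribution`, `clusterSizeTable`, `kaks`, `peaks` (per-class peak
#'   table with dated midpoints), `enrichment`, `setRegions`,
#'   `classSummary`, `recovery`, `params`.
#' @export
runPipeline <- function(config = defaultSimConfig(), outDir = tempfile("tdg"),
                        evalueMax = 1e-10, topN = 10, maxGap = 1,
                        lambda = 1.5e-8, binWidth = 0.1, ksCap = 3.5,
                        fdrMax = 0.05, lfcMin = 1,
                        specMin = 4, otherMax = 1, coMin = 7,
                        qMax = 0.05) {
  stopifnot(is(config, "SimConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- config@rngSeed
  params <- list(evalueMax = evalueMax, topN = topN, maxGap = maxGap,
                 lambda = lambda, binWidth = binWidth, ksCap = ksCap,
                 fdrMax = fdrMax, lfcMin = lfcMin, specMin = specMin,
                 otherMax = otherMax, coMin = coMin, qMax = qMax,
                 rngSeed = seed, kaksPairs = "consecutive_rank")

  # -- simulate ------------------------------------------------------------
  sim <- generateGenome(config)
  writeGeneAnnotation(sim$annotation, file.path(outDir, "genes.gff3"))
  Biostrings::writeXStringSet(sim$cds, file.path(outDir, "cds.fasta"))
  Biostrings::writeXStringSet(sim$proteins,
                              file.path(outDir, "proteins.fasta"))
  writeManifest(sim$manifest, file.path(outDir, "manifest.json"))
  hom <- generateHomologyTable(sim$annotation, sim$manifest,
                               noise = config@backgroundNoise,
                               seed = substreamSeed(seed, "homology"))
  writeHomologyTable(hom, file.path(outDir, "homology.tsv"))
  expr <- generateExpression(config, sim$manifest,
                             seed = substreamSeed(seed, "expression"))
  writeTsv(cbind(data.frame(gene_id = rownames(expr$counts)),
                 as.data.frame(expr$counts)),
           file.path(outDir, "counts.tsv"))
  writeTsv(expr$design, file.path(outDir, "design.tsv"))
  writeTsv(expr$de, file.path(outDir, "de.tsv"))

  # -- detect (from the on-disk intermediates) -----------------------------
  annotation <- readGeneAnnotation(file.path(outDir, "genes.gff3"))
  hits <- readHomologyTable(file.path(outDir, "homology.tsv"))
  clusters <- detectTandem(annotation, hits, evalueMax = evalueMax,
                           topN = topN, maxGap = maxGap)
  tdg <- tdgGenes(clusters)
  writeTsv(as.data.frame(clusters), file.path(outDir, "clusters.tsv"))
  dist <- chromosomeDistribution(tdg, annotation)
  writeTsv(dist, file.path(outDir, "tdg_distribution.tsv"))

  # -- Ka/Ks on consecutive within-cluster pairs ---------------------------
  cds <- Biostrings::readDNAStringSet(file.path(outDir, "cds.fasta"))
  prot <- Biostrings::readAAStringSet(file.path(outDir, "proteins.fasta"))
  pairs <- adjacentClusterPairs(clusters)
  kaks <- computeKaKs(pairs, cds, prot, lambda = lambda)
  writeTsv(kaks, file.path(outDir, "kaks.tsv"))

  # -- tissue classification ----------------------------------------------
  de <- readTsv(file.path(outDir, "de.tsv"))
  calls <- callUp(de, fdrMax = fdrMax, lfcMin = lfcMin)
  upCounts <- countUpEvents(calls)
  classes <- classifyTissue(upCounts, tissues = config@tissues,
                            specMin = specMin, otherMax = otherMax,
                            coMin = coMin)
  writeTsv(classes, file.path(outDir, "tissue_classes.tsv"))
  classSummary <- summarizeClasses(classes, tdg, tissues = config@tissues)

  # -- Ks landscape and dating --------------------------------------------
  cmp <- classKsCompare(kaks, classes[, c("gene_id", "label")],
                        classes = c(paste0(config@tissues, "_specific"),
                                    "co_expressed"),
                        ksCap = ksCap, binWidth = binWidth)
  peaks <- cmp$peakTable
  if (nrow(peaks)) {
    peaks$t_ma <- divergenceTime(peaks$midpoint, lambda)
    peaks$t_lo_ma <- divergenceTime(peaks$lo, lambda)
    peaks$t_hi_ma <- divergenceTime(peaks$hi, lambda)
  }
  writeTsv(peaks, file.path(outDir, "ks_peaks.tsv"))

  # -- enrichment ----------------------------------------------------------
  manifest <- readManifest(file.path(outDir, "manifest.json"))
  terms <- generateTermAssignments(manifest$genes, config@plantedTerms,
                                   study = tdg,
                                   seed = substreamSeed(seed, "terms"))
  writeTsv(terms, file.path(outDir, "term_assignments.tsv"))
  enr <- hypergeomEnrich(tdg, terms, background = manifest$genes,
                         qMax = qMax)
  writeTsv(enr, file.path(outDir, "enrichment.tsv"))
  classSets <- lapply(
    stats::setNames(nm = c(paste0(config@tissues, "_specific"),
                           "co_expressed")),
    function(cl) {
      st <- intersect(classes$gene_id[classes$label == cl], manifest$genes)
      e <- hypergeomEnrich(st, terms, background = manifest$genes,
                           qMax = qMax)
      e$term_id[e$significant]
    })
  setRegions <- setComparison(classSets)

  # -- report --------------------------------------------------------------
  recovery <- clusterRecovery(clusters, manifest)
  sizeTab <- table(factor(clusterSizes(clusters), levels = 2:9))
  report <- list(
    tdgCount = length(tdg),
    tdgFraction = tdgFraction(tdg, annotation),
    distribution = dist,
    clusterSizeTable = sizeTab,
    clusters = clusters,
    kaks = kaks,
    ksDistributions = cmp$distributions,
    peaks = peaks,
    enrichment = enr,
    setRegions = setRegions,
    classes = classes,
    classSummary = classSummary,
    recovery = recovery,
    params = params,
    outDir = outDir
  )
  jsonlite::write_json(params, file.path(outDir, "params.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
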
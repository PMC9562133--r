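# Synthetic-data generation: genomes with planted tandem arrays, codon
# pairs diverged at specified Ka and Ks, homology tables, term assignments
# with planted over-representation, and a salt-stress time-course
# expression design -- all tied to a ground-truth manifest.

#' Random stop-free coding sequence
#'
#' @param nCodons number of codons.
#' @param codeTable optional alternative genetic code.
#' @return a character CDS of length `3 * nCodons` with no stop codons.
#' @export
randomCDS <- function(nCodons, codeTable = NULL) {
  code <- geneticCode(codeTable)
  sense <- names(code)[code != "*"]
  paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}

# Apply a Poisson number of synonymous and nonsynonymous single-nucleotide
# substitutions to a codon vector. Events are uniform proposals over
# (codon, position, alternative base), rejection-sampled to the required
# class and rejecting stops, so each synonymous "site unit" receives equal
# rate. Calibration uses the ancestor's expected site counts; the
# substitution engine shares no difference-counting code with the NG86
# estimator it is used to test.
evolveLineage <- function(codons, dS, dN, codeTable = NULL) {
  tabs <- ng86Tables(codeTable)
  code <- tabs$code
  S0 <- sum(tabs$sites[codons])
  N0 <- 3 * length(codons) - S0
  nSyn <- stats::rpois(1L, dS * S0)
  nNon <- stats::rpois(1L, dN * N0)
  want <- sample(c(rep(TRUE, nSyn), rep(FALSE, nNon)))
  for (syn in want) {
    for (try in seq_len(10000L)) {
      i <- sample.int(length(codons), 1L)
      pos <- sample.int(3L, 1L)
      cur <- codons[[i]]
      curNts <- strsplit(cur, "")[[1]]
      alt <- sample(setdiff(NUCS, curNts[pos]), 1L)
      nxt <- curNts; nxt[pos] <- alt
      nxtCodon <- paste(nxt, collapse = "")
      if (code[[nxtCodon]] == "*") next
      isSyn <- code[[nxtCodon]] == code[[cur]]
      if (isSyn == syn) { codons[[i]] <- nxtCodon; break }
      if (try == 10000L) stop("substitution sampling failed", call. = FALSE)
    }
  }
  codons
}

#' Evolve a pair of coding sequences to a target Ks and Ka/Ks
#'
#' Two descendants of one ancestor, each receiving an independent Poisson
#' number of synonymous and nonsynonymous substitutions calibrated so that
#' the expected pairwise divergence is `targetKs` synonymous and
#' `targetKaks * targetKs` nonsynonymous substitutions per site. At
#' `targetKs = 0` (and a zero nonsynonymous target) both descendants equal
#' the ancestor.
#'
#' @param ancestor ancestral CDS (character; length a multiple of 3;
#'   >= 100 codons recommended for stable downstream estimation).
#' @param targetKs expected synonymous divergence between the descendants
#'   (>= 0).
#' @param targetKaks expected Ka/Ks of the pair (>= 0).
#' @param seed optional integer seed.
#' @param codeTable optional alternative genetic code.
#' @return list with character CDS `cdsA` and `cdsB`.
#' @export
evolveCodonPair <- function(ancestor, targetKs, targetKaks = 0.2,
                            seed = NULL, codeTable = NULL) {
  if (targetKs < 0) stop("targetKs must be >= 0", call. = FALSE)
  if (targetKaks < 0) stop("targetKaks must be >= 0", call. = FALSE)
  codons <- splitCodons(ancestor)
  withSeed(seed, {
    dS <- targetKs / 2
    dN <- targetKs * targetKaks / 2
    list(
      cdsA = paste(evolveLineage(codons, dS, dN, codeTable), collapse = ""),
      cdsB = paste(evolveLineage(codons, dS, dN, codeTable), collapse = "")
    )
  })
}

#' Generate a synthetic genome with planted tandem arrays
#'
#' Lays out ordered, non-overlapping genes on each chromosome (gene lengths
#' log-normal around 300 codons, fixed 500-bp intergenic gaps). Genes of a
#' planted cluster occupy consecutive ranks and descend from one ancestral
#' CDS, each lineage diverged so that pairwise Ks and Ka/Ks match the
#' cluster's planted truth. All other genes get independent random CDS. CDS
#' are stop-free multiples of 3 and translate exactly to the emitted
#' proteins.
#'
#' @param config a [SimConfig-class].
#' @return list: `annotation` (`GRanges` with `gene_id`), `cds`
#'   (`DNAStringSet`), `proteins` (`AAStringSet`), `manifest` (ground
#'   truth: cluster membership, per-pair true Ka/Ks, per-gene tissue class,
#'   planted enriched terms, gene lengths).
#' @export
generateGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withSeed(substreamSeed(config@rngSeed, "genome"), {
    chromNames <- sprintf("chr%02d", seq_len(config@nChromosomes))
    nPer <- config@genesPerChromosome
    pc <- config@plantedClusters
    if (nrow(pc) && is.null(pc$class)) pc$class <- NA_character_

    geneIds <- character(0); geneChrom <- character(0)
    geneStart <- integer(0); geneEnd <- integer(0); geneStrand <- character(0)
    cdsList <- character(0)
    clusters <- list(); pairTruth <- list()

    for (chr in chromNames) {
      nCod <- pmax(100L, as.integer(round(stats::rlnorm(nPer, log(300),
                                                        0.25))))
      ids <- sprintf("%sg%04d", chr, seq_len(nPer))
      cds <- vapply(nCod, randomCDS, "")
      sub <- pc[pc$chromosome == chr, , drop = FALSE]
      if (nrow(sub)) {
        for (ci in seq_len(nrow(sub))) {
          sz <- sub$size[ci]
          ancLen <- max(150L,
                        as.integer(round(stats::rlnorm(1, log(300), 0.25))))
          anc <- splitCodons(randomCDS(ancLen))
          dS <- sub$trueKs[ci] / 2
          dN <- sub$trueKs[ci] * sub$trueKaks[ci] / 2
          idx <- sub$startRank[ci] + seq_len(sz)  # ranks are 0-based
          memberCds <- vapply(seq_len(sz), function(k) {
            paste(evolveLineage(anc, dS, dN), collapse = "")
          }, "")
          cds[idx] <- memberCds
          nCod[idx] <- ancLen
          members <- ids[idx]
          clusters[[length(clusters) + 1L]] <- list(
            cluster_id = sprintf("PC%04d", length(clusters) + 1L),
            chromosome = chr, members = members,
            trueKs = sub$trueKs[ci], trueKaks = sub$trueKaks[ci],
            class = sub$class[ci]
          )
          if (sz >= 2L) {
            pairTruth[[length(pairTruth) + 1L]] <- data.frame(
              gene1 = members[-sz], gene2 = members[-1L],
              trueKs = sub$trueKs[ci], trueKaks = sub$trueKaks[ci],
              stringsAsFactors = FALSE
            )
          }
        }
      }
      lenBp <- 3L * nCod
      starts <- cumsum(c(1L, utils::head(lenBp, -1L) + 500L))
      geneIds <- c(geneIds, ids)
      geneChrom <- c(geneChrom, rep(chr, nPer))
      geneStart <- c(geneStart, starts)
      geneEnd <- c(geneEnd, starts + lenBp - 1L)
      geneStrand <- c(geneStrand, sample(c("+", "-"), nPer, replace = TRUE))
      cdsList <- c(cdsList, stats::setNames(cds, ids))
    }

    annotation <- GenomicRanges::GRanges(
      seqnames = geneChrom,
      ranges = IRanges::IRanges(start = geneStart, end = geneEnd),
      strand = geneStrand,
      gene_id = geneIds
    )
    cdsSet <- Biostrings::DNAStringSet(cdsList)
    proteins <- Biostrings::AAStringSet(vapply(cdsList, function(x) {
      paste(translateCodons(splitCodons(x)), collapse = "")
    }, ""))

    geneClasses <- do.call(rbind, lapply(clusters, function(cl) {
      if (is.na(cl$class)) return(NULL)
      data.frame(gene_id = cl$members, label = cl$class,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(geneClasses)) {
      geneClasses <- data.frame(gene_id = character(), label = character())
    }
    manifest <- list(
      genes = geneIds,
      geneLengths = stats::setNames(geneEnd - geneStart + 1L, geneIds),
      clusters = clusters,
      pairTruth = if (length(pairTruth)) {
        do.call(rbind, pairTruth)
      } else {
        data.frame(gene1 = character(), gene2 = character(),
                   trueKs = numeric(), trueKaks = numeric())
      },
      geneClasses = geneClasses,
      enrichedTerms = as.character(config@plantedTerms$term_id),
      rngSeed = config@rngSeed
    )
    list(annotation = annotation, cds = cdsSet, proteins = proteins,
         manifest = manifest)
  })
}

#' Generate a synthetic all-vs-all homology table
#'
#' Emits self-hits for every gene, both directions of every within-cluster
#' gene pair at E-values far below 1e-10, and (optionally) spurious
#' non-tandem noise pairs. A noise partner is never a planted-cluster gene,
#' so spurious hits cannot join two distinct planted clusters, and always
#' lies on another chromosome or more than `minNoiseGap` ranks away.
#'
#' @param annotation genome annotation (`GRanges` or frame).
#' @param manifest truth manifest from [generateGenome()].
#' @param noise per-gene probability of one spurious homolog pair.
#' @param seed optional integer seed.
#' @param minNoiseGap minimum rank separation of a same-chromosome noise
#'   pair (default 5).
#' @return data.frame in 12-column BLAST outfmt-6 layout.
#' @export
generateHomologyTable <- function(annotation, manifest, noise = 0,
                                  seed = NULL, minNoiseGap = 5L) {
  stopifnot(noise >= 0, noise <= 1)
  ranked <- assignRanks(annotation)
  aaLen <- as.integer(manifest$geneLengths[ranked$gene_id] / 3L)
  names(aaLen) <- ranked$gene_id
  withSeed(seed, {
    row6 <- function(q, s, pident, len, evalue, bits) {
      data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
                 mismatch = as.integer(round(len * (100 - pident) / 100)),
                 gapopen = 0L, qstart = 1L, qend = len, sstart = 1L,
                 send = len, evalue = evalue, bitscore = bits,
                 stringsAsFactors = FALSE)
    }
    out <- list(row6(ranked$gene_id, ranked$gene_id, 100,
                     unname(aaLen[ranked$gene_id]), 0,
                     round(1.9 * unname(aaLen[ranked$gene_id]))))
    clusterGenes <- unlist(lapply(manifest$clusters, `[[`, "members"),
                           use.names = FALSE)
    for (cl in manifest$clusters) {
      mm <- cl$members
      if (length(mm) < 2L) next
      prs <- utils::combn(mm, 2L)
      for (k in seq_len(ncol(prs))) {
        g1 <- prs[1, k]; g2 <- prs[2, k]
        len <- min(aaLen[[g1]], aaLen[[g2]])
        pid <- stats::runif(1, 80, 95)
        bits <- round(1.5 * len)
        out[[length(out) + 1L]] <- rbind(
          row6(g1, g2, pid, len, 1e-180, bits),
          row6(g2, g1, pid, len, 1e-180, bits)
        )
      }
    }
    if (noise > 0) {
      rankOf <- stats::setNames(ranked$rank, ranked$gene_id)
      chromOf <- stats::setNames(ranked$chromosome, ranked$gene_id)
      nonPlanted <- setdiff(ranked$gene_id, clusterGenes)
      noisy <- ranked$gene_id[stats::runif(nrow(ranked)) < noise]
      for (g in noisy) {
        ok <- nonPlanted[nonPlanted != g &
                           (chromOf[nonPlanted] != chromOf[[g]] |
                              abs(rankOf[nonPlanted] - rankOf[[g]]) >
                                minNoiseGap)]
        if (!length(ok)) next
        partner <- ok[sample.int(length(ok), 1L)]
        len <- min(aaLen[[g]], aaLen[[partner]])
        out[[length(out) + 1L]] <-
          row6(g, partner, stats::runif(1, 60, 80), len, 1e-20,
               round(0.8 * len))
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Generate term assignments with planted over-representation
#'
#' Each planted term receives `studyOverlap` genes from the study set and
#' `termSize - studyOverlap` from outside it; background terms draw genes
#' at random, so only planted terms are systematically over-represented.
#'
#' @param genes all gene ids (the annotated background).
#' @param plantedTerms data.frame `term_id`, `termSize`, `studyOverlap`.
#' @param study character vector of study genes (e.g. the planted TDG set).
#' @param seed optional integer seed.
#' @param nBackgroundTerms number of unplanted terms (default 25).
#' @param bgSizeRange size range for background terms.
#' @return data.frame `gene_id`, `term_id`, `term_name`, `namespace`.
#' @export
generateTermAssignments <- function(genes, plantedTerms, study,
                                    seed = NULL, nBackgroundTerms = 25L,
                                    bgSizeRange = c(10L, 50L)) {
  stopifnot(all(study %in% genes))
  withSeed(seed, {
    rows <- list()
    nonStudy <- setdiff(genes, study)
    if (nrow(plantedTerms)) {
      for (i in seq_len(nrow(plantedTerms))) {
        ov <- plantedTerms$studyOverlap[i]
        sz <- plantedTerms$termSize[i]
        stopifnot(ov <= sz, ov <= length(study),
                  sz - ov <= length(nonStudy))
        members <- c(sample(study, ov), sample(nonStudy, sz - ov))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = members,
          term_id = plantedTerms$term_id[i],
          term_name = paste("planted process", plantedTerms$term_id[i]),
          namespace = "biological_process",
          stringsAsFactors = FALSE
        )
      }
    }
    for (i in seq_len(nBackgroundTerms)) {
      sz <- sample(seq(bgSizeRange[1], bgSizeRange[2]), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sample(genes, sz),
        term_id = sprintf("BG:%04d", i),
        term_name = sprintf("background process %d", i),
        namespace = "biological_process",
        stringsAsFactors = FALSE
      )
    }
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res
  })
}

#' Generate a salt-stress time-course expression experiment
#'
#' Emulates a two-tissue, five-timepoint (8 h, 12 h, 24 h, 48 h, 5 d),
#' three-replicate design of 400 mM NaCl treatment versus water control.
#' Counts are negative binomial around per-gene log-normal baselines;
#' planted tissue-specific genes receive a 4-fold treatment effect at every
#' timepoint of their tissue and none in the other, and planted
#' co-expressed genes a 4-fold effect at four timepoints in each tissue
#' (8 events). The DE tables are the primary product: per gene x tissue x
#' timepoint records whose log2 fold changes and FDRs reflect the planted
#' truth plus observation noise, as an external DE engine would report
#' them.
#'
#' @param config a [SimConfig-class] (design dimensions and tissues).
#' @param manifest truth manifest from [generateGenome()] (gene ids,
#'   lengths, per-gene classes).
#' @param seed optional integer seed.
#' @return list: `counts` (gene x sample matrix), `lengths` (bp),
#'   `design` (sample, tissue, timepoint, condition, replicate), `de`
#'   (DE records: gene_id, tissue, timepoint, log2fc, fdr).
#' @export
generateExpression <- function(config, manifest, seed = NULL) {
  stopifnot(is(config, "SimConfig"))
  if (length(config@tissues) != 2L) {
    stop("expression design requires exactly two tissues", call. = FALSE)
  }
  genes <- manifest$genes
  classes <- manifest$geneClasses
  if (nrow(classes) > length(genes)) {
    stop("more planted class labels than genes", call. = FALSE)
  }
  tps <- if (config@nTimepoints == 5L) {
    c("8h", "12h", "24h", "48h", "5d")
  } else {
    sprintf("t%02d", seq_len(config@nTimepoints))
  }
  tissues <- config@tissues
  withSeed(seed, {
    nG <- length(genes)
    labelOf <- stats::setNames(rep(NA_character_, nG), genes)
    if (nrow(classes)) labelOf[classes$gene_id] <- classes$label

    # planted fold change per gene x (tissue, timepoint)
    contrasts <- expand.grid(tissue = tissues, timepoint = tps,
                             stringsAsFactors = FALSE)
    fold <- matrix(1, nrow = nG, ncol = nrow(contrasts),
                   dimnames = list(genes, paste(contrasts$tissue,
                                                contrasts$timepoint)))
    nCo <- min(config@nTimepoints, 4L)
    for (g in names(labelOf)[!is.na(labelOf)]) {
      lab <- labelOf[[g]]
      if (lab == paste0(tissues[1], "_specific")) {
        fold[g, contrasts$tissue == tissues[1]] <- 4
      } else if (lab == paste0(tissues[2], "_specific")) {
        fold[g, contrasts$tissue == tissues[2]] <- 4
      } else if (lab == "co_expressed") {
        for (ti in tissues) {
          cols <- which(contrasts$tissue == ti)[seq_len(nCo)]
          fold[g, cols] <- 4
        }
      }
    }

    design <- expand.grid(replicate = seq_len(config@nReplicates),
                          condition = c("control", "salt"),
                          timepoint = tps, tissue = tissues,
                          stringsAsFactors = FALSE)
    design$sample <- with(design, paste(tissue, timepoint, condition,
                                        paste0("r", replicate), sep = "_"))
    design <- design[, c("sample", "tissue", "timepoint", "condition",
                         "replicate")]

    mu <- stats::rlnorm(nG, log(200), 1)
    counts <- matrix(0L, nrow = nG, ncol = nrow(design),
                     dimnames = list(genes, design$sample))
    for (j in seq_len(nrow(design))) {
      fc <- if (design$condition[j] == "salt") {
        fold[, paste(design$tissue[j], design$timepoint[j])]
      } else rep(1, nG)
      counts[, j] <- stats::rnbinom(nG, mu = mu * fc, size = 10)
    }

    isEvent <- as.vector(fold >= 2)
    de <- data.frame(
      gene_id = rep(genes, times = nrow(contrasts)),
      tissue = rep(contrasts$tissue, each = nG),
      timepoint = rep(contrasts$timepoint, each = nG),
      stringsAsFactors = FALSE
    )
    # column-major over (gene, contrast), matching fold's layout
    de$log2fc <- ifelse(isEvent,
                        log2(as.vector(fold)) + stats::rnorm(nG * nrow(contrasts), 0, 0.05),
                        stats::rnorm(nG * nrow(contrasts), 0, 0.25))
    de$fdr <- ifelse(isEvent,
                     10^-stats::runif(nG * nrow(contrasts), 3, 6),
                     stats::runif(nG * nrow(contrasts)))
    list(counts = counts,
         lengths = unname(manifest$geneLengths[genes]),
         design = design, de = de)
  })
}

#' Default synthetic study configuration
#'
#' The packaged study conditions: a 10-chromosome genome of 4,400 genes
#' carrying 126 planted tandem clusters (390 TDGs, 8.86% of the gene set;
#' sizes 2-9). Most clusters diverged around Ks 0.65 (the recent
#' whole-genome-duplication regime); twelve leaf-specific clusters diverged
#' around Ks 2.45 (the older regime), so the leaf class carries a second,
#' older peak. Planted tissue classes total 48 leaf-specific, 116
#' root-specific and 138 co-expressed genes; ten planted terms are
#' over-represented in the TDG set.
#'
#' @param rngSeed integer seed driving placement and all downstream
#'   simulation.
#' @param backgroundNoise spurious-homolog probability (default 0).
#' @return a [SimConfig-class].
#' @export
defaultSimConfig <- function(rngSeed = 1L, backgroundNoise = 0) {
  spec <- rbind(
    data.frame(size = rep(2L, 12), ksMean = 2.45, class = "leaf_specific"),
    data.frame(size = rep(3L, 8), ksMean = 0.65, class = "leaf_specific"),
    data.frame(size = rep(4L, 29), ksMean = 0.65, class = "root_specific"),
    data.frame(size = rep(3L, 46), ksMean = 0.65, class = "co_expressed"),
    data.frame(size = rep(2L, 25), ksMean = 0.65, class = NA_character_),
    data.frame(size = c(3L, 5L, 6L, 7L, 8L, 9L), ksMean = 0.65,
               class = NA_character_)
  )
  nChrom <- 10L
  nPer <- 440L
  withSeed(substreamSeed(rngSeed, "general"), {
    spec$trueKs <- pmax(0.05, stats::rnorm(nrow(spec), spec$ksMean, 0.03))
    spec$trueKaks <- stats::runif(nrow(spec), 0.05, 0.4)
    spec$trueKaks[sample.int(nrow(spec), 2L)] <- 1.7  # a little positive selection
    spec$chromosome <- sprintf("chr%02d",
                               sample(rep_len(seq_len(nChrom), nrow(spec))))
    spec$startRank <- NA_integer_
    for (chr in unique(spec$chromosome)) {
      i <- which(spec$chromosome == chr)
      sizes <- spec$size[i]
      free <- nPer - sum(sizes) - 2L * length(i)
      cuts <- sort(sample.int(free + 1L, length(i), replace = TRUE)) - 1L
      spec$startRank[i] <- cuts + cumsum(c(0L, utils::head(sizes, -1L))) +
        2L * (seq_along(i) - 1L)
    }
    planted <- spec[, c("chromosome", "startRank", "size", "trueKs",
                        "trueKaks", "class")]
    terms <- data.frame(
      term_id = sprintf("PT:%04d", 1:10),
      termSize = c(20L, 24L, 30L, 16L, 40L, 12L, 25L, 18L, 35L, 28L),
      studyOverlap = c(15L, 16L, 18L, 12L, 20L, 9L, 15L, 12L, 18L, 14L)
    )
    simConfig(nChromosomes = nChrom, genesPerChromosome = nPer,
              plantedClusters = planted, backgroundNoise = backgroundNoise,
              plantedTerms = terms, rngSeed = rngSeed)
  })
}
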
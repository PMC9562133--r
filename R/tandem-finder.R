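# Tandem duplicate detection: homology filtering, gene ranking, tandem-pair
# extraction and cluster construction, plus chromosome-distribution summaries.

#' Read a gene annotation from GFF3
#'
#' Imports `gene` features (1-based, inclusive coordinates) with their `ID`
#' attribute as `gene_id`.
#'
#' @param path GFF3 file.
#' @return a `GRanges` with metadata column `gene_id`.
#' @export
readGeneAnnotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3", feature.type = "gene")
  ids <- as.character(gr$ID)
  if (anyNA(ids)) stop("gene features without ID attribute in ", path,
                       call. = FALSE)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene_id = ids)
  gr
}

#' Read an all-vs-all homology table (BLAST outfmt 6)
#'
#' @param path tab-separated file with the 12 standard columns (qseqid,
#'   sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#'   evalue, bitscore), no header.
#' @return data.frame with those column names.
#' @export
readHomologyTable <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  hits <- utils::read.delim(path, header = FALSE, col.names = cols,
                            stringsAsFactors = FALSE)
  bad <- which(!is.finite(hits$evalue) | hits$evalue < 0)
  if (length(bad)) {
    stop("malformed homology row at line ", bad[1], " of ", path,
         call. = FALSE)
  }
  hits
}

#' Filter homology hits and close them symmetrically
#'
#' Reproduces the intent of a BLASTP run kept at `E < evalueMax` with the
#' first `topN` matches: self-hits are dropped, hits at or above the E-value
#' cutoff are dropped, and per query only the `topN` best distinct subjects
#' survive (sorted by bitscore, ties by E-value then subject id, so the
#' selection is deterministic). Because duplication is a symmetric relation
#' the surviving directed hits are then collapsed to unordered pairs; a pair
#' is kept if either direction survives.
#'
#' @param hits data.frame with at least `qseqid`, `sseqid`, `evalue`,
#'   `bitscore` (as from [readHomologyTable()]).
#' @param evalueMax strict E-value cutoff (default 1e-10).
#' @param topN matches retained per query (default 10).
#' @return data.frame of unordered pairs: `gene1 < gene2`, `evalue` (best),
#'   `bitscore` (best).
#' @export
filterHits <- function(hits, evalueMax = 1e-10, topN = 10) {
  need <- c("qseqid", "sseqid", "evalue", "bitscore")
  if (!all(need %in% names(hits))) {
    stop("hits must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  h <- hits[hits$qseqid != hits$sseqid & hits$evalue < evalueMax, need,
            drop = FALSE]
  if (!nrow(h)) {
    return(data.frame(gene1 = character(), gene2 = character(),
                      evalue = numeric(), bitscore = numeric()))
  }
  # best row per directed (query, subject)
  h <- h[order(h$qseqid, h$sseqid, -h$bitscore, h$evalue), , drop = FALSE]
  h <- h[!duplicated(h[c("qseqid", "sseqid")]), , drop = FALSE]
  # top-N subjects per query, deterministic order
  h <- h[order(h$qseqid, -h$bitscore, h$evalue, h$sseqid), , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(h)), h$qseqid),
                        function(i) i[seq_len(min(topN, length(i)))]),
                 use.names = FALSE)
  h <- h[sort(keep), , drop = FALSE]
  # symmetric closure to unordered pairs
  g1 <- pmin(h$qseqid, h$sseqid)
  g2 <- pmax(h$qseqid, h$sseqid)
  key <- paste(g1, g2, sep = "\r")
  agg <- data.frame(gene1 = g1, gene2 = g2, evalue = h$evalue,
                    bitscore = h$bitscore)
  o <- order(key, agg$evalue, -agg$bitscore)
  agg <- agg[o, , drop = FALSE]
  agg <- agg[!duplicated(key[o]), , drop = FALSE]
  agg <- agg[order(agg$gene1, agg$gene2), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Assign chromosome-local gene ranks
#'
#' Ranks are 0-based ordinal positions by start coordinate within each
#' chromosome; ties in start are broken by end coordinate then gene id so
#' ranks are deterministic.
#'
#' @param annotation a `GRanges` with `gene_id` (see
#'   [readGeneAnnotation()]) or a data.frame with `gene_id`, `chromosome`,
#'   `start`, `end`.
#' @return data.frame with `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, `rank`.
#' @export
assignRanks <- function(annotation) {
  df <- annotationFrame(annotation)
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         df$gene_id[duplicated(df$gene_id)][1], call. = FALSE)
  }
  if (any(df$start > df$end)) {
    stop("gene with start > end in annotation", call. = FALSE)
  }
  df <- df[order(df$chromosome, df$start, df$end, df$gene_id), ,
           drop = FALSE]
  df$rank <- stats::ave(seq_len(nrow(df)), df$chromosome,
                        FUN = seq_along) - 1L
  rownames(df) <- NULL
  df
}

# Coerce GRanges or data.frame annotation to a plain frame.
annotationFrame <- function(annotation) {
  if (is(annotation, "GRanges")) {
    data.frame(
      gene_id = annotation$gene_id,
      chromosome = as.character(GenomicRanges::seqnames(annotation)),
      start = GenomicRanges::start(annotation),
      end = GenomicRanges::end(annotation),
      strand = as.character(GenomicRanges::strand(annotation)),
      stringsAsFactors = FALSE
    )
  } else {
    need <- c("gene_id", "chromosome", "start", "end")
    stopifnot(all(need %in% names(annotation)))
    df <- as.data.frame(annotation)
    if (is.null(df$strand)) df$strand <- "*"
    df
  }
}

#' Extract tandem duplicate pairs
#'
#' A homologous pair is tandem iff both genes lie on the same chromosome at
#' a rank distance of at most `maxGap` (default 1, strictly consecutive
#' genes).
#'
#' @param ranked output of [assignRanks()].
#' @param pairs filtered unordered homology pairs from [filterHits()].
#' @param maxGap maximum rank distance (default 1).
#' @return data.frame: `gene1`, `gene2`, `chromosome`, `rank1`, `rank2`,
#'   one row per unordered tandem pair.
#' @export
findTandemPairs <- function(ranked, pairs, maxGap = 1) {
  stopifnot(all(c("gene1", "gene2") %in% names(pairs)),
            "rank" %in% names(ranked))
  unknown <- setdiff(unique(c(pairs$gene1, pairs$gene2)), ranked$gene_id)
  if (length(unknown)) {
    stop("homology hit references unknown gene(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  idx <- match(pairs$gene1, ranked$gene_id)
  jdx <- match(pairs$gene2, ranked$gene_id)
  sameChr <- ranked$chromosome[idx] == ranked$chromosome[jdx]
  gap <- abs(ranked$rank[idx] - ranked$rank[jdx])
  keep <- sameChr & gap >= 1 & gap <= maxGap
  out <- data.frame(
    gene1 = pairs$gene1[keep], gene2 = pairs$gene2[keep],
    chromosome = ranked$chromosome[idx][keep],
    rank1 = ranked$rank[idx][keep], rank2 = ranked$rank[jdx][keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chromosome, pmin(out$rank1, out$rank2),
                   pmax(out$rank1, out$rank2)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chain tandem pairs into clusters
#'
#' Clusters are connected components of the tandem-pair graph; each is a
#' maximal tandem array on one chromosome with members ordered by rank.
#'
#' @param tandemPairs output of [findTandemPairs()].
#' @return a [TandemClusters-class] object (possibly empty).
#' @export
buildClusters <- function(tandemPairs) {
  if (!nrow(tandemPairs)) {
    return(new("TandemClusters", members = list(), chromosome = character()))
  }
  g <- igraph::graph_from_data_frame(
    tandemPairs[, c("gene1", "gene2")], directed = FALSE)
  comp <- igraph::components(g)
  ranks <- c(
    stats::setNames(tandemPairs$rank1, tandemPairs$gene1),
    stats::setNames(tandemPairs$rank2, tandemPairs$gene2)
  )
  ranks <- ranks[!duplicated(names(ranks))]
  chroms <- c(
    stats::setNames(tandemPairs$chromosome, tandemPairs$gene1),
    stats::setNames(tandemPairs$chromosome, tandemPairs$gene2)
  )
  chroms <- chroms[!duplicated(names(chroms))]
  membership <- split(names(comp$membership), comp$membership)
  members <- lapply(membership, function(gs) gs[order(ranks[gs], gs)])
  chr <- vapply(members, function(gs) unname(chroms[gs[1]]), "")
  # deterministic cluster order: chromosome, then first member rank
  o <- order(chr, vapply(members, function(gs) unname(ranks[gs[1]]), 0))
  new("TandemClusters", members = unname(members[o]),
      chromosome = unname(chr[o]))
}

#' Detect tandem clusters from annotation plus homology
#'
#' One-call wrapper: [filterHits()], [assignRanks()], [findTandemPairs()],
#' [buildClusters()].
#'
#' @param annotation `GRanges` or data.frame annotation.
#' @param hits raw homology hits (outfmt-6 frame).
#' @param evalueMax,topN homology filter parameters.
#' @param maxGap tandem rank-gap parameter.
#' @return a [TandemClusters-class] object.
#' @export
detectTandem <- function(annotation, hits, evalueMax = 1e-10, topN = 10,
                         maxGap = 1) {
  ranked <- assignRanks(annotation)
  pairs <- filterHits(hits, evalueMax = evalueMax, topN = topN)
  buildClusters(findTandemPairs(ranked, pairs, maxGap = maxGap))
}

#' Chromosome distribution of tandem duplicated genes
#'
#' @param tdg character vector of TDG ids (e.g. [tdgGenes()]).
#' @param annotation annotation (`GRanges` or frame) providing each gene's
#'   chromosome.
#' @return data.frame `chromosome`, `n_tdg`, `pct` (percent of all TDGs,
#'   2 decimals); zero rows when `tdg` is empty. Chromosomes without TDGs
#'   are reported with zero counts.
#' @export
chromosomeDistribution <- function(tdg, annotation) {
  df <- annotationFrame(annotation)
  if (!length(tdg)) {
    return(data.frame(chromosome = character(), n_tdg = integer(),
                      pct = numeric()))
  }
  chroms <- sort(unique(df$chromosome))
  counts <- table(factor(df$chromosome[df$gene_id %in% tdg],
                         levels = chroms))
  out <- data.frame(
    chromosome = chroms,
    n_tdg = as.integer(counts),
    pct = percentOf(as.integer(counts), length(tdg)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Fraction of the gene set that is tandem duplicated
#'
#' @param tdg character vector of TDG ids.
#' @param annotation full gene annotation.
#' @return percent of genes that are TDGs, 2 decimals.
#' @examples
#' # 2,542 TDGs in a 28,712-gene set -> 8.85
#' @export
tdgFraction <- function(tdg, annotation) {
  df <- annotationFrame(annotation)
  stopifnot(nrow(df) > 0)
  percentOf(length(unique(tdg)), nrow(df))
}
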
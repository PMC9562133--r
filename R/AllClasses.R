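#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

# ---------------------------------------------------------------------------
# SimConfig — parameters of the synthetic study design
# ---------------------------------------------------------------------------

#' Synthetic study configuration
#'
#' Describes a synthetic genome and expression experiment with planted
#' ground truth: tandem arrays of known size and divergence, per-gene
#' tissue-response classes, over-represented functional terms, and a
#' two-tissue, multi-timepoint, replicated salt-stress design.
#'
#' @slot nChromosomes number of chromosomes.
#' @slot genesPerChromosome genes per chromosome.
#' @slot plantedClusters data.frame with columns `chromosome`, `startRank`
#'   (0-based), `size` (2-9), `trueKs`, `trueKaks`, `class` (a tissue-response
#'   label or `NA`).
#' @slot backgroundNoise probability that a gene gains one spurious
#'   (non-tandem) homology partner.
#' @slot nTimepoints timepoints per tissue (default 5: 8 h, 12 h, 24 h,
#'   48 h, 5 d of 400 mM NaCl vs. water control).
#' @slot nReplicates biological replicates per condition (default 3).
#' @slot tissues tissue labels (default leaf, root).
#' @slot plantedTerms data.frame with columns `term_id`, `termSize`,
#'   `studyOverlap` describing terms to over-represent in the TDG set.
#' @slot rngSeed integer seed; all synthetic randomness derives from it.
#' @export
setClass("SimConfig", representation(
  nChromosomes = "integer",
  genesPerChromosome = "integer",
  plantedClusters = "data.frame",
  backgroundNoise = "numeric",
  nTimepoints = "integer",
  nReplicates = "integer",
  tissues = "character",
  plantedTerms = "data.frame",
  rngSeed = "integer"
))

setValidity("SimConfig", function(object) {
  msgs <- character()
  pc <- object@plantedClusters
  if (nrow(pc)) {
    need <- c("chromosome", "startRank", "size", "trueKs", "trueKaks")
    if (!all(need %in% names(pc))) {
      msgs <- c(msgs, paste("plantedClusters needs columns:",
                            paste(need, collapse = ", ")))
    } else {
      if (any(pc$size < 2L | pc$size > 9L))
        msgs <- c(msgs, "planted cluster sizes must be in [2, 9]")
      if (any(pc$trueKs < 0) || any(pc$trueKaks < 0))
        msgs <- c(msgs, "trueKs and trueKaks must be non-negative")
      if (any(pc$startRank < 0L) ||
          any(pc$startRank + pc$size > object@genesPerChromosome))
        msgs <- c(msgs, "planted cluster exceeds chromosome gene count")
      for (chr in unique(pc$chromosome)) {
        sub <- pc[pc$chromosome == chr, , drop = FALSE]
        sub <- sub[order(sub$startRank), , drop = FALSE]
        if (nrow(sub) > 1L) {
          ends <- sub$startRank + sub$size
          if (any(sub$startRank[-1L] < ends[-nrow(sub)]))
            msgs <- c(msgs, paste0("overlapping planted clusters on ", chr))
        }
      }
    }
  }
  if (object@backgroundNoise < 0 || object@backgroundNoise > 1)
    msgs <- c(msgs, "backgroundNoise must be a probability in [0, 1]")
  if (length(object@tissues) != length(unique(object@tissues)))
    msgs <- c(msgs, "tissues must be distinct")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimConfig
#'
#' @param nChromosomes,genesPerChromosome genome dimensions.
#' @param plantedClusters data.frame of planted tandem arrays (see
#'   [SimConfig-class]); zero rows plants nothing.
#' @param backgroundNoise spurious-homolog probability per gene.
#' @param nTimepoints,nReplicates,tissues expression design.
#' @param plantedTerms data.frame of planted over-represented terms.
#' @param rngSeed integer seed.
#' @return a validated [SimConfig-class] object.
#' @export
simConfig <- function(nChromosomes = 2L, genesPerChromosome = 100L,
                      plantedClusters = emptyClusterSpec(),
                      backgroundNoise = 0,
                      nTimepoints = 5L, nReplicates = 3L,
                      tissues = c("leaf", "root"),
                      plantedTerms = emptyTermSpec(),
                      rngSeed = 1L) {
  new("SimConfig",
      nChromosomes = as.integer(nChromosomes),
      genesPerChromosome = as.integer(genesPerChromosome),
      plantedClusters = as.data.frame(plantedClusters),
      backgroundNoise = as.numeric(backgroundNoise),
      nTimepoints = as.integer(nTimepoints),
      nReplicates = as.integer(nReplicates),
      tissues = as.character(tissues),
      plantedTerms = as.data.frame(plantedTerms),
      rngSeed = as.integer(rngSeed))
}

#' @rdname simConfig
#' @export
emptyClusterSpec <- function() {
  data.frame(chromosome = character(), startRank = integer(),
             size = integer(), trueKs = numeric(), trueKaks = numeric(),
             class = character())
}

#' @rdname simConfig
#' @export
emptyTermSpec <- function() {
  data.frame(term_id = character(), termSize = integer(),
             studyOverlap = integer())
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nChromosomes, "chromosome(s) x",
      object@genesPerChromosome, "genes\n")
  cat("  planted clusters:", nrow(object@plantedClusters),
      "| planted terms:", nrow(object@plantedTerms), "\n")
  cat("  design:", paste(object@tissues, collapse = "/"), "x",
      object@nTimepoints, "timepoints x", object@nReplicates,
      "replicates | noise:", object@backgroundNoise,
      "| seed:", object@rngSeed, "\n")
})

# ---------------------------------------------------------------------------
# TandemClusters — detected tandem arrays
# ---------------------------------------------------------------------------

#' Set of tandem duplicate clusters
#'
#' Each cluster is a maximal connected component of the tandem-pair graph on
#' one chromosome, with members ordered by chromosome-local gene rank.
#'
#' @slot members list of character vectors of gene ids, ordered by rank.
#' @slot chromosome chromosome of each cluster.
#' @export
setClass("TandemClusters", representation(
  members = "list",
  chromosome = "character"
))

setValidity("TandemClusters", function(object) {
  msgs <- character()
  if (length(object@members) != length(object@chromosome))
    msgs <- c(msgs, "one chromosome per cluster required")
  sizes <- lengths(object@members)
  if (length(sizes) && any(sizes < 2L))
    msgs <- c(msgs, "clusters must have >= 2 members")
  all_genes <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(all_genes))
    msgs <- c(msgs, "a gene may belong to only one cluster")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn TandemClusters-class number of clusters.
#' @param x,object a `TandemClusters` object.
#' @export
setMethod("length", "TandemClusters", function(x) length(x@members))

#' Cluster sizes
#' @param x a [TandemClusters-class] object.
#' @return integer vector of member counts per cluster.
#' @export
clusterSizes <- function(x) {
  stopifnot(is(x, "TandemClusters"))
  lengths(x@members)
}

#' All genes contained in any cluster (the TDG set)
#' @param x a [TandemClusters-class] object.
#' @return character vector of gene ids.
#' @export
tdgGenes <- function(x) {
  stopifnot(is(x, "TandemClusters"))
  sort(unlist(x@members, use.names = FALSE))
}

#' Cluster membership as a data.frame
#' @param x a [TandemClusters-class] object.
#' @param row.names,optional,... ignored; present for generic consistency.
#' @return data.frame with `cluster_id`, `chromosome`, `size`, `members`
#'   (comma-joined gene ids in rank order).
#' @export
as.data.frame.TandemClusters <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(
    cluster_id = sprintf("TC%04d", seq_along(x@members)),
    chromosome = x@chromosome,
    size = lengths(x@members),
    members = vapply(x@members, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
}

setMethod("show", "TandemClusters", function(object) {
  n <- length(object@members)
  cat("TandemClusters with", n, "cluster(s),",
      length(unlist(object@members)), "genes\n")
  if (n) {
    tab <- table(factor(lengths(object@members)))
    cat("  size distribution:",
        paste(sprintf("%s x size %s", tab, names(tab)), collapse = ", "),
        "\n")
  }
})

# ---------------------------------------------------------------------------
# CodonAlignment — codon-level pairwise alignment
# ---------------------------------------------------------------------------

#' Pairwise codon alignment
#'
#' A protein-guided back-translated alignment of two coding sequences.
#' Columns are codons ("---" for a gap); `excluded` marks columns not used
#' for Ka/Ks (gaps, stop codons, ambiguous bases).
#'
#' @slot id1,id2 sequence identifiers.
#' @slot codons1,codons2 aligned codon vectors.
#' @slot excluded logical mask over columns.
#' @export
setClass("CodonAlignment", representation(
  id1 = "character", id2 = "character",
  codons1 = "character", codons2 = "character",
  excluded = "logical"
))

setValidity("CodonAlignment", function(object) {
  msgs <- character()
  n <- length(object@codons1)
  if (length(object@codons2) != n || length(object@excluded) != n)
    msgs <- c(msgs, "codons1, codons2 and excluded must have equal length")
  ok <- function(x) all(x == "---" | nchar(x) == 3L)
  if (!ok(object@codons1) || !ok(object@codons2))
    msgs <- c(msgs, "codon columns must be 3 bases or '---'")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CodonAlignment-class number of codon columns.
#' @param x,object a `CodonAlignment`.
#' @export
setMethod("length", "CodonAlignment", function(x) length(x@codons1))

#' Included (analysable) codon columns of a codon alignment
#' @param x a [CodonAlignment-class] object.
#' @return logical vector, TRUE where the column enters Ka/Ks.
#' @export
includedCodons <- function(x) {
  stopifnot(is(x, "CodonAlignment"))
  !x@excluded
}

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment", object@id1, "vs", object@id2, "-",
      length(object@codons1), "codon columns,",
      sum(object@excluded), "excluded\n")
})

# ---------------------------------------------------------------------------
# KsDistribution — binned Ks values with detected peaks
# ---------------------------------------------------------------------------

#' Binned Ks distribution with modal-peak calls
#'
#' @slot label source label (e.g. "whole", "leaf_specific").
#' @slot values retained Ks values after filtering.
#' @slot binWidth histogram bin width.
#' @slot counts per-bin counts, bins `[k*w, (k+1)*w)` from 0.
#' @slot peaks data.frame of detected peak intervals (`lo`, `hi`,
#'   `midpoint`, `count`, `primary`); zero rows when undefined.
#' @export
setClass("KsDistribution", representation(
  label = "character",
  values = "numeric",
  binWidth = "numeric",
  counts = "numeric",
  peaks = "data.frame"
))

setValidity("KsDistribution", function(object) {
  if (length(object@values) != sum(object@counts))
    "bin counts must sum to the number of retained values"
  else TRUE
})

#' Retained Ks values of a distribution
#' @param x a [KsDistribution-class] object.
#' @export
ksValues <- function(x) {
  stopifnot(is(x, "KsDistribution"))
  x@values
}

#' Detected peak intervals of a Ks distribution
#' @param x a [KsDistribution-class] object.
#' @return data.frame with columns `lo`, `hi`, `midpoint`, `count`,
#'   `primary`.
#' @export
ksPeaks <- function(x) {
  stopifnot(is(x, "KsDistribution"))
  x@peaks
}

setMethod("show", "KsDistribution", function(object) {
  cat("KsDistribution [", object@label, "]: ", length(object@values),
      " values, bin width ", object@binWidth, "\n", sep = "")
  if (nrow(object@peaks)) {
    p <- object@peaks
    cat("  peaks:",
        paste(sprintf("[%.2g, %.2g)%s", p$lo, p$hi,
                      ifelse(p$primary, "*", "")), collapse = ", "), "\n")
  } else {
    cat("  peaks: undefined\n")
  }
})
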
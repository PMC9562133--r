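# Independent oracles used to cross-check the package implementations.
# These deliberately share no code with the package internals: the NG86
# oracle enumerates substitution pathways directly per codon pair, the
# tandem oracle tests all gene pairs and merges clusters by repeated
# scanning, the alignment oracle is a plain Gotoh DP, and the
# hypergeometric oracle enumerates every possible study draw.

GENCODE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

oracleSplitCodons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

# Per-codon synonymous site count: fraction of the 3 single-base changes at
# each position that preserve the amino acid (changes to stops count as
# nonsynonymous).
oracleSites <- function(codon) {
  aa <- GENCODE[[codon]]
  nts <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), nts[pos])) {
      mut <- nts; mut[pos] <- alt
      if (GENCODE[[paste(mut, collapse = "")]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# Pathway-averaged (Sd, Nd) for one codon pair by explicit enumeration of
# every substitution order; pathways through stop codons are dropped.
# Returns NULL when no pathway survives (pair unusable).
oraclePairDiffs <- function(c1, c2) {
  n1 <- strsplit(c1, "")[[1]]
  n2 <- strsplit(c2, "")[[1]]
  diffPos <- which(n1 != n2)
  if (!length(diffPos)) return(c(sd = 0, nd = 0))
  allOrders <- permuteAll(diffPos)
  sdS <- 0; ndS <- 0; nOK <- 0
  for (ord in allOrders) {
    cur <- n1; sd <- 0; nd <- 0; dropped <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- n2[p]
      aaF <- GENCODE[[paste(cur, collapse = "")]]
      aaT <- GENCODE[[paste(nxt, collapse = "")]]
      if (aaF == "*" || aaT == "*") { dropped <- TRUE; break }
      if (aaF == aaT) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (!dropped) { sdS <- sdS + sd; ndS <- ndS + nd; nOK <- nOK + 1 }
  }
  if (nOK == 0) return(NULL)
  c(sd = sdS / nOK, nd = ndS / nOK)
}

permuteAll <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permuteAll(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

# Full NG86 oracle on two equal-length, gap-free CDS strings.
oracleNg86 <- function(cds1, cds2) {
  co1 <- oracleSplitCodons(cds1)
  co2 <- oracleSplitCodons(cds2)
  stopifnot(length(co1) == length(co2))
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(co1)) {
    if (GENCODE[[co1[i]]] == "*" || GENCODE[[co2[i]]] == "*") next
    d <- oraclePairDiffs(co1[i], co2[i])
    if (is.null(d)) next
    si <- (oracleSites(co1[i]) + oracleSites(co2[i])) / 2
    S <- S + si
    N <- N + (3 - si)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       ks = jc(pS), ka = jc(pN))
}

# Brute-force tandem clustering: test every gene pair for (homology, same
# chromosome, rank gap <= maxGap), then merge overlapping pairs until
# stable. annotation: data.frame(gene_id, chromosome, start, end);
# homPairs: data.frame(gene1, gene2) of undirected homologous pairs.
oracleTandemClusters <- function(annotation, homPairs, maxGap = 1) {
  ann <- annotation[order(annotation$chromosome, annotation$start,
                          annotation$end, annotation$gene_id), ]
  ann$rank <- unlist(lapply(split(seq_len(nrow(ann)), ann$chromosome),
                            seq_along)) - 1
  ann <- ann[order(match(ann$gene_id, annotation$gene_id)), ]
  homKey <- unique(c(paste(homPairs$gene1, homPairs$gene2),
                     paste(homPairs$gene2, homPairs$gene1)))
  sets <- list()
  n <- nrow(ann)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      gi <- ann$gene_id[i]; gj <- ann$gene_id[j]
      if (!paste(gi, gj) %in% homKey) next
      if (ann$chromosome[i] != ann$chromosome[j]) next
      if (abs(ann$rank[i] - ann$rank[j]) > maxGap) next
      sets[[length(sets) + 1]] <- c(gi, gj)
    }
  }
  # merge until fixed point
  repeat {
    merged <- FALSE
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (j <= i) next
        if (length(intersect(sets[[i]], sets[[j]]))) {
          sets[[i]] <- union(sets[[i]], sets[[j]])
          sets[[j]] <- character(0)
          merged <- TRUE
        }
      }
    }
    sets <- sets[lengths(sets) > 0]
    if (!merged) break
  }
  lapply(sets, sort)
}

# Plain Gotoh affine-gap global alignment score; gap of length L costs
# open + L * ext.
oracleGotohScore <- function(s1, s2, mat, open, ext) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in s2 (vertical)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in s1 (horizontal)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- mat[a[i], b[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sc
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exhaustive hypergeometric upper tail: fraction of all C(N, m) study
# draws with at least k hits in the n term genes.
oracleHyperTail <- function(N, n, m, k) {
  draws <- utils::combn(N, m)
  hits <- colSums(draws <= n)  # genes 1..n are "in the term"
  mean(hits >= k)
}

# Gap-free codon alignment of two equal-length CDS (the true alignment for
# simulator output, which never contains indels); keeps oracle comparisons
# independent of the heuristic-free but gap-capable protein aligner.
ungappedCodonAlignment <- function(cdsA, cdsB) {
  tr <- function(x) paste(tandemdup:::translateCodons(
    tandemdup:::splitCodons(x)), collapse = "")
  backtranslate(list(aligned1 = tr(cdsA), aligned2 = tr(cdsB)), cdsA, cdsB)
}

# Random toy genome + homology for oracle comparisons.
randomToyGenome <- function(nGenes = 30, nChrom = 2, pHom = 0.08) {
  chrom <- sprintf("c%d", sample.int(nChrom, nGenes, replace = TRUE))
  start <- sample.int(100000, nGenes)
  ann <- data.frame(
    gene_id = sprintf("t%03d", seq_len(nGenes)),
    chromosome = chrom, start = start, end = start + 99,
    stringsAsFactors = FALSE
  )
  prs <- t(utils::combn(ann$gene_id, 2))
  keep <- stats::runif(nrow(prs)) < pHom
  list(annotation = ann,
       homPairs = data.frame(gene1 = prs[keep, 1], gene2 = prs[keep, 2],
                             stringsAsFactors = FALSE))
}
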
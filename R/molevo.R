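# Codon-level molecular evolution: protein-guided codon alignment,
# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction, selection-pressure
# labelling and molecular-clock dating T = Ks / (2 * lambda).

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties, used as the
#' guide for back-translation to a codon alignment. The dynamic programming
#' is delegated to [Biostrings::pairwiseAlignment()]; a gap of length L costs
#' `gapOpen + L * gapExtend`.
#'
#' @param p1,p2 amino-acid sequences (character or `AAString`).
#' @param substitutionMatrix scoring matrix name or matrix (default
#'   "BLOSUM62").
#' @param gapOpen,gapExtend affine gap penalties (positive costs).
#' @return list with `aligned1`, `aligned2` (equal-length aligned strings
#'   with `-` for gaps) and `score`.
#' @examples
#' alignProteins("ACD", "AD")$aligned2  # "A-D"
#' @export
alignProteins <- function(p1, p2, substitutionMatrix = "BLOSUM62",
                          gapOpen = 10, gapExtend = 0.5) {
  p1 <- as.character(p1); p2 <- as.character(p2)
  if (!nzchar(p1) || !nzchar(p2)) {
    stop("cannot align an empty protein sequence", call. = FALSE)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpen, gapExtension = gapExtend,
    type = "global"
  )
  list(
    aligned1 = as.character(Biostrings::alignedPattern(pa)),
    aligned2 = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)
  )
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned amino-acid column is replaced by its source codon; protein
#' gaps become codon gaps ("---"). Columns containing a gap, a stop codon or
#' an ambiguous base are flagged excluded and do not enter Ka/Ks.
#'
#' @param alignment result of [alignProteins()] (or any list with `aligned1`,
#'   `aligned2`).
#' @param cds1,cds2 unaligned coding sequences (character or `DNAString`),
#'   with `nchar(cds) == 3 * nchar(protein)` and translations matching the
#'   aligned proteins.
#' @param id1,id2 identifiers used in error messages and results.
#' @param codeTable optional alternative genetic code.
#' @return a [CodonAlignment-class] object.
#' @export
backtranslate <- function(alignment, cds1, cds2, id1 = "seq1", id2 = "seq2",
                          codeTable = NULL) {
  a1 <- strsplit(alignment$aligned1, "")[[1]]
  a2 <- strsplit(alignment$aligned2, "")[[1]]
  cod1 <- splitCodons(cds1)
  cod2 <- splitCodons(cds2)
  placeCodons <- function(aa, codons, id) {
    res <- sum(aa != "-")
    if (res != length(codons)) {
      stop("CDS of '", id, "' has ", length(codons),
           " codons but its aligned protein has ", res, " residues",
           call. = FALSE)
    }
    out <- rep("---", length(aa))
    out[aa != "-"] <- codons
    tr <- translateCodons(out, codeTable)
    tr[aa == "-"] <- "-"
    bad <- which(tr != aa & aa != "X")
    if (length(bad)) {
      stop("CDS of '", id, "' does not translate to its aligned protein ",
           "(first mismatch at alignment column ", bad[1], ")",
           call. = FALSE)
    }
    out
  }
  codons1 <- placeCodons(a1, cod1, id1)
  codons2 <- placeCodons(a2, cod2, id2)

  code <- geneticCode(codeTable)
  isBad <- function(cod) {
    cod == "---" | !cod %in% names(code) | unname(code[cod] == "*")
  }
  excluded <- isBad(codons1) | isBad(codons2)
  new("CodonAlignment", id1 = id1, id2 = id2,
      codons1 = codons1, codons2 = codons2, excluded = excluded)
}

#' Align two CDS at the codon level via their proteins
#'
#' Convenience wrapper: translate, [alignProteins()], [backtranslate()].
#'
#' @inheritParams backtranslate
#' @param ... passed to [alignProteins()].
#' @return a [CodonAlignment-class] object.
#' @export
alignCodonPair <- function(cds1, cds2, id1 = "seq1", id2 = "seq2",
                           codeTable = NULL, ...) {
  p1 <- paste(translateCodons(splitCodons(cds1), codeTable), collapse = "")
  p2 <- paste(translateCodons(splitCodons(cds2), codeTable), collapse = "")
  aln <- alignProteins(p1, p2, ...)
  backtranslate(aln, cds1, cds2, id1 = id1, id2 = id2,
                codeTable = codeTable)
}

#' Nei-Gojobori (1986) Ka/Ks on a codon alignment
#'
#' Classic counting method. Synonymous site fractions per codon position are
#' (synonymous single-nucleotide changes)/3, summed per codon and averaged
#' over the two sequences. Differences between unequal codons are averaged
#' over all k! substitution orders for k differing positions, each
#' single-nucleotide step classified against the genetic code; pathways
#' through stop codons are dropped, and a codon pair whose pathways all drop
#' is excluded entirely. Proportions are Jukes-Cantor corrected,
#' `d = -3/4 * log(1 - 4/3 * p)`. When `pS` or `pN` reaches the correction
#' singularity (>= 0.75) the estimate is saturated and returned as
#' `NA` with `selection = "undefined"`.
#'
#' @param ca a [CodonAlignment-class] object (or two raw CDS via
#'   [alignCodonPair()] upstream).
#' @param codeTable optional alternative genetic code.
#' @return list with `S`, `N` (site counts), `Sd`, `Nd` (pathway-averaged
#'   difference counts), `pS`, `pN`, `ka`, `ks`, `ratio`, `selection`
#'   (negative/neutral/positive/undefined) and `nCodons` (included columns).
#' @export
ng86 <- function(ca, codeTable = NULL) {
  stopifnot(is(ca, "CodonAlignment"))
  tabs <- ng86Tables(codeTable)
  keep <- !ca@excluded
  c1 <- ca@codons1[keep]
  c2 <- ca@codons2[keep]
  # drop pairs with no stop-free substitution pathway
  okPair <- tabs$diffs$OK[cbind(c1, c2)]
  c1 <- c1[okPair]; c2 <- c2[okPair]
  if (!length(c1)) {
    stop("no analysable codon columns in alignment ", ca@id1, " vs ",
         ca@id2, call. = FALSE)
  }
  S <- (sum(tabs$sites[c1]) + sum(tabs$sites[c2])) / 2
  N <- 3 * length(c1) - S
  Sd <- sum(tabs$diffs$SD[cbind(c1, c2)])
  Nd <- sum(tabs$diffs$ND[cbind(c1, c2)])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- jc(pS)
  ka <- jc(pN)
  saturated <- is.na(ks) || is.na(ka)
  ratio <- if (saturated || ks <= 0) NA_real_ else ka / ks
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       ka = ka, ks = ks, ratio = ratio,
       selection = classifySelection(ratio),
       saturated = saturated,
       nCodons = length(c1))
}

#' Ka/Ks ratio for report tables
#'
#' @param ka,ks substitution rates; `ks` must be positive for a defined
#'   ratio.
#' @return `ka/ks` rounded half-up to 2 decimals; `NA` when `ks` is 0 or
#'   either input is `NA` (undefined, never 0).
#' @examples
#' kaksRatio(0.34, 2.32) # 0.15
#' kaksRatio(0.24, 2.99) # 0.08
#' @export
kaksRatio <- function(ka, ks) {
  ifelse(is.na(ka) | is.na(ks) | ks <= 0, NA_real_,
         roundHalfUp(ka / ks, 2))
}

#' Selection-pressure label from a Ka/Ks ratio
#'
#' @param ratio Ka/Ks; `NA` yields "undefined".
#' @param tol equality tolerance for the neutral call.
#' @return "negative" (< 1, purifying), "neutral" (= 1), "positive" (> 1)
#'   or "undefined".
#' @export
classifySelection <- function(ratio, tol = 1e-9) {
  vapply(ratio, function(r) {
    if (is.na(r)) "undefined"
    else if (abs(r - 1) <= tol) "neutral"
    else if (r < 1) "negative"
    else "positive"
  }, "")
}

#' Molecular-clock divergence time from Ks
#'
#' `T = Ks / (2 * lambda)` in millions of years (Ma), with lambda the
#' synonymous substitution rate per site per year (default 1.5e-8, a
#' grass-lineage clock).
#'
#' @param ks synonymous substitutions per synonymous site (>= 0).
#' @param lambda substitution rate per site per year (> 0).
#' @param digits decimals for the reported value (default 1).
#' @return time in Ma.
#' @examples
#' divergenceTime(0.7) # 23.3
#' divergenceTime(2.5) # 83.3
#' @export
divergenceTime <- function(ks, lambda = 1.5e-8, digits = 1) {
  stopifnot(lambda > 0)
  if (any(ks < 0, na.rm = TRUE)) {
    stop("Ks must be non-negative", call. = FALSE)
  }
  roundHalfUp(ks / (2 * lambda) / 1e6, digits)
}

#' Ka/Ks for a set of gene pairs
#'
#' Aligns each CDS pair through its proteins, runs [ng86()] and assembles a
#' per-pair table including report-rounded ratio, selection label and
#' divergence time.
#'
#' @param pairs data.frame with columns `gene1`, `gene2`.
#' @param cds named `DNAStringSet` (or named character vector) of CDS.
#' @param proteins optional named `AAStringSet`; translated from `cds` when
#'   missing.
#' @param lambda clock rate for [divergenceTime()].
#' @param codeTable optional alternative genetic code.
#' @param ... alignment parameters passed to [alignProteins()].
#' @return data.frame: gene1, gene2, S, N, Sd, Nd, ka, ks, ratio (2 dp),
#'   selection, t_ma.
#' @export
computeKaKs <- function(pairs, cds, proteins = NULL, lambda = 1.5e-8,
                        codeTable = NULL, ...) {
  stopifnot(all(c("gene1", "gene2") %in% names(pairs)))
  cdsChar <- as.character(cds)
  missing <- setdiff(unique(c(pairs$gene1, pairs$gene2)), names(cdsChar))
  if (length(missing)) {
    stop("no CDS for gene(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    g1 <- pairs$gene1[i]; g2 <- pairs$gene2[i]
    ca <- alignCodonPair(cdsChar[[g1]], cdsChar[[g2]], id1 = g1, id2 = g2,
                         codeTable = codeTable, ...)
    r <- ng86(ca, codeTable = codeTable)
    data.frame(
      gene1 = g1, gene2 = g2,
      S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd,
      ka = r$ka, ks = r$ks,
      ratio = kaksRatio(r$ka, r$ks),
      selection = r$selection,
      t_ma = if (is.na(r$ks)) NA_real_ else divergenceTime(r$ks, lambda),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
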
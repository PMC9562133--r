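# Genetic-code machinery shared by the Ka/Ks estimator and the codon
# simulator. All tables use the universal code (Biostrings::GENETIC_CODE);
# an alternative code table can be injected through `codeTable` arguments.

.tdcache <- new.env(parent = emptyenv())

NUCS <- c("A", "C", "G", "T")

#' Universal genetic code as a named amino-acid vector
#'
#' @param codeTable named character vector mapping 64 codons to one-letter
#'   amino acids, `"*"` for stop. Defaults to the universal code.
#' @return the (validated) code table.
#' @keywords internal
geneticCode <- function(codeTable = NULL) {
  if (is.null(codeTable)) {
    gc <- Biostrings::GENETIC_CODE
    return(stats::setNames(as.character(gc), names(gc)))
  }
  stopifnot(length(codeTable) == 64L, !is.null(names(codeTable)))
  codeTable
}

allCodons <- function(codeTable = NULL) names(geneticCode(codeTable))

# Number of synonymous single-nucleotide changes at each codon position,
# and the per-codon synonymous site count S = sum(fs)/3 over positions.
# Changes producing a stop codon are counted as nonsynonymous (a codon
# position contributes fs to S and 1 - fs to N, so S + N = 3 per codon).
.codonSites <- function(codeTable = NULL) {
  code <- geneticCode(codeTable)
  codons <- names(code)
  s <- numeric(length(codons))
  names(s) <- codons
  for (cd in codons) {
    aa <- code[[cd]]
    if (aa == "*") { s[[cd]] <- NA_real_; next }
    nts <- strsplit(cd, "")[[1]]
    fs <- 0
    for (pos in 1:3) {
      for (alt in setdiff(NUCS, nts[pos])) {
        mut <- nts
        mut[pos] <- alt
        maa <- code[[paste(mut, collapse = "")]]
        if (maa == aa) fs <- fs + 1 / 3
      }
    }
    s[[cd]] <- fs
  }
  s
}

# Pathway-averaged synonymous/nonsynonymous difference counts for every
# ordered codon pair. For k differing positions all k! substitution orders
# are enumerated; each single-nucleotide step is synonymous iff the amino
# acid is unchanged. A pathway passing through (or starting/ending at) a
# stop codon is dropped; if every pathway is dropped the pair is unusable
# (valid = FALSE) and the codon column is excluded from site and difference
# counts altogether.
.codonPairDiffs <- function(codeTable = NULL) {
  code <- geneticCode(codeTable)
  codons <- names(code)
  n <- length(codons)
  SD <- matrix(0, n, n, dimnames = list(codons, codons))
  ND <- matrix(0, n, n, dimnames = list(codons, codons))
  OK <- matrix(TRUE, n, n, dimnames = list(codons, codons))

  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )

  for (i in seq_len(n)) {
    ci <- strsplit(codons[i], "")[[1]]
    for (j in seq_len(n)) {
      if (i == j) next
      cj <- strsplit(codons[j], "")[[1]]
      if (code[[codons[i]]] == "*" || code[[codons[j]]] == "*") {
        OK[i, j] <- FALSE
        next
      }
      diffPos <- which(ci != cj)
      k <- length(diffPos)
      sdSum <- 0; ndSum <- 0; nPath <- 0L
      for (ord in perms[[as.character(k)]]) {
        cur <- ci
        sd <- 0; nd <- 0; dropped <- FALSE
        for (step in diffPos[ord]) {
          nxt <- cur
          nxt[step] <- cj[step]
          aaFrom <- code[[paste(cur, collapse = "")]]
          aaTo <- code[[paste(nxt, collapse = "")]]
          if (aaTo == "*" || aaFrom == "*") { dropped <- TRUE; break }
          if (aaFrom == aaTo) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        if (!dropped) {
          sdSum <- sdSum + sd; ndSum <- ndSum + nd; nPath <- nPath + 1L
        }
      }
      if (nPath == 0L) {
        OK[i, j] <- FALSE
      } else {
        SD[i, j] <- sdSum / nPath
        ND[i, j] <- ndSum / nPath
      }
    }
  }
  list(SD = SD, ND = ND, OK = OK)
}

# Cached accessor: tables are computed once per session per code table.
ng86Tables <- function(codeTable = NULL) {
  key <- if (is.null(codeTable)) "universal" else
    paste(codeTable, collapse = "")
  key <- substr(digestKey(key), 1, 32)
  if (is.null(.tdcache[[key]])) {
    .tdcache[[key]] <- list(
      sites = .codonSites(codeTable),
      diffs = .codonPairDiffs(codeTable),
      code = geneticCode(codeTable)
    )
  }
  .tdcache[[key]]
}

# Cheap stable key (no digest dependency): sum of char codes + length.
digestKey <- function(x) {
  paste0("k", sum(utf8ToInt(x)), "_", nchar(x))
}

# Split a CDS string into codons; errors if not a multiple of 3.
splitCodons <- function(cds) {
  cds <- toupper(as.character(cds))
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    stop("CDS length ", n, " is not a multiple of 3", call. = FALSE)
  }
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

# Translate a codon vector ("---" -> "-"), unknown/ambiguous -> "X".
translateCodons <- function(codons, codeTable = NULL) {
  code <- geneticCode(codeTable)
  aa <- unname(code[codons])
  aa[codons == "---"] <- "-"
  aa[is.na(aa)] <- "X"
  aa
}
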
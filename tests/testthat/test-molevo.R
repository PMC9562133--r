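# Codon alignment, NG86 Ka/Ks, selection labels and clock dating.

test_that("identical CDS give Ka = Ks = 0 with an undefined ratio", {
  ca <- alignCodonPair("ATGAAATTTGGG", "ATGAAATTTGGG")
  r <- ng86(ca)
  expect_identical(r$ks, 0)
  expect_identical(r$ka, 0)
  expect_true(is.na(r$ratio))
  expect_identical(r$selection, "undefined")
})

test_that("a single synonymous change in a two-codon pair is hand-checkable", {
  # GGA GGG vs GGA GGA: one synonymous third-position difference.
  # Each glycine codon has synonymous site count 1 (third position
  # fourfold degenerate, others 0), so S = 2, Sd = 1, pS = 1/2 and
  # Ks = -3/4 log(1 - 2/3).
  ca <- alignCodonPair("GGAGGG", "GGAGGA")
  r <- ng86(ca)
  expect_equal(r$S, 2)
  expect_equal(r$N, 4)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$ks, -0.75 * log(1 - (4 / 3) * 0.5))
  expect_equal(r$ka, 0)
})

test_that("NG86 agrees with the brute-force pathway oracle", {
  set.seed(401)
  for (i in 1:8) {
    anc <- randomCDS(60)
    p <- evolveCodonPair(anc, runif(1, 0.1, 1.2), runif(1, 0, 0.8))
    ca <- ungappedCodonAlignment(p$cdsA, p$cdsB)
    r <- ng86(ca)
    o <- oracleNg86(p$cdsA, p$cdsB)
    expect_equal(r$S, o$S, tolerance = 1e-12)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-12)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-12)
    if (!is.na(o$ks)) expect_equal(r$ks, o$ks, tolerance = 1e-12)
  }
})

test_that("ng86 is symmetric in its two sequences", {
  set.seed(402)
  for (i in 1:5) {
    anc <- randomCDS(50)
    p <- evolveCodonPair(anc, 0.6, 0.3)
    r1 <- ng86(ungappedCodonAlignment(p$cdsA, p$cdsB))
    r2 <- ng86(ungappedCodonAlignment(p$cdsB, p$cdsA))
    expect_identical(r1$S, r2$S)
    expect_identical(r1$Sd, r2$Sd)
    expect_identical(r1$Nd, r2$Nd)
    expect_identical(r1$ks, r2$ks)
  }
})

test_that("site and difference counts pool additively over concatenation", {
  set.seed(403)
  a1 <- randomCDS(40); p1 <- evolveCodonPair(a1, 0.4, 0.2)
  a2 <- randomCDS(30); p2 <- evolveCodonPair(a2, 0.8, 0.5)
  rA <- ng86(ungappedCodonAlignment(p1$cdsA, p1$cdsB))
  rB <- ng86(ungappedCodonAlignment(p2$cdsA, p2$cdsB))
  rAB <- ng86(ungappedCodonAlignment(paste0(p1$cdsA, p2$cdsA),
                                     paste0(p1$cdsB, p2$cdsB)))
  expect_equal(rAB$S, rA$S + rB$S)
  expect_equal(rAB$N, rA$N + rB$N)
  expect_equal(rAB$Sd, rA$Sd + rB$Sd)
  expect_equal(rAB$Nd, rA$Nd + rB$Nd)
})

test_that("S + N equals 3 times the included codon count", {
  set.seed(404)
  anc <- randomCDS(80)
  p <- evolveCodonPair(anc, 0.5, 0.3)
  r <- ng86(alignCodonPair(p$cdsA, p$cdsB))
  expect_equal(r$S + r$N, 3 * r$nCodons)
})

test_that("protein alignment matches a Needleman-Wunsch/Gotoh DP oracle", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  aln <- alignProteins("ACD", "AD")
  expect_identical(aln$aligned2, "A-D")
  self <- alignProteins("MKVW", "MKVW")
  expect_equal(self$score,
               sum(diag(BLOSUM62[c("M", "K", "V", "W"),
                                 c("M", "K", "V", "W")])))
  set.seed(405)
  aas <- rownames(BLOSUM62)[1:20]
  for (i in 1:10) {
    s1 <- paste(sample(aas, 10, replace = TRUE), collapse = "")
    s2 <- paste(sample(aas, sample(7:12, 1), replace = TRUE), collapse = "")
    got <- alignProteins(s1, s2)$score
    want <- oracleGotohScore(s1, s2, BLOSUM62, open = 10, ext = 0.5)
    expect_equal(got, want)
  }
  expect_error(alignProteins("", "ACD"), "empty")
})

test_that("backtranslation maps residues to source codons and round-trips", {
  aln <- list(aligned1 = "MK-V", aligned2 = "MKAV")
  cds1 <- "ATGAAAGTT"      # M K V
  cds2 <- "ATGAAAGCAGTG"   # M K A V
  ca <- backtranslate(aln, cds1, cds2)
  expect_identical(ca@codons1, c("ATG", "AAA", "---", "GTT"))
  expect_identical(ca@codons2, c("ATG", "AAA", "GCA", "GTG"))
  expect_identical(ca@excluded, c(FALSE, FALSE, TRUE, FALSE))
  # round-trip: translating the codon rows reproduces the guide alignment
  set.seed(406)
  for (i in 1:5) {
    anc <- randomCDS(30)
    p <- evolveCodonPair(anc, 0.7, 0.4)
    ca <- alignCodonPair(p$cdsA, p$cdsB, id1 = "a", id2 = "b")
    tr1 <- paste(ifelse(ca@codons1 == "---", "-",
                        translateCodons(ca@codons1)), collapse = "")
    p1 <- paste(translateCodons(splitCodons(p$cdsA)), collapse = "")
    aln <- alignProteins(p1, paste(translateCodons(splitCodons(p$cdsB)),
                                   collapse = ""))
    expect_identical(tr1, aln$aligned1)
  }
  expect_error(backtranslate(aln, "ATGAAA", cds2, id1 = "geneX"), "geneX")
  expect_error(backtranslate(list(aligned1 = "MW", aligned2 = "MW"),
                             "ATGCCC", "ATGTGG", id1 = "bad"), "bad")
})

test_that("report ratio, selection labels and clock dating follow the rules", {
  expect_identical(kaksRatio(0.34, 2.32), 0.15)
  expect_identical(kaksRatio(0.24, 2.99), 0.08)
  expect_identical(kaksRatio(0, 1), 0)
  expect_true(is.na(kaksRatio(0.3, 0)))

  expect_identical(classifySelection(0.15), "negative")
  expect_identical(classifySelection(1), "neutral")
  expect_identical(classifySelection(1 + 1e-12), "neutral")
  expect_identical(classifySelection(1.7), "positive")
  expect_identical(classifySelection(NA_real_), "undefined")

  expect_identical(divergenceTime(0.6), 20.0)
  expect_identical(divergenceTime(0.7), 23.3)
  expect_identical(divergenceTime(2.5), 83.3)
  expect_error(divergenceTime(-0.1), "non-negative")
  # linearity in ks at full precision
  t1 <- divergenceTime(0.31, digits = 10)
  t3 <- divergenceTime(3 * 0.31, digits = 10)
  expect_equal(t3, 3 * t1)
})

test_that("computeKaKs assembles a per-pair table and errors on missing CDS", {
  set.seed(407)
  anc <- randomCDS(120)
  p <- evolveCodonPair(anc, 0.5, 0.2)
  cds <- Biostrings::DNAStringSet(c(gA = p$cdsA, gB = p$cdsB))
  tab <- computeKaKs(data.frame(gene1 = "gA", gene2 = "gB"), cds)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$selection, classifySelection(tab$ka / tab$ks))
  expect_identical(tab$t_ma, divergenceTime(tab$ks))
  expect_error(computeKaKs(data.frame(gene1 = "gA", gene2 = "gZ"), cds),
               "gZ")
})
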
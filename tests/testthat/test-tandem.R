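# Homology filtering, ranking, tandem-pair extraction, clustering and
# chromosome summaries.

mkHits <- function(q, s, evalue = 1e-50, bitscore = 100) {
  data.frame(qseqid = q, sseqid = s, evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

mkAnn <- function(ids, chrom, start) {
  data.frame(gene_id = ids, chromosome = chrom, start = start,
             end = start + 10, stringsAsFactors = FALSE)
}

test_that("homology filtering drops self-hits and weak E-values", {
  hits <- rbind(mkHits("A", "A"), mkHits("A", "B", evalue = 1e-9),
                mkHits("A", "C", evalue = 1e-11))
  out <- filterHits(hits)
  expect_identical(out$gene1, "A")
  expect_identical(out$gene2, "C")
  # the cutoff is strict: exactly 1e-10 is removed too
  expect_identical(nrow(filterHits(mkHits("A", "B", evalue = 1e-10))), 0L)
})

test_that("only the top-N subjects per query survive, deterministically", {
  subj <- sprintf("S%02d", 1:15)
  hits <- mkHits(rep("Q", 15), subj, evalue = 0,
                 bitscore = c(rep(500, 5), rep(400, 10)))
  out <- filterHits(hits, topN = 10)
  expect_identical(nrow(out), 10L)
  # ties broken by subject id: among the 400-bit hits the first five ids win
  expect_setequal(out$gene2, c(sprintf("S%02d", 1:5), sprintf("S%02d", 6:10)))
})

test_that("a pair is kept if either direction survives filtering", {
  hits <- rbind(mkHits("A", "B", evalue = 1e-20),
                mkHits("B", "A", evalue = 1e-5))  # reverse fails cutoff
  out <- filterHits(hits)
  expect_identical(nrow(out), 1L)
  expect_identical(out$gene1, "A")
  expect_identical(out$gene2, "B")
  # enumeration on a 3-gene toy: every surviving direction induces its pair
  toy <- rbind(mkHits("A", "B"), mkHits("B", "C", evalue = 1e-3),
               mkHits("C", "B"))
  out2 <- filterHits(toy)
  expect_identical(paste(out2$gene1, out2$gene2),
                   c("A B", "B C"))
})

test_that("malformed homology rows are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t90\t100\t5\t0\t1\t100\t1\t100\t1e-50\t200",
               "A\tC\t90\t100\t5\t0\t1\t100\t1\t100\t-3\t200"), f)
  expect_error(readHomologyTable(f), "line 2")
})

test_that("ranks are 0-based per chromosome with deterministic ties", {
  expect_identical(assignRanks(mkAnn("g1", "c1", 100))$rank, 0L)
  r <- assignRanks(mkAnn(c("a", "b", "c"), "c1", c(100, 50, 200)))
  expect_identical(r$gene_id[order(r$rank)], c("b", "a", "c"))
  two <- assignRanks(mkAnn(c("a", "b", "c", "d"), c("c1", "c1", "c2", "c2"),
                           c(10, 5, 7, 3)))
  expect_identical(sort(two$rank[two$chromosome == "c1"]), 0:1)
  expect_identical(sort(two$rank[two$chromosome == "c2"]), 0:1)
  # shared start: end then gene_id breaks the tie
  ann <- data.frame(gene_id = c("y", "x"), chromosome = "c1",
                    start = c(5, 5), end = c(20, 20))
  r2 <- assignRanks(ann)
  expect_identical(r2$gene_id[r2$rank == 0], "x")
  expect_error(assignRanks(mkAnn(c("a", "a"), "c1", c(1, 50))), "duplicate")
})

test_that("tandem pairs require same chromosome and rank gap <= maxGap", {
  ann <- mkAnn(sprintf("g%d", 1:10), "c1", seq(100, 1000, by = 100))
  ranked <- assignRanks(ann)
  adj <- findTandemPairs(ranked, data.frame(gene1 = "g6", gene2 = "g7"))
  expect_identical(nrow(adj), 1L)
  cross <- assignRanks(mkAnn(c("a", "b"), c("c1", "c2"), c(1, 1)))
  expect_identical(
    nrow(findTandemPairs(cross, data.frame(gene1 = "a", gene2 = "b"))), 0L)
  far <- data.frame(gene1 = "g6", gene2 = "g9")  # ranks 5 and 8
  expect_identical(nrow(findTandemPairs(ranked, far, maxGap = 1)), 0L)
  expect_identical(nrow(findTandemPairs(ranked, far, maxGap = 3)), 1L)
  # brute-force over all pairs of the toy chromosome at both gaps
  for (gap in c(1, 3)) {
    prs <- t(utils::combn(ann$gene_id, 2))
    hom <- data.frame(gene1 = prs[, 1], gene2 = prs[, 2])
    got <- findTandemPairs(ranked, hom, maxGap = gap)
    want <- oracleTandemClusters(ann, hom, maxGap = gap)
    expect_identical(sort(unique(c(got$gene1, got$gene2))),
                     sort(unique(unlist(want))))
  }
  expect_error(findTandemPairs(ranked, data.frame(gene1 = "g1",
                                                  gene2 = "nope")),
               "unknown")
})

test_that("clusters are connected components ordered by rank", {
  ann <- mkAnn(c("A", "B", "C", "D"), "c1", c(10, 20, 30, 40))
  ranked <- assignRanks(ann)
  cl <- buildClusters(findTandemPairs(
    ranked, data.frame(gene1 = c("A", "B"), gene2 = c("B", "C"))))
  expect_identical(length(cl), 1L)
  expect_identical(cl@members[[1]], c("A", "B", "C"))
  cl2 <- buildClusters(findTandemPairs(
    ranked, data.frame(gene1 = c("A", "C"), gene2 = c("B", "D"))))
  expect_identical(clusterSizes(cl2), c(2L, 2L))
})

test_that("cluster membership is invariant to hit row order", {
  set.seed(501)
  toy <- randomToyGenome(40)
  ranked <- assignRanks(toy$annotation)
  p1 <- findTandemPairs(ranked, toy$homPairs)
  shuffled <- toy$homPairs[sample(nrow(toy$homPairs)), , drop = FALSE]
  p2 <- findTandemPairs(ranked, shuffled)
  key <- function(cl) sort(vapply(cl@members, paste, "", collapse = ","))
  expect_identical(key(buildClusters(p1)), key(buildClusters(p2)))
})

test_that("detection matches the brute-force oracle on random toy genomes", {
  set.seed(502)
  for (i in 1:25) {
    toy <- randomToyGenome(nGenes = sample(10:50, 1))
    ranked <- assignRanks(toy$annotation)
    cl <- buildClusters(findTandemPairs(ranked, toy$homPairs))
    want <- oracleTandemClusters(toy$annotation, toy$homPairs)
    got <- lapply(cl@members, sort)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
    # no cluster spans chromosomes; no gene in two clusters
    chroms <- stats::setNames(toy$annotation$chromosome,
                              toy$annotation$gene_id)
    expect_true(all(vapply(cl@members,
                           function(m) length(unique(chroms[m])) == 1L,
                           TRUE)))
    expect_false(anyDuplicated(unlist(cl@members)) > 0)
  }
})

test_that("chromosome distribution and TDG fraction report 2-decimal percents", {
  ann <- mkAnn(sprintf("g%d", 1:6), rep(c("c1", "c2"), each = 3),
               rep(c(10, 20, 30), 2))
  d <- chromosomeDistribution(c("g1", "g2", "g4"), ann)
  expect_identical(d$n_tdg, c(2L, 1L))
  expect_identical(d$pct, c(66.67, 33.33))
  one <- chromosomeDistribution(c("g1", "g2"), ann[ann$chromosome == "c1", ])
  expect_identical(one$pct, 100)
  empty <- chromosomeDistribution(character(), ann)
  expect_identical(nrow(empty), 0L)
  expect_identical(tdgFraction(character(), ann), 0)
  expect_identical(tdgFraction(ann$gene_id, ann), 100)
  expect_identical(tdgFraction(c("g1", "g2", "g3"), ann), 50)
})
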
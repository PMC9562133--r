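# Synthetic-data generator: genomes with planted arrays, codon-pair
# evolution, homology tables and the expression design.

test_that("an empty configuration plants nothing", {
  cfg <- simConfig(nChromosomes = 1, genesPerChromosome = 20, rngSeed = 5)
  sim <- generateGenome(cfg)
  expect_identical(length(sim$manifest$clusters), 0L)
  hom <- generateHomologyTable(sim$annotation, sim$manifest, seed = 1)
  cl <- detectTandem(sim$annotation, hom)
  expect_identical(length(cl), 0L)
})

test_that("a planted 9-gene array is mutually homologous and recorded", {
  cfg <- simConfig(nChromosomes = 1, genesPerChromosome = 15,
                   plantedClusters = data.frame(
                     chromosome = "chr01", startRank = 3L, size = 9L,
                     trueKs = 0.3, trueKaks = 0.2, class = NA_character_),
                   rngSeed = 6)
  sim <- generateGenome(cfg)
  expect_identical(lengths(lapply(sim$manifest$clusters, `[[`, "members")),
                   9L)
  mm <- sim$manifest$clusters[[1]]$members
  # members occupy consecutive ranks 3..11
  ranked <- assignRanks(sim$annotation)
  expect_identical(sort(ranked$rank[match(mm, ranked$gene_id)]), 3:11)
  # all pairs alignable with moderate divergence
  cds <- as.character(sim$cds)
  for (pair in list(mm[c(1, 9)], mm[c(4, 5)])) {
    r <- ng86(alignCodonPair(cds[[pair[1]]], cds[[pair[2]]]))
    expect_lt(r$ks, 1.5)
  }
})

test_that("genome layout is ordered, non-overlapping and translates cleanly", {
  cfg <- simConfig(nChromosomes = 2, genesPerChromosome = 30,
                   plantedClusters = data.frame(
                     chromosome = "chr02", startRank = 0L, size = 3L,
                     trueKs = 0.5, trueKaks = 0.2, class = NA_character_),
                   rngSeed = 7)
  sim <- generateGenome(cfg)
  df <- assignRanks(sim$annotation)
  for (chr in unique(df$chromosome)) {
    sub <- df[df$chromosome == chr, ]
    sub <- sub[order(sub$start), ]
    expect_true(all(diff(sub$start) > 0))
    expect_true(all(utils::head(sub$end, -1) < sub$start[-1]))
    expect_identical(sort(sub$rank), seq_len(nrow(sub)) - 1L)
  }
  # CDS are stop-free multiples of 3 and translate to the emitted proteins
  expect_true(all(Biostrings::width(sim$cds) %% 3 == 0))
  expect_identical(as.character(Biostrings::translate(sim$cds,
                                                      no.init.codon = TRUE)),
                   as.character(sim$proteins))
  expect_false(any(grepl("\\*", as.character(sim$proteins))))
})

test_that("overlapping planted clusters are rejected at construction", {
  expect_error(simConfig(nChromosomes = 1, genesPerChromosome = 20,
                         plantedClusters = data.frame(
                           chromosome = "chr01", startRank = c(2L, 4L),
                           size = c(4L, 2L), trueKs = 0.3, trueKaks = 0.2,
                           class = NA_character_)),
               "overlap")
  expect_error(simConfig(plantedClusters = data.frame(
    chromosome = "chr01", startRank = 0L, size = 12L, trueKs = 0.3,
    trueKaks = 0.2, class = NA_character_)), "\\[2, 9\\]")
})

test_that("codon-pair evolution honours its zero and error contracts", {
  set.seed(901)
  anc <- randomCDS(150)
  same <- evolveCodonPair(anc, 0, 0, seed = 3)
  expect_identical(same$cdsA, anc)
  expect_identical(same$cdsB, anc)
  expect_error(evolveCodonPair(anc, 0.5, -0.1), ">= 0")
  expect_error(evolveCodonPair(anc, -0.5, 0.1), ">= 0")
  # evolved sequences stay stop-free and in frame
  p <- evolveCodonPair(anc, 1.0, 0.5, seed = 4)
  expect_identical(nchar(p$cdsA), nchar(anc))
  expect_false(grepl("\\*", paste(translateCodons(splitCodons(p$cdsA)),
                                  collapse = "")))
})

test_that("homology tables contain the planted pair graph exactly", {
  cfg <- simConfig(nChromosomes = 1, genesPerChromosome = 12,
                   plantedClusters = data.frame(
                     chromosome = "chr01", startRank = 4L, size = 3L,
                     trueKs = 0.3, trueKaks = 0.2, class = NA_character_),
                   rngSeed = 8)
  sim <- generateGenome(cfg)
  hom <- generateHomologyTable(sim$annotation, sim$manifest, seed = 2)
  self <- hom[hom$qseqid == hom$sseqid, ]
  expect_identical(nrow(self), 12L)
  inform <- hom[hom$qseqid != hom$sseqid, ]
  key <- paste(pmin(inform$qseqid, inform$sseqid),
               pmax(inform$qseqid, inform$sseqid))
  expect_identical(length(unique(key)), 3L)  # complete graph on 3 genes
  expect_true(all(inform$evalue < 1e-10))
  # both directions present
  expect_identical(nrow(inform), 6L)
})

test_that("homology noise never joins two distinct planted clusters", {
  cfg <- simConfig(nChromosomes = 2, genesPerChromosome = 100,
                   plantedClusters = data.frame(
                     chromosome = rep(c("chr01", "chr02"), each = 3),
                     startRank = c(0L, 10L, 40L, 5L, 30L, 70L),
                     size = 3L, trueKs = 0.3, trueKaks = 0.2,
                     class = NA_character_),
                   backgroundNoise = 0.05, rngSeed = 9)
  sim <- generateGenome(cfg)
  hom <- generateHomologyTable(sim$annotation, sim$manifest, noise = 0.05,
                               seed = 10)
  planted <- lapply(sim$manifest$clusters, `[[`, "members")
  clusterOf <- stats::setNames(
    rep(seq_along(planted), lengths(planted)), unlist(planted))
  inform <- hom[hom$qseqid != hom$sseqid, ]
  q <- clusterOf[inform$qseqid]; s <- clusterOf[inform$sseqid]
  both <- !is.na(q) & !is.na(s)
  expect_true(all(q[both] == s[both]))
  # and detection still recovers the planted clusters exactly
  rec <- clusterRecovery(detectTandem(sim$annotation, hom), sim$manifest)
  expect_identical(rec$ari, 1)
})

test_that("expression design plants the advertised up-regulation events", {
  cfg <- simConfig(nChromosomes = 1, genesPerChromosome = 40, rngSeed = 10)
  manifest <- list(
    genes = sprintf("g%02d", 1:40),
    geneLengths = stats::setNames(rep(900, 40), sprintf("g%02d", 1:40)),
    geneClasses = data.frame(gene_id = "g01", label = "leaf_specific")
  )
  expr <- generateExpression(cfg, manifest, seed = 11)
  expect_identical(dim(expr$counts), c(40L, 60L))  # 2*5*2*3 samples
  cnt <- countUpEvents(callUp(expr$de))
  expect_identical(cnt$leaf[cnt$gene_id == "g01"], 5L)
  expect_identical(cnt$root[cnt$gene_id == "g01"], 0L)
  badCfg <- simConfig(tissues = c("leaf", "root", "stem"))
  expect_error(generateExpression(badCfg, manifest), "two tissues")
})

test_that("a null expression design yields essentially no up-calls", {
  cfg <- simConfig(nChromosomes = 1, genesPerChromosome = 100, rngSeed = 12)
  manifest <- list(genes = sprintf("g%03d", 1:100),
                   geneLengths = stats::setNames(rep(900, 100),
                                                 sprintf("g%03d", 1:100)),
                   geneClasses = data.frame(gene_id = character(),
                                            label = character()))
  expr <- generateExpression(cfg, manifest, seed = 13)
  de <- simpleDE(expr$counts, expr$design)
  expect_lt(mean(callUp(de)$up), 0.005)
})
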
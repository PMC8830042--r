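# Desk-scale configs are deliberately small here; the full recovery runs live
# in the acceptance suite.
small_cfg <- function(...) {
  args <- list(chromLength = 5e5, nGenes = 50, nDmrBins = 10,
               nHigh = 4, nAverage = 4)
  do.call(simulationConfig, utils::modifyList(args, list(...)))
}

test_that("the toy genome represents every feature class and round-trips via GTF", {
  cfg <- small_cfg(seed = 2)
  gen <- simulateGenome(cfg)
  tl <- buildTiling(gen$chromSizes)
  ann <- annotateBins(tl, gen$geneModels)
  expect_setequal(unique(as.character(mcols(ann)$feature)),
                  c("promoter", "UTR", "coding", "intron", "intergenic"))

  # no genes: everything intergenic
  gen0 <- simulateGenome(small_cfg(seed = 2, nGenes = 1, nDeg = 0))
  gm0 <- geneModels(genes(gen0$geneModels)[0])
  ann0 <- annotateBins(tl, gm0)
  expect_true(all(as.character(mcols(ann0)$feature) == "intergenic"))

  # GTF round trip is lossless for spans, exons, CDS and UTRs
  gtf <- tempfile(fileext = ".gtf")
  writeGeneModelsGTF(gen$geneModels, gtf)
  back <- readGeneModels(gtf, chromSizes = gen$chromSizes)
  orig <- gen$geneModels
  expect_equal(granges(genes(back)), granges(genes(orig)))
  expect_equal(mcols(genes(back))$tss, mcols(genes(orig))$tss)
  ids <- mcols(genes(orig))$gene_id
  for (nm in c("exons", "cds", "utr5", "utr3")) {
    a <- slot(back, nm)[ids]
    b <- slot(orig, nm)[ids]
    expect_equal(unname(as.list(ranges(a))), unname(as.list(ranges(b))),
                 info = nm)
  }

  # infeasible density errors out
  expect_error(simulateGenome(simulationConfig(chromLength = 2.5e5,
                                               nGenes = 200)),
               "infeasible")
})

test_that("fragment simulation is deterministic and matches its ground truth", {
  cfg <- small_cfg(seed = 4)
  s1 <- simulateFragments(cfg)
  s2 <- simulateFragments(cfg)
  expect_identical(s1$fragments, s2$fragments)
  expect_identical(s1$truth, s2$truth)

  # BED output is byte-identical on rerun
  f1 <- tempfile(); f2 <- tempfile()
  writeFragmentsBed(s1$fragments[[1]], f1)
  writeFragmentsBed(s2$fragments[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))

  # sample sheet: groups sized as configured, risk scores consistent
  expect_equal(sum(s1$sampleSheet$group == "high"), 4L)
  expect_equal(assignRiskGroup(s1$sampleSheet$risk_score), s1$sampleSheet$group)

  # planted bins are flagged with direction and effect, disjoint from nulls
  expect_equal(nrow(s1$truth), 10L)
  expect_true(all(s1$truth$direction %in% c("hyper", "hypo")))
  expect_equal(sum(s1$truth$direction == "hyper"),
               round(0.989 * 10))
  expect_false(anyDuplicated(s1$truth$bin_id) > 0)
})

test_that("count simulation is deterministic with NB marginals and planted effects", {
  cfg <- small_cfg(seed = 6, nDeg = 5, degLog2fc = 2)
  c1 <- simulateCounts(cfg)
  c2 <- simulateCounts(cfg)
  expect_identical(c1$counts, c2$counts)
  expect_equal(dim(c1$counts), c(50L, 8L))
  expect_true(all(c1$counts >= 0) && all(c1$counts == round(c1$counts)))
  expect_equal(nrow(c1$truth), 5L)

  # null config: essentially no FDR-significant genes
  cfg0 <- simulationConfig(seed = 6, nHigh = 10, nAverage = 10,
                           nGenes = 500, nDeg = 0)
  sim0 <- simulateCounts(cfg0)
  g <- stats::setNames(sim0$sampleSheet$group, sim0$sampleSheet$sample_id)
  de0 <- deTTest(sim0$counts, g)
  expect_lte(sum(de0$q_value < 0.05), 5L)
})

test_that("methylation-expression links plant correlations of the right sign", {
  cfg <- simulationConfig(seed = 8, nHigh = 10, nAverage = 10, nGenes = 50,
                          nDeg = 0)
  set.seed(99)
  z <- matrix(rnorm(5 * 20), 5, 20,
              dimnames = list(paste0("b", 1:5), sample_names <- c(
                sprintf("H%02d", 1:10), sprintf("A%02d", 1:10))))
  sc <- simulateCounts(cfg)
  links <- data.frame(bin = c("b1", "b2"), gene = c("g00001", "g00002"),
                      r = c(-0.6, 0.6))
  lk <- linkMethExpr(cfg, z, sc$counts, links)
  cp <- correlatePairs(links, z, lk$counts)
  expect_lt(cp$r[1], 0)
  expect_gt(cp$r[2], 0)

  # r sign preserved under count scaling
  cp2 <- correlatePairs(links, z, lk$counts * 3)
  expect_equal(sign(cp2$r), sign(cp$r))

  expect_error(linkMethExpr(cfg, z, sc$counts,
                            data.frame(bin = "b1", gene = "g00001", r = 1)),
               "< 1")
})

test_that("paired simulation keeps subject pairing and plants both effect sets", {
  cfg <- simulationConfig(seed = 10, nGenes = 100, pairedHigh = 5,
                          pairedAverage = 8, nAgeFeatures = 10, nEnhanced = 3,
                          chromLength = 5e5, nAgeBins = 8, nEnhancedBins = 2)
  pp <- simulatePaired(cfg, what = "counts")
  des <- pp$design
  expect_equal(nrow(des), 2 * 13)
  expect_true(all(table(des$subject_id) == 2))
  expect_identical(pp$design, simulatePaired(cfg, what = "counts")$design)
  expect_true(all(pp$truth$enhanced_genes %in% pp$truth$age_genes$gene))
  expect_equal(colnames(pp$counts), des$sample_id)

  # fragment arm produces one fragment set per sample and flags planted bins
  pf <- simulatePaired(cfg, what = "fragments")
  expect_equal(length(pf$fragments), 2 * 13)
  expect_setequal(names(pf$fragments), des$sample_id)
  expect_equal(sum(pf$truth$age_bins$enhanced), 2L)
})
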
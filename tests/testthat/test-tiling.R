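test_that("tiling covers whole bins only and assigns regions by containment", {
  # exact tiling
  tl <- buildTiling(c(chrA = 1000L), binWidth = 250, regionWidth = 1000,
                    minBinsPerRegion = 4)
  expect_equal(length(bins(tl)), 4L)
  expect_equal(length(regions(tl)), 1L)

  # trailing partial bin dropped
  tl2 <- buildTiling(c(chrA = 600L), binWidth = 250, regionWidth = 500,
                     minBinsPerRegion = 1)
  expect_equal(start(bins(tl2)) - 1L, c(0L, 250L))
  expect_equal(end(bins(tl2)), c(250L, 500L))

  # 50 kb, default widths: 200 bins, 2 regions; bin at 0-based 30000 is in
  # the second region
  tl3 <- buildTiling(c(chr1 = 50000L))
  expect_equal(length(bins(tl3)), 200L)
  expect_equal(length(regions(tl3)), 2L)
  b <- bins(tl3)
  expect_equal(mcols(b)$region_id[start(b) == 30001L], 2L)

  # union of retained bins covers floor(L / W) * W bases, disjoint and sorted
  tl4 <- buildTiling(c(c1 = 1234L, c2 = 777L), binWidth = 100,
                     regionWidth = 300, minBinsPerRegion = 2)
  b4 <- bins(tl4)
  expect_true(all(start(sort(b4)) == start(b4)))
  expect_equal(sum(width(GenomicRanges::reduce(b4))), 12L * 100L + 7L * 100L)
  expect_equal(sum(GenomicRanges::countOverlaps(b4, b4)), length(b4))

  expect_error(buildTiling(c(chrA = 1000L), binWidth = 250, regionWidth = 900),
               "divisible")
  expect_equal(length(bins(buildTiling(
    data.frame(name = character(), length = integer())))), 0L)
})

test_that("regions below the minimum bin count are flagged unusable", {
  tl <- buildTiling(c(chr1 = 27000L), binWidth = 250, regionWidth = 25000,
                    minBinsPerRegion = 10)
  r <- regions(tl)
  expect_equal(mcols(r)$n_bins, c(100L, 8L))
  expect_equal(mcols(r)$usable, c(TRUE, FALSE))
  expect_false(any(mcols(bins(tl))$region_usable[
    mcols(bins(tl))$region_id == 2L]))
})

test_that("bin annotation follows promoter > UTR > coding > intron precedence", {
  gm <- tiny_gene_models()
  tl <- buildTiling(c(chr1 = 50000L), minBinsPerRegion = 1)
  ann <- annotateBins(tl, gm)
  f <- stats::setNames(as.character(mcols(ann)$feature),
                       paste0(start(ann) - 1L, "-", end(ann)))

  # bin [8500, 8750) sits in geneA's promoter window (TSS 10000 0-based)
  expect_equal(unname(f["8500-8750"]), "promoter")
  # promoter wins over the 5' UTR it covers
  expect_equal(unname(f["10000-10250"]), "promoter")
  # bin inside geneA's intron
  expect_equal(unname(f["11000-11250"]), "intron")
  # 3' UTR bin of geneA (outside the promoter window)
  expect_equal(unname(f["11750-12000"]), "UTR")
  # far from both genes
  expect_equal(unname(f["40000-40250"]), "intergenic")
  expect_true(all(lengths(mcols(ann)$gene_names[
    as.character(mcols(ann)$feature) == "intergenic"]) == 0L))

  # minus-strand promoter: geneB TSS at 30000 (1-based end), upstream right
  expect_equal(unname(f["30250-30500"]), "promoter")

  # precedence with two genes: a bin overlapping geneA's CDS and an intron of
  # an overlapping second gene is coding and lists only the CDS gene
  si <- GenomeInfoDb::Seqinfo("chr1", 50000L)
  gB <- GRanges("chr1", IRanges(9001, 13000), strand = "+", seqinfo = si)
  mcols(gB)$gene_id <- "geneC"; mcols(gB)$gene_name <- "C"
  g2 <- c(genes(tiny_gene_models())[1], gB)
  gm2 <- geneModels(g2, exons = tiny_gene_models()@exons["geneA"],
                    cds = tiny_gene_models()@cds["geneA"],
                    utr5 = tiny_gene_models()@utr5["geneA"],
                    utr3 = tiny_gene_models()@utr3["geneA"])
  qbin <- GRanges("chr1", IRanges(11401, 11650), seqinfo = si)
  a2 <- annotateBins(qbin, gm2, promoterUpstream = 100, promoterDownstream = 0)
  expect_equal(as.character(mcols(a2)$feature), "coding")
  expect_equal(as.character(unlist(mcols(a2)$gene_names)), "A")

  # independent of gene input order
  gm3 <- geneModels(rev(g2), exons = gm2@exons, cds = gm2@cds,
                    utr5 = gm2@utr5, utr3 = gm2@utr3)
  a3 <- annotateBins(qbin, gm3, promoterUpstream = 100, promoterDownstream = 0)
  expect_identical(mcols(a3)$feature, mcols(a2)$feature)
  expect_identical(as.list(mcols(a3)$gene_names), as.list(mcols(a2)$gene_names))

  # unknown chromosome
  expect_error(annotateBins(GRanges("chrUn", IRanges(1, 250)), gm),
               "unknown")
})

test_that("localization percentages match a direct tally and sum to 100", {
  s <- localizationSummary(rep("intron", 10), rep("hyper", 10))
  expect_equal(s$percent[s$feature == "intron"], 100)
  expect_equal(sum(s$percent[s$feature %in%
                             c("promoter", "UTR", "coding", "intron")]), 100)

  s2 <- localizationSummary(c("promoter", "coding"), c("hyper", "hyper"))
  expect_equal(s2$percent[s2$feature %in% c("promoter", "coding")], c(50, 50))

  set.seed(42)
  feats <- sample(c("promoter", "UTR", "coding", "intron", "intergenic"),
                  1000, replace = TRUE, prob = c(.1, .1, .2, .5, .1))
  dirs <- sample(c("hyper", "hypo"), 1000, replace = TRUE, prob = c(.9, .1))
  s3 <- localizationSummary(feats, dirs)
  for (d in c("hyper", "hypo")) {
    genic <- feats[dirs == d & feats != "intergenic"]
    for (cls in c("promoter", "UTR", "coding", "intron")) {
      expect_equal(s3$percent[s3$direction == d & s3$feature == cls],
                   100 * sum(genic == cls) / length(genic))
    }
    expect_equal(sum(s3$percent[s3$direction == d & s3$feature != "intergenic"]),
                 100, tolerance = 1e-10)
  }

  expect_equal(nrow(localizationSummary(character(), character())), 0L)
})
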
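suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

# Two genes on a 50-kb chromosome: geneA (+) with TSS at 10001, geneB (-)
# with TSS at 30000 (span end).  Each: two exons, CDS in both, UTRs at the
# ends.  Used wherever a small deterministic annotation target is needed.
tiny_gene_models <- function() {
  si <- GenomeInfoDb::Seqinfo("chr1", 50000L)
  g <- GRanges("chr1", IRanges(c(10001, 28001), c(12000, 30000)),
               strand = c("+", "-"), seqinfo = si)
  mcols(g)$gene_id <- c("geneA", "geneB")
  mcols(g)$gene_name <- c("A", "B")
  exons <- GRangesList(
    geneA = GRanges("chr1", IRanges(c(10001, 11401), c(10600, 12000)),
                    strand = "+", seqinfo = si),
    geneB = GRanges("chr1", IRanges(c(28001, 29401), c(28600, 30000)),
                    strand = "-", seqinfo = si))
  cds <- GRangesList(
    geneA = GRanges("chr1", IRanges(c(10201, 11401), c(10600, 11700)),
                    strand = "+", seqinfo = si),
    geneB = GRanges("chr1", IRanges(c(28301, 29401), c(28600, 29800)),
                    strand = "-", seqinfo = si))
  utr5 <- GRangesList(
    geneA = GRanges("chr1", IRanges(10001, 10200), strand = "+", seqinfo = si),
    geneB = GRanges("chr1", IRanges(29801, 30000), strand = "-", seqinfo = si))
  utr3 <- GRangesList(
    geneA = GRanges("chr1", IRanges(11701, 12000), strand = "+", seqinfo = si),
    geneB = GRanges("chr1", IRanges(28001, 28300), strand = "-", seqinfo = si))
  geneModels(g, exons = exons, cds = cds, utr5 = utr5, utr3 = utr3)
}

# Small methylation pipeline on simulated fragments; returns everything the
# recovery assertions need.
run_meth_pipeline <- function(config, tiling = NULL) {
  sim <- simulateFragments(config, tiling)
  fr <- deduplicateFragments(sim$fragments)
  se <- regionZScores(binCoverage(fr, sim$tiling))
  z <- SummarizedExperiment::assay(se, "z")
  grp <- stats::setNames(sim$sampleSheet$group, sim$sampleSheet$sample_id)
  tt <- binTTest(z, grp)
  dz <- deltaZ(z, grp)
  q <- bhFdr(tt$p_value)
  dmrs <- callDmrs(sim$tiling, dz, tt$p_value, q,
                   z_ratio = zRatio(z, grp), t_stat = tt$t_stat)
  list(sim = sim, z = z, groups = grp, dz = dz, tt = tt, q = q, dmrs = dmrs,
       bin_ids = mcols(bins(sim$tiling))$bin_id)
}

# Naive O(m^2) BH step-up, straight from the definition:
# q_i = min over j with p_j >= p_i of p_j * m / rank_j, capped at 1.
naive_bh <- function(p) {
  ok <- !is.na(p)
  m <- sum(ok)
  rk <- rep(NA_real_, length(p))
  rk[ok] <- vapply(p[ok], function(pi) sum(p[ok] <= pi), numeric(1))
  q <- rep(NA_real_, length(p))
  for (i in which(ok)) {
    cand <- which(ok & p >= p[i])
    q[i] <- min(1, min(p[cand] * m / rk[cand]))
  }
  q
}

table1_path <- function() {
  system.file("extdata", "table1_degs.tsv", package = "methRisk")
}
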
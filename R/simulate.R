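#' Configuration for the synthetic study generator
#'
#' Defaults describe the desk-scale study: one 5-Mb chromosome (20,000 bins of
#' 250 bp in 200 regions of 25 kb), 10 high-risk vs 10 average-risk samples,
#' 100 planted differential bins with a target group z-difference of 2 of
#' which 98.9\% are hypermethylated, 1000 genes with negative-binomial counts
#' and 50 planted differentially expressed genes, and a paired subcohort of
#' 10 high + 25 average subjects donating at two timepoints.  The full-scale
#' cohort (68 vs 78 samples) is obtained by setting \code{nHigh}/
#' \code{nAverage}.
#'
#' @param seed integer seed; every generator is deterministic given it.
#' @param nChrom,chromLength chromosome count and length (bp).
#' @param binWidth,regionWidth,minBinsPerRegion tiling parameters.
#' @param nHigh,nAverage samples per risk group.
#' @param regionDepthMean expected fragments per bin (region baseline).
#' @param regionDepthSdLog log-sd of between-region baseline variability.
#' @param binProfileSdLog log-sd of the fixed within-region per-bin intensity
#'   profile (shared across samples; emulates capture affinity/CpG density).
#' @param sampleDepthSdLog log-sd of per-sample library depth.
#' @param fragmentLengthMean,fragmentLengthSd insert length distribution
#'   (normal, clipped to [50, 1000] bp).
#' @param nDmrBins,dmrEffect,dmrHyperFraction planted differential bins: count,
#'   target group z-difference, and fraction hypermethylated.
#' @param nGenes,countMeanLog,countSdLog,nbDispersion expression baseline:
#'   gene count, lognormal mean/sd of base means, NB dispersion.
#' @param nDeg,degLog2fc planted differentially expressed genes and their
#'   log2 fold change (high over average).
#' @param pairedHigh,pairedAverage subjects per group in the two-timepoint
#'   subcohort.
#' @param nAgeFeatures,ageLog2fc age-shifted features at the second donation.
#' @param nEnhanced,enhancedLog2fc subset of age features receiving an extra
#'   high-group shift.
#' @param subjectSdLog2 per-subject baseline spread (log2 scale).
#' @param changeSdLog2 per-subject donation-to-donation noise (log2 scale).
#' @param nAgeBins,ageEffectZ,nEnhancedBins,enhancedEffectZ methylation
#'   analogues of the paired design (bin z-shifts at the second donation).
#' @return validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L, nChrom = 1L, chromLength = 5e6,
                             binWidth = 250L, regionWidth = 25000L,
                             minBinsPerRegion = 10L,
                             nHigh = 10L, nAverage = 10L,
                             regionDepthMean = 10, regionDepthSdLog = 0.4,
                             binProfileSdLog = 0.5, sampleDepthSdLog = 0.1,
                             fragmentLengthMean = 300, fragmentLengthSd = 50,
                             nDmrBins = 100L, dmrEffect = 2,
                             dmrHyperFraction = 0.989,
                             nGenes = 1000L, countMeanLog = log(200),
                             countSdLog = 1, nbDispersion = 0.05,
                             nDeg = 50L, degLog2fc = 2,
                             pairedHigh = 10L, pairedAverage = 25L,
                             nAgeFeatures = 25L, ageLog2fc = 1.2,
                             nEnhanced = 5L, enhancedLog2fc = 1.5,
                             subjectSdLog2 = 0.3, changeSdLog2 = 0.2,
                             nAgeBins = 50L, ageEffectZ = 1.5,
                             nEnhancedBins = 5L, enhancedEffectZ = 1.5) {
  cfg <- as.list(environment())
  stopifnot(cfg$nChrom >= 1, cfg$chromLength >= cfg$regionWidth,
            cfg$nHigh >= 2, cfg$nAverage >= 2,
            cfg$dmrHyperFraction >= 0, cfg$dmrHyperFraction <= 1,
            cfg$regionDepthMean > 0, cfg$nGenes >= 1,
            cfg$nDeg <= cfg$nGenes, cfg$nbDispersion > 0,
            cfg$nEnhanced <= cfg$nAgeFeatures,
            cfg$nEnhancedBins <= cfg$nAgeBins)
  class(cfg) <- "SimulationConfig"
  cfg
}

sim_chrom_sizes <- function(config) {
  data.frame(name = paste0("chr", seq_len(config$nChrom)),
             length = as.integer(config$chromLength),
             stringsAsFactors = FALSE)
}

#' Simulate a toy genome with structured gene models
#'
#' Places genes on a regular grid so that every feature class (promoter, UTR,
#' coding, intron, intergenic) is represented: each 2-kb gene has two exons
#' (UTR + CDS each) separated by an intron, with strand drawn at random and
#' the structure mirrored on the minus strand.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{chromSizes} (data.frame) and \code{geneModels}
#'   (\linkS4class{GeneModels}).
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (config$chromLength < 10 * config$regionWidth)
    stop("chromLength must cover at least 10 regions")
  set.seed(config$seed + 11L)
  cs <- sim_chrom_sizes(config)
  si <- Seqinfo(cs$name, cs$length)
  n_per <- diff(round(seq(0, config$nGenes, length.out = config$nChrom + 1)))
  gene_w <- 2000L
  gl <- list(); el <- list(); cl <- list(); u5 <- list(); u3 <- list()
  gid <- 0L
  for (i in seq_len(config$nChrom)) {
    n <- n_per[i]
    if (n == 0L) next
    slot <- floor(cs$length[i] / n)
    if (slot < gene_w + 500L)
      stop("gene density infeasible: ", n, " genes do not fit on a ",
           cs$length[i], " bp chromosome")
    # bin-aligned span start, with room upstream for a promoter window
    starts <- (seq_len(n) - 1L) * slot + 2001L
    starts <- (starts %/% config$binWidth) * config$binWidth + 1L
    strands <- sample(c("+", "-"), n, replace = TRUE)
    ids <- sprintf("g%05d", gid + seq_len(n))
    spans <- GRanges(cs$name[i], IRanges(starts, width = gene_w),
                     strand = strands, seqinfo = si)
    mcols(spans)$gene_id <- ids
    mcols(spans)$gene_name <- toupper(ids)
    mcols(spans)$tss <- ifelse(strands == "+", starts, starts + gene_w - 1L)
    # relative layout (plus strand): utr5 0-199, cds 200-599 & 1400-1699,
    # intron 600-1399, utr3 1700-1999; mirrored on minus strand
    piece <- function(a, b) cbind(a, b)   # 0-based rel [a, b)
    lay <- list(exons = rbind(piece(0, 600), piece(1400, 2000)),
                cds = rbind(piece(200, 600), piece(1400, 1700)),
                utr5 = piece(0, 200), utr3 = piece(1700, 2000))
    mk <- function(rel, st, strand_) {
      if (strand_ == "-") rel <- cbind(gene_w - rel[, 2], gene_w - rel[, 1])
      rel <- rel[order(rel[, 1]), , drop = FALSE]
      GRanges(cs$name[i], IRanges(st + rel[, 1], st + rel[, 2] - 1L),
              strand = strand_, seqinfo = si)
    }
    for (k in seq_len(n)) {
      g <- gid + k
      el[[g]] <- mk(lay$exons, starts[k], strands[k])
      cl[[g]] <- mk(lay$cds, starts[k], strands[k])
      u5[[g]] <- mk(lay$utr5, starts[k], strands[k])
      u3[[g]] <- mk(lay$utr3, starts[k], strands[k])
    }
    gl[[i]] <- spans
    gid <- gid + n
  }
  genes <- if (length(gl)) do.call(c, gl) else
    GRanges(seqinfo = si)
  ids <- if (length(genes)) mcols(genes)$gene_id else character()
  gm <- new("GeneModels", genes = genes,
            exons = grl_named(el, ids), cds = grl_named(cl, ids),
            utr5 = grl_named(u5, ids), utr3 = grl_named(u3, ids))
  list(chromSizes = cs, geneModels = gm)
}

grl_named <- function(lst, ids) {
  if (!length(lst)) return(GenomicRanges::GRangesList())
  out <- GenomicRanges::GRangesList(lst)
  names(out) <- ids
  out
}

# Variance of mean per-base depth over a window of width W, for fragments
# starting as a Poisson process at rate rho per bp with mean length Lmean:
# Var = (rho / W^2) * sum_k (W - |k|) * max(Lmean - |k|, 0), k in -(W-1)..(W-1)
coverage_var_factor <- function(W, Lmean) {
  k <- seq(-(W - 1L), W - 1L)
  sum((W - abs(k)) * pmax(Lmean - abs(k), 0)) / W^2
}

# Draw one sample's fragments given per-bin expected fragment counts.
# Fragments are placed by their midpoint, uniform within the bin, so the
# coverage mass a bin's own fragments deposit outside it spills symmetrically
# into both neighbours (and hyper/hypo shifts act symmetrically).
frag_sample <- function(bins_gr, lambda, lenMean, lenSd) {
  n <- stats::rpois(length(lambda), lambda)
  tot <- sum(n)
  if (!tot) return(GRanges(seqinfo = seqinfo(bins_gr)))
  idx <- rep.int(seq_along(lambda), n)
  w <- width(bins_gr)[1]
  mid <- start(bins_gr)[idx] + floor(stats::runif(tot) * w)
  lens <- pmin(pmax(round(stats::rnorm(tot, lenMean, lenSd)), 50L), 1000L)
  starts <- pmax(mid - lens %/% 2L, 1L)
  chr <- as.character(seqnames(bins_gr))[idx]
  sl <- seqlengths(bins_gr)
  ends <- pmin(starts + lens - 1L, sl[chr])
  gr <- GRanges(chr, IRanges(starts, ends), seqinfo = seqinfo(bins_gr))
  sort(gr)
}

# Expected overlap (bp) between a bin of width W and one of its own
# fragments (midpoint uniform in the bin, clipped-normal length).  This is
# the coverage mass one planted fragment deposits in its own bin; the rest
# spills into the neighbours.
own_overlap_mean <- function(W, lenMean, lenSd) {
  L <- 50:1000
  wgt <- stats::dnorm(L, lenMean, lenSd)
  wgt <- wgt / sum(wgt)
  u <- seq_len(W) - 0.5                 # midpoint offset within the bin
  ov <- vapply(L, function(l) {
    mean(pmin(u + l / 2, W) - pmax(u - l / 2, 0))
  }, numeric(1))
  sum(ov * wgt)
}

# Shared machinery: lambda profile, region sds in coverage units, and the
# lambda increment equivalent to a z-shift of one.
sim_lambda_profile <- function(config, tiling) {
  b <- bins(tiling)
  rid <- mcols(b)$region_id
  n_region <- length(regions(tiling))
  lam_region <- stats::rlnorm(n_region,
                              log(config$regionDepthMean) -
                                config$regionDepthSdLog^2 / 2,
                              config$regionDepthSdLog)
  m_b <- stats::rlnorm(length(b), -config$binProfileSdLog^2 / 2,
                       config$binProfileSdLog)
  lambda <- lam_region[rid] * m_b
  W <- binWidth(tiling)
  L <- config$fragmentLengthMean
  e_own <- own_overlap_mean(W, L, config$fragmentLengthSd)
  s_nb <- (L - e_own) / 2                     # mass spilled per neighbour
  lam_prev <- c(lambda[1], lambda[-length(lambda)])
  lam_next <- c(lambda[-1], lambda[length(lambda)])
  # expected per-base depth, accounting for symmetric spill between bins
  e_cov <- (e_own * lambda + s_nb * (lam_prev + lam_next)) / W
  vf <- coverage_var_factor(W, L)
  grp <- match(rid, unique(rid))
  nb <- tabulate(grp)
  mu_e <- rowsum(e_cov, grp, reorder = FALSE)[, 1] / nb
  var_prof <- rowsum((e_cov - mu_e[grp])^2, grp, reorder = FALSE)[, 1] /
    pmax(nb - 1L, 1L)
  var_pois <- rowsum(lambda / W * vf, grp, reorder = FALSE)[, 1] / nb
  sd_region <- sqrt(var_prof + var_pois)      # coverage units, per region
  list(lambda = lambda, sd_region = sd_region, grp = grp,
       dlam_per_z = sd_region * W / e_own)    # lambda shift for z-shift 1
}

sample_ids <- function(nHigh, nAverage) {
  c(sprintf("H%02d", seq_len(nHigh)), sprintf("A%02d", seq_len(nAverage)))
}

#' Simulate per-sample capture fragments with planted differential bins
#'
#' Region-structured fragment coverage: each region has a lognormal baseline
#' intensity, each bin a fixed lognormal intensity multiplier shared across
#' samples, and per-sample bin fragment counts are Poisson.  Planted bins
#' receive a group-specific intensity shift calibrated (from the expected
#' within-region coverage standard deviation) so the expected group
#' z-difference equals \code{dmrEffect}; hyper/hypo is assigned by
#' \code{dmrHyperFraction}.  Fragment lengths are clipped normal.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param tiling optional \linkS4class{BinTiling}; built from the config
#'   when missing.
#' @return list with \code{fragments} (named \code{GRangesList}),
#'   \code{sampleSheet} (data.frame), \code{truth} (data.frame of planted
#'   bins: bin_id, chrom, start, end, direction, effect) and \code{tiling}.
#' @export
simulateFragments <- function(config, tiling = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (is.null(tiling))
    tiling <- buildTiling(sim_chrom_sizes(config), config$binWidth,
                          config$regionWidth, config$minBinsPerRegion)
  set.seed(config$seed + 23L)
  b <- bins(tiling)
  prof <- sim_lambda_profile(config, tiling)

  usable <- which(mcols(b)$region_usable)
  nplant <- min(config$nDmrBins, length(usable))
  planted <- sample(usable, nplant)
  n_hyper <- round(config$dmrHyperFraction * nplant)
  direction <- rep("hypo", nplant)
  if (n_hyper > 0) direction[seq_len(n_hyper)] <- "hyper"

  dlam <- prof$dlam_per_z[prof$grp[planted]] * config$dmrEffect
  lam_high <- prof$lambda
  lam_high[planted] <- lam_high[planted] + ifelse(direction == "hyper", 1, -1) * dlam
  if (any(lam_high[planted] < 0)) {
    warning(sum(lam_high[planted] < 0),
            " hypomethylation effect(s) truncated at zero intensity")
    lam_high[planted] <- pmax(lam_high[planted], 0)
  }

  ids <- sample_ids(config$nHigh, config$nAverage)
  group <- rep(c("high", "average"), c(config$nHigh, config$nAverage))
  frl <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    sf <- stats::rlnorm(1, 0, config$sampleDepthSdLog)
    lam <- if (group[j] == "high") lam_high else prof$lambda
    frl[[j]] <- frag_sample(b, sf * lam, config$fragmentLengthMean,
                            config$fragmentLengthSd)
  }
  names(frl) <- ids
  risk <- ifelse(group == "high", stats::runif(length(ids), 22, 40),
                 stats::runif(length(ids), 5, 18))
  sheet <- data.frame(sample_id = ids, subject_id = ids, group = group,
                      timepoint = "none", risk_score = round(risk, 1),
                      stringsAsFactors = FALSE)
  truth <- data.frame(bin_id = mcols(b)$bin_id[planted],
                      chrom = as.character(seqnames(b))[planted],
                      start = start(b)[planted] - 1L, end = end(b)[planted],
                      direction = direction,
                      effect = rep(config$dmrEffect, nplant),
                      stringsAsFactors = FALSE)
  list(fragments = GenomicRanges::GRangesList(frl), sampleSheet = sheet,
       truth = truth, tiling = tiling)
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Gene base means are lognormal; per-sample size factors are lognormal(0,
#' 0.2); counts are negative binomial with the configured dispersion.  The
#' first \code{nDeg} randomly chosen genes multiply the high-group mean by
#' \code{2^degLog2fc}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param geneIds optional gene identifiers (defaults to g0001...).
#' @return list with \code{counts} (genes x samples integer matrix),
#'   \code{sampleSheet} and \code{truth} (data.frame gene, log2fc).
#' @export
simulateCounts <- function(config, geneIds = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 37L)
  n_g <- config$nGenes
  if (is.null(geneIds)) geneIds <- sprintf("g%05d", seq_len(n_g))
  stopifnot(length(geneIds) == n_g)
  base <- stats::rlnorm(n_g, config$countMeanLog - config$countSdLog^2 / 2,
                        config$countSdLog)
  ids <- sample_ids(config$nHigh, config$nAverage)
  group <- rep(c("high", "average"), c(config$nHigh, config$nAverage))
  sf <- stats::rlnorm(length(ids), 0, 0.2)
  deg <- if (config$nDeg > 0) sample(n_g, config$nDeg) else integer()
  fc <- rep(1, n_g)
  fc[deg] <- 2^config$degLog2fc
  mu <- outer(base, sf)
  mu[, group == "high"] <- mu[, group == "high"] * fc
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$nbDispersion),
                   nrow = n_g, dimnames = list(geneIds, ids))
  sheet <- data.frame(sample_id = ids, subject_id = ids, group = group,
                      timepoint = "none", stringsAsFactors = FALSE)
  truth <- data.frame(gene = geneIds[deg],
                      log2fc = rep(config$degLog2fc, length(deg)),
                      stringsAsFactors = FALSE)
  list(counts = counts, sampleSheet = sheet, truth = truth)
}

#' Plant methylation-expression correlations into a count matrix
#'
#' For each (bin, gene, r) link, the gene's per-sample log2 mean is perturbed
#' by a scaled mixture of the bin's standardized z-scores and independent
#' noise so the expected Pearson correlation between bin z and log2 expression
#' equals approximately r (mildly attenuated by counting noise).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param z bins x samples z matrix (rownames = bin ids).
#' @param counts genes x samples count matrix to adjust.
#' @param links data.frame with columns \code{bin}, \code{gene}, \code{r}
#'   (|r| < 1).
#' @param tau log2-scale amplitude of the planted signal (default 1.5).
#' @return list with \code{counts} (adjusted) and \code{truth} (the links).
#' @export
linkMethExpr <- function(config, z, counts, links, tau = 1.5) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (any(abs(links$r) >= 1)) stop("link target |r| must be < 1")
  set.seed(config$seed + 53L)
  z <- get_z(z)
  shared <- intersect(colnames(z), colnames(counts))
  if (!length(shared)) stop("no shared samples between z and counts")
  for (i in seq_len(nrow(links))) {
    bin <- as.character(links$bin[i]); gene <- as.character(links$gene[i])
    if (!bin %in% rownames(z) || !gene %in% rownames(counts))
      stop("link ", i, " references unknown bin or gene")
    x <- z[bin, shared]
    if (anyNA(x) || stats::sd(x) == 0) {
      warning("bin ", bin, " has undefined z-scores; link skipped")
      next
    }
    xs <- (x - mean(x)) / stats::sd(x)
    sig <- links$r[i] * xs + sqrt(1 - links$r[i]^2) * stats::rnorm(length(xs))
    base <- exp(mean(log(counts[gene, shared] + 1)))
    mu <- base * 2^(tau * (sig - mean(sig)))
    counts[gene, shared] <- stats::rnbinom(length(mu), mu = mu, size = 1 / 0.02)
  }
  list(counts = counts, truth = links)
}

paired_sample_sheet <- function(config) {
  n <- config$pairedHigh + config$pairedAverage
  subj <- sprintf("S%02d", seq_len(n))
  group <- rep(c("high", "average"), c(config$pairedHigh, config$pairedAverage))
  data.frame(subject_id = rep(subj, each = 2),
             sample_id = paste0(rep(subj, each = 2), "_", c("D1", "D2")),
             timepoint = rep(c("D1", "D2"), n),
             group = rep(group, each = 2), stringsAsFactors = FALSE)
}

#' Simulate the paired two-timepoint subcohort
#'
#' Expression: per-subject gene baselines (lognormal subject effect shared by
#' both donations) with NB counts; planted age features shift the second
#' donation for every subject, and enhanced features receive an extra shift in
#' high-risk subjects only.  Methylation: per-subject-timepoint fragments with
#' the analogous z-calibrated bin shifts.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param what \code{"counts"}, \code{"fragments"}, or both.
#' @param tiling optional \linkS4class{BinTiling} for the fragment arm.
#' @return list with \code{design} and, per requested arm, \code{counts}
#'   (genes x samples), \code{fragments} (named \code{GRangesList}),
#'   \code{tiling}, and \code{truth} (lists of planted age and enhanced
#'   features/bins).
#' @export
simulatePaired <- function(config, what = c("counts", "fragments"),
                           tiling = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  what <- match.arg(what, several.ok = TRUE)
  design <- paired_sample_sheet(config)
  out <- list(design = design)
  subj <- unique(design$subject_id)
  grp <- stats::setNames(design$group[match(subj, design$subject_id)], subj)

  if ("counts" %in% what) {
    set.seed(config$seed + 71L)
    n_g <- config$nGenes
    geneIds <- sprintf("g%05d", seq_len(n_g))
    base <- stats::rlnorm(n_g, config$countMeanLog - config$countSdLog^2 / 2,
                          config$countSdLog)
    age <- sample(n_g, config$nAgeFeatures)
    age_sign <- sample(c(1, -1), config$nAgeFeatures, replace = TRUE)
    enh_idx <- seq_len(config$nEnhanced)
    enh <- age[enh_idx]
    shift_age <- rep(0, n_g); shift_age[age] <- age_sign * config$ageLog2fc
    shift_enh <- rep(0, n_g)
    shift_enh[enh] <- age_sign[enh_idx] * config$enhancedLog2fc
    counts <- matrix(0L, n_g, nrow(design),
                     dimnames = list(geneIds, design$sample_id))
    for (s in subj) {
      u <- 2^stats::rnorm(n_g, 0, config$subjectSdLog2)
      mu1 <- base * u
      extra <- if (grp[s] == "high") shift_enh else 0
      eps <- stats::rnorm(n_g, 0, config$changeSdLog2)
      mu2 <- mu1 * 2^(shift_age + extra + eps)
      counts[, paste0(s, "_D1")] <-
        stats::rnbinom(n_g, mu = mu1, size = 1 / config$nbDispersion)
      counts[, paste0(s, "_D2")] <-
        stats::rnbinom(n_g, mu = mu2, size = 1 / config$nbDispersion)
    }
    out$counts <- counts
    out$truth$age_genes <- data.frame(gene = geneIds[age],
                                      log2fc = age_sign * config$ageLog2fc,
                                      stringsAsFactors = FALSE)
    out$truth$enhanced_genes <- geneIds[enh]
  }

  if ("fragments" %in% what) {
    if (is.null(tiling))
      tiling <- buildTiling(sim_chrom_sizes(config), config$binWidth,
                            config$regionWidth, config$minBinsPerRegion)
    set.seed(config$seed + 89L)
    b <- bins(tiling)
    prof <- sim_lambda_profile(config, tiling)
    usable <- which(mcols(b)$region_usable)
    n_age <- min(config$nAgeBins, length(usable))
    age_bins <- sample(usable, n_age)
    age_sign <- sample(c(1, -1), n_age, replace = TRUE)
    enh_sel <- seq_len(min(config$nEnhancedBins, n_age))
    dlam <- prof$dlam_per_z[prof$grp[age_bins]]
    frl <- list()
    for (s in subj) {
      su <- 2^stats::rnorm(1, 0, config$sampleDepthSdLog)
      lam1 <- su * prof$lambda
      lam2 <- lam1
      shift_z <- age_sign * config$ageEffectZ
      if (grp[s] == "high")
        shift_z[enh_sel] <- shift_z[enh_sel] +
          sign(age_sign[enh_sel]) * config$enhancedEffectZ
      lam2[age_bins] <- pmax(lam2[age_bins] + su * shift_z * dlam, 0)
      frl[[paste0(s, "_D1")]] <- frag_sample(b, lam1, config$fragmentLengthMean,
                                             config$fragmentLengthSd)
      frl[[paste0(s, "_D2")]] <- frag_sample(b, lam2, config$fragmentLengthMean,
                                             config$fragmentLengthSd)
    }
    out$fragments <- GenomicRanges::GRangesList(frl)
    out$tiling <- tiling
    out$truth$age_bins <- data.frame(
      bin_id = mcols(b)$bin_id[age_bins],
      effect_z = age_sign * config$ageEffectZ,
      enhanced = seq_len(n_age) %in% enh_sel, stringsAsFactors = FALSE)
  }
  out
}
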
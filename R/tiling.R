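#' Build the fixed bin/region tiling
#'
#' Tiles every chromosome with non-overlapping bins of \code{binWidth} bp
#' (default 250) whose z-scores are later computed relative to enclosing
#' regions of \code{regionWidth} bp (default 25 kb).  A trailing bin shorter
#' than \code{binWidth} is dropped.  The last region of a chromosome may be
#' shorter than \code{regionWidth}; any region holding fewer than
#' \code{minBinsPerRegion} bins is flagged unusable and its bins are excluded
#' from z-scoring.
#'
#' @param chromSizes data.frame with columns \code{name} and \code{length}, or
#'   a named integer vector of chromosome lengths.
#' @param binWidth,regionWidth bin and region width in bp;
#'   \code{regionWidth} must be a multiple of \code{binWidth}.
#' @param minBinsPerRegion minimum bins for a region to be usable.
#' @return A \linkS4class{BinTiling}.
#' @examples
#' tl <- buildTiling(c(chr1 = 50000L), binWidth = 250, regionWidth = 25000)
#' length(bins(tl))  # 200
#' @export
buildTiling <- function(chromSizes, binWidth = 250L, regionWidth = 25000L,
                        minBinsPerRegion = 10L) {
  chromSizes <- as_chrom_sizes(chromSizes)
  binWidth <- as.integer(binWidth)
  regionWidth <- as.integer(regionWidth)
  minBinsPerRegion <- as.integer(minBinsPerRegion)
  if (binWidth < 1L) stop("binWidth must be >= 1")
  if (regionWidth %% binWidth != 0L)
    stop("regionWidth (", regionWidth, ") must be divisible by binWidth (",
         binWidth, ")")

  si <- Seqinfo(seqnames = chromSizes$name,
                seqlengths = chromSizes$length)
  bin_list <- vector("list", nrow(chromSizes))
  reg_list <- vector("list", nrow(chromSizes))
  region_offset <- 0L
  bin_offset <- 0L
  for (i in seq_len(nrow(chromSizes))) {
    L <- chromSizes$length[i]
    nm <- chromSizes$name[i]
    nbin <- L %/% binWidth
    nreg <- as.integer(ceiling(L / regionWidth))
    if (nbin > 0L) {
      starts <- (seq_len(nbin) - 1L) * binWidth + 1L
      rid_local <- (starts - 1L) %/% regionWidth
      b <- GRanges(nm, IRanges(starts, width = binWidth), seqinfo = si)
      mcols(b)$bin_id <- bin_offset + seq_len(nbin)
      mcols(b)$region_id <- region_offset + rid_local + 1L
      bin_list[[i]] <- b
    }
    if (nreg > 0L) {
      rstarts <- (seq_len(nreg) - 1L) * regionWidth + 1L
      rends <- pmin(rstarts + regionWidth - 1L, L)
      r <- GRanges(nm, IRanges(rstarts, rends), seqinfo = si)
      mcols(r)$region_id <- region_offset + seq_len(nreg)
      n_bins <- if (nbin > 0L)
        tabulate((starts - 1L) %/% regionWidth + 1L, nbins = nreg)
      else integer(nreg)
      mcols(r)$n_bins <- n_bins
      mcols(r)$usable <- n_bins >= minBinsPerRegion
      reg_list[[i]] <- r
    }
    region_offset <- region_offset + nreg
    bin_offset <- bin_offset + nbin
  }
  all_bins <- if (length(bin_list)) do.call(c, bin_list[!vapply(bin_list, is.null, TRUE)])
              else GRanges()
  all_regs <- if (length(reg_list)) do.call(c, reg_list[!vapply(reg_list, is.null, TRUE)])
              else GRanges()
  if (length(all_bins)) {
    usable <- mcols(all_regs)$usable[mcols(all_bins)$region_id]
    mcols(all_bins)$region_usable <- usable
  }
  new("BinTiling", bins = all_bins, regions = all_regs, binWidth = binWidth,
      regionWidth = regionWidth, minBinsPerRegion = minBinsPerRegion)
}

as_chrom_sizes <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("name", "length") %in% names(x)))
      stop("chromSizes data.frame needs columns 'name' and 'length'")
    out <- data.frame(name = as.character(x$name),
                      length = as.integer(x$length),
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(names(x))) stop("chromSizes vector must be named")
    out <- data.frame(name = names(x), length = as.integer(x),
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$name)) stop("chromosome names must be unique")
  if (any(is.na(out$length)) || any(out$length < 1L))
    stop("chromosome lengths must be positive integers")
  out
}

#' Annotate bins with genomic features
#'
#' Each bin is assigned exactly one feature label by positional overlap,
#' using the precedence promoter > UTR > coding > intron > intergenic.  The
#' promoter window is strand-aware: \code{promoterUpstream} bp upstream to
#' \code{promoterDownstream} bp downstream of the TSS.  Residual overlap with
#' a gene span (outside promoter, UTR and CDS) counts as intron.  All genes
#' contributing the winning label are listed, sorted by gene_id.
#'
#' @param tiling a \linkS4class{BinTiling}, or a \code{GRanges} of query bins.
#' @param geneModels a \linkS4class{GeneModels}.
#' @param promoterUpstream,promoterDownstream promoter window around the TSS
#'   in bp (defaults 2000/500).
#' @return \code{GRanges} of the bins with metadata columns \code{feature}
#'   (factor: promoter, UTR, coding, intron, intergenic) and
#'   \code{gene_names} (\code{CharacterList}, empty iff intergenic).
#' @export
annotateBins <- function(tiling, geneModels, promoterUpstream = 2000L,
                         promoterDownstream = 500L) {
  b <- if (is(tiling, "BinTiling")) bins(tiling) else tiling
  stopifnot(is(geneModels, "GeneModels"))
  g <- genes(geneModels)
  known <- seqlevels(g)
  if (length(b) && length(known)) {
    bad <- setdiff(unique(as.character(seqnames(b))), known)
    if (length(bad))
      stop("bins lie on chromosome(s) unknown to the gene models: ",
           paste(bad, collapse = ", "))
  }

  lvls <- c("promoter", "UTR", "coding", "intron", "intergenic")
  feature <- rep.int(NA_integer_, length(b))
  gene_names <- vector("list", length(b))

  prom <- promoters_of(geneModels, promoterUpstream, promoterDownstream)
  utr <- unlist_grl_tagged(geneModels@utr5, geneModels@utr3,
                           ids = mcols(g)$gene_id, names_ = mcols(g)$gene_name)
  cds <- unlist_grl_one(geneModels@cds, g)
  span <- g

  sets <- list(promoter = prom, UTR = utr, coding = cds, intron = span)
  for (k in seq_along(sets)) {
    s <- sets[[k]]
    if (!length(s)) next
    hits <- findOverlaps(b, s, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits)
    keep <- is.na(feature[qh])
    qh <- qh[keep]
    sh <- S4Vectors::subjectHits(hits)[keep]
    if (!length(qh)) next
    ids <- mcols(s)$gene_id[sh]
    nms <- mcols(s)$gene_name[sh]
    o <- order(qh, ids)
    qh <- qh[o]; nms <- nms[o]
    per_bin <- split(nms, qh)
    idx <- as.integer(names(per_bin))
    feature[idx] <- k
    gene_names[idx] <- lapply(per_bin, function(v) unique(as.character(v)))
  }
  feature[is.na(feature)] <- 5L
  gene_names[feature == 5L] <- list(character())
  out <- b
  mcols(out)$feature <- factor(lvls[feature], levels = lvls)
  mcols(out)$gene_names <- CharacterList(gene_names)
  out
}

promoters_of <- function(gm, up, down) {
  g <- genes(gm)
  if (!length(g)) return(g)
  p <- suppressWarnings(promoters(g, upstream = as.integer(up),
                                  downstream = as.integer(down)))
  p <- GenomicRanges::trim(p)
  start(p) <- pmax(start(p), 1L)
  p
}

unlist_grl_tagged <- function(grl1, grl2, ids, names_) {
  key <- stats::setNames(names_, ids)
  pieces <- list()
  for (grl in list(grl1, grl2)) {
    if (!length(grl)) next
    u <- unlist(grl, use.names = TRUE)
    if (!length(u)) next
    mcols(u)$gene_id <- names(u)
    mcols(u)$gene_name <- unname(key[names(u)])
    names(u) <- NULL
    pieces[[length(pieces) + 1L]] <- u
  }
  if (!length(pieces)) return(GRanges())
  do.call(c, pieces)
}

unlist_grl_one <- function(grl, g) {
  if (!length(grl)) return(GRanges())
  u <- unlist(grl, use.names = TRUE)
  if (!length(u)) return(GRanges())
  key <- stats::setNames(mcols(g)$gene_name, mcols(g)$gene_id)
  mcols(u)$gene_id <- names(u)
  mcols(u)$gene_name <- unname(key[names(u)])
  names(u) <- NULL
  u
}

#' Tabulate feature localization of differential bins
#'
#' For each direction (hyper/hypo) computes the percentage of bins in each of
#' the four genic feature classes (promoter, UTR, coding, intron); the genic
#' percentages sum to 100 within a direction.  Intergenic bins are tallied
#' separately (their percentage is of all bins in the direction).
#'
#' @param feature factor/character of per-bin feature labels.
#' @param direction factor/character of per-bin directions (e.g. hyper/hypo).
#' @return data.frame with columns \code{direction}, \code{feature}, \code{n},
#'   \code{percent}.  Empty input gives a zero-row frame.
#' @export
localizationSummary <- function(feature, direction) {
  if (length(feature) != length(direction))
    stop("feature and direction must have equal length")
  if (!length(feature))
    return(data.frame(direction = character(), feature = character(),
                      n = integer(), percent = numeric()))
  genic <- c("promoter", "UTR", "coding", "intron")
  feature <- as.character(feature)
  direction <- as.character(direction)
  out <- list()
  for (d in sort(unique(direction))) {
    f <- feature[direction == d]
    n_total <- length(f)
    n_genic <- sum(f %in% genic)
    for (cls in genic) {
      n <- sum(f == cls)
      out[[length(out) + 1L]] <- data.frame(
        direction = d, feature = cls, n = n,
        percent = if (n_genic > 0) 100 * n / n_genic else NA_real_)
    }
    n_int <- sum(f == "intergenic")
    out[[length(out) + 1L]] <- data.frame(
      direction = d, feature = "intergenic", n = n_int,
      percent = 100 * n_int / n_total)
  }
  do.call(rbind, out)
}
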
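#' Impute insert fragments from concordant read pairs
#'
#' One fragment per concordantly mapped pair, spanning from the leftmost mate
#' start to the rightmost mate end.  Pairs are discordant (and dropped) when
#' the mates map to different chromosomes, when strands are given and not
#' opposite, or when the implied insert exceeds \code{maxInsert}.
#'
#' @param pairs data.frame in BEDPE layout: \code{chrom1,start1,end1,chrom2,
#'   start2,end2} (0-based half-open starts, as read by \code{readBedpe});
#'   optional \code{strand1,strand2}.
#' @param maxInsert maximum allowed insert length in bp (default 2000).
#' @return list with \code{fragments} (\code{GRanges}, 1-based) and
#'   \code{n_discordant}.
#' @export
imputeInserts <- function(pairs, maxInsert = 2000L) {
  req <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  miss <- setdiff(req, names(pairs))
  if (length(miss))
    stop("pairs is missing required column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(pairs$start1) | is.na(pairs$end1) | is.na(pairs$start2) |
               is.na(pairs$end2) | pairs$start1 >= pairs$end1 |
               pairs$start2 >= pairs$end2)
  if (length(bad))
    stop("malformed read-pair record(s) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  fs <- pmin(pairs$start1, pairs$start2)
  fe <- pmax(pairs$end1, pairs$end2)
  concordant <- pairs$chrom1 == pairs$chrom2 & (fe - fs) <= maxInsert
  if (all(c("strand1", "strand2") %in% names(pairs))) {
    s1 <- as.character(pairs$strand1); s2 <- as.character(pairs$strand2)
    has_strand <- s1 %in% c("+", "-") & s2 %in% c("+", "-")
    concordant <- concordant & (!has_strand | s1 != s2)
  }
  frag <- GRanges(pairs$chrom1[concordant],
                  IRanges(fs[concordant] + 1L, fe[concordant]))
  list(fragments = frag, n_discordant = sum(!concordant))
}

#' Remove duplicate fragments
#'
#' Within one sample, fragments with identical (chrom, start, end) collapse to
#' a single fragment - the standard fragment-level deduplication for capture
#' libraries, where identical inserts are presumed PCR duplicates.
#'
#' @param fragments \code{GRanges} (one sample) or \code{GRangesList} (one
#'   element per sample).
#' @return Object of the same class with duplicates removed; the number of
#'   removed fragments is attached as attribute/metadata \code{n_duplicates}.
#' @export
deduplicateFragments <- function(fragments) {
  if (is(fragments, "GRangesList")) {
    out <- GenomicRanges::GRangesList(lapply(fragments, dedup_one))
    removed <- sum(lengths(fragments)) - sum(lengths(out))
    metadata(out)$n_duplicates <- removed
    return(out)
  }
  dedup_one(fragments)
}

dedup_one <- function(gr) {
  key <- paste(as.character(seqnames(gr)), start(gr), end(gr))
  keep <- !duplicated(key)
  out <- gr[keep]
  attr(out, "n_duplicates") <- sum(!keep)
  metadata(out)$n_duplicates <- sum(!keep)
  out
}

#' Per-bin deduplicated insert coverage
#'
#' The coverage of bin b in sample s is the mean per-base depth of sample s's
#' deduplicated fragments over b: (sum over fragments f of |f intersect b|)
#' divided by the bin width.  Fragments on chromosomes absent from the tiling
#' are skipped with a warning and counted.
#'
#' @param fragments named \code{GRangesList}, one element per sample (names are
#'   sample ids), or a single \code{GRanges} for a one-sample matrix.
#' @param tiling a \linkS4class{BinTiling}.
#' @return \code{RangedSummarizedExperiment} with assay \code{"coverage"}
#'   (bins x samples), \code{rowRanges} the tiling bins.  The tiling is kept
#'   in \code{metadata()$tiling}; skipped-fragment counts in
#'   \code{metadata()$n_skipped}.
#' @export
binCoverage <- function(fragments, tiling) {
  stopifnot(is(tiling, "BinTiling"))
  if (is(fragments, "GRanges"))
    fragments <- GenomicRanges::GRangesList(sample1 = fragments)
  if (is.null(names(fragments)))
    names(fragments) <- paste0("sample", seq_along(fragments))
  b <- bins(tiling)
  chroms <- seqlevels(b)
  sl <- seqlengths(b)
  bin_by_chrom <- split(seq_along(b), as.character(seqnames(b)))
  mat <- matrix(0, nrow = length(b), ncol = length(fragments),
                dimnames = list(bin_names(b), names(fragments)))
  n_skipped <- integer(length(fragments))
  for (j in seq_along(fragments)) {
    gr <- fragments[[j]]
    on_known <- as.character(seqnames(gr)) %in% chroms
    if (any(!on_known)) {
      warning(sum(!on_known), " fragment(s) of sample ", names(fragments)[j],
              " on unknown chromosome(s); skipped")
      n_skipped[j] <- sum(!on_known)
      gr <- gr[on_known]
    }
    gr <- GRanges(as.character(seqnames(gr)),
                  IRanges(pmax(start(gr), 1L),
                          pmin(end(gr), sl[as.character(seqnames(gr))])))
    cvg <- coverage(gr, width = as.list(sl))
    for (chr in names(bin_by_chrom)) {
      idx <- bin_by_chrom[[chr]]
      v <- Views(cvg[[chr]], start(b)[idx], end(b)[idx])
      mat[idx, j] <- viewMeans(v)
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(coverage = mat), rowRanges = b)
  metadata(se)$tiling <- tiling
  metadata(se)$n_skipped <- stats::setNames(n_skipped, names(fragments))
  se
}

bin_names <- function(b) {
  paste0(as.character(seqnames(b)), ":", start(b) - 1L, "-", end(b))
}
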
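#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<- Rle
#' @importFrom IRanges IRanges Views viewMeans CharacterList start<- end<-
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand start end width
#'   findOverlaps promoters granges coverage
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqinfo Seqinfo
NULL

#' Fixed-width bin/region tiling of a genome
#'
#' A \code{BinTiling} holds the non-overlapping fixed-width bins used to
#' quantify capture coverage, and the larger fixed regions relative to which
#' each bin's z-score is computed.  Bins tile each chromosome from position 1
#' in steps of \code{binWidth}; a trailing partial bin is dropped.  Regions
#' tile in steps of \code{regionWidth} (the last region of a chromosome may be
#' shorter) and a region is usable only when it contains at least
#' \code{minBinsPerRegion} bins, since the region standard deviation is
#' unstable in ragged windows.
#'
#' @slot bins \code{GRanges} of retained bins with metadata columns
#'   \code{bin_id} (integer, global), \code{region_id} (integer, global) and
#'   \code{region_usable} (logical).
#' @slot regions \code{GRanges} of regions with \code{region_id},
#'   \code{n_bins} and \code{usable}.
#' @slot binWidth,regionWidth,minBinsPerRegion integer tiling parameters.
#' @export
setClass("BinTiling",
  representation(bins = "GRanges", regions = "GRanges",
                 binWidth = "integer", regionWidth = "integer",
                 minBinsPerRegion = "integer"))

setValidity("BinTiling", function(object) {
  msg <- character()
  b <- object@bins
  if (length(b)) {
    if (!all(width(b) == object@binWidth))
      msg <- c(msg, "all bins must have width binWidth")
    if (!all((start(b) - 1L) %% object@binWidth == 0L))
      msg <- c(msg, "bin starts must be aligned to binWidth")
    if (is.null(mcols(b)$region_id) || anyNA(mcols(b)$region_id))
      msg <- c(msg, "every bin must carry a region_id")
  }
  if (object@regionWidth %% object@binWidth != 0L)
    msg <- c(msg, "regionWidth must be divisible by binWidth")
  if (length(msg)) msg else TRUE
})

#' Gene models for feature annotation
#'
#' Gene-level (transcript-union) models: one span per gene plus exon, CDS and
#' UTR intervals, as read from a GTF or built by the simulator.  The TSS is
#' the strand-aware 5' end of the gene span.
#'
#' @slot genes \code{GRanges} of gene spans with \code{gene_id},
#'   \code{gene_name} and \code{tss} metadata columns.
#' @slot exons,cds,utr5,utr3 \code{GRangesList} named by \code{gene_id}.
#' @export
setClass("GeneModels",
  representation(genes = "GRanges", exons = "GRangesList",
                 cds = "GRangesList", utr5 = "GRangesList",
                 utr3 = "GRangesList"))

setValidity("GeneModels", function(object) {
  msg <- character()
  g <- object@genes
  ids <- mcols(g)$gene_id
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "genes must carry unique gene_id")
  if (!all(as.character(strand(g)) %in% c("+", "-")))
    msg <- c(msg, "gene strand must be + or -")
  tss <- mcols(g)$tss
  if (!is.null(tss) && length(g)) {
    plus <- as.character(strand(g)) == "+"
    ok <- ifelse(plus, tss == start(g), tss == end(g))
    if (!all(ok)) msg <- c(msg, "tss must be the strand-aware 5' end of the span")
  }
  for (nm in c("exons", "cds", "utr5", "utr3")) {
    grl <- slot(object, nm)
    if (length(grl) && !all(names(grl) %in% ids))
      msg <- c(msg, sprintf("%s names must be gene_ids", nm))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn BinTiling number of bins
#' @param x,object a \code{BinTiling}
#' @export
setMethod("length", "BinTiling", function(x) length(x@bins))

setMethod("show", "BinTiling", function(object) {
  cat(sprintf("BinTiling: %d bins of %d bp in %d regions of %d bp (%d usable)\n",
              length(object@bins), object@binWidth, length(object@regions),
              object@regionWidth, sum(mcols(object@regions)$usable)))
})

setMethod("show", "GeneModels", function(object) {
  cat(sprintf("GeneModels: %d genes on %d sequence(s)\n",
              length(object@genes), length(seqlevels(object@genes))))
})

#' @rdname BinTiling-accessors
#' @param x a \code{BinTiling} or \code{GeneModels}
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))

#' @rdname BinTiling-accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname BinTiling-accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname BinTiling-accessors
#' @export
setGeneric("regionWidth", function(x) standardGeneric("regionWidth"))

#' @rdname BinTiling-accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' Accessors for tiling and gene-model objects
#'
#' @name BinTiling-accessors
#' @return \code{bins}/\code{regions} return \code{GRanges};
#'   \code{binWidth}/\code{regionWidth} integers; \code{genes} the gene-span
#'   \code{GRanges} of a \code{GeneModels}.
NULL

#' @rdname BinTiling-accessors
#' @export
setMethod("bins", "BinTiling", function(x) x@bins)

#' @rdname BinTiling-accessors
#' @export
setMethod("regions", "BinTiling", function(x) x@regions)

#' @rdname BinTiling-accessors
#' @export
setMethod("binWidth", "BinTiling", function(x) x@binWidth)

#' @rdname BinTiling-accessors
#' @export
setMethod("regionWidth", "BinTiling", function(x) x@regionWidth)

#' @rdname BinTiling-accessors
#' @export
setMethod("genes", "GeneModels", function(x) x@genes)

#' Construct a GeneModels object
#'
#' @param genes \code{GRanges} of gene spans with \code{gene_id},
#'   \code{gene_name} (defaults to the id) and \code{tss} (defaults to the
#'   strand-aware span 5' end) metadata columns.
#' @param exons,cds,utr5,utr3 \code{GRangesList} named by gene_id; missing
#'   genes get empty elements.
#' @return A \linkS4class{GeneModels}.
#' @export
geneModels <- function(genes, exons = NULL, cds = NULL, utr5 = NULL,
                       utr3 = NULL) {
  if (is.null(mcols(genes)$gene_id)) stop("genes must carry gene_id")
  if (is.null(mcols(genes)$gene_name))
    mcols(genes)$gene_name <- mcols(genes)$gene_id
  plus <- as.character(strand(genes)) == "+"
  tss_default <- ifelse(plus, start(genes), end(genes))
  if (is.null(mcols(genes)$tss)) {
    mcols(genes)$tss <- tss_default
  } else {
    na <- is.na(mcols(genes)$tss)
    mcols(genes)$tss[na] <- tss_default[na]
  }
  ids <- mcols(genes)$gene_id
  pad <- function(grl) {
    if (is.null(grl)) grl <- GenomicRanges::GRangesList()
    if (!length(ids)) return(GenomicRanges::GRangesList())
    miss <- setdiff(ids, names(grl))
    if (length(miss)) {
      empty <- stats::setNames(
        lapply(miss, function(i) GRanges(seqinfo = seqinfo(genes))), miss)
      grl <- c(GenomicRanges::GRangesList(as.list(grl)),
               GenomicRanges::GRangesList(empty))
    }
    grl[ids]
  }
  new("GeneModels", genes = genes, exons = pad(exons), cds = pad(cds),
      utr5 = pad(utr5), utr3 = pad(utr3))
}
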
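pkg_version <- function() as.character(utils::packageVersion("methRisk"))

# FNV-1a hash of a deparsed object; gives outputs a stable provenance stamp
# without external digest dependencies.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

provenance_header <- function(params = list()) {
  c(sprintf("# methRisk v%s", pkg_version()),
    sprintf("# params_hash=%s", config_hash(params)),
    if (length(params))
      sprintf("# params: %s",
              paste(names(params), unlist(lapply(params, format)),
                    sep = "=", collapse = " ")))
}

#' Assign the risk group from a lifetime risk score
#'
#' High risk at or above the 20\% lifetime-risk threshold, average below.
#'
#' @param score numeric vector of lifetime risk percentages (>= 0).
#' @return character vector of \code{"high"}/\code{"average"}.
#' @examples assignRiskGroup(c(19.9, 20, 35))
#' @export
assignRiskGroup <- function(score) {
  if (any(is.na(score)) || any(score < 0))
    stop("risk scores must be non-negative and non-missing")
  ifelse(score >= 20, "high", "average")
}

#' Read a two-column chromosome sizes file
#'
#' @param path TSV with columns name, length (no header).
#' @return data.frame with \code{name} and \code{length}.
#' @export
readChromSizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("name", "length"),
                          colClasses = c("character", "integer"))
  as_chrom_sizes(df)
}

#' @rdname readChromSizes
#' @param chromSizes data.frame with \code{name}, \code{length}.
#' @export
writeChromSizes <- function(chromSizes, path) {
  utils::write.table(as_chrom_sizes(chromSizes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Requires \code{sample_id}; \code{subject_id} defaults to the sample id,
#' \code{timepoint} to "none".  When \code{group} is absent it is derived from
#' \code{risk_score} via \code{\link{assignRiskGroup}}.
#'
#' @param path TSV with a header line.
#' @return data.frame.
#' @export
readSampleSheet <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (!"sample_id" %in% names(df))
    stop("sample sheet is missing required column: sample_id")
  if (anyDuplicated(df$sample_id)) stop("sample_id values must be unique")
  if (is.null(df$subject_id)) df$subject_id <- df$sample_id
  if (is.null(df$timepoint)) df$timepoint <- "none"
  if (is.null(df$group)) {
    if (is.null(df$risk_score))
      stop("sample sheet needs either a 'group' or a 'risk_score' column")
    df$group <- assignRiskGroup(df$risk_score)
  }
  df
}

#' @rdname readSampleSheet
#' @param sheet sample sheet data.frame.
#' @export
writeSampleSheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write fragment BED files
#'
#' Fragments are stored as BED3 (0-based half-open); \code{GRanges} in memory
#' (1-based closed).
#'
#' @param path BED file path.
#' @return \code{GRanges}.
#' @export
readFragmentsBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("fragment BED needs at least 3 columns: ", path)
  bad <- which(is.na(df[[2]]) | is.na(df[[3]]) | df[[2]] >= df[[3]])
  if (length(bad))
    stop("malformed BED line(s) in ", path, ": ",
         paste(utils::head(bad, 5), collapse = ", "))
  GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]))
}

#' @rdname readFragmentsBed
#' @param fragments \code{GRanges} of fragments.
#' @export
writeFragmentsBed <- function(fragments, path) {
  df <- data.frame(chrom = as.character(seqnames(fragments)),
                   start = start(fragments) - 1L, end = end(fragments))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE file of aligned read pairs
#'
#' Expects at least the six coordinate columns
#' (chrom1,start1,end1,chrom2,start2,end2); name/score/strand1/strand2 are
#' kept when present.  Malformed lines are reported with their line numbers.
#'
#' @param path BEDPE file path.
#' @return data.frame ready for \code{\link{imputeInserts}}.
#' @export
readBedpe <- function(path) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE, fill = TRUE),
    error = function(e) stop("cannot parse BEDPE ", path, ": ",
                             conditionMessage(e)))
  if (ncol(df) < 6) stop("BEDPE needs at least 6 columns: ", path)
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score", "strand1", "strand2")
  names(df)[seq_len(min(ncol(df), length(cols)))] <-
    cols[seq_len(min(ncol(df), length(cols)))]
  num <- c("start1", "end1", "start2", "end2")
  bad <- which(Reduce(`|`, lapply(df[num], function(x) is.na(suppressWarnings(as.integer(x))))))
  if (length(bad))
    stop("malformed BEDPE line(s) in ", path, ": ",
         paste(utils::head(bad, 5), collapse = ", "))
  for (cn in num) df[[cn]] <- as.integer(df[[cn]])
  df
}

#' Read gene models from a GTF file
#'
#' Accepts feature rows \code{gene}, \code{exon}, \code{CDS},
#' \code{five_prime_utr}/\code{three_prime_utr} (or \code{UTR}, split by
#' position relative to the CDS).  GTF coordinates (1-based inclusive) match
#' the internal \code{GRanges} convention.  Gene spans default to the union
#' of a gene's exons when no \code{gene} row is present.
#'
#' @param path GTF file path.
#' @param chromSizes optional chromosome sizes to pin the seqinfo.
#' @return A \linkS4class{GeneModels}.
#' @export
readGeneModels <- function(path, chromSizes = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (!is.null(chromSizes)) {
    cs <- as_chrom_sizes(chromSizes)
    GenomeInfoDb::seqlevels(gr) <- cs$name
    seqlengths(gr) <- cs$length
  }
  type <- as.character(mcols(gr)$type)
  gid <- as.character(mcols(gr)$gene_id)
  gname <- if (!is.null(mcols(gr)$gene_name)) as.character(mcols(gr)$gene_name)
           else gid
  if (is.null(gid)) stop("GTF lacks gene_id attributes")

  take <- function(t) {
    sel <- type %in% t
    S4Vectors::split(granges(gr[sel]), gid[sel])
  }
  exons <- take("exon")
  cds <- take("CDS")
  utr5 <- take("five_prime_utr")
  utr3 <- take("three_prime_utr")

  is_gene <- type == "gene"
  if (any(is_gene)) {
    genes_gr <- granges(gr[is_gene])
    ids <- gid[is_gene]; nms <- gname[is_gene]
  } else {
    rng <- unlist(range(exons))
    genes_gr <- rng
    ids <- names(rng)
    nms <- gname[match(ids, gid)]
  }
  o <- order(as.factor(seqnames(genes_gr)), start(genes_gr))
  genes_gr <- genes_gr[o]; ids <- ids[o]; nms <- nms[o]
  mcols(genes_gr)$gene_id <- ids
  mcols(genes_gr)$gene_name <- nms
  plus <- as.character(strand(genes_gr)) == "+"
  mcols(genes_gr)$tss <- ifelse(plus, start(genes_gr), end(genes_gr))

  # plain UTR rows: 5' when strictly 5' of the gene's CDS span, else 3'
  if ("UTR" %in% type) {
    sel <- type == "UTR"
    u <- S4Vectors::split(granges(gr[sel]), gid[sel])
    for (id in names(u)) {
      if (!id %in% names(cds) || !length(cds[[id]])) next
      cspan <- range(cds[[id]])
      g_plus <- as.character(strand(genes_gr))[match(id, ids)] == "+"
      before <- end(u[[id]]) < min(start(cspan))
      five <- if (g_plus) before else !before & start(u[[id]]) > max(end(cspan))
      add5 <- u[[id]][five]; add3 <- u[[id]][!five]
      if (length(add5))
        utr5[[id]] <- if (id %in% names(utr5)) sort(c(utr5[[id]], add5)) else add5
      if (length(add3))
        utr3[[id]] <- if (id %in% names(utr3)) sort(c(utr3[[id]], add3)) else add3
    }
  }
  pad <- function(grl) {
    miss <- setdiff(ids, names(grl))
    if (length(miss)) {
      empty <- stats::setNames(
        lapply(miss, function(i) GRanges(seqinfo = seqinfo(genes_gr))), miss)
      grl <- c(GenomicRanges::GRangesList(as.list(grl)),
               GenomicRanges::GRangesList(empty))
    }
    grl[ids]
  }
  new("GeneModels", genes = genes_gr, exons = pad(exons), cds = pad(cds),
      utr5 = pad(utr5), utr3 = pad(utr3))
}

#' Write gene models to GTF
#'
#' Emits gene, exon, CDS, five_prime_utr and three_prime_utr rows.
#'
#' @param geneModels a \linkS4class{GeneModels}.
#' @param path output file.
#' @export
writeGeneModelsGTF <- function(geneModels, path) {
  g <- genes(geneModels)
  rows <- list()
  add <- function(gr, type, gene_ids, gene_names) {
    if (!length(gr)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      seqname = as.character(seqnames(gr)), source = "methRisk",
      feature = type, start = start(gr), end = end(gr), score = ".",
      strand = as.character(strand(gr)), frame = ".",
      attribute = sprintf('gene_id "%s"; gene_name "%s";',
                          gene_ids, gene_names), stringsAsFactors = FALSE)
  }
  add(g, "gene", mcols(g)$gene_id, mcols(g)$gene_name)
  key <- stats::setNames(mcols(g)$gene_name, mcols(g)$gene_id)
  slot_types <- c(exons = "exon", cds = "CDS", utr5 = "five_prime_utr",
                  utr3 = "three_prime_utr")
  for (nm in names(slot_types)) {
    grl <- slot(geneModels, nm)
    if (!length(grl)) next
    u <- unlist(grl, use.names = TRUE)
    if (!length(u)) next
    add(u, slot_types[[nm]], names(u), unname(key[names(u)]))
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$seqname, df$start, df$feature), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene count matrix
#'
#' @param path TSV: first column gene id, remaining columns samples.
#' @return genes x samples integer matrix.
#' @export
readCountsMatrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, comment.char = "#")
  as.matrix(df)
}

#' @rdname readCountsMatrix
#' @param counts genes x samples matrix.
#' @export
writeCountsMatrix <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read the differential-methylation table
#'
#' TSV in BED-style coordinates (0-based start) with columns chrom, start,
#' end, delta_z, z_ratio, t_stat, p_value, q_value, direction, feature,
#' gene_names; a provenance comment header records the package version and a
#' parameter hash.
#'
#' @param dmrs \code{GRanges} from \code{\link{callDmrs}}.
#' @param path output TSV.
#' @param params list echoed into the provenance header.
#' @export
writeDmrTable <- function(dmrs, path, params = list()) {
  m <- mcols(dmrs)
  df <- data.frame(chrom = as.character(seqnames(dmrs)),
                   start = start(dmrs) - 1L, end = end(dmrs),
                   delta_z = m$delta_z, z_ratio = m$z_ratio,
                   t_stat = m$t_stat, p_value = m$p_value,
                   q_value = m$q_value, direction = as.character(m$direction),
                   feature = if (!is.null(m$feature)) as.character(m$feature)
                             else NA_character_,
                   gene_names = if (!is.null(m$gene_names))
                     vapply(m$gene_names, paste, "", collapse = ",")
                   else NA_character_, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDmrTable
#' @return \code{readDmrTable}: \code{GRanges} equivalent to the written one.
#' @export
readDmrTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  mcols(gr)$delta_z <- df$delta_z
  mcols(gr)$z_ratio <- df$z_ratio
  mcols(gr)$t_stat <- df$t_stat
  mcols(gr)$p_value <- df$p_value
  mcols(gr)$q_value <- df$q_value
  mcols(gr)$direction <- factor(df$direction, levels = c("hyper", "hypo"))
  if (!all(is.na(df$feature)))
    mcols(gr)$feature <- factor(df$feature,
      levels = c("promoter", "UTR", "coding", "intron", "intergenic"))
  if (!all(is.na(df$gene_names)))
    mcols(gr)$gene_names <- CharacterList(strsplit(ifelse(
      is.na(df$gene_names) | df$gene_names == "", "", df$gene_names), ","))
  gr
}

#' Write the differential-expression table
#'
#' @param records data.frame from \code{\link{deTTest}}/\code{\link{callDegs}}.
#' @param path output TSV (provenance comment header included).
#' @param params list echoed into the provenance header.
#' @export
writeDegTable <- function(records, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(params), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a signature file
#'
#' TSV of gene symbols (first column; optional header) or a BED of loci.
#'
#' @param path input file.
#' @param name signature name (defaults to the file name).
#' @param format \code{"genes"} or \code{"bed"}.
#' @return a \code{\link{signatureSet}}.
#' @export
readSignature <- function(path, name = basename(path),
                          format = c("genes", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    return(signatureSet(name, readFragmentsBed(path)))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  members <- as.character(df[[1]])
  if (length(members) && members[1] %in% c("gene", "gene_name", "symbol"))
    members <- members[-1]
  signatureSet(name, members)
}

#' Read a candidate-gene annotation table
#'
#' Expected columns: gene, log2fc, fdr, alteration_pct,
#' tumor_normal_significant, amplification_significant, oncoscore.  The
#' packaged transcription of the published differential-expression table is at
#' \code{system.file("extdata", "table1_degs.tsv", package = "methRisk")}.
#'
#' @param path TSV with header.
#' @return data.frame.
#' @export
readCandidateTable <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Write ground truth as JSON
#'
#' @param truth list (e.g. from the simulators).
#' @param path output JSON path.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
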
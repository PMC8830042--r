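#' Pearson correlation with two-sided p-value
#'
#' Standard Pearson r over complete pairs with the t-transform p-value:
#' t = r * sqrt((n-2) / (1-r^2)) on n-2 degrees of freedom, two-sided.
#' Requires at least three complete pairs; zero variance in either argument
#' gives r = NA.
#'
#' @param x,y numeric vectors (paired per sample; NA pairs dropped).
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
pearsonWithP <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(list(r = NA_real_, p = NA_real_, n = n))
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sqrt(sum(xc^2)); sy <- sqrt(sum(yc^2))
  if (sx == 0 || sy == 0) return(list(r = NA_real_, p = NA_real_, n = n))
  r <- sum(xc * yc) / (sx * sy)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(list(r = r, p = 0, n = n))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2), n = n)
}

classify_correlation <- function(r, p, alpha = 0.05) {
  ifelse(is.na(r) | is.na(p), NA_character_,
         ifelse(p < alpha & r > 0, "direct",
                ifelse(p < alpha & r < 0, "inverse", "none")))
}

#' Correlate bin methylation with gene expression
#'
#' One record per (gene, bin) link: Pearson correlation between the bin's
#' per-sample z-scores and the gene's per-sample log2(normalized count +
#' pseudocount), over samples present in both matrices.  Classification:
#' direct when r > 0 and p < alpha, inverse when r < 0 and p < alpha, else
#' none; records with undefined r (e.g. constant expression) have class NA.
#'
#' @param links data.frame with columns \code{gene} and \code{bin} (bin ids
#'   matching \code{rownames(z)}), e.g. derived from
#'   \code{\link{annotateBins}}'s gene lists.
#' @param z bins x samples z matrix (rownames = bin ids).
#' @param expr genes x samples normalized count matrix.
#' @param pseudocount added before the log (default 0.5).
#' @param alpha significance level for classification (default 0.05).
#' @return data.frame: \code{gene}, \code{bin}, \code{r}, \code{p}, \code{n},
#'   \code{class}.
#' @export
correlatePairs <- function(links, z, expr, pseudocount = 0.5, alpha = 0.05) {
  z <- get_z(z)
  expr <- as.matrix(expr)
  shared <- intersect(colnames(z), colnames(expr))
  if (!length(shared))
    stop("no shared samples between methylation and expression matrices")
  res <- lapply(seq_len(nrow(links)), function(i) {
    g <- as.character(links$gene[i]); b <- as.character(links$bin[i])
    if (!g %in% rownames(expr) || !b %in% rownames(z))
      return(data.frame(gene = g, bin = b, r = NA_real_, p = NA_real_,
                        n = 0L, stringsAsFactors = FALSE))
    pw <- pearsonWithP(z[b, shared], log2(expr[g, shared] + pseudocount))
    data.frame(gene = g, bin = b, r = pw$r, p = pw$p, n = pw$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$class <- classify_correlation(out$r, out$p, alpha)
  out
}

#' A named signature set
#'
#' @param name label of the signature.
#' @param members character vector of gene symbols, or a \code{GRanges} of
#'   loci, defining the signature; must be non-empty.
#' @return list with \code{name}, \code{members}, \code{size}.
#' @export
signatureSet <- function(name, members) {
  if (is(members, "GRanges")) {
    size <- length(members)
  } else {
    members <- unique(as.character(members))
    size <- length(members)
  }
  if (size == 0L) stop("signature '", name, "' is empty")
  list(name = name, members = members, size = size)
}

#' Overlap of a query set with a signature
#'
#' Gene mode: intersection of gene-symbol sets.  Locus mode (signature members
#' given as \code{GRanges}): a signature locus scores a hit when it falls
#' inside any query bin (positional overlap at bin resolution).  The percent
#' is the intersection count over the signature size, rounded to the nearest
#' integer.
#'
#' @param query character vector of gene symbols, or \code{GRanges} of bins.
#' @param signature a \code{\link{signatureSet}}.
#' @return list with \code{count} and \code{percent}.
#' @export
signatureOverlap <- function(query, signature) {
  if (is.null(signature$size) || signature$size == 0L)
    stop("signature must be a non-empty signatureSet")
  if (is(signature$members, "GRanges")) {
    if (!is(query, "GRanges"))
      stop("locus-mode signatures require a GRanges query")
    count <- sum(IRanges::overlapsAny(signature$members, query,
                                      ignore.strand = TRUE))
  } else {
    count <- length(intersect(unique(as.character(query)), signature$members))
  }
  list(count = count, percent = round(100 * count / signature$size))
}

#' Prioritize candidate genes from a cancer-annotation table
#'
#' Keeps genes with alteration frequency above \code{alterationMin} percent,
#' Oncoscore above \code{oncoscoreMin}, and significant tumor-vs-normal
#' overexpression and amplification flags.  Genes with missing fields are
#' skipped with a warning.
#'
#' @param annotations data.frame with columns \code{gene},
#'   \code{alteration_pct}, \code{tumor_normal_significant},
#'   \code{amplification_significant}, \code{oncoscore}.
#' @param alterationMin alteration percentage floor (default 10, exclusive).
#' @param oncoscoreMin Oncoscore floor (default 50, exclusive).
#' @return character vector of prioritized gene symbols.
#' @export
prioritizeCandidates <- function(annotations, alterationMin = 10,
                                 oncoscoreMin = 50) {
  if (!nrow(annotations)) return(character())
  req <- c("gene", "alteration_pct", "tumor_normal_significant",
           "amplification_significant", "oncoscore")
  miss <- setdiff(req, names(annotations))
  if (length(miss))
    stop("annotations missing column(s): ", paste(miss, collapse = ", "))
  complete <- stats::complete.cases(annotations[, req])
  if (any(!complete))
    warning(sum(!complete), " gene(s) with missing annotation fields skipped")
  a <- annotations[complete, , drop = FALSE]
  keep <- a$alteration_pct > alterationMin & a$oncoscore > oncoscoreMin &
    as.logical(a$tumor_normal_significant) &
    as.logical(a$amplification_significant)
  as.character(a$gene[keep])
}
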
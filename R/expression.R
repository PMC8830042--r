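#' Median-of-ratios size factors
#'
#' For sample s, the size factor is the median over genes of
#' count(g,s) / geometric-mean(count(g,.)), using only genes with nonzero
#' counts in every sample.  When no such gene exists, falls back (with a
#' warning) to per-sample medians of the nonzero ratios.  Normalized counts
#' are raw counts divided by the sample's factor.
#'
#' @param counts genes x samples matrix of non-negative integer counts.
#' @return named numeric vector of positive per-sample size factors.
#' @export
computeSizeFactors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    sub <- counts[all_pos, , drop = FALSE]
    log_gm <- rowMeans(log(sub))
    sf <- apply(sub / exp(log_gm), 2, stats::median)
  } else {
    warning("no gene has nonzero counts in every sample; ",
            "using median of nonzero ratios")
    log_gm <- apply(counts, 1, function(r) {
      pos <- r > 0
      if (!any(pos)) NA_real_ else mean(log(r[pos]))
    })
    ratio <- counts / exp(log_gm)
    sf <- apply(ratio, 2, function(cl) stats::median(cl[cl > 0], na.rm = TRUE))
  }
  if (any(!is.finite(sf) | sf <= 0))
    stop("could not derive positive size factors; at least one gene must be ",
         "expressed in every sample")
  sf
}

#' Normalize counts by size factors
#'
#' @param counts genes x samples count matrix.
#' @param sizeFactors per-sample factors from \code{\link{computeSizeFactors}};
#'   computed when missing.
#' @return matrix of normalized counts (counts / size factor).
#' @export
normalizeCounts <- function(counts, sizeFactors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
  sweep(counts, 2, sizeFactors, "/")
}

#' Two-group differential expression by Welch t-test
#'
#' The t-test arm of the expression analysis: per gene, a Welch two-sample
#' t-test of log2(normalized count + pseudocount) between the high-risk and
#' average-risk replicates, with BH correction across all tested genes.  The
#' reported log2 fold change is log2((mean_high + c) / (mean_avg + c)) on the
#' normalized scale.  Genes with all-zero counts in both groups are excluded
#' from testing.
#'
#' @param counts genes x samples matrix of raw counts (normalized internally),
#'   or already-normalized counts with \code{normalized = TRUE}.
#' @param groups named character vector: sample id -> "high"/"average".
#' @param pseudocount stabilizing constant c (default 0.5).
#' @param normalized set TRUE when \code{counts} is already normalized.
#' @return data.frame with one row per tested gene: \code{gene},
#'   \code{mean_norm_high}, \code{mean_norm_avg}, \code{log2fc},
#'   \code{t_stat}, \code{p_value}, \code{q_value}.
#' @export
deTTest <- function(counts, groups, pseudocount = 0.5, normalized = FALSE) {
  counts <- as.matrix(counts)
  norm <- if (normalized) counts else normalizeCounts(counts)
  gi <- group_index(groups, colnames(norm))
  if (length(gi$high) < 2L || length(gi$average) < 2L)
    stop("at least two samples per group are required")
  all_zero <- rowSums(norm) == 0
  if (any(all_zero))
    message(sum(all_zero), " gene(s) with zero counts in all samples excluded")
  norm <- norm[!all_zero, , drop = FALSE]
  lx <- log2(norm + pseudocount)
  w <- row_welch(lx[, gi$high, drop = FALSE], lx[, gi$average, drop = FALSE])
  mh <- rowMeans(norm[, gi$high, drop = FALSE])
  ma <- rowMeans(norm[, gi$average, drop = FALSE])
  data.frame(gene = rownames(norm),
             mean_norm_high = mh, mean_norm_avg = ma,
             log2fc = log2((mh + pseudocount) / (ma + pseudocount)),
             t_stat = w$t, p_value = w$p, q_value = bhFdr(w$p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tiered filtering of differential expression records
#'
#' Mirrors the nested reporting of the study: tier 1 keeps genes significant
#' at the FDR ceiling (q < fdrMax); tier 2 additionally requires t-test
#' p <= pMax; tier 3 additionally requires |log2fc| >= log2(fcMin).  When a
#' record has no p-value (e.g. a published table carrying only FDR), tier 2
#' equals tier 1.  \code{passes_fc2} flags |log2fc| >= log2(fcMin) AND
#' q < fdrMax.
#'
#' @param records data.frame with columns \code{gene}, \code{log2fc},
#'   \code{q_value} and optionally \code{p_value}.
#' @param fcMin fold-change floor (default 2).
#' @param fdrMax FDR ceiling (default 0.05).
#' @param pMax t-test p ceiling (default 0.05).
#' @return list with \code{records} (input plus logical \code{tier1},
#'   \code{tier2}, \code{tier3}, \code{passes_fc2}) and \code{counts}
#'   (data.frame: tier, up, down, total).
#' @export
callDegs <- function(records, fcMin = 2, fdrMax = 0.05, pMax = 0.05) {
  req <- c("gene", "log2fc", "q_value")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  lfc_min <- log2(fcMin)
  q <- records$q_value
  p <- if ("p_value" %in% names(records)) records$p_value else rep(NA_real_, nrow(records))
  lfc <- records$log2fc
  tier1 <- !is.na(q) & q < fdrMax
  tier2 <- tier1 & (is.na(p) | p <= pMax)
  tier3 <- tier2 & !is.na(lfc) & abs(lfc) >= lfc_min
  records$tier1 <- tier1
  records$tier2 <- tier2
  records$tier3 <- tier3
  records$passes_fc2 <- tier1 & !is.na(lfc) & abs(lfc) >= lfc_min
  cnt <- function(sel) c(up = sum(sel & lfc > 0, na.rm = TRUE),
                         down = sum(sel & lfc < 0, na.rm = TRUE),
                         total = sum(sel))
  counts <- rbind(tier1 = cnt(tier1), tier2 = cnt(tier2), tier3 = cnt(tier3))
  counts <- data.frame(tier = rownames(counts), counts, row.names = NULL)
  list(records = records, counts = counts)
}

#' Comparative-CT (ddCt) relative quantification
#'
#' Per sample: dCt = target Ct - reference Ct; ddCt = dCt - mean dCt of the
#' calibrator group; relative quantity RQ = 2^(-ddCt).  Samples missing a Ct
#' are skipped with a warning.
#'
#' @param measurements data.frame with columns \code{sample},
#'   \code{target_ct}, \code{reference_ct} and either a logical
#'   \code{calibrator} column or a \code{group} column.
#' @param calibratorGroup when \code{group} is used, the group serving as
#'   calibrator.
#' @return data.frame with \code{sample}, \code{dct}, \code{ddct}, \code{rq}.
#' @export
ddctQuantify <- function(measurements, calibratorGroup = NULL) {
  req <- c("sample", "target_ct", "reference_ct")
  miss <- setdiff(req, names(measurements))
  if (length(miss))
    stop("measurements missing column(s): ", paste(miss, collapse = ", "))
  ok <- !is.na(measurements$target_ct) & !is.na(measurements$reference_ct)
  if (any(!ok)) {
    warning(sum(!ok), " sample(s) missing a Ct value; skipped")
    measurements <- measurements[ok, , drop = FALSE]
  }
  ct <- measurements$target_ct
  if (any(ct <= 0 | ct >= 45) ||
      any(measurements$reference_ct <= 0 | measurements$reference_ct >= 45))
    stop("Ct values must lie in (0, 45)")
  if (!is.null(measurements$calibrator)) {
    cal <- as.logical(measurements$calibrator)
  } else {
    if (is.null(calibratorGroup) || is.null(measurements$group))
      stop("either a 'calibrator' column or group + calibratorGroup is required")
    cal <- measurements$group == calibratorGroup
  }
  if (!any(cal)) stop("calibrator group is empty")
  dct <- measurements$target_ct - measurements$reference_ct
  ddct <- dct - mean(dct[cal])
  data.frame(sample = measurements$sample, dct = dct, ddct = ddct,
             rq = 2^(-ddct), row.names = NULL, stringsAsFactors = FALSE)
}
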
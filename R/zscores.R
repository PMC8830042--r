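#' Region-relative bin z-scores
#'
#' For each sample, a bin's coverage is expressed as the number of standard
#' deviations from the mean coverage of the region containing it:
#' z(b,s) = (c(b,s) - mu(r,s)) / sigma(r,s), with mu and sigma the mean and
#' sample standard deviation (denominator n-1) over the region's retained
#' bins.  This is an implicit within-sample depth normalization: multiplying a
#' sample's coverage by any positive constant leaves its z-scores unchanged.
#' Regions with zero standard deviation, and regions flagged unusable by the
#' tiling, yield NA.
#'
#' @param x \code{RangedSummarizedExperiment} from \code{\link{binCoverage}},
#'   or a bins x samples coverage matrix (then \code{tiling} is required).
#' @param tiling a \linkS4class{BinTiling}; taken from \code{metadata(x)} when
#'   missing.
#' @return For a SummarizedExperiment input, the same object with an added
#'   assay \code{"z"}; for a matrix input, the z matrix.
#' @export
regionZScores <- function(x, tiling = NULL) {
  if (is(x, "SummarizedExperiment")) {
    if (is.null(tiling)) tiling <- metadata(x)$tiling
    cov <- SummarizedExperiment::assay(x, "coverage")
  } else cov <- as.matrix(x)
  if (is.null(tiling)) stop("a BinTiling is required")
  b <- bins(tiling)
  if (nrow(cov) != length(b))
    stop("coverage rows do not match the tiling bins (tiling contract violated)")
  rid <- mcols(b)$region_id
  grp <- match(rid, unique(rid))          # compact region index
  n <- tabulate(grp)
  mu <- rowsum(cov, grp, reorder = FALSE) / n
  dev <- cov - mu[grp, , drop = FALSE]
  ss <- rowsum(dev^2, grp, reorder = FALSE)
  sd_ <- sqrt(ss / pmax(n - 1L, 1L))
  sd_[n < 2L, ] <- NA_real_
  sd_[sd_ == 0] <- NA_real_
  z <- dev / sd_[grp, , drop = FALSE]
  z[!mcols(b)$region_usable, ] <- NA_real_
  dimnames(z) <- dimnames(cov)
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assays(x)$z <- z
    return(x)
  }
  z
}

group_index <- function(groups, samples) {
  if (is.null(names(groups)))
    stop("groups must be a named vector (names = sample ids)")
  g <- as.character(groups)
  names(g) <- names(groups)
  if (!all(samples %in% names(g)))
    stop("groups missing for sample(s): ",
         paste(setdiff(samples, names(g)), collapse = ", "))
  g <- g[samples]
  bad <- setdiff(unique(g), c("high", "average"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected 'high'/'average')")
  list(high = which(g == "high"), average = which(g == "average"))
}

#' Group difference of mean z-scores (delta-Z)
#'
#' delta-Z = mean z over high-risk samples minus mean z over average-risk
#' samples, per bin.  Positive values mean hypermethylation in the high-risk
#' group.  Bins with fewer than two non-NA samples in either group yield NA.
#'
#' @param z bins x samples z matrix (or SummarizedExperiment with a "z" assay).
#' @param groups named character vector mapping sample id to
#'   \code{"high"}/\code{"average"}.
#' @return numeric vector of per-bin delta-Z.
#' @export
deltaZ <- function(z, groups) {
  z <- get_z(z)
  gi <- group_index(groups, colnames(z))
  zh <- z[, gi$high, drop = FALSE]
  za <- z[, gi$average, drop = FALSE]
  nh <- rowSums(!is.na(zh)); na <- rowSums(!is.na(za))
  dz <- rowMeans(zh, na.rm = TRUE) - rowMeans(za, na.rm = TRUE)
  dz[nh < 2L | na < 2L] <- NA_real_
  dz
}

#' Group ratio of mean z-scores (Z-ratio)
#'
#' Guarded ratio mean(high z) / mean(average z); NA when either group has
#' fewer than two non-NA samples or when the denominator's magnitude does not
#' exceed \code{epsilon}.  Computed for reporting alongside delta-Z; the
#' selection filters operate on delta-Z only.
#'
#' @inheritParams deltaZ
#' @param epsilon guard on the denominator magnitude (default 0.1).
#' @return numeric vector of per-bin ratios.
#' @export
zRatio <- function(z, groups, epsilon = 0.1) {
  z <- get_z(z)
  gi <- group_index(groups, colnames(z))
  zh <- z[, gi$high, drop = FALSE]
  za <- z[, gi$average, drop = FALSE]
  nh <- rowSums(!is.na(zh)); na <- rowSums(!is.na(za))
  mh <- rowMeans(zh, na.rm = TRUE); ma <- rowMeans(za, na.rm = TRUE)
  r <- mh / ma
  r[nh < 2L | na < 2L | abs(ma) <= epsilon] <- NA_real_
  r
}

get_z <- function(z) {
  if (is(z, "SummarizedExperiment"))
    z <- SummarizedExperiment::assay(z, "z")
  as.matrix(z)
}

# Vectorized Welch two-sample t-test over matrix rows.
# Degenerate rows (zero variance in both groups): p = 1 when means equal,
# p = 0 otherwise.  Rows with < 2 non-NA values in either group give NA.
row_welch <- function(x1, x2) {
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- rowSums((x1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1L, 1L)
  v2 <- rowSums((x2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1L, 1L)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- v1 == 0 & v2 == 0
  p[degen & m1 == m2] <- 1
  p[degen & m1 != m2] <- 0
  t[degen & m1 == m2] <- 0
  t[degen & m1 != m2] <- sign(m1 - m2)[degen & m1 != m2] * Inf
  bad <- n1 < 2L | n2 < 2L
  t[bad] <- NA_real_; p[bad] <- NA_real_
  list(t = t, p = p, df = df, mean1 = m1, mean2 = m2)
}

#' Per-bin Welch t-test on z-scores
#'
#' Welch (unequal-variance) two-sample t-test of the per-sample z-scores of
#' the high-risk group against the average-risk group, per bin, two-sided.
#' Bins where more than \code{naMaxFrac} of either group's samples are NA are
#' dropped from testing (NA), as are bins with fewer than two non-NA samples
#' in either group.  When both groups have zero variance: p = 1 if the means
#' are equal, p = 0 otherwise.
#'
#' @inheritParams deltaZ
#' @param naMaxFrac maximum tolerated NA fraction per group (default 0.2).
#' @return data.frame with columns \code{t_stat} and \code{p_value}.
#' @export
binTTest <- function(z, groups, naMaxFrac = 0.2) {
  z <- get_z(z)
  gi <- group_index(groups, colnames(z))
  zh <- z[, gi$high, drop = FALSE]
  za <- z[, gi$average, drop = FALSE]
  drop <- rowMeans(is.na(zh)) > naMaxFrac | rowMeans(is.na(za)) > naMaxFrac
  w <- row_welch(zh, za)
  w$t[drop] <- NA_real_; w$p[drop] <- NA_real_
  data.frame(t_stat = w$t, p_value = w$p, row.names = rownames(z))
}

#' Benjamini-Hochberg step-up q-values
#'
#' q_i = min over j with p_j >= p_i of (p_j * m / rank_j), capped at 1.
#' NAs are excluded from m and propagate to the output.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same length and order as \code{p}.
#' @export
bhFdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(q)
  o <- order(p[ok])
  adj <- p[ok][o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  q[ok[o]] <- pmin(adj, 1)
  q
}

#' Thresholds for calling differentially methylated bins
#'
#' Defaults follow the selection rule: |delta-Z| >= 1 (hyper when positive,
#' hypo when negative), q < 0.05 (5\% FDR) and t-test p <= 0.05.
#'
#' @param deltaZMin minimum |delta-Z| (default 1).
#' @param fdrMax FDR ceiling (default 0.05).
#' @param pMax t-test p ceiling (default 0.05).
#' @return list of validated thresholds.
#' @export
dmrThresholds <- function(deltaZMin = 1, fdrMax = 0.05, pMax = 0.05) {
  stopifnot(deltaZMin > 0, fdrMax > 0, fdrMax <= 1, pMax > 0, pMax <= 1)
  list(deltaZMin = deltaZMin, fdrMax = fdrMax, pMax = pMax)
}

#' Call differentially methylated bins
#'
#' Retains bins satisfying all three thresholds: |delta-Z| >= deltaZMin AND
#' q < fdrMax AND p <= pMax.  Direction is hyper when delta-Z > 0, hypo
#' otherwise.  Records are sorted by q, then decreasing |delta-Z|.
#'
#' @param tiling a \linkS4class{BinTiling}, or the bin \code{GRanges} aligned
#'   with the statistics vectors (e.g. the output of
#'   \code{\link{annotateBins}}, whose feature/gene annotation is then carried
#'   through).
#' @param delta_z,p,q per-bin statistics, aligned with the bins.
#' @param thresholds from \code{\link{dmrThresholds}}.
#' @param z_ratio optional per-bin Z-ratio, carried through for reporting.
#' @param t_stat optional per-bin t statistic.
#' @return \code{GRanges} of retained bins with metadata columns
#'   \code{delta_z}, \code{z_ratio}, \code{t_stat}, \code{p_value},
#'   \code{q_value}, \code{direction} and, when the input bins are annotated,
#'   \code{feature} and \code{gene_names}.
#' @export
callDmrs <- function(tiling, delta_z, p, q, thresholds = dmrThresholds(),
                     z_ratio = NULL, t_stat = NULL) {
  b <- if (is(tiling, "BinTiling")) bins(tiling) else tiling
  n <- length(b)
  if (length(delta_z) != n || length(p) != n || length(q) != n)
    stop("statistics are not aligned with the bins")
  if (!is.null(z_ratio) && length(z_ratio) != n)
    stop("z_ratio is not aligned with the bins")
  keep <- which(!is.na(delta_z) & !is.na(p) & !is.na(q) &
                abs(delta_z) >= thresholds$deltaZMin &
                q < thresholds$fdrMax & p <= thresholds$pMax)
  out <- b[keep]
  mcols(out)$delta_z <- delta_z[keep]
  mcols(out)$z_ratio <- if (is.null(z_ratio)) NA_real_ else z_ratio[keep]
  mcols(out)$t_stat <- if (is.null(t_stat)) NA_real_ else t_stat[keep]
  mcols(out)$p_value <- p[keep]
  mcols(out)$q_value <- q[keep]
  mcols(out)$direction <- factor(ifelse(delta_z[keep] > 0, "hyper", "hypo"),
                                 levels = c("hyper", "hypo"))
  o <- order(mcols(out)$q_value, -abs(mcols(out)$delta_z))
  out[o]
}

#' Fraction of hypermethylated calls
#'
#' Fraction of called bins whose direction is hyper, with an exact binomial
#' sign test against an even hyper/hypo split.
#'
#' @param dmrs output of \code{\link{callDmrs}} (or any vector/factor of
#'   directions).
#' @return list with \code{fraction}, \code{n_hyper}, \code{n} and
#'   \code{p_value}; fraction NA on empty input.
#' @export
hyperFraction <- function(dmrs) {
  dir <- if (is(dmrs, "GRanges")) mcols(dmrs)$direction else dmrs
  dir <- as.character(dir)
  n <- length(dir)
  if (!n) return(list(fraction = NA_real_, n_hyper = 0L, n = 0L,
                      p_value = NA_real_))
  k <- sum(dir == "hyper")
  list(fraction = k / n, n_hyper = k, n = n,
       p_value = stats::binom.test(k, n, p = 0.5)$p.value)
}
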
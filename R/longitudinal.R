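#' Validate a paired two-timepoint design
#'
#' @param design data.frame with columns \code{subject_id}, \code{sample_id},
#'   \code{timepoint} (\code{"D1"}/\code{"D2"}) and \code{group}
#'   (\code{"high"}/\code{"average"}); each subject must have exactly one
#'   sample per timepoint.
#' @return the design, with subjects lacking a timepoint dropped (message).
#' @export
pairedDesign <- function(design) {
  req <- c("subject_id", "sample_id", "timepoint", "group")
  miss <- setdiff(req, names(design))
  if (length(miss))
    stop("design missing column(s): ", paste(miss, collapse = ", "))
  if (!all(design$timepoint %in% c("D1", "D2")))
    stop("timepoint must be 'D1' or 'D2'")
  if (!all(design$group %in% c("high", "average")))
    stop("group must be 'high' or 'average'")
  tab <- table(design$subject_id, design$timepoint)
  complete <- rownames(tab)[tab[, "D1"] == 1L & tab[, "D2"] == 1L]
  dropped <- setdiff(unique(design$subject_id), complete)
  if (length(dropped))
    message(length(dropped), " subject(s) without both timepoints excluded: ",
            paste(dropped, collapse = ", "))
  design[design$subject_id %in% complete, , drop = FALSE]
}

#' Per-subject two-timepoint change and paired test
#'
#' For expression, the per-subject change is log2((D2 + c) / (D1 + c)) on
#' normalized counts; for methylation it is z(D2) - z(D1).  Each feature's
#' changes are tested against zero with a one-sample t-test (two-sided) and
#' BH-corrected across features.  All-zero change vectors give p = 1 (zero
#' variance at zero mean); zero variance at nonzero mean gives p = 0.
#'
#' @param x features x samples matrix holding both timepoints (columns named
#'   by sample id).
#' @param design validated design from \code{\link{pairedDesign}}.
#' @param type \code{"expression"} (log-ratio) or \code{"methylation"}
#'   (z difference).
#' @param pseudocount for the expression log-ratio (default 0.5).
#' @return list with \code{changes} (features x subjects matrix) and
#'   \code{stats} (data.frame: feature, mean_change, t_stat, p_value,
#'   q_value).
#' @export
pairedChange <- function(x, design, type = c("expression", "methylation"),
                         pseudocount = 0.5) {
  type <- match.arg(type)
  design <- pairedDesign(design)
  x <- as.matrix(x)
  d1 <- design[design$timepoint == "D1", ]
  d2 <- design[design$timepoint == "D2", ]
  d2 <- d2[match(d1$subject_id, d2$subject_id), ]
  have <- d1$sample_id %in% colnames(x) & d2$sample_id %in% colnames(x)
  if (any(!have))
    message(sum(!have), " subject(s) with missing sample column(s) excluded")
  d1 <- d1[have, ]; d2 <- d2[have, ]
  if (nrow(d1) < 3L) stop("at least three complete subjects are required")
  m1 <- x[, d1$sample_id, drop = FALSE]
  m2 <- x[, d2$sample_id, drop = FALSE]
  changes <- switch(type,
    expression = log2(m2 + pseudocount) - log2(m1 + pseudocount),
    methylation = m2 - m1)
  colnames(changes) <- d1$subject_id
  n <- rowSums(!is.na(changes))
  mu <- rowMeans(changes, na.rm = TRUE)
  v <- rowSums((changes - mu)^2, na.rm = TRUE) / pmax(n - 1L, 1L)
  t <- mu / sqrt(v / n)
  p <- 2 * stats::pt(-abs(t), df = n - 1L)
  degen <- v == 0
  p[degen & mu == 0] <- 1
  p[degen & mu != 0] <- 0
  t[degen & mu == 0] <- 0
  bad <- n < 3L
  t[bad] <- NA_real_; p[bad] <- NA_real_
  stats_ <- data.frame(feature = rownames(x), mean_change = mu, t_stat = t,
                       p_value = p, q_value = bhFdr(p), row.names = NULL,
                       stringsAsFactors = FALSE)
  list(changes = changes, stats = stats_)
}

#' Test for risk-group enhancement of per-subject changes
#'
#' Welch two-sample t-test of the per-subject changes between the high-risk
#' and average-risk groups, per feature.  A feature is flagged enhanced when
#' the between-group p-value is below \code{alpha} AND the magnitude of the
#' high-group mean change exceeds that of the average group.
#'
#' @param changes features x subjects matrix from \code{\link{pairedChange}}.
#' @param design validated design (one row per subject suffices; the
#'   subject -> group map is taken from it).
#' @param alpha significance level (default 0.05).
#' @return data.frame: \code{feature}, \code{mean_high}, \code{mean_average},
#'   \code{p_value}, \code{q_value} (BH across features; the enhanced flag
#'   itself uses the nominal p, matching per-gene reporting), \code{enhanced}.
#'   Groups below three subjects give NA.
#' @export
enhancementTest <- function(changes, design, alpha = 0.05) {
  grp <- unique(design[, c("subject_id", "group")])
  g <- stats::setNames(as.character(grp$group), as.character(grp$subject_id))
  subj <- colnames(changes)
  if (!all(subj %in% names(g)))
    stop("design missing group for subject(s): ",
         paste(setdiff(subj, names(g)), collapse = ", "))
  hi <- subj[g[subj] == "high"]
  av <- subj[g[subj] == "average"]
  if (length(hi) < 3L || length(av) < 3L) {
    return(data.frame(feature = rownames(changes), mean_high = NA_real_,
                      mean_average = NA_real_, p_value = NA_real_,
                      q_value = NA_real_, enhanced = NA,
                      stringsAsFactors = FALSE))
  }
  w <- row_welch(changes[, hi, drop = FALSE], changes[, av, drop = FALSE])
  enhanced <- !is.na(w$p) & w$p < alpha & abs(w$mean1) > abs(w$mean2)
  data.frame(feature = rownames(changes), mean_high = w$mean1,
             mean_average = w$mean2, p_value = w$p, q_value = bhFdr(w$p),
             enhanced = enhanced, row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlap of age-related methylation genes with an epigenetic-clock list
#'
#' Thin wrapper over \code{\link{signatureOverlap}} for age-associated
#' methylation signatures (e.g. published epigenetic-clock loci).
#'
#' @param ageGenes character vector of genes linked to age-related
#'   differentially methylated bins (or \code{GRanges} for locus mode).
#' @param clock a \code{\link{signatureSet}}.
#' @return list with \code{count} and \code{percent}.
#' @export
clockOverlap <- function(ageGenes, clock) signatureOverlap(ageGenes, clock)
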
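test_that("median-of-ratios size factors behave like a scaling estimator", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("A", "B")))
  sf <- computeSizeFactors(m)
  expect_equal(sf["B"] / sf["A"], 2, ignore_attr = TRUE)

  ident <- cbind(A = c(5, 9, 14), B = c(5, 9, 14))
  expect_equal(unname(diff(computeSizeFactors(ident))), 0)

  # hand-computed 3-gene x 2-sample case
  w <- matrix(c(4, 9, 25, 1, 4, 100), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("A", "B")))
  gm <- exp(rowMeans(log(w)))
  expect_equal(computeSizeFactors(w),
               apply(w / gm, 2, stats::median))

  # agreement with the reference median-of-ratios implementation
  set.seed(21)
  cm <- matrix(rnbinom(200 * 6, mu = 50, size = 5), 200, 6,
               dimnames = list(NULL, paste0("s", 1:6)))
  cm <- sweep(cm, 2, c(1, 2, 0.5, 1, 1.5, 0.8), "*")
  # (reference takes the median on the log scale, so agreement is to the
  # geometric-vs-arithmetic midpoint difference at even gene counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(cm)
  expect_equal(unname(computeSizeFactors(cm)), unname(ref), tolerance = 1e-3)

  # fallback when every gene has a zero somewhere
  z <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_warning(sfz <- computeSizeFactors(z), "nonzero")
  expect_true(all(sfz > 0))

  # normalization idempotence
  norm <- normalizeCounts(cm)
  expect_equal(unname(computeSizeFactors(norm)), rep(1, 6), tolerance = 0.05)
})

test_that("t-test differential expression recovers planted fold changes", {
  # identical groups: fc 0, p 1 by the degenerate convention
  m <- matrix(rep(c(10, 30, 50), 4), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("h1", "h2", "a1", "a2")))
  grp <- stats::setNames(rep(c("high", "average"), each = 2), colnames(m))
  de0 <- deTTest(m, grp, normalized = TRUE)
  expect_equal(de0$log2fc, rep(0, 3))
  expect_equal(de0$p_value, rep(1, 3))

  # exact 4x difference: log2fc = 2 up to the pseudocount
  m4 <- cbind(h1 = c(400, 80), h2 = c(400, 80),
              a1 = c(100, 20), a2 = c(100, 20))
  rownames(m4) <- c("g1", "g2")
  de4 <- deTTest(m4, grp, normalized = TRUE)
  expect_equal(de4$log2fc, c(2, 2), tolerance = 0.02)

  # all-zero genes are excluded with a message
  mz <- rbind(m4, g3 = 0)
  expect_message(dez <- deTTest(mz, grp, normalized = TRUE), "excluded")
  expect_equal(nrow(dez), 2L)

  # NB simulation, 20 vs 20, planted log2fc 1.5 recovered within 0.3
  cfg <- simulationConfig(seed = 5, nHigh = 20, nAverage = 20,
                          nGenes = 400, nDeg = 40, degLog2fc = 1.5)
  sim <- simulateCounts(cfg)
  g <- stats::setNames(sim$sampleSheet$group, sim$sampleSheet$sample_id)
  de <- deTTest(sim$counts, g)
  est <- de$log2fc[match(sim$truth$gene, de$gene)]
  expect_equal(mean(est), 1.5, tolerance = 0.3)
  expect_true(all(abs(est - 1.5) < 1))
})

test_that("tiered DEG filtering mirrors the nested reporting and is order-invariant", {
  rec <- data.frame(
    gene = paste0("G", 1:5),
    log2fc = c(1.2, 0.9, -1.4, 2.0, 1.1),
    p_value = c(0.004, 0.01, 0.02, 0.2, 0.01),
    q_value = c(0.005, 0.01, 0.03, 0.04, 0.2))
  out <- callDegs(rec)
  r <- out$records
  # the strong up-regulated pattern: tier3 despite moderate fold change
  expect_true(r$tier3[r$gene == "G1"])
  # fold change below 2: tier2 only
  expect_true(r$tier2[r$gene == "G2"] && !r$tier3[r$gene == "G2"])
  # down-regulated gene passes
  expect_true(r$tier3[r$gene == "G3"])
  # fails the p <= 0.05 cut: tier1 only
  expect_true(r$tier1[r$gene == "G4"] && !r$tier2[r$gene == "G4"])
  # fails FDR: no tier
  expect_false(r$tier1[r$gene == "G5"])
  expect_equal(out$counts$total, c(4L, 3L, 2L))
  # passes_fc2 is |lfc| >= 1 AND q < 0.05 (independent of p)
  expect_equal(r$passes_fc2, c(TRUE, FALSE, TRUE, TRUE, FALSE))

  shuf <- callDegs(rec[sample(5), ])
  expect_equal(shuf$counts, out$counts)
})

test_that("comparative-CT quantification follows RQ = 2^-ddCt", {
  meas <- data.frame(sample = c("c1", "c2", "t1"),
                     target_ct = c(30, 32, 28),
                     reference_ct = c(24, 24, 23),
                     group = c("ctl", "ctl", "trt"))
  rq <- ddctQuantify(meas, calibratorGroup = "ctl")
  # calibrator mean dCt = 7; sample at dCt 5 -> RQ 4
  expect_equal(rq$rq[rq$sample == "t1"], 4)
  # a calibrator sample at the calibrator mean has RQ 1
  meas2 <- rbind(meas, data.frame(sample = "c3", target_ct = 31,
                                  reference_ct = 24, group = "ctl"))
  rq2 <- ddctQuantify(meas2, calibratorGroup = "ctl")
  expect_equal(rq2$rq[rq2$sample == "c3"], 1)
  # RQ strictly decreasing in target Ct, all else fixed
  grid <- data.frame(sample = paste0("s", 1:5),
                     target_ct = seq(26, 34, 2), reference_ct = 24,
                     calibrator = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(all(diff(ddctQuantify(grid)$rq) < 0))
  # missing reference Ct: skipped with a warning
  miss <- meas
  miss$reference_ct[2] <- NA
  expect_warning(rqm <- ddctQuantify(miss, calibratorGroup = "ctl"), "skip")
  expect_equal(nrow(rqm), 2L)
})
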
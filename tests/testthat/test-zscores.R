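test_that("region z-scores match hand computation and center to zero", {
  tl <- buildTiling(c(chr1 = 1000L), binWidth = 250, regionWidth = 1000,
                    minBinsPerRegion = 4)
  cov <- matrix(c(2, 4, 6, 8), ncol = 1, dimnames = list(NULL, "s1"))
  z <- regionZScores(cov, tl)
  sd_ <- sqrt(sum((c(2, 4, 6, 8) - 5)^2) / 3)   # 2.5819889...
  expect_equal(unname(z[4, 1]), 3 / sd_, tolerance = 1e-9)
  expect_equal(unname(z[4, 1]), 1.161895, tolerance = 1e-6)
  expect_equal(sum(z[, 1]), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z[, 1]), 1, tolerance = 1e-9)

  # constant region -> sigma = 0 -> NA
  zc <- regionZScores(matrix(5, 4, 2), tl)
  expect_true(all(is.na(zc)))

  # unusable regions yield NA
  tl2 <- buildTiling(c(chr1 = 1000L), binWidth = 250, regionWidth = 1000,
                     minBinsPerRegion = 10)
  expect_true(all(is.na(regionZScores(cov, tl2))))
})

test_that("z-scores are invariant to per-sample scaling and regional shifts", {
  set.seed(3)
  tl <- buildTiling(c(chr1 = 20000L), binWidth = 250, regionWidth = 5000,
                    minBinsPerRegion = 10)
  cov <- matrix(rgamma(80 * 4, 5, 1), 80, 4,
                dimnames = list(NULL, paste0("s", 1:4)))
  z0 <- regionZScores(cov, tl)
  # capture-depth normalization is implicit: scale one sample by 7.3
  cov_k <- cov; cov_k[, 2] <- cov_k[, 2] * 7.3
  expect_equal(regionZScores(cov_k, tl)[, 2], z0[, 2], tolerance = 1e-12)
  # adding a constant to all bins of one region of one sample
  rid <- mcols(bins(tl))$region_id
  cov_s <- cov; cov_s[rid == 2, 3] <- cov_s[rid == 2, 3] + 4.2
  expect_equal(regionZScores(cov_s, tl)[, 3], z0[, 3], tolerance = 1e-12)
  # per-region per-sample sums are zero
  for (r in unique(rid))
    expect_equal(colSums(z0[rid == r, ]), rep(0, 4), tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("delta-Z and Z-ratio follow their definitions and guards", {
  z <- rbind(c(1, 1, 0, 0),
             c(0.5, 0.5, 0.5, 0.5),
             c(2, 2, 1, 1),
             c(1, 3, 0.05, 0.05))
  colnames(z) <- c("h1", "h2", "a1", "a2")
  grp <- c(h1 = "high", h2 = "high", a1 = "average", a2 = "average")
  expect_equal(deltaZ(z, grp), c(1, 0, 1, 1.95))
  r <- zRatio(z, grp)
  expect_equal(r[3], 2)           # 2.0 / 1.0
  expect_true(is.na(r[4]))        # denominator 0.05 under epsilon 0.1
  expect_equal(zRatio(z, grp, epsilon = 0.01)[4], 2 / 0.05)

  # sign convention: positive delta-Z = hypermethylated in high risk
  expect_gt(deltaZ(z, grp)[1], 0)
  zneg <- -z
  expect_lt(deltaZ(zneg, grp)[1], 0)

  # fewer than 2 non-NA per group -> NA
  z[1, 1] <- NA
  expect_true(is.na(deltaZ(z, grp)[1]))
  expect_error(deltaZ(z, c(h1 = "hi", h2 = "high", a1 = "average",
                           a2 = "average")), "unknown group")
})

test_that("per-bin Welch test agrees with stats::t.test and handles degeneracy", {
  set.seed(9)
  z <- matrix(rnorm(60 * 9), 60, 9)
  colnames(z) <- c(paste0("h", 1:4), paste0("a", 1:5))
  grp <- stats::setNames(rep(c("high", "average"), c(4, 5)), colnames(z))
  got <- binTTest(z, grp)
  for (i in seq_len(nrow(z))) {
    ref <- stats::t.test(z[i, 1:4], z[i, 5:9])
    expect_equal(got$t_stat[i], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value[i], ref$p.value, tolerance = 1e-12)
  }
  # t sign matches delta-Z sign
  dz <- deltaZ(z, grp)
  expect_true(all(sign(got$t_stat) == sign(dz)))

  # identical groups -> p = 1; distinct constant groups -> p = 0
  zc <- rbind(rep(1, 9), rep(c(2, 0), c(4, 5)))
  colnames(zc) <- colnames(z)
  gotc <- binTTest(zc, grp)
  expect_equal(gotc$p_value, c(1, 0))

  # strongly separated groups are significant
  zs <- matrix(c(3, 3.1, 2.9, 3, 0, 0.1, -0.1, 0, 0.05), 1)
  colnames(zs) <- colnames(z)
  expect_lt(binTTest(zs, grp)$p_value, 0.01)

  # NA-heavy bins are dropped from testing
  zna <- z
  zna[1, 1:2] <- NA
  expect_true(is.na(binTTest(zna, grp, naMaxFrac = 0.2)$p_value[1]))
})

test_that("BH step-up matches the naive definition and stats::p.adjust", {
  expect_equal(bhFdr(0.03), 0.03)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(13)
  for (i in 1:25) {
    m <- sample(1:200, 1)
    p <- round(runif(m), sample(1:3, 1))   # induce ties
    if (i %% 5 == 0) p[sample(m, min(m, 3))] <- NA
    q <- bhFdr(p)
    expect_equal(q, naive_bh(p))
    expect_equal(q[!is.na(p)], stats::p.adjust(p[!is.na(p)], "BH"))
  }
})

test_that("DMR calling applies all three thresholds and sorts by strength", {
  tl <- buildTiling(c(chr1 = 1250L), binWidth = 250, regionWidth = 1250,
                    minBinsPerRegion = 5)
  dz <- c(1.5, 0.8, -1.4, 1.2, 1.0)
  p  <- c(0.01, 0.001, 0.01, 0.2, 0.04)
  q  <- c(0.01, 0.001, 2e-17, 0.01, 0.04)
  dmrs <- callDmrs(tl, dz, p, q)
  # bin 1 retained hyper; bin 2 fails |dZ| >= 1 despite tiny q; bin 3
  # retained hypo (the strongly negative case); bin 4 fails p; bin 5 retained
  expect_equal(length(dmrs), 3L)
  expect_equal(as.character(mcols(dmrs)$direction), c("hypo", "hyper", "hyper"))
  expect_equal(mcols(dmrs)$delta_z, c(-1.4, 1.5, 1.0))
  # sorted by q then |dZ| descending
  expect_true(!is.unsorted(mcols(dmrs)$q_value))

  expect_error(callDmrs(tl, dz[1:3], p, q), "aligned")
})

test_that("hyper fraction and its sign test match exact binomial results", {
  expect_equal(hyperFraction(factor(rep("hyper", 5)))$fraction, 1)
  hf <- hyperFraction(c("hyper", "hypo"))
  expect_equal(hf$fraction, 0.5)
  expect_equal(hf$p_value, 1)
  hf2 <- hyperFraction(rep(c("hyper", "hypo"), c(990, 10)))
  expect_equal(hf2$fraction, 0.99)
  expect_equal(hf2$p_value, stats::binom.test(990, 1000, 0.5)$p.value)
  expect_lt(hf2$p_value, 1e-3)
  expect_true(is.na(hyperFraction(character())$fraction))
})
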
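test_that("kinship matches a hand-computed VanRaden normalization", {
  # 3 strains x 4 markers, spreadsheet-style computation
  calls <- rbind(s1 = c(0L, 1L, 1L, 0L),
                 s2 = c(0L, 1L, 0L, 1L),
                 s3 = c(1L, 0L, 1L, 1L))
  mm <- data.frame(marker_id = sprintf("I_%d", 1:4), chromosome = "I",
                   position_bp = 1:4 * 100L, genetic_pos_cM = 1:4)
  colnames(calls) <- mm$marker_id
  g <- GenotypeMatrix(calls, mm)
  p <- colMeans(calls)                      # (1/3, 2/3, 2/3, 2/3)
  W <- 2 * sweep(calls, 2, p)               # centered -1/+1 codes
  K_hand <- W %*% t(W) / (2 * sum(p * (1 - p)))
  K <- computeKinship(g)
  expect_equal(unname(K), unname(K_hand), tolerance = 1e-12)
  expect_true(isSymmetric(K))
  # clones: off-diagonal equals the diagonal
  calls2 <- rbind(a = c(0L, 1L, 0L, 1L), b = c(0L, 1L, 0L, 1L),
                  c = c(1L, 0L, 1L, 0L))
  colnames(calls2) <- mm$marker_id
  K2 <- computeKinship(GenotypeMatrix(calls2, mm))
  expect_equal(K2["a", "b"], K2["a", "a"], tolerance = 1e-12)
  # inbred diagonal averages ~ 1 + f = 2; label swap leaves K unchanged
  mm3 <- tinyMap(100, chroms = c("I", "II"))
  set.seed(21)
  w <- simulateWildPanel(40, mm3, 1, 0, seed = 22)
  Kw <- computeKinship(w)
  expect_lt(abs(mean(diag(Kw)) - 2), 0.2)
  wflip <- GenotypeMatrix(1L - genotypeCalls(w), markerMap(w))
  expect_equal(computeKinship(wflip), Kw, tolerance = 1e-12)
  # independently drawn strains decorrelate as markers grow (the
  # within-sample centering adds a small -2/n offset, so use a panel
  # large enough for it to be negligible)
  mm4 <- tinyMap(5000, chroms = "I", len_bp = 5e6)
  w4 <- simulateWildPanel(100, mm4, 1, 0, seed = 23)
  K4 <- computeKinship(w4)
  w4s <- w4[, 1:500]
  K4s <- computeKinship(w4s)
  expect_lt(mean(abs(K4[upper.tri(K4)])), 0.06)
  expect_lt(mean(abs(K4[upper.tri(K4)])),
            mean(abs(K4s[upper.tri(K4s)])))
  expect_error(computeKinship(GenotypeMatrix(
    matrix(1L, 3, 4, dimnames = list(c("a", "b", "c"), mm$marker_id)),
    mm)), "polymorphic")
})

test_that("EMMA REML attains the dense brute-force optimum on toy instances", {
  set.seed(24)
  for (n in c(6, 9, 12)) {
    Z <- matrix(rbinom(n * 40, 1, 0.5), n, 40)
    K <- tcrossprod(Z - 0.5) / 10 + diag(n) * 0.05
    y <- rnorm(n) + Z[, 1]
    X <- cbind(1, Z[, 2])
    vc <- emmaReml(y, X, K)
    oracle <- denseGlsOracle(y, X, K)
    expect_lt(abs(vc@remlLogLik - oracle$loglik), 1e-6)
    # marker p-value through the package's scan path
    tst <- toxqtl:::glsMarkerTest(y, X, K, vc)
    expect_lt(abs(tst$p - oracle$p), 1e-6)
  }
  # K = I aliasing: only the total variance is identified
  set.seed(25)
  y <- rnorm(30)
  vc_i <- emmaReml(y, K = diag(30))
  expect_lt(abs((vc_i@sigma2G + vc_i@sigma2E) - var(y)) / var(y), 0.1)
  # constant trait is flagged with zero components
  vc_c <- emmaReml(rep(2, 10), K = diag(10))
  expect_equal(vc_c@sigma2G + vc_c@sigma2E, 0)
  expect_match(vc_c@note, "constant")
  expect_error(emmaReml(rnorm(5), K = -diag(5)), "positive semi-definite")
})

test_that("EMMA recovers simulated variance components on a structured kinship", {
  mm <- tinyMap(150, chroms = c("I", "II"))
  w <- simulateWildPanel(300, mm, 3, 0.25, seed = 26)
  K <- computeKinship(w)
  ek <- eigen(K, symmetric = TRUE)
  L <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0)))
  set.seed(27)
  est <- t(vapply(1:100, function(i) {
    y <- as.vector(L %*% rnorm(300)) * sqrt(2) + rnorm(300, 0, 1)
    vc <- emmaReml(y, K = K)
    c(vc@sigma2G, vc@sigma2E)
  }, numeric(2)))
  expect_lt(abs(median(est[, 1]) - 2) / 2, 0.25)
  expect_lt(abs(median(est[, 2]) - 1) / 1, 0.25)
})

test_that("the mixed-model scan is calibrated under the structured null and filters by MAF", {
  mm <- tinyMap(60, chroms = c("I", "II"))
  w <- simulateWildPanel(60, mm, 2, 0.3, seed = 28)
  # null traits with polygenic structure only: pooled p-values stay flat
  set.seed(29)
  K <- computeKinship(w)
  pvals <- unlist(lapply(1:25, function(i) {
    tr <- simulatePhenotypes(w, NULL, polygenic_h2 = 0.5,
                             seed = 3000 + i)
    10^(-gwaTable(gwaScan(w, tr, K = K))$negLog10P)
  }))
  lambda <- median(qchisq(1 - pvals, 1)) / qchisq(0.5, 1)
  expect_lt(abs(lambda - 1), 0.1)
  # subpopulation mean shift: naive correlation inflates, EMMA does not
  pop <- as.integer(sub("^sub(\\d+)_.*$", "\\1", strainNames(w)))
  tr_shift <- strainTraitTable(strainNames(w),
                               ifelse(pop == 1, 1, -1) + rnorm(60, 0, 0.5))
  p_naive <- apply(genotypeCalls(w), 2, function(g)
    if (sd(g) == 0) 1 else cor.test(g, tr_shift$value)$p.value)
  lam_naive <- median(qchisq(1 - p_naive, 1)) / qchisq(0.5, 1)
  p_mixed <- 10^(-gwaTable(gwaScan(w, tr_shift, K = K))$negLog10P)
  lam_mixed <- median(qchisq(1 - p_mixed, 1)) / qchisq(0.5, 1)
  expect_gt(lam_naive, lam_mixed)
  expect_lt(lam_mixed, 1.5)
  # MAF filter edge: a 4% marker is absent from the result
  calls <- genotypeCalls(w)
  rare <- c(rep(1L, 2), rep(0L, 58))  # MAF 0.033 < 0.05
  calls <- cbind(calls, X_999 = rare)
  mm2 <- rbind(markerMap(w),
               data.frame(marker_id = "X_999", chromosome = "X",
                          position_bp = 999L, genetic_pos_cM = 1))
  w2 <- GenotypeMatrix(calls, mm2)
  res <- gwaScan(w2, tr_shift, min_maf = 0.05)
  expect_false("X_999" %in% gwaTable(res)$marker_id)
  expect_true(all(gwaTable(res)$maf >= 0.05))
})

test_that("ROI width calibration shrinks with effect size and respects quantile edges", {
  mm <- tinyMap(75, chroms = c("I", "II"))
  w <- simulateWildPanel(200, mm, 1, 0, seed = 30)
  W_by_ve <- vapply(c(0.1, 0.2, 0.4), function(ve)
    as.integer(calibrateRoiWidth(w, ve = ve, seed = 31)), integer(1))
  expect_true(W_by_ve[1] >= W_by_ve[2] && W_by_ve[2] >= W_by_ve[3])
  # near-noiseless: the top marker is the causal one
  expect_equal(as.integer(calibrateRoiWidth(w, ve = 0.999, seed = 32)), 0)
  # capture = 0: width 0 by the quantile edge
  expect_equal(as.integer(calibrateRoiWidth(w, ve = 0.2, capture = 0,
                                            seed = 33)), 0)
  # determinism
  expect_identical(as.integer(calibrateRoiWidth(w, seed = 34)),
                   as.integer(calibrateRoiWidth(w, seed = 34)))
})

mkGwa <- function(sig_ranks, m = 200) {
  tab <- data.frame(marker_id = sprintf("II_%d", seq_len(m)),
                    chromosome = "II", position_bp = seq_len(m) * 1000L,
                    maf = 0.3, effect = 0,
                    negLog10P = ifelse(seq_len(m) %in% sig_ranks, 10, 0.5),
                    significant = seq_len(m) %in% sig_ranks)
  new("GwaResult", gwaTable = tab, bonferroni = 4, alpha = 0.05,
      regions = toxqtl:::emptyRegions())
}

test_that("regions of interest extend significant clusters by the calibrated width", {
  # single significant SNV mid-chromosome: ranks [peak-50, peak+50]
  r <- regions(defineRoi(mkGwa(100), width_in_snvs = 50))
  expect_equal(c(r$left_rank, r$right_rank), c(50, 150))
  expect_equal(c(r$left_bp, r$right_bp), c(50000, 150000))
  # clipping at the chromosome start
  r2 <- regions(defineRoi(mkGwa(10), width_in_snvs = 50))
  expect_equal(r2$left_rank, 1)
  expect_equal(r2$right_rank, 60)
  # two significant SNVs 30 ranks apart merge with shared margins
  r3 <- regions(defineRoi(mkGwa(c(100, 130)), width_in_snvs = 50))
  expect_equal(nrow(r3), 1)
  expect_equal(c(r3$left_rank, r3$right_rank), c(50, 180))
  expect_equal(r3$n_significant, 2)
  # no significant markers: empty region list
  expect_equal(nrow(regions(defineRoi(mkGwa(integer(0))))), 0)
})
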
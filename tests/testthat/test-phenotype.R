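mkWell <- function(lengths, strain = "s1", assay = "a1", cond = "drug",
                   brood = 30, sorted = 3) {
  data.frame(assay_id = assay, plate = "p1", well = "A1", strain = strain,
             condition = cond, drug_name = "etoposide", sorted_n = sorted,
             animal_lengths = I(list(lengths)), brood_count = brood,
             fluorescence = 0, exclude = FALSE)
}

test_that("well summaries use type-7 quantiles and normalized broods", {
  ws <- summarizeWells(mkWell(c(100, 200, 300)))
  expect_equal(ws$q50, 200)
  expect_equal(ws$norm_n, 10)
  # constant lengths: all quantiles equal
  wc <- summarizeWells(mkWell(rep(7, 20)))
  expect_equal(unlist(wc[c("q10", "q25", "q50", "q75", "q90")]),
               rep(7, 5), ignore_attr = TRUE)
  # sampled quantiles near truth for a known distribution
  set.seed(1)
  x <- rnorm(1000, 100, 10)
  wq <- summarizeWells(mkWell(x))
  expect_equal(wq$q25, quantile(x, 0.25, type = 7, names = FALSE))
  expect_lt(abs(wq$q50 - 100), 1.5)
  expect_lt(abs(wq$q90 - (100 + 10 * qnorm(0.9))), 2)
  # error and edge handling
  expect_error(summarizeWells(mkWell(c(1, 2), sorted = 0)), "sorted_n")
  expect_equal(nrow(summarizeWells(data.frame())), 0)
  # excluded wells are dropped
  wx <- rbind(mkWell(1:3), mkWell(4:6, strain = "s2"))
  wx$exclude <- c(FALSE, TRUE)
  expect_equal(summarizeWells(wx)$strain, "s1")
})

test_that("assay regression removes additive shifts and centers single assays", {
  base <- rep(c(10, 20, 30), 2)
  tr <- data.frame(assay_id = rep(c("a1", "a2"), each = 3),
                   value = base + rep(c(5, -5), each = 3))
  out <- regressAssay(tr)
  expect_equal(out$value, base - mean(base), tolerance = 1e-12)
  # residuals sum to zero within each assay
  expect_equal(as.numeric(tapply(out$value, out$assay_id, sum)), c(0, 0),
               tolerance = 1e-10)
  one <- data.frame(assay_id = "a1", value = c(3, 5, 10))
  expect_equal(regressAssay(one)$value, c(3, 5, 10) - 6)
  # regression reduces variance when assay shifts dominate
  set.seed(2)
  sim <- data.frame(assay_id = rep(sprintf("a%d", 1:8), each = 12),
                    value = rnorm(96) + rep(rnorm(8, 0, 10), each = 12))
  expect_lt(var(regressAssay(sim)$value), var(sim$value))
  # idempotent on its own output
  expect_equal(regressAssay(regressAssay(sim))$value,
               regressAssay(sim)$value, tolerance = 1e-10)
})

test_that("outlier pruning applies the single-pass IQR rule with its escape clause", {
  # 19 values in [0,1] plus one at 100: quartiles of the 20-vector leave
  # only the extreme point outside Q75 + 2 IQR
  v <- c(seq(0, 1, length.out = 19), 100)
  q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  expect_true(100 > q[2] + 2 * (q[2] - q[1]))  # hand-checked flag
  pr <- pruneOutliers(v)
  expect_equal(sum(pr$removed), 1)
  expect_true(pr$removed[20])
  # escape clause: 2 outliers out of 20 is >= 5%, nothing removed
  v2 <- c(seq(0, 1, length.out = 18), 100, 200)
  pr2 <- pruneOutliers(v2)
  expect_equal(sum(pr2$removed), 0)
  # constant vector: IQR 0, no strict exceedance
  expect_equal(sum(pruneOutliers(rep(3, 10))$removed), 0)
  expect_warning(pruneOutliers(c(1, 2, 3)), "fewer than 4")
})

test_that("control regression returns residuals orthogonal to control values", {
  s <- sprintf("s%d", 1:30)
  set.seed(3)
  ctrl <- strainTraitTable(s, rnorm(30), condition = "control")
  drug <- strainTraitTable(s, 2 * ctrl$value)
  out <- regressControl(drug, ctrl)
  expect_equal(out$value, rep(0, 30), tolerance = 1e-10)
  # constant control: residuals are centered drug values
  cc <- strainTraitTable(s, rep(5, 30), condition = "control")
  d2 <- strainTraitTable(s, rnorm(30))
  expect_equal(regressControl(d2, cc)$value, d2$value - mean(d2$value))
  # simulated coupling: residual-control correlation vanishes
  d3 <- strainTraitTable(s, 0.6 * ctrl$value + rnorm(30))
  r3 <- regressControl(d3, ctrl)
  expect_lt(abs(cor(r3$value, ctrl$value[match(r3$strain, ctrl$strain)])),
            1e-10)
  # unmatched strains dropped with warning; too few matched errors
  expect_warning(regressControl(drug, ctrl[1:20, ]), "unmatched")
  expect_error(suppressWarnings(regressControl(drug[1:2, ], ctrl)),
               "matched")
})

test_that("heritability REML matches the balanced ANOVA moment estimator and clamps edge cases", {
  # replicates identical within strain, strains differ -> H2 = 1
  d1 <- data.frame(strain = rep(c("a", "b", "c"), each = 3),
                   value = rep(c(1, 5, 9), each = 3))
  expect_equal(estimateHeritability(d1)@H2, 1, tolerance = 1e-6)
  # identical strain means, pure noise -> H2 ~ 0 (clamped at 0)
  set.seed(4)
  d0 <- data.frame(strain = rep(sprintf("s%d", 1:20), each = 5),
                   value = rnorm(100))
  expect_lt(estimateHeritability(d0)@H2, 0.15)
  # all values identical -> flagged 0
  dz <- data.frame(strain = rep(c("a", "b"), each = 3), value = 1)
  hz <- estimateHeritability(dz)
  expect_equal(hz@H2, 0)
  expect_match(hz@note, "zero total variance")
  # balanced design: REML agrees with (MSB - MSW)/k oracle
  set.seed(5)
  k <- 4
  d <- data.frame(strain = rep(sprintf("s%02d", 1:50), each = k),
                  value = rep(rnorm(50, 0, sqrt(3)), each = k) +
                    rnorm(200, 0, 1))
  h <- estimateHeritability(d)
  expect_lt(abs(h@H2 - 0.75), 0.07)
  a <- anova(aov(value ~ factor(strain), data = d))
  vs_mom <- (a$`Mean Sq`[1] - a$`Mean Sq`[2]) / k
  h2_mom <- vs_mom / (vs_mom + a$`Mean Sq`[2])
  expect_lt(abs(h@H2 - h2_mom), 1e-6)
  # invariant to affine rescaling of the trait
  d_aff <- transform(d, value = 100 - 7 * value)
  expect_equal(estimateHeritability(d_aff)@H2, h@H2, tolerance = 1e-6)
})

test_that("fluorescence gating labels heterozygotes between parental gates", {
  dark <- seq(0, 1, length.out = 50)
  bright <- seq(10, 11, length.out = 50)
  expect_equal(classifyHeterozygotes(5, bright, dark), "het")
  expect_equal(classifyHeterozygotes(0.5, bright, dark), "parental_dark")
  expect_equal(classifyHeterozygotes(10.8, bright, dark),
               "parental_bright")
  expect_error(classifyHeterozygotes(5, bright = dark, dark = dark),
               "gates")
  # trimodal mixture at 5-SD separation: >= 95% correct
  set.seed(6)
  truth <- sample(c("parental_dark", "het", "parental_bright"), 600,
                  replace = TRUE)
  mu <- c(parental_dark = 0, het = 5, parental_bright = 10)
  x <- rnorm(600, mu[truth], 1)
  lab <- classifyHeterozygotes(x, bright_parent = rnorm(200, 10, 1),
                               dark_parent = rnorm(200, 0, 1))
  expect_gt(mean(lab == truth), 0.95)
})

test_that("Tukey HSD strain comparisons are calibrated and powered", {
  set.seed(7)
  same <- data.frame(strain = rep(c("a", "b"), each = 10),
                     value = rnorm(20))
  base <- compareStrains(same)
  expect_true(all(base$p_adj >= 0 & base$p_adj <= 1))
  # 10-SD shift: overwhelming significance (studentized-range tail)
  shift <- data.frame(strain = rep(c("a", "b"), each = 10),
                      value = c(rnorm(10), rnorm(10) + 10))
  expect_lt(compareStrains(shift)$p_adj, 1e-6)
  # identical groups: p ~ 1
  ident <- data.frame(strain = rep(c("a", "b"), each = 6),
                      value = rep(c(1, 2, 3, 1, 2, 3), 2))
  expect_gt(compareStrains(ident)$p_adj, 0.99)
  # family-wise type-I error calibration under permuted labels
  set.seed(8)
  rej <- vapply(seq_len(1000), function(i) {
    d <- data.frame(strain = rep(c("a", "b", "c"), each = 6),
                    value = rnorm(18))
    any(compareStrains(d)$p_adj < 0.05)
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.025)
})

test_that("the full well-to-trait pipeline runs in its documented order", {
  # coupling 0: the drug-specific strain effect survives control
  # regression (a strongly coupled control would absorb it by design)
  set.seed(9)
  eff <- strainTraitTable(sprintf("s%02d", 1:20), rnorm(20, 0, 15))
  wells <- simulateWellData(eff, n_assays = 3, assay_shift_sd = 10,
                            control_coupling = 0, seed = 10)
  tt <- processWellTraits(wells)
  expect_true(all(tt$strain %in% eff$strain))
  expect_gt(cor(tt$value, eff$value[match(tt$strain, eff$strain)]), 0.8)
  # alternative order also runs
  tt2 <- processWellTraits(wells, prune_before_control = FALSE)
  expect_equal(nrow(tt2), 20)
})
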
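test_that("simulators are deterministic for a fixed seed and leave global RNG alone", {
  mm <- tinyMap(8)
  set.seed(99)
  before <- .Random.seed
  g1 <- simulateRiailGenotypes(20, mm, 4, seed = 7)
  expect_identical(.Random.seed, before)
  g2 <- simulateRiailGenotypes(20, mm, 4, seed = 7)
  expect_identical(genotypeCalls(g1), genotypeCalls(g2))
  w1 <- simulateWildPanel(15, mm, 2, 0.2, seed = 5)
  w2 <- simulateWildPanel(15, mm, 2, 0.2, seed = 5)
  expect_identical(genotypeCalls(w1), genotypeCalls(w2))
  t1 <- simulatePhenotypes(g1, seed = 3)
  t2 <- simulatePhenotypes(g1, seed = 3)
  expect_identical(t1$value, t2$value)
  r1 <- simulatePooledReadcounts(0.01, 2, 5, 1e4, seed = 11)
  r2 <- simulatePooledReadcounts(0.01, 2, 5, 1e4, seed = 11)
  expect_identical(r1, r2)
})

test_that("RIAIL panel matches analytic breakpoint and allele-frequency expectations", {
  # selfing only: expected crossovers per chromosome = map length in
  # Morgans per meiosis (0.5 for a 50 cM chromosome)
  mm <- tinyMap(25, chroms = c("I", "II", "III"))
  g <- simulateRiailGenotypes(1000, mm, n_intercross_generations = 0,
                              seed = 21)
  bp <- meanBreakpoints(g)
  expect_true(all(abs(bp - 0.5) < 3 * sqrt(0.5 / 1000) + 0.02))
  # whole-panel allele frequency ~ 0.5 per marker
  f <- alleleFreq(g)
  se <- 0.5 / sqrt(1000)
  expect_gt(mean(abs(f - 0.5) <= 3 * se), 0.95)
  # map expansion: more intercross generations, more breakpoints
  g8 <- simulateRiailGenotypes(500, mm, n_intercross_generations = 9,
                               seed = 22)
  expect_true(all(meanBreakpoints(g8) > meanBreakpoints(g)[1] * 3))
})

test_that("adjacent-marker correlation decays with genetic distance and co-located markers never recombine", {
  mm <- tinyMap(30, chroms = "I")
  g <- simulateRiailGenotypes(600, mm, 2, seed = 31)
  calls <- genotypeCalls(g)
  r_adj <- cor(calls[, 1], calls[, 2])
  r_far <- cor(calls[, 1], calls[, 30])
  expect_gt(r_adj, r_far + 0.2)
  # two markers at an identical genetic position
  mm2 <- data.frame(marker_id = c("I_a", "I_b"), chromosome = "I",
                    position_bp = c(100L, 200L), genetic_pos_cM = c(10, 10))
  g2 <- simulateRiailGenotypes(300, mm2, 10, seed = 32)
  expect_identical(unname(genotypeCalls(g2)[, 1]),
                   unname(genotypeCalls(g2)[, 2]))
})

test_that("wild panel structure follows the divergence parameter", {
  mm <- tinyMap(100, chroms = c("I", "II"))
  expect_error(simulateWildPanel(10, mm, 2, 1.2, seed = 1),
               "fst_like_divergence")
  expect_error(simulateWildPanel(10, mm, 2, -0.1, seed = 1),
               "fst_like_divergence")
  # single strain: degenerate but valid
  expect_equal(nStrains(simulateWildPanel(1, mm, 1, 0, seed = 2)), 1)
  # divergence 0: mean off-diagonal kinship ~ 0
  w0 <- simulateWildPanel(80, mm, 2, 0, seed = 3)
  K0 <- computeKinship(w0)
  expect_lt(abs(mean(K0[upper.tri(K0)])), 0.05)
  # divergence 0.3, 2 subpopulations: leading kinship eigenvector
  # separates the subpopulations by sign
  w <- simulateWildPanel(200, mm, 2, 0.3, seed = 4)
  K <- computeKinship(w)
  v1 <- eigen(K, symmetric = TRUE)$vectors[, 1]
  pop <- as.integer(sub("^sub(\\d+)_.*$", "\\1", strainNames(w)))
  agree <- mean((v1 > 0) == (pop == 1))
  expect_gt(max(agree, 1 - agree), 0.95)
  # within-subpopulation kinship exceeds between
  same <- outer(pop, pop, "==")
  off <- upper.tri(K)
  expect_gt(mean(K[off & same]), mean(K[off & !same]))
  # founder-mosaic mode induces local LD (absent from the
  # independent-sites default) that decays with distance
  adjR2 <- function(g) {
    cl <- genotypeCalls(g)
    poly <- which(apply(cl, 2, sd) > 0)
    mean(diag(cor(cl[, poly[-length(poly)]], cl[, poly[-1]])^2),
         na.rm = TRUE)
  }
  wl <- simulateWildPanel(120, tinyMap(60, chroms = "I"), 1, 0, seed = 5,
                          n_founder_haplotypes = 6,
                          founder_switch_prob = 0.05)
  wi <- simulateWildPanel(120, tinyMap(60, chroms = "I"), 1, 0, seed = 5)
  expect_gt(adjR2(wl), 5 * adjR2(wi))
  cl <- genotypeCalls(wl)
  poly <- which(apply(cl, 2, sd) > 0)
  far <- cor(cl[, poly[1]], cl[, poly[length(poly)]])^2
  expect_gt(adjR2(wl), far)
})

test_that("phenotype simulator realizes the requested variance decomposition", {
  mm <- tinyMap(15)
  g <- simulateRiailGenotypes(500, mm, 4, seed = 41)
  qtl <- data.frame(marker_id = markerMap(g)$marker_id[8],
                    variance_explained = 0.20)
  r2 <- vapply(seq_len(100), function(i) {
    tr <- simulatePhenotypes(g, qtl, seed = 1000 + i)
    cor(tr$value, genotypeCalls(g)[, qtl$marker_id])^2
  }, numeric(1))
  expect_lt(abs(mean(r2) - 0.20), 0.05)
  # noiseless limit: trait is an affine function of the genotype
  qtl1 <- data.frame(marker_id = qtl$marker_id,
                     variance_explained = 1 - 1e-9)
  tr1 <- simulatePhenotypes(g, qtl1, seed = 5, standardize = FALSE)
  expect_gt(cor(tr1$value, genotypeCalls(g)[, qtl$marker_id])^2, 0.999)
  # over-committed variance errors out
  expect_error(simulatePhenotypes(g, data.frame(
    marker_id = markerMap(g)$marker_id[1:2],
    variance_explained = c(0.6, 0.5)), seed = 1), "sum")
})

test_that("well-record simulator carries strain, assay and control structure", {
  eff <- strainTraitTable(sprintf("s%02d", 1:12), rnorm(12, 0, 20))
  wells <- simulateWellData(eff, n_assays = 8, assay_shift_sd = 30,
                            control_coupling = 0, noise_sd = 5, seed = 51)
  ws <- summarizeWells(wells)
  ws$value <- ws$q50
  drug <- ws[ws$condition == "drug", ]
  # huge assay shifts: the assay factor explains most variance
  fit <- lm(value ~ factor(assay_id), data = drug)
  expect_gt(summary(fit)$r.squared, 0.5)
  # nuisance-free limit: well medians track strain effects
  wells0 <- simulateWellData(eff, n_assays = 2, assay_shift_sd = 0,
                             control_coupling = 0, noise_sd = 2, seed = 52)
  ws0 <- summarizeWells(wells0)
  d0 <- ws0[ws0$condition == "drug", ]
  m <- tapply(d0$q50, d0$strain, mean) - 250
  expect_gt(cor(m[eff$strain], eff$value), 0.99)
  # two strains of different true length separate by rank test
  eff2 <- strainTraitTable(c("short", "long"), c(-30, 30))
  w2 <- simulateWellData(eff2, n_assays = 6, assay_shift_sd = 0,
                         animals_per_well = 50, noise_sd = 15, seed = 53)
  s2 <- summarizeWells(w2)
  s2 <- s2[s2$condition == "drug", ]
  pw <- wilcox.test(q50 ~ strain, data = s2)$p.value
  expect_lt(pw, 0.01)
})

test_that("pooled read counts follow the analytic selection recursion", {
  expect_error(simulatePooledReadcounts(0.5, 1, 5, 0, seed = 1), "depth")
  # neutral selection: expected post fraction = pre fraction
  expect_equal(selectionRecursion(0.3, 1, 12), 0.3)
  # fitness and generations chosen so the deterministic expectation is
  # 0.144 starting from 0.001: w^g = (0.144/0.856) * (0.999/0.001)
  w <- (0.144 / 0.856 * 0.999 / 0.001)^(1 / 10)
  expect_equal(selectionRecursion(0.001, w, 10), 0.144, tolerance = 1e-12)
  rc <- simulatePooledReadcounts(0.001, w, 10, depth = 1e6, seed = 61)
  post <- rc[rc$condition == "etoposide" & rc$timepoint == "post", ]
  pre <- rc[rc$condition == "etoposide" & rc$timepoint == "pre", ]
  fold <- (post$edited_reads / (post$edited_reads + post$wildtype_reads)) /
    (pre$edited_reads / (pre$edited_reads + pre$wildtype_reads))
  expect_lt(abs(fold - 144), 15)  # ~3 sigma of the binomial pre-count error
})
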
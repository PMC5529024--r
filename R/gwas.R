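#' @include linkage.R
NULL

#' Realized additive relationship (kinship) matrix
#'
#' VanRaden normalization on inbred-homozygote coding: calls are coded
#' -1/+1, columns centered by allele frequency, and the cross-product is
#' scaled by the summed expected marker variance
#' \eqn{2\sum_k p_k (1 - p_k)}, so the diagonal averages
#' \eqn{1 + f \approx 2} on fully inbred panels. Missing calls are imputed
#' with the marker mean. Adding a constant to all genotype codes leaves
#' the result unchanged (double centering).
#'
#' @param genotypes a [GenotypeMatrix-class] (>= 2 strains, >= 2
#'   polymorphic markers).
#' @return symmetric strains x strains numeric matrix with strain
#'   dimnames.
#' @export
computeKinship <- function(genotypes) {
  calls <- genotypeCalls(genotypes)
  if (nrow(calls) < 2) stop("need >= 2 strains")
  p <- colMeans(calls, na.rm = TRUE)
  poly <- p > 0 & p < 1 & !is.na(p)
  if (sum(poly) < 2) stop("need >= 2 polymorphic markers")
  C <- calls[, poly, drop = FALSE]
  p <- p[poly]
  for (j in which(colSums(is.na(C)) > 0)) C[is.na(C[, j]), j] <- p[j]
  W <- 2 * sweep(C, 2, p)  # (-1/+1 coding) - (2p - 1)
  K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(rownames(calls), rownames(calls))
  (K + t(K)) / 2
}

#' Exact REML for the kinship mixed model (EMMA)
#'
#' Maximizes the restricted likelihood of
#' \eqn{y = X\beta + u + e}, \eqn{u \sim N(0, \sigma^2_g K)},
#' \eqn{e \sim N(0, \sigma^2_e I)}, by a single eigendecomposition of the
#' projected kinship \eqn{S(K + I)S} (with \eqn{S = I - X(X'X)^{-1}X'})
#' followed by 1-D optimization of the variance ratio
#' \eqn{\delta = \sigma^2_e/\sigma^2_g} over a \eqn{\log_{10}\delta \in
#' [-5, 5]} grid of 100 intervals with local refinement, returning the
#' global optimum over the searched range.
#'
#' @param y numeric trait vector (length n).
#' @param X fixed-effect design matrix (n x q; default intercept only).
#' @param K kinship matrix (n x n, symmetric PSD to numerical tolerance).
#' @param grid_points number of grid intervals for log10(delta)
#'   (default 100).
#' @return a [VarianceComponents-class].
#' @examples
#' K <- diag(5)
#' emmaReml(rnorm(5), K = K)
#' @export
emmaReml <- function(y, X = NULL, K, grid_points = 100) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  q <- qr(X)$rank
  if (n < q + 2) stop("need n >= rank(X) + 2")
  K <- as.matrix(K)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6 * max(abs(ev), 1))
    stop("K is not positive semi-definite to tolerance")
  if (sd(y) == 0)
    return(new("VarianceComponents", sigma2G = 0, sigma2E = 0,
               delta = NaN, remlLogLik = NA_real_,
               beta = rep(mean(y), ncol(X)), note = "constant trait"))
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  # eigen of S(K+I)S: the n-q informative eigenvalues are lambda + 1,
  # the null space of S contributes exact zeros
  es <- eigen(S %*% (K + diag(n)) %*% S, symmetric = TRUE)
  m <- n - q
  lambda <- pmax(es$values[seq_len(m)] - 1, 0)
  eta <- crossprod(es$vectors[, seq_len(m), drop = FALSE], y)[, 1]
  eta2 <- eta^2
  restLL <- function(logdelta) {
    d <- 10^logdelta
    ss <- sum(eta2 / (lambda + d))
    0.5 * (m * (log(m / (2 * pi)) - 1 - log(ss)) - sum(log(lambda + d)))
  }
  gridv <- seq(-5, 5, length.out = grid_points + 1)
  ll <- vapply(gridv, restLL, numeric(1))
  i <- which.max(ll)
  lo <- gridv[max(i - 1, 1)]; hi <- gridv[min(i + 1, length(gridv))]
  opt <- optimize(restLL, c(lo, hi), maximum = TRUE, tol = 1e-10)
  if (opt$objective < ll[i]) {
    logdelta <- gridv[i]; best <- ll[i]
  } else {
    logdelta <- opt$maximum; best <- opt$objective
  }
  delta <- 10^logdelta
  s2g <- sum(eta2 / (lambda + delta)) / m
  s2e <- delta * s2g
  H <- K + delta * diag(n)
  HiX <- solve(H, X)
  beta <- solve(crossprod(X, HiX), crossprod(HiX, y))[, 1]
  new("VarianceComponents", sigma2G = s2g, sigma2E = s2e, delta = delta,
      remlLogLik = best, beta = beta, note = "")
}

## GLS t-test for the last column of X at the REML optimum
glsMarkerTest <- function(y, X, K, vc) {
  n <- length(y)
  H <- K + vc@delta * diag(n)
  HiX <- solve(H, X)
  XtHiX <- crossprod(X, HiX)
  beta <- solve(XtHiX, crossprod(HiX, y))[, 1]
  covb <- vc@sigma2G * solve(XtHiX)
  j <- ncol(X)
  tstat <- beta[j] / sqrt(covb[j, j])
  df <- n - ncol(X)
  list(effect = beta[j], t = tstat,
       p = 2 * pt(abs(tstat), df, lower.tail = FALSE))
}

#' Kinship-corrected genome-wide association scan
#'
#' For every marker passing the minor-allele-frequency filter, the marker
#' genotype enters the fixed-effect design next to the intercept and is
#' tested with a t-test on its generalized-least-squares coefficient at
#' the marker's own REML optimum (variance components re-estimated per
#' marker, the exact / P3D = FALSE mode; `p3d = TRUE` reuses the
#' null-model variance ratio for speed). The genome-wide threshold is
#' Bonferroni: `alpha /` number of tested markers, reported on the
#' -log10 scale.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param trait strain-trait table.
#' @param K kinship matrix (default: computed from `genotypes` on the
#'   shared strains).
#' @param min_maf minor-allele-frequency cutoff, computed on the
#'   phenotyped strains (default 0.05).
#' @param alpha Bonferroni family-wise alpha (default 0.05).
#' @param p3d reuse null-model variance components (default `FALSE`).
#' @return a [GwaResult-class] (regions slot empty; see [defineRoi()]).
#' @export
gwaScan <- function(genotypes, trait, K = NULL, min_maf = 0.05,
                    alpha = 0.05, p3d = FALSE) {
  shared <- intersect(strainNames(genotypes), trait$strain)
  if (length(shared) < 3) stop("trait/strain mismatch: too few shared strains")
  if (length(shared) < 20)
    warning("fewer than 20 shared strains; association will be unstable")
  g <- genotypes[shared, ]
  y <- trait$value[match(shared, trait$strain)]
  if (is.null(K)) K <- computeKinship(g)
  K <- K[shared, shared]
  maf <- minorAlleleFreq(g)
  keep <- !is.na(maf) & maf >= min_maf
  g <- g[, keep]
  calls <- genotypeCalls(g)
  m <- ncol(calls)
  if (m == 0) stop("no markers pass the MAF filter")
  n <- length(y)
  ones <- matrix(1, n, 1)
  vc0 <- emmaReml(y, ones, K)
  eff <- pv <- numeric(m)
  for (j in seq_len(m)) {
    x <- calls[, j]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    X <- cbind(ones, x)
    vc <- if (p3d) vc0 else emmaReml(y, X, K)
    tst <- glsMarkerTest(y, X, K, vc)
    eff[j] <- tst$effect; pv[j] <- tst$p
  }
  mm <- markerMap(g)
  bonf <- -log10(alpha / m)
  tab <- data.frame(marker_id = mm$marker_id, chromosome = mm$chromosome,
                    position_bp = mm$position_bp,
                    maf = as.numeric(minorAlleleFreq(g)),
                    effect = eff, negLog10P = -log10(pmax(pv, 1e-300)),
                    significant = -log10(pmax(pv, 1e-300)) > bonf)
  new("GwaResult", gwaTable = tab, bonferroni = bonf, alpha = alpha,
      regions = emptyRegions())
}

emptyRegions <- function() {
  data.frame(chromosome = character(), left_bp = integer(),
             right_bp = integer(), left_rank = integer(),
             right_rank = integer(), n_significant = integer(),
             peak_marker = character())
}

#' Calibrate the region-of-interest width by QTL simulation
#'
#' For each marker of the MAF-filtered panel, simulates a trait in which
#' that marker explains `ve` of the variance (plus Gaussian noise),
#' identifies the most-correlated marker of the panel, and records the
#' rank distance (in SNV ordering) between the simulated and recovered
#' markers. Returns the smallest width `W` such that at least `capture`
#' of the distances are `<= W`.
#'
#' @param genotypes a [GenotypeMatrix-class], MAF-filtered (markers below
#'   `min_maf` are dropped here).
#' @param ve simulated QTL variance explained (default 0.20).
#' @param capture target capture fraction (default 0.95).
#' @param n_reps_per_marker simulated traits per marker (default 1).
#' @param min_maf MAF filter applied before calibration (default 0.05).
#' @param seed integer RNG seed.
#' @return integer width in SNVs, with attribute `"distances"`.
#' @export
calibrateRoiWidth <- function(genotypes, ve = 0.20, capture = 0.95,
                              n_reps_per_marker = 1, min_maf = 0.05, seed) {
  stopifnot(ve > 0, ve < 1, capture >= 0, capture <= 1)
  maf <- minorAlleleFreq(genotypes)
  g <- genotypes[, !is.na(maf) & maf >= min_maf]
  calls <- genotypeCalls(g)
  m <- ncol(calls)
  if (m < 10) stop("too few markers after MAF filtering (< 10)")
  n <- nrow(calls)
  Cimp <- calls
  for (j in which(colSums(is.na(Cimp)) > 0))
    Cimp[is.na(Cimp[, j]), j] <- mean(Cimp[, j], na.rm = TRUE)
  dists <- withSeed(seed, {
    out <- integer(0)
    for (rep in seq_len(n_reps_per_marker)) {
      Ysim <- sqrt(ve) * scale(Cimp) + sqrt(1 - ve) *
        matrix(rnorm(n * m), n, m)
      r <- abs(cor(Cimp, Ysim))
      hit <- max.col(t(r), ties.method = "first")
      out <- c(out, abs(hit - seq_len(m)))
    }
    out
  })
  sorted <- sort(dists)
  idx <- ceiling(capture * length(sorted))
  W <- if (idx < 1) 0L else as.integer(sorted[idx])
  structure(W, distances = dists)
}

#' Regions of interest around significant association signals
#'
#' Per chromosome, significant SNVs separated by at most `width_in_snvs`
#' ranks (in the tested-SNV ordering) merge into one cluster; each
#' cluster's region spans from `width_in_snvs` SNVs left of its leftmost
#' significant SNV to `width_in_snvs` SNVs right of its rightmost
#' significant SNV, clipped at chromosome ends, and is reported in bp.
#' The reported peak marker is the smallest p-value, ties breaking to the
#' leftmost position.
#'
#' @param result a [GwaResult-class].
#' @param width_in_snvs region half-width in SNV ranks (default 50; see
#'   [calibrateRoiWidth()]).
#' @return `result` with its `regions` slot filled (empty when no marker
#'   is significant).
#' @export
defineRoi <- function(result, width_in_snvs = 50) {
  tab <- result@gwaTable
  rows <- list()
  for (chr in unique(tab$chromosome)) {
    s <- tab[tab$chromosome == chr, ]
    s <- s[order(s$position_bp), ]
    sig <- which(s$significant)
    if (!length(sig)) next
    cluster_id <- cumsum(c(1, diff(sig) > width_in_snvs))
    for (cl in split(sig, cluster_id)) {
      lr <- max(min(cl) - width_in_snvs, 1L)
      rr <- min(max(cl) + width_in_snvs, nrow(s))
      peak <- cl[order(-s$negLog10P[cl], s$position_bp[cl])][1]
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = chr, left_bp = s$position_bp[lr],
        right_bp = s$position_bp[rr], left_rank = as.integer(lr),
        right_rank = as.integer(rr), n_significant = length(cl),
        peak_marker = s$marker_id[peak])
    }
  }
  result@regions <- if (length(rows)) do.call(rbind, rows) else
    emptyRegions()
  validObject(result)
  result
}
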
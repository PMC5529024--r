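# Independent oracles used across the suite. Each re-derives its quantity
# by brute force / closed form, never through the package's own code path.

# small marker map on two chromosomes for quick tests
tinyMap <- function(n_per_chrom = 10, chroms = c("I", "II"),
                    len_bp = 1e6, len_cM = 50) {
  do.call(rbind, lapply(chroms, function(ch) {
    pos <- as.integer(seq(1, len_bp, length.out = n_per_chrom))
    data.frame(marker_id = sprintf("%s_%d", ch, pos), chromosome = ch,
               position_bp = pos,
               genetic_pos_cM = seq(0, len_cM, length.out = n_per_chrom))
  }))
}

# all permutations of 1..n (n <= 7)
allPerms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in allPerms(n - 1))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# exact two-sided Spearman p by enumerating all rank permutations:
# fraction of permutations whose |rho| (average ranks) reaches the
# observed |rho|
spearmanExactOracle <- function(g, y) {
  n <- length(g)
  rg <- rank(g); ry <- rank(y)
  rho_obs <- cor(rg, ry)
  rho_all <- vapply(allPerms(n), function(p) cor(rg, ry[p]), numeric(1))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-9)
}

# two-sided Fisher exact p: sum of hypergeometric probabilities of all
# tables with the observed margins no more likely than the observed table
fisherExactOracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# dense-matrix restricted log-likelihood of the kinship mixed model at a
# given variance ratio delta (sigma2_g profiled out), matching the
# constant convention of the eigendecomposition form
denseRemlLogLik <- function(y, X, K, delta) {
  n <- length(y); q <- ncol(X); m <- n - q
  V <- K + delta * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  R <- as.numeric(t(r) %*% Vi %*% r)
  as.numeric(0.5 * (m * log(m / (2 * pi)) - m - m * log(R) -
                      determinant(V)$modulus -
                      determinant(XtViX)$modulus +
                      determinant(crossprod(X))$modulus))
}

# brute-force GLS marker test at the dense-grid REML optimum
denseGlsOracle <- function(y, X, K, n_grid = 1e4) {
  grid <- seq(-5, 5, length.out = n_grid)
  ll <- vapply(grid, function(ld) denseRemlLogLik(y, X, K, 10^ld),
               numeric(1))
  i <- which.max(ll)
  o <- optimize(function(ld) denseRemlLogLik(y, X, K, 10^ld),
                c(grid[max(i - 1, 1)], grid[min(i + 1, n_grid)]),
                maximum = TRUE, tol = 1e-12)
  delta <- 10^o$maximum
  if (o$objective < ll[i]) delta <- 10^grid[i]
  n <- length(y); q <- ncol(X); m <- n - q
  V <- K + delta * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  s2g <- as.numeric(t(r) %*% Vi %*% r) / m
  covb <- s2g * solve(XtViX)
  tstat <- beta[q] / sqrt(covb[q, q])
  list(loglik = max(o$objective, ll[i]), delta = delta,
       p = 2 * pt(abs(tstat), m, lower.tail = FALSE))
}

# neutral coalescent haplotype simulator (infinite sites): lineage
# tip-sets accumulate Poisson(theta/2 * t) mutations per interval
simNeutralHaplotypes <- function(n, theta) {
  lineages <- as.list(seq_len(n))
  sites <- list()
  k <- n
  while (k > 1) {
    t_int <- rexp(1, rate = choose(k, 2))
    nmut <- rpois(k, theta / 2 * t_int)
    for (i in which(nmut > 0))
      for (j in seq_len(nmut[i]))
        sites[[length(sites) + 1L]] <- lineages[[i]]
    pair <- sample.int(k, 2)
    lineages[[pair[1]]] <- c(lineages[[pair[1]]], lineages[[pair[2]]])
    lineages[[pair[2]]] <- NULL
    k <- k - 1L
  }
  if (!length(sites)) return(matrix(0L, n, 0))
  h <- matrix(0L, n, length(sites))
  for (s in seq_along(sites)) h[sites[[s]], s] <- 1L
  h
}

# adjacent-marker state changes per chromosome, averaged over lines
meanBreakpoints <- function(genotypes) {
  calls <- genotypeCalls(genotypes)
  mm <- markerMap(genotypes)
  per_chrom <- vapply(split(seq_len(ncol(calls)), mm$chromosome),
                      function(idx) {
                        g <- calls[, idx, drop = FALSE]
                        mean(rowSums(abs(g[, -1, drop = FALSE] -
                                           g[, -length(idx), drop = FALSE])))
                      }, numeric(1))
  per_chrom
}
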
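#' @include phenotype.R
NULL

#' Correlation LOD score
#'
#' Linkage statistic for inbred-line panels:
#' \deqn{LOD = -n \ln(1 - r^2) / (2 \ln 10)}
#' where `r` is the Pearson correlation between marker genotype and trait
#' and `n` the number of pairwise-complete strain observations. Equivalent
#' to \eqn{-(n/2)\log_{10}(1 - r^2)}.
#'
#' @param genotype numeric marker calls over strains (0/1, NA allowed).
#' @param phenotype numeric trait values over the same strains.
#' @return non-negative LOD score; 0 (with a warning) when genotype or
#'   phenotype has zero variance over the complete pairs.
#' @examples
#' lodScore(rep(0:1, each = 10), c(rnorm(10), rnorm(10) + 2))
#' @export
lodScore <- function(genotype, phenotype) {
  ok <- !is.na(genotype) & !is.na(phenotype)
  n <- sum(ok)
  if (n < 3) stop("need >= 3 pairwise-complete observations")
  g <- genotype[ok]; y <- phenotype[ok]
  if (sd(g) == 0 || sd(y) == 0) {
    warning("zero-variance genotype or phenotype; LOD set to 0")
    return(0)
  }
  r <- cor(g, y)
  -n * log(1 - r^2) / (2 * log(10))
}

## vectorized scan core: LOD for every column of `calls` against trait
## matrix `Y` (strains x traits); traits assumed complete, genotypes may
## have NA (pairwise-complete n per marker).
lodMatrix <- function(calls, Y) {
  Y <- as.matrix(Y)
  n_per <- colSums(!is.na(calls))
  r <- suppressWarnings(cor(calls, Y, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  lod <- -n_per * log(pmax(1 - r^2, .Machine$double.eps)) / (2 * log(10))
  dim(lod) <- dim(r)
  lod
}

#' Genome scan with the correlation LOD statistic
#'
#' Computes the LOD statistic at every marker (standardizing the trait to
#' mean 0, variance 1 first) and retains the maximum-LOD marker of each
#' chromosome as that chromosome's peak; ties break to the leftmost
#' position.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param traits strain-trait table (see [strainTraitTable()]).
#' @param standardize scale the trait before scanning (default `TRUE`).
#' @return a [ScanResult-class] (threshold and intervals unset; see
#'   [permutationThreshold()] and [lodDropIntervals()]).
#' @export
genomeScan <- function(genotypes, traits, standardize = TRUE) {
  shared <- intersect(strainNames(genotypes), traits$strain)
  if (length(shared) == 0) stop("no strains shared between genotypes and traits")
  if (length(shared) < 10)
    warning("fewer than 10 shared strains; scan will be unstable")
  g <- genotypes[shared, ]
  y <- traits$value[match(shared, traits$strain)]
  if (standardize && sd(y) > 0) y <- as.vector(scale(y))
  calls <- genotypeCalls(g)
  lod <- as.vector(lodMatrix(calls, y))
  mm <- markerMap(g)
  tab <- data.frame(marker_id = mm$marker_id, chromosome = mm$chromosome,
                    position_bp = mm$position_bp, lod = lod,
                    n = colSums(!is.na(calls)))
  pk <- do.call(rbind, lapply(split(tab, chromFactor(tab$chromosome)), function(s) {
    s[which.max(s$lod), c("chromosome", "marker_id", "position_bp", "lod", "n")]
  }))
  rownames(pk) <- NULL
  new("ScanResult", scanTable = tab, threshold = NA_real_,
      thresholdMode = "none", peaks = pk,
      intervals = emptyIntervals(), trait = traits$trait[1])
}

emptyIntervals <- function() {
  data.frame(chromosome = character(), left_bp = integer(),
             right_bp = integer(), peak_marker = character(),
             peak_lod = numeric(), variance_explained = numeric(),
             fraction_of_h2 = numeric())
}

#' Permutation-based genome-wide LOD threshold
#'
#' Strain labels are permuted jointly across all supplied traits (rows
#' moved as units) so the trait-trait correlation structure is preserved.
#' Two modes:
#' \describe{
#'   \item{`max-lod-quantile`}{(default) the `1 - alpha` quantile of the
#'     per-permutation genome-wide maximum LOD.}
#'   \item{`peak-ratio`}{the smallest observed chromosome-peak LOD at which
#'     the ratio of expected (mean permuted) chromosome-wise peaks above
#'     the candidate to observed peaks above it is at most `alpha`. This
#'     reading of the expected/observed peak criterion counts
#'     chromosome-wise maxima above a candidate threshold as peaks; it is
#'     documented, not claimed to reproduce any particular published
#'     cutoff.}
#' }
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param trait_matrix numeric matrix, strains x traits (rownames = strain
#'   ids), or a strain-trait table for a single trait.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param alpha genome-wide error rate (default 0.05).
#' @param seed integer RNG seed.
#' @param mode `"max-lod-quantile"` or `"peak-ratio"`.
#' @return numeric threshold in LOD units, with attribute `"maxima"`
#'   carrying the per-permutation genome-wide maxima.
#' @export
permutationThreshold <- function(genotypes, trait_matrix, n_perm = 1000,
                                 alpha = 0.05, seed,
                                 mode = c("max-lod-quantile", "peak-ratio")) {
  mode <- match.arg(mode)
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (is.data.frame(trait_matrix) && "value" %in% names(trait_matrix)) {
    tm <- matrix(trait_matrix$value, ncol = 1,
                 dimnames = list(trait_matrix$strain, trait_matrix$trait[1]))
  } else tm <- as.matrix(trait_matrix)
  shared <- intersect(strainNames(genotypes), rownames(tm))
  if (length(shared) < 3) stop("too few shared strains")
  g <- genotypes[shared, ]
  Y <- tm[shared, , drop = FALSE]
  Y <- scale(Y)
  calls <- genotypeCalls(g)
  n <- nrow(Y)
  perms <- withSeed(seed, replicate(n_perm, sample.int(n), simplify = FALSE))
  chrom <- chromFactor(markerMap(g)$chromosome)
  maxima <- numeric(n_perm)
  permPeaks <- matrix(NA_real_, n_perm, nlevels(chrom))
  for (b in seq_len(n_perm)) {
    lod <- lodMatrix(calls, Y[perms[[b]], , drop = FALSE])
    maxima[b] <- max(lod)
    if (mode == "peak-ratio") {
      lodmax <- apply(lod, 1, max)  # best trait per marker
      permPeaks[b, ] <- tapply(lodmax, chrom, max)
    }
  }
  if (mode == "max-lod-quantile") {
    thr <- quantile(maxima, 1 - alpha, type = 7, names = FALSE)
  } else {
    lod0 <- lodMatrix(calls, Y)
    obsPeaks <- tapply(apply(lod0, 1, max), chrom, max)
    cand <- sort(unique(obsPeaks))
    thr <- NA_real_
    for (t0 in cand) {
      expected <- mean(rowSums(permPeaks >= t0))
      observed <- sum(obsPeaks >= t0)
      if (observed > 0 && expected / observed <= alpha) { thr <- t0; break }
    }
    if (is.na(thr)) thr <- max(maxima)
  }
  structure(thr, maxima = maxima)
}

#' LOD-drop confidence intervals
#'
#' For each chromosome peak above the scan threshold, the interval is the
#' maximal contiguous marker run around the peak with
#' `LOD >= peak - drop` (default drop 1.5); endpoints are marker
#' positions. When `h2` is supplied, each interval also carries the peak's
#' variance explained and its fraction of the broad-sense heritability.
#'
#' @param scan a [ScanResult-class]; its `threshold` slot must be set (or
#'   pass `threshold`).
#' @param drop LOD drop defining the interval (default 1.5).
#' @param h2 broad-sense heritability in (0, 1] for the
#'   variance-explained accounting (optional).
#' @param threshold overrides the scan's stored threshold.
#' @return the scan with its `intervals` slot filled (peaks below the
#'   threshold yield no interval).
#' @export
lodDropIntervals <- function(scan, drop = 1.5, h2 = NULL, threshold = NULL) {
  thr <- if (!is.null(threshold)) threshold else scan@threshold
  if (is.na(thr)) stop("scan has no threshold; pass `threshold`")
  tab <- scan@scanTable
  rows <- list()
  for (k in seq_len(nrow(scan@peaks))) {
    pk <- scan@peaks[k, ]
    if (pk$lod < thr) next
    s <- tab[tab$chromosome == pk$chromosome, ]
    ipk <- match(pk$marker_id, s$marker_id)
    keep <- s$lod >= pk$lod - drop
    l <- ipk; while (l > 1 && keep[l - 1]) l <- l - 1
    r <- ipk; while (r < nrow(s) && keep[r + 1]) r <- r + 1
    ve <- fh <- NA_real_
    if (!is.null(h2)) {
      v <- varianceExplained(pk$lod, pk$n, h2)
      ve <- v[["ve"]]; fh <- v[["fraction_of_h2"]]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chromosome = pk$chromosome, left_bp = s$position_bp[l],
      right_bp = s$position_bp[r], peak_marker = pk$marker_id,
      peak_lod = pk$lod, variance_explained = ve, fraction_of_h2 = fh)
  }
  scan@intervals <- if (length(rows)) do.call(rbind, rows) else
    emptyIntervals()
  scan@threshold <- thr
  if (!is.null(threshold) && scan@thresholdMode == "none")
    scan@thresholdMode <- "supplied"
  validObject(scan)
  scan
}

#' Variance explained by a QTL peak
#'
#' Inverts the correlation-LOD formula:
#' \eqn{VE = r^2 = 1 - 10^{-2 LOD / n}}, and divides by the broad-sense
#' heritability to give the fraction of heritable variance the QTL
#' accounts for.
#'
#' @param peak_lod LOD at the peak marker.
#' @param n number of strains behind the LOD score.
#' @param h2 broad-sense heritability in (0, 1].
#' @return named numeric: `ve` and `fraction_of_h2`.
#' @examples
#' varianceExplained(peak_lod = 7, n = 250, h2 = 0.62)
#' @export
varianceExplained <- function(peak_lod, n, h2) {
  if (n < 3) stop("n must be >= 3")
  if (!is.numeric(h2) || h2 <= 0 || h2 > 1)
    stop("h2 must lie in (0, 1]; fraction undefined at h2 = 0")
  ve <- 1 - 10^(-2 * peak_lod / n)
  c(ve = ve, fraction_of_h2 = ve / h2)
}
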
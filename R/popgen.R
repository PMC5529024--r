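#' @include finemap.R
NULL

## Tajima's D normalizing constants for a sample of n sequences
tajimaConstants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D for a sample of biallelic haplotypes
#'
#' \deqn{D = (\pi - S/a_1) / \sqrt{e_1 S + e_2 S (S - 1)}}
#' with the standard normalizing constants, where \eqn{\pi} is the mean
#' number of pairwise differences and `S` the number of segregating
#' sites. Monomorphic sites are removed first. Missing calls are handled
#' site-wise: each site contributes pairwise differences over its
#' non-missing calls only, and segregation is determined on non-missing
#' calls; the constants use the nominal sample size `n`.
#'
#' @param haplotypes matrix of 0/1 (NA allowed) calls, n sequences in
#'   rows, sites in columns; n >= 4.
#' @return Tajima's D; `NA` with attribute `flag = "no segregating
#'   sites"` when S = 0. The attributes `S` and `pi` carry the
#'   intermediate statistics.
#' @examples
#' h <- rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0), c(0, 0, 0))
#' tajimasD(h)
#' @export
tajimasD <- function(haplotypes) {
  h <- as.matrix(haplotypes)
  n <- nrow(h)
  if (n < 4) stop("need >= 4 sequences")
  nc <- colSums(!is.na(h))
  x1 <- colSums(h == 1, na.rm = TRUE)
  x0 <- nc - x1
  seg <- x1 > 0 & x0 > 0 & nc >= 2
  S <- sum(seg)
  if (S == 0)
    return(structure(NA_real_, flag = "no segregating sites", S = 0L,
                     pi = 0))
  # mean pairwise differences, site-wise pairwise-complete
  pi_site <- x1[seg] * x0[seg] / choose(nc[seg], 2)
  pi <- sum(pi_site)
  k <- tajimaConstants(n)
  D <- (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  structure(D, S = as.integer(S), pi = pi)
}

#' Sliding-window Tajima's D over a genotype panel
#'
#' Windows advance in SNV-rank units (`window_snvs` wide, `step_snvs`
#' apart) and never span chromosomes; chromosomes with fewer SNVs than
#' one window are skipped with a warning. The outgroup strain (reference
#' strain by default) is excluded from the sample before computing S and
#' \eqn{\pi} — the statistic needs no polarization, so exclusion simply
#' keeps the reference haplotype out of the within-sample diversity; set
#' `include_outgroup = TRUE` to keep it.
#'
#' @param genotypes a [GenotypeMatrix-class].
#' @param window_snvs window width in SNVs (default 300).
#' @param step_snvs window step in SNVs (default 100).
#' @param outgroup strain id to exclude (default `"N2"`; ignored when
#'   absent from the panel).
#' @param include_outgroup keep the outgroup in the sample (default
#'   `FALSE`).
#' @return data.frame with one row per window: `chromosome`, `window`,
#'   `start_rank`, `end_rank`, `start_bp`, `end_bp`, `bp_midpoint`, `S`,
#'   `pi`, `D`.
#' @export
slidingTajimasD <- function(genotypes, window_snvs = 300, step_snvs = 100,
                            outgroup = "N2", include_outgroup = FALSE) {
  stopifnot(window_snvs >= 1, step_snvs >= 1)
  calls <- genotypeCalls(genotypes)
  if (!include_outgroup && !is.null(outgroup) &&
      outgroup %in% rownames(calls))
    calls <- calls[setdiff(rownames(calls), outgroup), , drop = FALSE]
  mm <- markerMap(genotypes)
  rows <- list()
  for (chr in levels(chromFactor(mm$chromosome))) {
    idx <- which(mm$chromosome == chr)
    nsnv <- length(idx)
    if (nsnv == 0) next
    if (nsnv < window_snvs) {
      warning(sprintf("chromosome %s has %d SNVs (< window of %d): skipped",
                      chr, nsnv, window_snvs))
      next
    }
    starts <- seq(1L, nsnv - window_snvs + 1L, by = step_snvs)
    for (w in seq_along(starts)) {
      a <- starts[w]; b <- a + window_snvs - 1L
      D <- tajimasD(calls[, idx[a:b], drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = chr, window = w, start_rank = a, end_rank = b,
        start_bp = mm$position_bp[idx[a]],
        end_bp = mm$position_bp[idx[b]],
        bp_midpoint = (mm$position_bp[idx[a]] +
                         mm$position_bp[idx[b]]) / 2,
        S = attr(D, "S"), pi = attr(D, "pi"), D = as.numeric(D))
    }
  }
  if (!length(rows))
    return(data.frame(chromosome = character(), window = integer(),
                      start_rank = integer(), end_rank = integer(),
                      start_bp = integer(), end_bp = integer(),
                      bp_midpoint = numeric(), S = integer(),
                      pi = numeric(), D = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
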
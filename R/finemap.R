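#' @include gwas.R
NULL

#' Kinship-correct a phenotype
#'
#' Fits the intercept-only kinship mixed model by [emmaReml()] and removes
#' the polygenic signal. Two modes:
#' \describe{
#'   \item{`blup`}{(default) subtracts the best linear unbiased prediction
#'     of the polygenic effect, \eqn{\hat u = K (K + \hat\delta I)^{-1}
#'     (y - \hat\beta_0)}, returning the pseudo-phenotype
#'     \eqn{y - \hat\beta_0 - \hat u}.}
#'   \item{`whiten`}{pre-multiplies the centered trait by
#'     \eqn{(K + \hat\delta I)^{-1/2}}, fully exchangeable residual
#'     covariance.}
#' }
#' When the REML optimum carries no genetic variance (large delta) the
#' correction degenerates to centering.
#'
#' @param trait strain-trait table.
#' @param K kinship matrix covering the trait's strains.
#' @param method `"blup"` (default) or `"whiten"`.
#' @return strain-trait table of corrected values (same strain order).
#' @export
correctPhenotypeForKinship <- function(trait, K,
                                       method = c("blup", "whiten")) {
  method <- match.arg(method)
  shared <- intersect(trait$strain, rownames(K))
  if (length(shared) < 3) stop("too few strains shared between trait and K")
  y <- trait$value[match(shared, trait$strain)]
  Kc <- K[shared, shared]
  vc <- emmaReml(y, K = Kc)
  centered <- y - vc@beta[1]
  out <- if (method == "blup") {
    u <- Kc %*% solve(Kc + vc@delta * diag(length(y)), centered)
    centered - as.vector(u)
  } else {
    e <- eigen(Kc + vc@delta * diag(length(y)), symmetric = TRUE)
    as.vector(e$vectors %*% (crossprod(e$vectors, centered) /
                               sqrt(pmax(e$values, 1e-12))))
  }
  strainTraitTable(shared, out, trait = trait$trait[1],
                   condition = trait$condition[1])
}

## all permutations of 1..n as a matrix (n <= 8, cached per session)
permCache <- new.env(parent = emptyenv())
allPermutations <- function(n) {
  key <- as.character(n)
  if (!is.null(permCache[[key]])) return(permCache[[key]])
  rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], rec(v[-i]))))
  }
  P <- rec(seq_len(n))
  permCache[[key]] <- P
  P
}

## Spearman rho (average ranks) with a two-sided p: exact permutation
## enumeration for n <= 8, t approximation otherwise
spearmanTest <- function(g, y) {
  n <- length(g)
  rg <- rank(g); ry <- rank(y)
  rho <- cor(rg, ry)
  if (n <= 8) {
    P <- allPermutations(n)
    rgc <- rg - mean(rg)
    ryp <- matrix(ry[P], nrow(P), n) # rows: permuted ranks
    stat <- as.vector(ryp %*% rgc)   # proportional to rho per permutation
    obs <- sum(ry * rgc)
    p <- mean(abs(stat) >= abs(obs) - 1e-9)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = min(p, 1))
}

#' Spearman fine mapping of annotated variants
#'
#' For each variant whose predicted effect class passes the filter,
#' computes Spearman's rho between the variant genotype and the
#' (kinship-corrected) phenotype over pairwise-complete strains (average
#' ranks for ties — genotype vectors are binary, so ties are the rule),
#' with its two-sided p-value: exact by full enumeration of the rank
#' permutation distribution for n <= 8, Student-t approximation
#' otherwise. Variants with
#' constant genotype over the scored strains are excluded (rho
#' undefined), as are variants with fewer than `min_strains` complete
#' pairs. Results are sorted by genomic position.
#'
#' @param variants annotated variant table: metadata columns
#'   `variant_id`, `chromosome`, `position_bp`, `gene`, `effect_class`
#'   (HIGH/MODERATE/LOW/MODIFIER), plus one 0/1/NA genotype column per
#'   strain (see [readAnnotatedVariants()]).
#' @param corrected_trait strain-trait table (typically from
#'   [correctPhenotypeForKinship()]).
#' @param effect_filter effect classes retained
#'   (default `c("HIGH", "MODERATE")`).
#' @param min_strains minimum complete pairs per variant (default 5).
#' @return data.frame per retained variant: `variant_id`, `chromosome`,
#'   `position_bp`, `gene`, `effect_class`, `n`, `rho`, `p_value`,
#'   `negLog10P`.
#' @export
variantCorrelation <- function(variants, corrected_trait,
                               effect_filter = c("HIGH", "MODERATE"),
                               min_strains = 5) {
  meta_cols <- c("variant_id", "chromosome", "position_bp", "gene",
                 "effect_class")
  stopifnot(all(meta_cols %in% names(variants)))
  strain_cols <- intersect(names(variants), corrected_trait$strain)
  keep <- variants$effect_class %in% effect_filter
  variants <- variants[keep, , drop = FALSE]
  empty <- data.frame(variant_id = character(), chromosome = character(),
                      position_bp = integer(), gene = character(),
                      effect_class = character(), n = integer(),
                      rho = numeric(), p_value = numeric(),
                      negLog10P = numeric())
  if (nrow(variants) == 0) {
    warning("all variants removed by the effect-class filter")
    return(empty)
  }
  y_all <- corrected_trait$value[match(strain_cols, corrected_trait$strain)]
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    g <- as.numeric(variants[i, strain_cols])
    ok <- !is.na(g) & !is.na(y_all)
    n <- sum(ok)
    if (n < min_strains) return(NULL)
    if (sd(g[ok]) == 0) return(NULL)
    sp <- spearmanTest(g[ok], y_all[ok])
    p <- min(max(sp$p, 1e-300), 1)
    data.frame(variant_id = variants$variant_id[i],
               chromosome = variants$chromosome[i],
               position_bp = variants$position_bp[i],
               gene = variants$gene[i],
               effect_class = variants$effect_class[i],
               n = n, rho = sp$rho, p_value = p,
               negLog10P = -log10(p))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("no variant had enough non-constant, complete genotype calls")
    return(empty)
  }
  out <- do.call(rbind, rows)
  out <- out[order(as.integer(chromFactor(out$chromosome)),
                   out$position_bp), ]
  rownames(out) <- NULL
  out
}
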
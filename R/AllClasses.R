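#' @import methods
#' @importFrom stats as.formula aov TukeyHSD anova coef cor cor.test fisher.test
#'   lm median optimize pbinom pnorm pt quantile resid rbinom rnorm rpois runif
#'   rbeta sd setNames var complete.cases
#' @importFrom utils read.csv read.delim write.csv write.table head
NULL

## Chromosome handling ---------------------------------------------------

#' Karyotype-ordered chromosome factor
#'
#' Orders *C. elegans* chromosome labels I-V then X; unknown labels are
#' appended in lexical order so the package also works on other genomes.
#'
#' @param x character vector of chromosome labels.
#' @return factor with karyotype-ordered levels.
#' @export
chromFactor <- function(x) {
  x <- as.character(x)
  canonical <- c("I", "II", "III", "IV", "V", "X")
  extra <- sort(setdiff(unique(x), canonical))
  factor(x, levels = c(canonical[canonical %in% x | canonical %in% unique(x)],
                       extra))
}

validateMarkerMap <- function(markers) {
  required <- c("marker_id", "chromosome", "position_bp", "genetic_pos_cM")
  if (!is.data.frame(markers) || nrow(markers) == 0L)
    return("marker map must be a non-empty data.frame")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols) > 0L)
    return(paste("marker map lacks columns:", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(markers$marker_id))
    return("duplicated marker_id values")
  if (any(markers$position_bp < 1))
    return("position_bp must be >= 1 (1-based)")
  if (any(markers$genetic_pos_cM < 0))
    return("genetic_pos_cM must be non-negative")
  for (chr in unique(markers$chromosome)) {
    sub <- markers[markers$chromosome == chr, ]
    if (is.unsorted(sub$position_bp, strictly = TRUE))
      return(sprintf("positions not strictly increasing on chromosome %s", chr))
    if (is.unsorted(sub$genetic_pos_cM))
      return(sprintf("genetic positions not non-decreasing on chromosome %s", chr))
  }
  TRUE
}

sortMarkerMap <- function(markers) {
  chr <- chromFactor(markers$chromosome)
  ord <- order(as.integer(chr), markers$position_bp)
  markers <- markers[ord, , drop = FALSE]
  markers$chromosome <- as.character(markers$chromosome)
  rownames(markers) <- NULL
  markers
}

## GenotypeMatrix --------------------------------------------------------

#' GenotypeMatrix: inbred strains by biallelic markers
#'
#' Container for homozygous-inbred genotype calls. Calls are coded
#' `0` = reference (Bristol-like) allele, `1` = alternate allele, `NA` =
#' missing; heterozygous calls are disallowed (isotype / recombinant inbred
#' panels are effectively homozygous).
#'
#' @slot calls integer matrix, strains in rows (rownames = strain ids),
#'   markers in columns (colnames = marker ids), values in \{0, 1, NA\}.
#' @slot markers data.frame marker map with columns `marker_id`,
#'   `chromosome`, `position_bp` (1-based), `genetic_pos_cM`; one row per
#'   column of `calls`, sorted in karyotype order with strictly increasing
#'   physical positions per chromosome.
#' @export
setClass("GenotypeMatrix",
  representation(calls = "matrix", markers = "data.frame"),
  validity = function(object) {
    msg <- validateMarkerMap(object@markers)
    if (!isTRUE(msg)) return(msg)
    if (ncol(object@calls) != nrow(object@markers))
      return("ncol(calls) != nrow(markers)")
    if (!identical(colnames(object@calls), object@markers$marker_id))
      return("colnames(calls) must equal markers$marker_id")
    if (is.null(rownames(object@calls)))
      return("calls must carry strain ids as rownames")
    vals <- object@calls[!is.na(object@calls)]
    if (length(vals) && !all(vals %in% c(0L, 1L)))
      return("calls must be 0, 1 or NA (no heterozygotes)")
    TRUE
  })

#' Construct a GenotypeMatrix
#'
#' Markers are re-sorted deterministically by (chromosome, position) in
#' karyotype order and the call columns reordered to match.
#'
#' @param calls numeric/integer matrix of 0/1/NA calls with strain rownames
#'   and marker colnames.
#' @param markers marker map data.frame (see [GenotypeMatrix-class]).
#' @return a [GenotypeMatrix-class] object.
#' @examples
#' mm <- data.frame(marker_id = c("m1", "m2"), chromosome = "I",
#'                  position_bp = c(100L, 200L), genetic_pos_cM = c(0, 1))
#' g <- matrix(c(0L, 1L, 1L, 0L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("m1", "m2")))
#' GenotypeMatrix(g, mm)
#' @export
GenotypeMatrix <- function(calls, markers) {
  if (is.null(dim(calls))) stop("calls must be a matrix")
  markers <- sortMarkerMap(as.data.frame(markers))
  storage.mode(calls) <- "integer"
  if (is.null(colnames(calls))) colnames(calls) <- markers$marker_id
  calls <- calls[, markers$marker_id, drop = FALSE]
  new("GenotypeMatrix", calls = calls, markers = markers)
}

## ScanResult ------------------------------------------------------------

#' ScanResult: genome-scan statistics with thresholds, peaks and intervals
#'
#' @slot scanTable data.frame with one row per marker: `marker_id`,
#'   `chromosome`, `position_bp`, `lod`, `n` (complete pairs used).
#' @slot threshold numeric genome-wide significance threshold (LOD units;
#'   `NA` if none computed).
#' @slot thresholdMode character, `"max-lod-quantile"` or `"peak-ratio"`.
#' @slot peaks data.frame of per-chromosome maxima (one retained peak per
#'   chromosome): `chromosome`, `marker_id`, `position_bp`, `lod`, `n`.
#' @slot intervals data.frame of 1.5-LOD-drop (or custom drop) intervals:
#'   `chromosome`, `left_bp`, `right_bp`, `peak_marker`, `peak_lod`,
#'   `variance_explained`, `fraction_of_h2`.
#' @slot trait character trait label.
#' @export
setClass("ScanResult",
  representation(scanTable = "data.frame", threshold = "numeric",
                 thresholdMode = "character", peaks = "data.frame",
                 intervals = "data.frame", trait = "character"),
  validity = function(object) {
    need <- c("marker_id", "chromosome", "position_bp", "lod")
    if (!all(need %in% names(object@scanTable)))
      return("scanTable lacks required columns")
    if (any(object@scanTable$lod < -1e-12, na.rm = TRUE))
      return("LOD scores must be non-negative")
    if (nrow(object@peaks) &&
        anyDuplicated(object@peaks$chromosome))
      return("at most one retained peak per chromosome")
    TRUE
  })

## GwaResult -------------------------------------------------------------

#' GwaResult: mixed-model association scan
#'
#' @slot gwaTable data.frame per tested marker (MAF-filtered): `marker_id`,
#'   `chromosome`, `position_bp`, `maf`, `effect`, `negLog10P`,
#'   `significant`.
#' @slot bonferroni numeric Bonferroni threshold on the -log10(p) scale.
#' @slot alpha numeric family-wise alpha used.
#' @slot regions data.frame regions of interest: `chromosome`, `left_bp`,
#'   `right_bp`, `left_rank`, `right_rank`, `n_significant`,
#'   `peak_marker`.
#' @export
setClass("GwaResult",
  representation(gwaTable = "data.frame", bonferroni = "numeric",
                 alpha = "numeric", regions = "data.frame"),
  validity = function(object) {
    need <- c("marker_id", "chromosome", "position_bp", "maf", "negLog10P")
    if (!all(need %in% names(object@gwaTable)))
      return("gwaTable lacks required columns")
    if (any(object@gwaTable$negLog10P < 0, na.rm = TRUE))
      return("-log10 p must be non-negative")
    TRUE
  })

## VarianceComponents ----------------------------------------------------

#' VarianceComponents: REML variance components of the kinship mixed model
#'
#' Components of \eqn{y = X\beta + u + e}, \eqn{u \sim (0, \sigma^2_g K)},
#' \eqn{e \sim (0, \sigma^2_e I)}.
#'
#' @slot sigma2G numeric genetic variance (>= 0).
#' @slot sigma2E numeric residual variance (>= 0).
#' @slot delta numeric variance ratio \eqn{\sigma^2_e/\sigma^2_g} (can be
#'   `Inf` when the genetic variance is 0).
#' @slot remlLogLik numeric maximised restricted log-likelihood.
#' @slot beta numeric fixed-effect estimates at the optimum.
#' @slot note character diagnostic flag ("" when clean).
#' @export
setClass("VarianceComponents",
  representation(sigma2G = "numeric", sigma2E = "numeric", delta = "numeric",
                 remlLogLik = "numeric", beta = "numeric", note = "character"),
  validity = function(object) {
    if (object@sigma2G < 0 || object@sigma2E < 0)
      return("variance components must be non-negative")
    TRUE
  })

## HeritabilityEstimate --------------------------------------------------

#' HeritabilityEstimate: broad-sense heritability from replicated strains
#'
#' @slot H2 numeric in `[0, 1]`, `varStrain / (varStrain + varResid)`.
#' @slot varStrain numeric among-strain variance component (>= 0).
#' @slot varResid numeric within-strain residual variance (>= 0).
#' @slot note character diagnostic flag ("" when clean).
#' @export
setClass("HeritabilityEstimate",
  representation(H2 = "numeric", varStrain = "numeric", varResid = "numeric",
                 note = "character"),
  validity = function(object) {
    if (object@varStrain < 0 || object@varResid < 0)
      return("variance components must be non-negative")
    tot <- object@varStrain + object@varResid
    if (tot > 0 && abs(object@H2 - object@varStrain / tot) > 1e-8)
      return("H2 must equal varStrain/(varStrain+varResid)")
    if (object@H2 < 0 || object@H2 > 1) return("H2 must lie in [0, 1]")
    TRUE
  })
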
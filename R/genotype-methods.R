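#' @include AllGenerics.R
NULL

#' @rdname genotype-accessors
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)

#' @rdname genotype-accessors
#' @export
setMethod("markerMap", "GenotypeMatrix", function(x) x@markers)

#' @rdname genotype-accessors
#' @export
setMethod("strainNames", "GenotypeMatrix", function(x) rownames(x@calls))

#' @rdname genotype-accessors
#' @export
setMethod("nStrains", "GenotypeMatrix", function(x) nrow(x@calls))

#' @rdname genotype-accessors
#' @export
setMethod("nMarkers", "GenotypeMatrix", function(x) ncol(x@calls))

#' @rdname genotype-accessors
#' @export
setMethod("alleleFreq", "GenotypeMatrix", function(x)
  colMeans(x@calls, na.rm = TRUE))

#' @rdname genotype-accessors
#' @export
setMethod("minorAlleleFreq", "GenotypeMatrix", function(x) {
  f <- alleleFreq(x)
  pmin(f, 1 - f)
})

#' Subset a GenotypeMatrix
#'
#' `x[i, j]` subsets strains (`i`) and/or markers (`j`); the marker map is
#' kept in sync.
#'
#' @param x a [GenotypeMatrix-class].
#' @param i strain index (integer, logical or strain id).
#' @param j marker index (integer, logical or marker id).
#' @param ... ignored.
#' @param drop ignored (never drops).
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  calls <- x@calls
  markers <- x@markers
  if (!missing(j)) {
    if (is.character(j)) j <- match(j, colnames(calls))
    calls <- calls[, j, drop = FALSE]
    markers <- markers[match(colnames(calls), markers$marker_id), , drop = FALSE]
    rownames(markers) <- NULL
  }
  if (!missing(i)) calls <- calls[i, , drop = FALSE]
  new("GenotypeMatrix", calls = calls, markers = markers)
})

setMethod("show", "GenotypeMatrix", function(object) {
  chroms <- table(chromFactor(object@markers$chromosome))
  cat(sprintf("GenotypeMatrix: %d strains x %d markers\n",
              nStrains(object), nMarkers(object)))
  cat("  markers per chromosome:",
      paste(sprintf("%s=%d", names(chroms), chroms), collapse = " "), "\n")
  nmiss <- sum(is.na(object@calls))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nmiss,
              100 * nmiss / length(object@calls)))
})

#' @rdname scan-accessors
#' @export
setMethod("scanTable", "ScanResult", function(x) x@scanTable)
#' @rdname scan-accessors
#' @export
setMethod("peaks", "ScanResult", function(x) x@peaks)
#' @rdname scan-accessors
#' @export
setMethod("intervals", "ScanResult", function(x) x@intervals)
#' @rdname scan-accessors
#' @export
setMethod("threshold", "ScanResult", function(x) x@threshold)

setMethod("show", "ScanResult", function(object) {
  cat(sprintf("ScanResult (%s): %d markers, max LOD = %.3f\n",
              object@trait, nrow(object@scanTable),
              suppressWarnings(max(object@scanTable$lod, na.rm = TRUE))))
  if (!is.na(object@threshold))
    cat(sprintf("  threshold (%s): %.3f\n", object@thresholdMode,
                object@threshold))
  if (nrow(object@intervals)) {
    cat("  QTL intervals:\n")
    print(object@intervals)
  }
})

#' @rdname scan-accessors
#' @export
setMethod("gwaTable", "GwaResult", function(x) x@gwaTable)
#' @rdname scan-accessors
#' @export
setMethod("regions", "GwaResult", function(x) x@regions)
#' @rdname scan-accessors
#' @export
setMethod("threshold", "GwaResult", function(x) x@bonferroni)

setMethod("show", "GwaResult", function(object) {
  cat(sprintf("GwaResult: %d markers tested, Bonferroni -log10(p) = %.3f\n",
              nrow(object@gwaTable), object@bonferroni))
  cat(sprintf("  significant markers: %d; regions of interest: %d\n",
              sum(object@gwaTable$significant), nrow(object@regions)))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf(
    "VarianceComponents: sigma2_g = %.4g, sigma2_e = %.4g (delta = %.4g)\n",
    object@sigma2G, object@sigma2E, object@delta))
  cat(sprintf("  REML log-likelihood: %.6g%s\n", object@remlLogLik,
              if (nzchar(object@note)) paste0(" [", object@note, "]") else ""))
})

setMethod("show", "HeritabilityEstimate", function(object) {
  cat(sprintf("HeritabilityEstimate: H2 = %.3f (var_strain = %.4g, var_resid = %.4g)%s\n",
              object@H2, object@varStrain, object@varResid,
              if (nzchar(object@note)) paste0(" [", object@note, "]") else ""))
})
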
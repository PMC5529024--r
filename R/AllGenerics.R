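#' @include AllClasses.R
NULL

#' Accessors for GenotypeMatrix
#'
#' `genotypeCalls` returns the strains x markers call matrix,
#' `markerMap` the marker map, `strainNames` the strain ids,
#' `nStrains`/`nMarkers` the panel dimensions, `alleleFreq` the per-marker
#' frequency of the alternate (coded 1) allele ignoring missing calls, and
#' `minorAlleleFreq` `pmin(f, 1 - f)`.
#'
#' @param x a [GenotypeMatrix-class].
#' @return see description.
#' @name genotype-accessors
#' @aliases genotypeCalls markerMap strainNames nStrains nMarkers alleleFreq
#'   minorAlleleFreq
NULL

#' @rdname genotype-accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname genotype-accessors
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))
#' @rdname genotype-accessors
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))
#' @rdname genotype-accessors
#' @export
setGeneric("nStrains", function(x) standardGeneric("nStrains"))
#' @rdname genotype-accessors
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
#' @rdname genotype-accessors
#' @export
setGeneric("alleleFreq", function(x) standardGeneric("alleleFreq"))
#' @rdname genotype-accessors
#' @export
setGeneric("minorAlleleFreq", function(x) standardGeneric("minorAlleleFreq"))

#' Accessors for scan and association results
#'
#' @param x a [ScanResult-class] or [GwaResult-class].
#' @return `scanTable`/`gwaTable` return the per-marker data.frame,
#'   `peaks` the retained per-chromosome peaks, `intervals` /`regions` the
#'   confidence intervals or regions of interest, `threshold` the
#'   genome-wide significance cutoff.
#' @name scan-accessors
#' @aliases scanTable peaks intervals threshold gwaTable regions
NULL

#' @rdname scan-accessors
#' @export
setGeneric("scanTable", function(x) standardGeneric("scanTable"))
#' @rdname scan-accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @rdname scan-accessors
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))
#' @rdname scan-accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))
#' @rdname scan-accessors
#' @export
setGeneric("gwaTable", function(x) standardGeneric("gwaTable"))
#' @rdname scan-accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
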
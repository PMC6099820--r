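#' @rdname ConnectivityMatrix-class
#' @param x a ConnectivityMatrix.
#' @export
setGeneric("probMatrix", function(x) standardGeneric("probMatrix"))

#' @rdname EigenvectorBasis-class
#' @param x an EigenvectorBasis.
#' @export
setGeneric("basisVectors", function(x) standardGeneric("basisVectors"))

#' @rdname EigenvectorBasis-class
#' @export
setGeneric("basisValues", function(x) standardGeneric("basisValues"))

#' @rdname EigenvectorBasis-class
#' @export
setGeneric("basisKind", function(x) standardGeneric("basisKind"))

#' @rdname EigenvectorBasis-class
#' @export
setGeneric("basisScales", function(x) standardGeneric("basisScales"))

#' @rdname SitesByEdges-class
#' @param x a SitesByEdges.
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' @rdname SitesByEdges-class
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))

#' @rdname SitesByEdges-class
#' @export
setGeneric("rootSites", function(x) standardGeneric("rootSites"))

#' @rdname PredictorSet-class
#' @param x a PredictorSet.
#' @export
setGeneric("predictorMatrix", function(x) standardGeneric("predictorMatrix"))

#' @rdname PredictorSet-class
#' @export
setGeneric("predictorFamily", function(x) standardGeneric("predictorFamily"))

#' @rdname AlleleFreqSet-class
#' @param x an AlleleFreqSet.
#' @export
setGeneric("freqMatrix", function(x) standardGeneric("freqMatrix"))

#' @rdname AlleleFreqSet-class
#' @export
setGeneric("poolSizes", function(x) standardGeneric("poolSizes"))

#' @rdname AlleleFreqSet-class
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))

#' @rdname AlleleFreqSet-class
#' @export
setGeneric("lociIds", function(x) standardGeneric("lociIds"))
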
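#' Accessors for Ki67Global S4 objects
#'
#' Accessor generics so user code never touches slots directly:
#' \code{area()} returns the assessed area in mm^2, \code{piPercent()} the
#' proliferation index, \code{hScore()} the H-score, \code{classCounts()} the
#' four class counts, \code{positiveDensity()} / \code{strongDensity()} the
#' densities per mm^2, \code{positiveCount()} the hotspot window count,
#' \code{stainVectors()} the 3x3 stain matrix, \code{roiMask()} the rasterised
#' mask, \code{truthNuclei()} / \code{truthSummary()} the planted ground truth,
#' and \code{pValue()} / \code{effectSize()} the test outcome.
#'
#' @param x an S4 object from this package.
#' @return the corresponding value; see details per method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("area", function(x) standardGeneric("area"))
#' @rdname accessors
#' @export
setMethod("area", "ROISet", function(x) x@areaMm2)
#' @rdname accessors
#' @export
setMethod("area", "SlideMetrics", function(x) x@areaMm2)

#' @rdname accessors
#' @export
setGeneric("piPercent", function(x) standardGeneric("piPercent"))
#' @rdname accessors
#' @export
setMethod("piPercent", "SlideMetrics", function(x) x@piPercent)

#' @rdname accessors
#' @export
setGeneric("hScore", function(x) standardGeneric("hScore"))
#' @rdname accessors
#' @export
setMethod("hScore", "SlideMetrics", function(x) x@hScore)

#' @rdname accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))
#' @rdname accessors
#' @export
setMethod("classCounts", "SlideMetrics", function(x)
  c(negative = x@nNegative, weak = x@nWeak,
    moderate = x@nModerate, strong = x@nStrong))

#' @rdname accessors
#' @export
setGeneric("positiveDensity", function(x) standardGeneric("positiveDensity"))
#' @rdname accessors
#' @export
setMethod("positiveDensity", "SlideMetrics", function(x) x@positiveDensity)

#' @rdname accessors
#' @export
setGeneric("strongDensity", function(x) standardGeneric("strongDensity"))
#' @rdname accessors
#' @export
setMethod("strongDensity", "SlideMetrics", function(x) x@strongDensity)

#' @rdname accessors
#' @export
setGeneric("positiveCount", function(x) standardGeneric("positiveCount"))
#' @rdname accessors
#' @export
setMethod("positiveCount", "HotspotResult", function(x) x@positiveCount)

#' @rdname accessors
#' @export
setGeneric("stainVectors", function(x) standardGeneric("stainVectors"))
#' @rdname accessors
#' @export
setMethod("stainVectors", "StainBasis", function(x) x@vectors)

#' @rdname accessors
#' @export
setGeneric("roiMask", function(x) standardGeneric("roiMask"))
#' @rdname accessors
#' @export
setMethod("roiMask", "ROISet", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("truthNuclei", function(x) standardGeneric("truthNuclei"))
#' @rdname accessors
#' @export
setMethod("truthNuclei", "GroundTruth", function(x) x@nuclei)

#' @rdname accessors
#' @export
setGeneric("truthSummary", function(x) standardGeneric("truthSummary"))
#' @rdname accessors
#' @export
setMethod("truthSummary", "GroundTruth", function(x) x@summary)

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setMethod("pValue", "TestResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setGeneric("effectSize", function(x) standardGeneric("effectSize"))
#' @rdname accessors
#' @export
setMethod("effectSize", "TestResult", function(x) x@effect)
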
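#' @describeIn StainBasis-class print the stain vectors
#' @param object a \code{StainBasis}
#' @export
setMethod("show", "StainBasis", function(object) {
  cat("StainBasis (rows are unit OD vectors)\n")
  print(round(object@vectors, 4))
})

#' @describeIn ROISet-class brief summary
#' @param object a \code{ROISet}
#' @export
setMethod("show", "ROISet", function(object) {
  cat(sprintf(
    "ROISet: %d tumour / %d exclusion polygon(s), mask %d x %d px, %.4f mm2\n",
    length(object@tumour), length(object@exclusions),
    nrow(object@mask), ncol(object@mask), object@areaMm2))
})

#' @describeIn SlideMetrics-class brief summary
#' @param object a \code{SlideMetrics}
#' @export
setMethod("show", "SlideMetrics", function(object) {
  cat(sprintf("SlideMetrics '%s'\n", object@slideId))
  cat(sprintf("  area: %.4f mm2, nuclei: %d (neg %d / weak %d / mod %d / strong %d)\n",
              object@areaMm2, object@nTotal, object@nNegative, object@nWeak,
              object@nModerate, object@nStrong))
  cat(sprintf("  PI: %.1f%%  H-score: %.1f  positive: %.1f/mm2  strong: %.1f/mm2\n",
              object@piPercent, object@hScore, object@positiveDensity,
              object@strongDensity))
})

#' @describeIn QualityScores-class brief summary
#' @param object a \code{QualityScores}
#' @export
setMethod("show", "QualityScores", function(object) {
  cat(sprintf("QualityScores: tissue %d, inflammation %d, segmentation %d\n",
              object@tissue, object@inflammation, object@segmentation))
})

#' @describeIn HotspotResult-class brief summary
#' @param object a \code{HotspotResult}
#' @export
setMethod("show", "HotspotResult", function(object) {
  cat(sprintf(
    "HotspotResult: %d positives in %.4f mm2 window at (%.1f, %.1f) um\n",
    object@positiveCount, object@windowAreaMm2,
    object@windowOriginUm[1], object@windowOriginUm[2]))
  cat(sprintf("  density %.1f/mm2, Webster category '%s', proliferation factor %s\n",
              object@hotspotDensity, object@websterCategory,
              ifelse(is.na(object@proliferationFactor), "NA",
                     sprintf("%.2f", object@proliferationFactor))))
})

#' @describeIn SlideSpec-class brief summary
#' @param object a \code{SlideSpec}
#' @export
setMethod("show", "SlideSpec", function(object) {
  cat(sprintf("SlideSpec: %d x %d px @ %.2f um/px, %d nuclei, law '%s', seed %d\n",
              object@widthPx, object@heightPx, object@micronsPerPixel,
              object@nNuclei, object@spatialLaw$type, object@seed))
  cat("  quotas:", paste(sprintf("%s %.3f", names(object@classQuotas),
                                 object@classQuotas), collapse = ", "), "\n")
})

#' @describeIn GroundTruth-class brief summary
#' @param object a \code{GroundTruth}
#' @export
setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d planted nuclei (%d inflammatory)\n",
              nrow(object@nuclei), sum(object@nuclei$inflammatory)))
  show(object@summary)
})

#' @describeIn TestResult-class brief summary
#' @param object a \code{TestResult}
#' @export
setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult: %s\n", object@test))
  cat(sprintf("  statistic %.4g, p %.4g", object@statistic, object@pValue))
  if (!is.na(object@effect)) {
    cat(sprintf(", effect %.4g", object@effect))
    if (!is.na(object@ciLower))
      cat(sprintf(" (95%% CI %.4g-%.4g)", object@ciLower, object@ciUpper))
  }
  cat("\n")
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})
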
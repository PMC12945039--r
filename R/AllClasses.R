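#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib Ki67Global, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## StainBasis
## ---------------------------------------------------------------------------

#' Stain basis for H-DAB colour deconvolution
#'
#' Three unit-norm optical-density direction vectors (hematoxylin, DAB and a
#' residual channel), stored as rows of a 3x3 matrix. Rows are re-normalised
#' on construction. The matrix must be well conditioned (condition number
#' below 1e6) and non-negative.
#'
#' @slot vectors 3x3 numeric matrix, one stain vector per row, rows named
#'   \code{hematoxylin}, \code{dab}, \code{residual}, columns \code{r,g,b}.
#' @seealso [hdabBasis()], [separateStains()]
#' @export
setClass("StainBasis", representation(vectors = "matrix"))

setValidity("StainBasis", function(object) {
  v <- object@vectors
  if (!is.numeric(v) || !identical(dim(v), c(3L, 3L)))
    return("stain basis must be a numeric 3x3 matrix")
  if (any(!is.finite(v)) || any(v < 0))
    return("stain vectors must be finite and non-negative")
  nrm <- sqrt(rowSums(v^2))
  if (any(abs(nrm - 1) > 1e-8))
    return("stain vectors must have unit norm")
  if (.condNumber(v) >= 1e6)
    return("stain matrix is ill-conditioned (condition number >= 1e6)")
  TRUE
})

## 2-norm condition number; Inf for exactly singular matrices
.condNumber <- function(m) {
  s <- svd(m, nu = 0, nv = 0)$d
  if (min(s) == 0) Inf else max(s) / min(s)
}

## ---------------------------------------------------------------------------
## ROISet
## ---------------------------------------------------------------------------

#' Region-of-interest set
#'
#' Tumour outline polygon(s) minus exclusion polygon(s), rasterised to a
#' boolean mask at image resolution. Polygons live in 0-based pixel
#' coordinates (x rightward, y downward); the mask is a matrix indexed
#' \code{[y, x]}. The assessed area in mm^2 is the true-pixel count times
#' the squared pixel pitch.
#'
#' @slot tumour list of Nx2 matrices (pixel-space polygon rings).
#' @slot exclusions list of Nx2 matrices.
#' @slot exclusionCategories character vector, one per exclusion polygon
#'   (e.g. \code{adnexa}, \code{vessel}, \code{adipose}, \code{lymphoid},
#'   \code{artefact}, \code{ulcer}).
#' @slot mask logical matrix \code{[height, width]}.
#' @slot micronsPerPixel positive scalar.
#' @slot areaMm2 assessed area in mm^2.
#' @seealso [loadROI()], [roiFromPolygons()], [filterNuclei()]
#' @export
setClass("ROISet", representation(
  tumour = "list",
  exclusions = "list",
  exclusionCategories = "character",
  mask = "matrix",
  micronsPerPixel = "numeric",
  areaMm2 = "numeric"
))

setValidity("ROISet", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (length(object@micronsPerPixel) != 1L || object@micronsPerPixel <= 0)
    return("micronsPerPixel must be a positive scalar")
  expect <- sum(object@mask) * object@micronsPerPixel^2 / 1e6
  if (abs(object@areaMm2 - expect) > 1e-9 * max(1, expect))
    return("areaMm2 inconsistent with mask true-pixel count")
  TRUE
})

## ---------------------------------------------------------------------------
## SlideMetrics
## ---------------------------------------------------------------------------

#' Per-slide Ki-67 metrics
#'
#' Class counts, proliferation index (percentage of positive nuclei among all
#' assessed nuclei), H-score (1 x \%weak + 2 x \%moderate + 3 x \%strong,
#' range 0-300) and positive / strong nuclear densities per mm^2 of assessed
#' tumour tissue.
#'
#' @slot slideId character scalar.
#' @slot areaMm2 assessed area, mm^2.
#' @slot nNegative,nWeak,nModerate,nStrong,nTotal,nPositive class counts.
#' @slot piPercent proliferation index, 0-100.
#' @slot hScore H-score, 0-300.
#' @slot positiveDensity positive nuclei per mm^2.
#' @slot strongDensity strongly positive nuclei per mm^2.
#' @seealso [summarizeSlide()]
#' @export
setClass("SlideMetrics", representation(
  slideId = "character",
  areaMm2 = "numeric",
  nNegative = "integer",
  nWeak = "integer",
  nModerate = "integer",
  nStrong = "integer",
  nTotal = "integer",
  nPositive = "integer",
  piPercent = "numeric",
  hScore = "numeric",
  positiveDensity = "numeric",
  strongDensity = "numeric"
))

setValidity("SlideMetrics", function(object) {
  cnt <- c(object@nNegative, object@nWeak, object@nModerate, object@nStrong)
  if (any(cnt < 0)) return("class counts must be non-negative")
  if (object@nTotal != sum(cnt)) return("nTotal must equal the class count sum")
  if (object@nPositive != object@nWeak + object@nModerate + object@nStrong)
    return("nPositive must equal nWeak + nModerate + nStrong")
  eps <- 1e-9
  if (object@piPercent > object@hScore + eps ||
      object@hScore > 3 * object@piPercent + eps)
    return("H-score must satisfy PI <= H <= 3 PI")
  if (object@strongDensity > object@positiveDensity + eps)
    return("strong density cannot exceed positive density")
  TRUE
})

## ---------------------------------------------------------------------------
## QualityScores
## ---------------------------------------------------------------------------

#' Slide quality scores
#'
#' Three-axis quality rubric: tissue section completeness, inflammation and
#' nuclear segmentation, each scored 0 (worst) to 2 (best).
#'
#' @slot tissue,inflammation,segmentation integer in \{0, 1, 2\}.
#' @seealso [scoreTissue()], [scoreInflammation()], [scoreSegmentation()]
#' @export
setClass("QualityScores", representation(
  tissue = "integer", inflammation = "integer", segmentation = "integer"
))

setValidity("QualityScores", function(object) {
  v <- c(object@tissue, object@inflammation, object@segmentation)
  if (length(v) != 3L || any(!v %in% 0:2))
    return("each quality score must be 0, 1 or 2")
  TRUE
})

## ---------------------------------------------------------------------------
## HotspotResult
## ---------------------------------------------------------------------------

#' Hotspot search result
#'
#' The axis-aligned square window of fixed area (0.3125 mm^2) maximising the
#' count of Ki-67-positive nucleus centroids, with the Webster category
#' (low when count <= 23, high when count > 23), the hotspot density
#' (count / 0.3125 per mm^2) and the proliferation factor (hotspot density
#' over global strong-positive density; NA when the latter is zero).
#'
#' @slot windowOriginUm window origin (x, y) in microns.
#' @slot windowAreaMm2 window area, always 0.3125.
#' @slot positiveCount positive centroids inside the window.
#' @slot hotspotDensity positives per mm^2 of window.
#' @slot websterCategory \code{"low"} or \code{"high"}.
#' @slot proliferationFactor numeric; NA when undefined.
#' @seealso [findHotspot()], [websterCategory()], [proliferationFactor()]
#' @export
setClass("HotspotResult", representation(
  windowOriginUm = "numeric",
  windowAreaMm2 = "numeric",
  positiveCount = "integer",
  hotspotDensity = "numeric",
  websterCategory = "character",
  proliferationFactor = "numeric"
))

setValidity("HotspotResult", function(object) {
  if (object@positiveCount < 0) return("positiveCount must be non-negative")
  if (abs(object@hotspotDensity -
          object@positiveCount / object@windowAreaMm2) > 1e-9)
    return("hotspotDensity must equal positiveCount / window area")
  want <- if (object@positiveCount > 23L) "high" else "low"
  if (!identical(object@websterCategory, want))
    return("websterCategory inconsistent with positiveCount")
  TRUE
})

## ---------------------------------------------------------------------------
## SlideSpec / GroundTruth
## ---------------------------------------------------------------------------

#' Synthetic slide specification
#'
#' Fully determines a synthetic H-DAB slide: geometry, nucleus count, class
#' quotas (negative, weak, moderate, strong; exact largest-remainder
#' apportionment), per-class pseudo-intensity bands (each strictly inside the
#' corresponding classification band so the planted class is recoverable),
#' nucleus radius range, spatial law, inflammation fraction, exclusion
#' polygons, and the seed of the slide's private random stream.
#'
#' @slot widthPx,heightPx image size in pixels.
#' @slot micronsPerPixel pixel pitch (default 0.23).
#' @slot nNuclei number of (non-inflammatory) nuclei.
#' @slot classQuotas named numeric of length 4 summing to 1.
#' @slot intensityBands 4x2 matrix of per-class intensity intervals.
#' @slot nucleusRadiusUm length-2 (min, max) nucleus radius in microns.
#' @slot spatialLaw list: \code{list(type = "uniform")} or
#'   \code{list(type = "clustered", centerUm =, radiusUm =, enrichment =)}.
#' @slot inflammationFraction fraction of all nuclei that are small,
#'   weakly staining inflammatory stand-ins.
#' @slot exclusionPolygons list of pixel-space polygons.
#' @slot seed integer seed.
#' @slot hotspotPlan empty list, or \code{list(originUm =, count =)} set by
#'   [plantHotspot()].
#' @seealso [slideSpec()], [generateSlide()]
#' @export
setClass("SlideSpec", representation(
  widthPx = "integer",
  heightPx = "integer",
  micronsPerPixel = "numeric",
  nNuclei = "integer",
  classQuotas = "numeric",
  intensityBands = "matrix",
  nucleusRadiusUm = "numeric",
  spatialLaw = "list",
  inflammationFraction = "numeric",
  exclusionPolygons = "list",
  seed = "integer",
  hotspotPlan = "list"
))

setValidity("SlideSpec", function(object) {
  if (object@widthPx < 1L || object@heightPx < 1L)
    return("image dimensions must be positive")
  if (object@micronsPerPixel <= 0) return("micronsPerPixel must be positive")
  if (object@nNuclei < 0L) return("nNuclei must be non-negative")
  q <- object@classQuotas
  if (length(q) != 4L || any(q < 0))
    return("classQuotas must be 4 non-negative fractions")
  if (abs(sum(q) - 1) > 1e-9) return("classQuotas must sum to 1 (+- 1e-9)")
  b <- object@intensityBands
  if (!identical(dim(b), c(4L, 2L)) || any(b[, 1] > b[, 2]))
    return("intensityBands must be a 4x2 matrix of intervals")
  ## strictly inside the classification bands so planting is recoverable
  ok <- b["negative", 1] > 170 && b["negative", 2] <= 255 &&
    b["weak", 1] > 120 && b["weak", 2] < 170 &&
    b["moderate", 1] > 70 && b["moderate", 2] < 120 &&
    b["strong", 1] >= 0 && b["strong", 2] < 70
  if (!ok)
    return("each intensity band must lie strictly inside its classification band")
  r <- object@nucleusRadiusUm
  if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
    return("nucleusRadiusUm must be (min, max) with 0 < min <= max")
  if (object@inflammationFraction < 0 || object@inflammationFraction >= 1)
    return("inflammationFraction must be in [0, 1)")
  if (!object@spatialLaw$type %in% c("uniform", "clustered"))
    return("spatialLaw$type must be 'uniform' or 'clustered'")
  if (object@spatialLaw$type == "clustered") {
    sl <- object@spatialLaw
    if (is.null(sl$centerUm) || is.null(sl$radiusUm) || is.null(sl$enrichment))
      return("clustered law needs centerUm, radiusUm, enrichment")
    if (sl$enrichment < 1) return("cluster enrichment must be >= 1")
  }
  TRUE
})

#' Planted ground truth of a synthetic slide
#'
#' @slot nuclei data.frame with one row per planted nucleus: \code{id},
#'   \code{x_um}, \code{y_um}, \code{radius_um}, \code{planted_class},
#'   \code{planted_mean_intensity}, \code{inflammatory}.
#' @slot summary a [SlideMetrics-class] computed from the planted class
#'   tallies with the same arithmetic as [summarizeSlide()].
#' @export
setClass("GroundTruth", representation(
  nuclei = "data.frame", summary = "SlideMetrics"
))

setValidity("GroundTruth", function(object) {
  n <- object@nuclei
  need <- c("id", "x_um", "y_um", "radius_um", "planted_class",
            "planted_mean_intensity", "inflammatory")
  if (!all(need %in% names(n))) return("ground-truth table missing columns")
  tal <- table(factor(n$planted_class,
                      levels = c("negative", "weak", "moderate", "strong")))
  s <- object@summary
  if (!identical(as.integer(tal),
                 c(s@nNegative, s@nWeak, s@nModerate, s@nStrong)))
    return("summary counts must equal per-nucleus tallies")
  TRUE
})

## ---------------------------------------------------------------------------
## TestResult
## ---------------------------------------------------------------------------

#' Result of one statistical test
#'
#' @slot test test name.
#' @slot statistic test statistic (NA when not applicable).
#' @slot pValue p-value in [0, 1] (NA when flagged).
#' @slot effect effect size (Spearman's rho, hazard ratio, ...; NA if none).
#' @slot ciLower,ciUpper 95\% confidence bounds for the effect (NA if none).
#' @slot n named integer vector of group sizes.
#' @slot note character; non-empty when the result is flagged.
#' @export
setClass("TestResult", representation(
  test = "character", statistic = "numeric", pValue = "numeric",
  effect = "numeric", ciLower = "numeric", ciUpper = "numeric",
  n = "integer", note = "character"
))

setValidity("TestResult", function(object) {
  p <- object@pValue
  if (!is.na(p) && (p < 0 || p > 1)) return("p-value must be in [0, 1]")
  if (!is.na(object@ciLower) && !is.na(object@effect) &&
      !is.na(object@ciUpper) &&
      (object@ciLower > object@effect + 1e-9 ||
       object@effect > object@ciUpper + 1e-9))
    return("effect must lie inside its confidence interval")
  TRUE
})

.testResult <- function(test, statistic = NA_real_, pValue = NA_real_,
                        effect = NA_real_, ciLower = NA_real_,
                        ciUpper = NA_real_, n = integer(), note = "") {
  ni <- as.integer(n)
  names(ni) <- names(n)
  new("TestResult", test = test, statistic = as.numeric(statistic),
      pValue = as.numeric(pValue), effect = as.numeric(effect),
      ciLower = as.numeric(ciLower), ciUpper = as.numeric(ciUpper),
      n = ni, note = note)
}
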
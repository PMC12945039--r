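## Hotspot analysis: maximal-count fixed-area window of Ki-67-positive
## nuclei, Webster dichotomisation at 23, hotspot density and the
## proliferation factor.

#' Hotspot window geometry
#'
#' The hotspot is an axis-aligned square window of fixed area 0.3125 mm^2
#' (side sqrt(0.3125) mm = 559.02 um). Only the area is specified by the
#' manual counting convention; the square shape is this package's choice.
#'
#' @return window area in mm^2 / side length in microns.
#' @export
#' @examples
#' hotspotWindowAreaMm2(); hotspotWindowSideUm()
hotspotWindowAreaMm2 <- function() 0.3125

#' @rdname hotspotWindowAreaMm2
#' @export
hotspotWindowSideUm <- function() sqrt(0.3125) * 1000

#' Webster category from a hotspot count
#'
#' @param count non-negative integer count of positive cells in the hotspot.
#' @return \code{"low"} when count <= 23, \code{"high"} when count > 23.
#' @export
#' @examples
#' websterCategory(c(0, 23, 24))
websterCategory <- function(count) {
  if (any(is.na(count)) || any(count < 0))
    stop("hotspot counts must be non-negative")
  ifelse(count > 23, "high", "low")
}

#' Hotspot density
#'
#' @param count non-negative positive-cell count in the window.
#' @return density in cells per mm^2 (count / 0.3125).
#' @export
#' @examples
#' hotspotDensity(23)
hotspotDensity <- function(count) {
  if (any(is.na(count)) || any(count < 0))
    stop("hotspot counts must be non-negative")
  count / hotspotWindowAreaMm2()
}

#' Proliferation factor
#'
#' Fold difference between the hotspot and the whole-section Ki-67 burden:
#' hotspot positive-cell density divided by the global density of strongly
#' positive cells (the strong-only density is the global comparator because
#' weak / moderate staining is frequently non-neoplastic).
#'
#' @param hotspotDensityPerMm2 hotspot density, >= 0.
#' @param globalStrongDensityPerMm2 global strong-positive density, >= 0.
#' @return the ratio; \code{NA} (with a warning) when the global strong
#'   density is zero.
#' @export
#' @examples
#' proliferationFactor(200, 100)
proliferationFactor <- function(hotspotDensityPerMm2,
                                globalStrongDensityPerMm2) {
  if (hotspotDensityPerMm2 < 0 || globalStrongDensityPerMm2 < 0)
    stop("densities must be non-negative")
  if (globalStrongDensityPerMm2 == 0) {
    warning("global strong density is zero: proliferation factor undefined")
    return(NA_real_)
  }
  hotspotDensityPerMm2 / globalStrongDensityPerMm2
}

## candidate anchor set along one axis: nucleus coordinates clamped so the
## window stays inside the bounds, plus the lower bound itself
.anchorCandidates <- function(coords, lo, hi, side, stride = NULL) {
  span <- hi - lo
  if (span <= side) return(lo)          # window clipped to the bounds corner
  cand <- pmin(pmax(coords, lo), hi - side)
  if (!is.null(stride) && stride > 0)
    cand <- c(cand, seq(lo, hi - side, by = stride))
  sort(unique(c(lo, cand)))
}

#' Find the maximal-count hotspot window
#'
#' Exhaustive search over axis-aligned square windows of area 0.3125 mm^2
#' anchored at every positive-nucleus coordinate pair (a set that provably
#' contains a maximiser for half-open windows \code{[x0, x0 + side) x
#' [y0, y0 + side)}), optionally augmented by a coarse stride grid. Ties are
#' broken by the lexicographically smallest (y0, x0). Anchors are clamped so
#' the window stays inside the ROI bounding box; when the box is smaller
#' than the window along an axis, the window is anchored at the box corner.
#'
#' @param nuclei data.frame with \code{x_um}, \code{y_um}, \code{class} and
#'   optionally \code{inside_roi}; positives (weak, moderate or strong)
#'   inside the ROI are counted.
#' @param roiBoundsUm numeric \code{c(xmin, ymin, xmax, ymax)} in microns.
#' @param strideUm optional stride for an additional grid of anchors.
#' @param globalStrongDensityPerMm2 optional global strong density used to
#'   fill the proliferation factor (NA otherwise).
#' @return a [HotspotResult-class].
#' @export
findHotspot <- function(nuclei, roiBoundsUm, strideUm = NULL,
                        globalStrongDensityPerMm2 = NA_real_) {
  stopifnot(length(roiBoundsUm) == 4L)
  side <- hotspotWindowSideUm()
  keep <- nuclei$class %in% c("weak", "moderate", "strong")
  if ("inside_roi" %in% names(nuclei)) keep <- keep & nuclei$inside_roi
  x <- nuclei$x_um[keep]
  y <- nuclei$y_um[keep]
  pf <- function(cnt) {
    if (is.na(globalStrongDensityPerMm2) || globalStrongDensityPerMm2 <= 0)
      NA_real_
    else hotspotDensity(cnt) / globalStrongDensityPerMm2
  }
  if (!length(x)) {
    return(new("HotspotResult",
               windowOriginUm = c(roiBoundsUm[1], roiBoundsUm[2]),
               windowAreaMm2 = hotspotWindowAreaMm2(), positiveCount = 0L,
               hotspotDensity = 0, websterCategory = "low",
               proliferationFactor = pf(0)))
  }
  xc <- .anchorCandidates(x, roiBoundsUm[1], roiBoundsUm[3], side, strideUm)
  bestCnt <- -1L; bestX <- NA_real_; bestY <- NA_real_
  for (x0 in xc) {
    inX <- x >= x0 & x < x0 + side
    if (sum(inX) < bestCnt) next         # cannot beat or tie the incumbent
    ys <- sort(y[inX])
    yc <- .anchorCandidates(ys, roiBoundsUm[2], roiBoundsUm[4], side,
                            strideUm)
    cnt <- findInterval(yc + side, ys, left.open = TRUE) -
      findInterval(yc, ys, left.open = TRUE)
    for (j in seq_along(yc)) {
      better <- cnt[j] > bestCnt ||
        (cnt[j] == bestCnt &&
         (yc[j] < bestY || (yc[j] == bestY && x0 < bestX)))
      if (better) {
        bestCnt <- cnt[j]; bestX <- x0; bestY <- yc[j]
      }
    }
  }
  bestCnt <- as.integer(bestCnt)
  new("HotspotResult", windowOriginUm = c(bestX, bestY),
      windowAreaMm2 = hotspotWindowAreaMm2(), positiveCount = bestCnt,
      hotspotDensity = hotspotDensity(bestCnt),
      websterCategory = websterCategory(bestCnt),
      proliferationFactor = pf(bestCnt))
}
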
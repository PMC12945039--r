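## Region-of-interest handling: GeoJSON polygon annotations, pixel-center
## even-odd rasterisation, assessed-area computation and nucleus filtering.
##
## Conventions: 0-based pixel coordinates, x rightward, y downward; the
## center of pixel (ix, iy) sits at (ix + 0.5, iy + 0.5). Masks are logical
## matrices indexed [y, x] (row = y + 1, column = x + 1).

.roiCategories <- c("adnexa", "vessel", "adipose", "lymphoid", "artefact",
                    "ulcer")

## proper / improper segment intersection test for the self-intersection check
.segmentsCross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
    (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on <- function(a, b, c)
    d(a, b, c) == 0 && min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
    min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  on(p1, p2, q1) || on(p1, p2, q2) || on(q1, q2, p1) || on(q1, q2, p2)
}

.polygonSelfIntersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4L) return(FALSE)
  for (i in seq_len(n)) {
    i2 <- if (i == n) 1L else i + 1L
    for (j in seq_len(n)) {
      if (j <= i) next
      j2 <- if (j == n) 1L else j + 1L
      ## skip adjacent edges (share a vertex)
      if (i2 == j || j2 == i || (i == 1L && j == n)) next
      if (.segmentsCross(poly[i, ], poly[i2, ], poly[j, ], poly[j2, ]))
        return(TRUE)
    }
  }
  FALSE
}

.checkPolygon <- function(poly, what) {
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L)
    stop(sprintf("%s polygon must have >= 3 (x, y) vertices", what))
  ## drop an explicit closing vertex
  if (all(poly[1, ] == poly[nrow(poly), ]) && nrow(poly) > 3L)
    poly <- poly[-nrow(poly), , drop = FALSE]
  if (.polygonSelfIntersects(poly))
    stop(sprintf("self-intersecting polygon ring: %s", what))
  poly
}

## Scanline even-odd rasterisation at pixel centers. Returns logical [H, W].
.rasterizePolygon <- function(poly, heightPx, widthPx) {
  mask <- matrix(FALSE, heightPx, widthPx)
  n <- nrow(poly)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1), 1]; y2 <- poly[c(2:n, 1), 2]
  keep <- y1 != y2                       # horizontal edges never cross a scanline
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  if (!length(x1)) return(mask)
  ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
  ## rows whose center yc = iy + 0.5 satisfies ylo <= yc < yhi
  iyFrom <- pmax(0L, as.integer(ceiling(ylo - 0.5)))
  iyTo <- pmin(heightPx - 1L, as.integer(ceiling(yhi - 0.5)) - 1L)
  rows <- list(); xs <- list()
  for (e in seq_along(x1)) {
    if (iyFrom[e] > iyTo[e]) next
    iy <- iyFrom[e]:iyTo[e]
    yc <- iy + 0.5
    rows[[length(rows) + 1L]] <- iy
    xs[[length(xs) + 1L]] <-
      x1[e] + (yc - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
  }
  if (!length(rows)) return(mask)
  rows <- unlist(rows); xs <- unlist(xs)
  o <- order(rows, xs)
  rows <- rows[o]; xs <- xs[o]
  bounds <- c(which(c(TRUE, diff(rows) != 0)), length(rows) + 1L)
  for (b in seq_len(length(bounds) - 1L)) {
    i0 <- bounds[b]; i1 <- bounds[b + 1L] - 1L
    iy <- rows[i0]
    cr <- xs[i0:i1]
    nc <- length(cr)
    if (nc %% 2L != 0L) next             # numerically degenerate; skip row
    for (k in seq(1L, nc, by = 2L)) {
      ixlo <- max(0L, as.integer(floor(cr[k] - 0.5)) + 1L)
      ixhi <- min(widthPx - 1L, as.integer(ceiling(cr[k + 1L] - 0.5)) - 1L)
      if (ixlo <= ixhi) mask[iy + 1L, (ixlo:ixhi) + 1L] <- TRUE
    }
  }
  mask
}

.rasterizePolygons <- function(polys, heightPx, widthPx) {
  mask <- matrix(FALSE, heightPx, widthPx)
  for (p in polys) mask <- mask | .rasterizePolygon(p, heightPx, widthPx)
  mask
}

#' Build a region-of-interest set from polygons
#'
#' Rasterises tumour polygons (logical union), subtracts the union of the
#' exclusion polygons (so overlapping or nested exclusions are removed
#' exactly once), and computes the assessed area in mm^2 from the true-pixel
#' count.
#'
#' @param tumour list of Nx2 matrices (or a single matrix), pixel coordinates.
#' @param exclusions list of Nx2 matrices (possibly empty).
#' @param imageDim integer \code{c(heightPx, widthPx)}.
#' @param micronsPerPixel pixel pitch in microns.
#' @param categories optional character vector of exclusion categories
#'   (one of adnexa, vessel, adipose, lymphoid, artefact, ulcer).
#' @return a [ROISet-class].
#' @export
#' @examples
#' sq <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
#' roiFromPolygons(sq, imageDim = c(120, 120), micronsPerPixel = 0.23)
roiFromPolygons <- function(tumour, exclusions = list(), imageDim,
                            micronsPerPixel = 0.23, categories = character()) {
  if (is.matrix(tumour)) tumour <- list(tumour)
  if (is.matrix(exclusions)) exclusions <- list(exclusions)
  if (!length(tumour)) stop("no tumour polygon supplied")
  tumour <- lapply(seq_along(tumour), function(i)
    .checkPolygon(tumour[[i]], sprintf("tumour ring %d", i)))
  exclusions <- lapply(seq_along(exclusions), function(i)
    .checkPolygon(exclusions[[i]], sprintf("exclusion ring %d", i)))
  if (length(categories) && length(categories) != length(exclusions))
    stop("categories must match the number of exclusion polygons")
  h <- as.integer(imageDim[1]); w <- as.integer(imageDim[2])
  mask <- .rasterizePolygons(tumour, h, w)
  if (length(exclusions))
    mask <- mask & !.rasterizePolygons(exclusions, h, w)
  new("ROISet", tumour = tumour, exclusions = exclusions,
      exclusionCategories = as.character(categories), mask = mask,
      micronsPerPixel = micronsPerPixel,
      areaMm2 = sum(mask) * micronsPerPixel^2 / 1e6)
}

#' Load an ROI annotation file (GeoJSON)
#'
#' Reads a FeatureCollection of polygons; each feature carries a property
#' \code{role} of \code{"tumour"} or \code{"exclusion"} (and optionally
#' \code{category}). Coordinates are pixel-space polygon rings.
#'
#' @param path GeoJSON file.
#' @param imageDim integer \code{c(heightPx, widthPx)}.
#' @param micronsPerPixel pixel pitch in microns.
#' @return a [ROISet-class].
#' @export
loadROI <- function(path, imageDim, micronsPerPixel = 0.23) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(js$features)) stop("annotation file is not a FeatureCollection")
  tumour <- list(); excl <- list(); cats <- character()
  for (f in js$features) {
    role <- f$properties$role
    if (is.null(role)) next
    ring <- f$geometry$coordinates[[1]]   # outer ring
    poly <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
    if (identical(role, "tumour")) {
      tumour[[length(tumour) + 1L]] <- poly
    } else if (identical(role, "exclusion")) {
      excl[[length(excl) + 1L]] <- poly
      cats <- c(cats, if (is.null(f$properties$category)) NA_character_
                else f$properties$category)
    }
  }
  if (!length(tumour)) stop("no tumour polygon in annotation file")
  roiFromPolygons(tumour, excl, imageDim, micronsPerPixel, cats)
}

#' Write an ROI set (plus optional hotspot window) as GeoJSON
#'
#' @param roi a [ROISet-class].
#' @param path output file.
#' @param hotspot optional [HotspotResult-class]; its window polygon is
#'   written with role \code{"hotspot"}.
#' @return invisibly, the path.
#' @export
writeROIGeoJSON <- function(roi, path, hotspot = NULL) {
  ringOf <- function(poly) {
    closed <- rbind(poly, poly[1, , drop = FALSE])
    list(lapply(seq_len(nrow(closed)),
                function(i) c(closed[i, 1], closed[i, 2])))
  }
  feat <- function(poly, role, category = NULL) {
    props <- list(role = role)
    if (!is.null(category) && !is.na(category)) props$category <- category
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = ringOf(poly)))
  }
  features <- lapply(roi@tumour, feat, role = "tumour")
  for (i in seq_along(roi@exclusions)) {
    cat_i <- if (length(roi@exclusionCategories) >= i)
      roi@exclusionCategories[i] else NULL
    features[[length(features) + 1L]] <-
      feat(roi@exclusions[[i]], "exclusion", cat_i)
  }
  if (!is.null(hotspot)) {
    side <- hotspotWindowSideUm() / roi@micronsPerPixel
    o <- hotspot@windowOriginUm / roi@micronsPerPixel
    win <- cbind(c(o[1], o[1] + side, o[1] + side, o[1]),
                 c(o[2], o[2], o[2] + side, o[2] + side))
    features[[length(features) + 1L]] <- feat(win, "hotspot")
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Flag nuclei by ROI membership
#'
#' A nucleus is inside the ROI iff the mask is true at the pixel containing
#' its centroid (pixel-center rule, order-independent). Centroids outside the
#' image are flagged outside with a warning.
#'
#' @param nuclei data.frame from [detectNuclei()] (needs \code{x_um},
#'   \code{y_um}).
#' @param roi a [ROISet-class].
#' @return the data.frame with column \code{inside_roi} set.
#' @export
filterNuclei <- function(nuclei, roi) {
  stopifnot(is(roi, "ROISet"))
  if (!nrow(nuclei)) {
    nuclei$inside_roi <- logical(0)
    return(nuclei)
  }
  mpp <- roi@micronsPerPixel
  ix <- floor(nuclei$x_um / mpp)        # 0-based pixel indices
  iy <- floor(nuclei$y_um / mpp)
  h <- nrow(roi@mask); w <- ncol(roi@mask)
  inImg <- ix >= 0 & ix < w & iy >= 0 & iy < h
  if (any(!inImg))
    warning(sprintf("%d nucleus centroid(s) outside the image", sum(!inImg)))
  inside <- logical(nrow(nuclei))
  idx <- which(inImg)
  inside[idx] <- roi@mask[cbind(iy[idx] + 1L, ix[idx] + 1L)]
  nuclei$inside_roi <- inside
  nuclei
}
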
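## Nucleus detection and four-band Ki-67 intensity classification.
##
## The detector is a classical segmentation pipeline honouring the output
## contract of the commercial nuclei-detection application it stands in for:
## combined nuclear OD (hematoxylin + DAB) -> Gaussian smoothing ->
## thresholding -> hole filling -> distance-transform watershed splitting of
## touching objects -> area filtering.

#' Classification bands for nuclear mean DAB pseudo-intensity
#'
#' Thresholds on the 0-255 pseudo-intensity scale: strong below
#' \code{tStrong}, moderate from \code{tStrong} to below \code{tWeak}, weak
#' from \code{tWeak} up to and including \code{tNegative}, negative above
#' \code{tNegative}. Values printed on band boundaries follow a single
#' half-open-from-below convention: strong [0, 70), moderate [70, 120),
#' weak [120, 170], negative (170, 255].
#'
#' @param tNegative,tWeak,tStrong band thresholds, default 170 / 120 / 70.
#' @return a validated list with class \code{"ClassBands"}.
#' @export
#' @examples
#' classBands()
classBands <- function(tNegative = 170, tWeak = 120, tStrong = 70) {
  if (!(0 < tStrong && tStrong < tWeak && tWeak < tNegative &&
        tNegative < 255))
    stop("need 0 < tStrong < tWeak < tNegative < 255")
  structure(list(tNegative = tNegative, tWeak = tWeak, tStrong = tStrong),
            class = "ClassBands")
}

#' Classify nuclei from mean central DAB pseudo-intensity
#'
#' @param v numeric vector of mean pseudo-intensities in [0, 255].
#' @param bands a [classBands()] object.
#' @return factor with levels negative, weak, moderate, strong.
#' @export
#' @examples
#' classifyNucleus(c(39, 89, 150, 200))
classifyNucleus <- function(v, bands = classBands()) {
  if (any(is.na(v)) || any(v < 0 | v > 255))
    stop("pseudo-intensities must lie in [0, 255]")
  cls <- ifelse(v < bands$tStrong, "strong",
         ifelse(v < bands$tWeak, "moderate",
         ifelse(v <= bands$tNegative, "weak", "negative")))
  factor(cls, levels = c("negative", "weak", "moderate", "strong"))
}

#' Detection parameters
#'
#' @param odThreshold threshold on the smoothed combined (hematoxylin + DAB)
#'   optical density.
#' @param smoothSigmaUm Gaussian smoothing sigma in microns.
#' @param minAreaUm2,maxAreaUm2 accepted object area range in square microns.
#' @return a named list with class \code{"NucleusDetectionParams"}.
#' @export
nucleusDetectionParams <- function(odThreshold = 0.15, smoothSigmaUm = 0.5,
                                   minAreaUm2 = 8, maxAreaUm2 = 150) {
  .assertScalarNumber(odThreshold, "odThreshold", 0, strict.lower = TRUE)
  .assertScalarNumber(smoothSigmaUm, "smoothSigmaUm", 0, strict.lower = TRUE)
  if (minAreaUm2 <= 0 || maxAreaUm2 <= minAreaUm2)
    stop("need 0 < minAreaUm2 < maxAreaUm2")
  structure(list(odThreshold = odThreshold, smoothSigmaUm = smoothSigmaUm,
                 minAreaUm2 = minAreaUm2, maxAreaUm2 = maxAreaUm2),
            class = "NucleusDetectionParams")
}

## distance-to-boundary transform of a single-object mask, treating
## everything outside the mask (including the image border) as background
.objectDistmap <- function(mask) {
  padded <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  dm <- EBImage::distmap(padded)
  dm[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L), drop = FALSE]
}

## indices (within `dist`/`n` ordering) of the central 25-75% distance-rank
## band; objects of <= 4 pixels keep everything
.centralRankSelect <- function(dist) {
  n <- length(dist)
  if (n <= 4L) return(seq_len(n))
  o <- order(dist, seq_len(n))          # ascending distance, stable ties
  lo <- floor(0.25 * n) + 1L
  hi <- floor(0.75 * n)
  o[lo:hi]
}

#' Central 25-75\% pixels of a nuclear object
#'
#' Pixels are ranked by their Euclidean distance to the object boundary
#' (distance transform within the object); the pixels whose rank percentile
#' lies in the central [25\%, 75\%] band are kept, excluding both the
#' outermost quartile (rim, edge artefacts) and the innermost quartile
#' (chromatin-clearing highlights). Objects with four or fewer pixels are
#' returned whole.
#'
#' @param mask logical (or 0/1) matrix containing a single object.
#' @return logical matrix of the same shape selecting the central pixels.
#' @export
#' @examples
#' m <- matrix(TRUE, 5, 5)
#' sum(centralPixels(m))
centralPixels <- function(mask) {
  mask <- mask != 0
  idx <- which(mask)
  if (!length(idx)) stop("empty object")
  dm <- .objectDistmap(mask)
  sel <- .centralRankSelect(dm[idx])
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[idx[sel]] <- TRUE
  out
}

#' Detect and classify nuclei
#'
#' Runs the classical segmentation pipeline on the combined nuclear optical
#' density, splits touching objects by distance-transform watershed (applied
#' per connected component, which is equivalent to a whole-image watershed
#' because basins never cross background), filters by area, measures each
#' object's mean DAB pseudo-intensity over its central 25-75\% pixels and
#' classifies it. Objects whose centroid lies outside \code{roi} are flagged
#' \code{inside_roi = FALSE}; downstream metrics use only in-ROI nuclei.
#'
#' @param hema,dab hematoxylin and DAB OD matrices from [separateStains()].
#' @param roi optional [ROISet-class]; \code{NULL} means the whole image.
#' @param params a [nucleusDetectionParams()] list.
#' @param micronsPerPixel pixel pitch in microns.
#' @param bands a [classBands()] object.
#' @return data.frame with columns \code{id}, \code{x_um}, \code{y_um},
#'   \code{area_um2}, \code{central_mean_dab}, \code{class},
#'   \code{inside_roi}.
#' @export
detectNuclei <- function(hema, dab, roi = NULL,
                         params = nucleusDetectionParams(),
                         micronsPerPixel = 0.23, bands = classBands()) {
  stopifnot(is.matrix(hema), is.matrix(dab),
            identical(dim(hema), dim(dab)))
  empty <- data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                      area_um2 = numeric(), central_mean_dab = numeric(),
                      class = factor(character(),
                                     levels = c("negative", "weak",
                                                "moderate", "strong")),
                      inside_roi = logical())
  if (!is.null(roi) && !any(roi@mask)) {
    warning("empty ROI mask: no nuclei assessed")
    return(empty)
  }
  mpp <- micronsPerPixel
  sm <- gaussBlurSep(hema + dab, params$smoothSigmaUm / mpp)
  bw <- sm > params$odThreshold
  rm(sm)
  bw <- EBImage::fillHull(bw)
  cc <- EBImage::bwlabel(bw)
  rm(bw)
  ncc <- max(cc)
  if (ncc == 0L) return(empty)

  h <- nrow(cc)
  idx <- which(cc > 0)
  lab <- cc[idx]
  rm(cc)
  o <- order(lab)
  idx <- idx[o]; lab <- lab[o]
  bounds <- c(which(c(TRUE, diff(lab) != 0)), length(lab) + 1L)

  minPx <- params$minAreaUm2 / mpp^2
  maxPx <- params$maxAreaUm2 / mpp^2
  dabI <- NULL                           # lazily index dab per object

  ids <- list(); xs <- list(); ys <- list(); areas <- list(); means <- list()
  k <- 0L
  for (b in seq_len(length(bounds) - 1L)) {
    gidx <- idx[bounds[b]:(bounds[b + 1L] - 1L)]
    r <- (gidx - 1L) %% h + 1L
    cl <- (gidx - 1L) %/% h + 1L
    r0 <- min(r); c0 <- min(cl)
    lm <- matrix(FALSE, max(r) - r0 + 1L, max(cl) - c0 + 1L)
    lidx <- cbind(r - r0 + 1L, cl - c0 + 1L)
    lm[lidx] <- TRUE
    dm <- .objectDistmap(lm)
    ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
    wlab <- ws[lidx]
    if (max(wlab) > 1L) {
      parts <- split(seq_along(gidx), wlab)
      parts <- parts[names(parts) != "0"]
    } else {
      parts <- list(seq_along(gidx))
    }
    for (p in parts) {
      npx <- length(p)
      if (npx < minPx || npx > maxPx) next
      if (length(parts) == 1L) {
        d <- dm[lidx[p, , drop = FALSE]]
      } else {
        sm2 <- matrix(FALSE, nrow(lm), ncol(lm))
        sm2[lidx[p, , drop = FALSE]] <- TRUE
        d <- .objectDistmap(sm2)[lidx[p, , drop = FALSE]]
      }
      sel <- p[.centralRankSelect(d)]
      k <- k + 1L
      ids[[k]] <- k
      xs[[k]] <- (mean(cl[p]) - 0.5) * mpp
      ys[[k]] <- (mean(r[p]) - 0.5) * mpp
      areas[[k]] <- npx * mpp^2
      means[[k]] <- mean(pmin(255, 255 * 10^(-dab[gidx[sel]])))
    }
  }
  if (k == 0L) return(empty)
  out <- data.frame(id = unlist(ids), x_um = unlist(xs), y_um = unlist(ys),
                    area_um2 = unlist(areas),
                    central_mean_dab = unlist(means))
  out$class <- classifyNucleus(out$central_mean_dab, bands)
  out$inside_roi <- TRUE
  if (!is.null(roi)) out <- filterNuclei(out, roi)
  out
}
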
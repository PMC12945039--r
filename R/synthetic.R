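## Synthetic H-DAB slide generator with planted ground truth.
##
## Images are composited in optical-density space: a white background plus,
## per nucleus, a disk carrying hematoxylin OD and a DAB OD chosen so that
## the rendered mean central pseudo-intensity equals the planted intensity
## (up to 8-bit quantisation, within +-2 units). Class counts follow exact
## largest-remainder apportionment; nuclei never overlap (rejection sampling
## with a bounded retry budget); one private random stream per slide.

.classNames <- c("negative", "weak", "moderate", "strong")

.defaultIntensityBands <- function() {
  b <- rbind(negative = c(185, 245), weak = c(130, 160),
             moderate = c(80, 110), strong = c(30, 60))
  colnames(b) <- c("lo", "hi")
  b
}

## radius range of the small inflammatory stand-ins (granulocyte-like,
## weak-band staining)
.inflRadiusUm <- c(2.8, 3.4)

#' Construct a synthetic slide specification
#'
#' Defaults emulate the cohort-average slide: class quotas
#' (0.86, 0.06, 0.04, 0.04) give a planted proliferation index of 14\% and
#' an H-score of 26; the pixel pitch is the 0.23 um scan resolution; nucleus
#' radii span 4-6 um with small (2.8-3.4 um) weakly staining inflammatory
#' stand-ins making up 5\% of all nuclei (a "mild" inflammation slide).
#'
#' @param widthPx,heightPx image size in pixels.
#' @param nNuclei number of non-inflammatory nuclei.
#' @param micronsPerPixel pixel pitch, microns.
#' @param classQuotas four fractions (negative, weak, moderate, strong)
#'   summing to 1.
#' @param intensityBands 4x2 matrix of per-class pseudo-intensity intervals,
#'   each strictly inside its classification band.
#' @param nucleusRadiusUm (min, max) nucleus radius in microns.
#' @param spatialLaw \code{list(type = "uniform")} or
#'   \code{list(type = "clustered", centerUm =, radiusUm =, enrichment =)};
#'   a clustered law enriches Ki-67-positive nuclei inside the cluster disk.
#' @param inflammationFraction fraction of all nuclei that are inflammatory
#'   stand-ins.
#' @param exclusionPolygons list of pixel-space polygons excluded from the
#'   ROI (no nuclei are planted there).
#' @param seed integer seed of the slide's private random stream.
#' @return a validated [SlideSpec-class].
#' @export
#' @examples
#' slideSpec(400, 400, nNuclei = 50, seed = 7)
slideSpec <- function(widthPx, heightPx, nNuclei,
                      micronsPerPixel = 0.23,
                      classQuotas = c(negative = 0.86, weak = 0.06,
                                      moderate = 0.04, strong = 0.04),
                      intensityBands = .defaultIntensityBands(),
                      nucleusRadiusUm = c(4, 6),
                      spatialLaw = list(type = "uniform"),
                      inflammationFraction = 0.05,
                      exclusionPolygons = list(),
                      seed = 1L) {
  q <- as.numeric(classQuotas)
  names(q) <- .classNames
  b <- as.matrix(intensityBands)
  rownames(b) <- .classNames
  new("SlideSpec", widthPx = as.integer(widthPx),
      heightPx = as.integer(heightPx),
      micronsPerPixel = micronsPerPixel, nNuclei = as.integer(nNuclei),
      classQuotas = q, intensityBands = b,
      nucleusRadiusUm = as.numeric(nucleusRadiusUm),
      spatialLaw = spatialLaw,
      inflammationFraction = inflammationFraction,
      exclusionPolygons = exclusionPolygons,
      seed = as.integer(seed), hotspotPlan = list())
}

#' Largest-remainder apportionment of class counts
#'
#' Deterministic integer apportionment of \code{n} into quota shares: floors
#' first, then one extra to the largest fractional remainders (ties resolved
#' in class order). Exact fractions yield exact counts.
#'
#' @param n total count.
#' @param quotas non-negative fractions summing to 1.
#' @return integer vector of counts summing to \code{n}.
#' @export
#' @examples
#' apportionCounts(200, c(0.6, 0.2, 0.15, 0.05))
apportionCounts <- function(n, quotas) {
  if (abs(sum(quotas) - 1) > 1e-9) stop("quotas must sum to 1")
  raw <- n * quotas
  base <- floor(raw)
  left <- round(n - sum(base))
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  cnt <- as.integer(base)
  names(cnt) <- names(quotas)
  cnt
}

## sample a nucleus position (in um) under the spatial law; positives may be
## enriched in a cluster disk
.samplePosition <- function(law, loUm, hiUm, positive) {
  if (law$type == "clustered" && positive) {
    ac <- pi * law$radiusUm^2
    atot <- (hiUm[1] - loUm[1]) * (hiUm[2] - loUm[2])
    w <- law$enrichment * ac / (max(atot - ac, 0) + law$enrichment * ac)
    if (stats::runif(1) < w) {
      th <- stats::runif(1, 0, 2 * pi)
      rr <- law$radiusUm * sqrt(stats::runif(1))
      return(law$centerUm + rr * c(cos(th), sin(th)))
    }
  }
  c(stats::runif(1, loUm[1], hiUm[1]), stats::runif(1, loUm[2], hiUm[2]))
}

## grid-hash placement of non-overlapping disks; returns NULL on failure
.placeNuclei <- function(radii, positive, spec, excludeMask, retries = 100L,
                         plan = NULL) {
  mpp <- spec@micronsPerPixel
  wUm <- spec@widthPx * mpp
  hUm <- spec@heightPx * mpp
  marginUm <- 3                          # keep the blur halo off the border
  n <- length(radii)
  x <- numeric(n); y <- numeric(n)
  cell <- 2 * max(radii, spec@nucleusRadiusUm[2]) + 2
  ncx <- max(1L, as.integer(ceiling(wUm / cell)))
  ncy <- max(1L, as.integer(ceiling(hUm / cell)))
  grid <- vector("list", ncx * ncy)
  sepUm <- 2                             # minimum edge-to-edge separation
  ## placement order: planted hotspot nuclei first (they are constrained to
  ## the window), then the rest largest-first, which packs far better than
  ## arrival order while staying deterministic under the slide seed
  nPlan <- if (is.null(plan)) 0L else plan$count
  rest <- setdiff(seq_len(n), seq_len(nPlan))
  ord <- c(seq_len(nPlan), rest[order(radii[rest], decreasing = TRUE)])
  for (i in ord) {
    r <- radii[i]
    lo <- c(r + marginUm, r + marginUm)
    hi <- c(wUm - r - marginUm, hUm - r - marginUm)
    if (any(hi <= lo)) return(NULL)
    ok <- FALSE
    for (t in seq_len(retries)) {
      if (!is.null(plan) && i <= plan$count) {
        ## planted hotspot positives: uniform inside the inset window
        p <- c(stats::runif(1, plan$insetLo[1], plan$insetHi[1]),
               stats::runif(1, plan$insetLo[2], plan$insetHi[2]))
      } else {
        p <- .samplePosition(spec@spatialLaw, lo, hi, positive[i])
      }
      p <- pmin(pmax(p, lo), hi)
      ## exclusion polygons: reject centroids inside
      if (!is.null(excludeMask)) {
        ix <- floor(p[1] / mpp) + 1; iy <- floor(p[2] / mpp) + 1
        if (excludeMask[iy, ix]) next
      }
      gx <- min(ncx, max(1L, as.integer(p[1] %/% cell) + 1L))
      gy <- min(ncy, max(1L, as.integer(p[2] %/% cell) + 1L))
      clash <- FALSE
      for (dx in -1:1) for (dy in -1:1) {
        cx <- gx + dx; cy <- gy + dy
        if (cx < 1L || cx > ncx || cy < 1L || cy > ncy) next
        js <- grid[[(cx - 1L) * ncy + cy]]
        if (length(js) &&
            any((x[js] - p[1])^2 + (y[js] - p[2])^2 <
                (radii[js] + r + sepUm)^2)) {
          clash <- TRUE
          break
        }
      }
      if (clash) next
      x[i] <- p[1]; y[i] <- p[2]
      gi <- (gx - 1L) * ncy + gy
      grid[[gi]] <- c(grid[[gi]], i)
      ok <- TRUE
      break
    }
    if (!ok) return(NULL)
  }
  cbind(x, y)
}

#' Generate a synthetic slide
#'
#' Produces the RGB image (integer array \code{[height, width, 3]}), the
#' planted [GroundTruth-class] and the [ROISet-class] (full image minus the
#' spec's exclusion polygons). Identical specs (including seed) give
#' bit-identical outputs.
#'
#' @param spec a [SlideSpec-class].
#' @return list with elements \code{image}, \code{truth}, \code{roi}.
#' @export
#' @examples
#' s <- generateSlide(slideSpec(300, 300, nNuclei = 20,
#'                              inflammationFraction = 0, seed = 2))
#' truthSummary(s$truth)
generateSlide <- function(spec) {
  stopifnot(is(spec, "SlideSpec"))
  validObject(spec)
  withLocalSeed(spec@seed, .generateSlideImpl(spec))
}

.generateSlideImpl <- function(spec) {
  mpp <- spec@micronsPerPixel
  w <- spec@widthPx; h <- spec@heightPx
  rect <- cbind(c(0, w, w, 0), c(0, 0, h, h))
  roi <- roiFromPolygons(list(rect), spec@exclusionPolygons, c(h, w), mpp)
  excludeMask <- if (length(spec@exclusionPolygons))
    .rasterizePolygons(lapply(spec@exclusionPolygons, .checkPolygon,
                              what = "exclusion"), h, w)
  else NULL

  plan <- spec@hotspotPlan
  planCount <- if (length(plan)) plan$count else 0L

  ## class assignment: exact quotas over the base nuclei, plus planted
  ## hotspot positives and weak inflammatory stand-ins
  counts <- apportionCounts(spec@nNuclei, spec@classQuotas)
  classes <- rep(.classNames, counts)
  if (length(classes) > 1L) classes <- sample(classes)
  planClasses <- character(0)
  if (planCount > 0L) {
    posQ <- spec@classQuotas[c("weak", "moderate", "strong")]
    if (sum(posQ) <= 0) posQ <- c(weak = 0, moderate = 0, strong = 1)
    planClasses <- rep(c("weak", "moderate", "strong"),
                       apportionCounts(planCount, posQ / sum(posQ)))
  }
  nBase <- length(classes) + planCount
  f <- spec@inflammationFraction
  nInfl <- if (f > 0) as.integer(round(nBase * f / (1 - f))) else 0L
  allClasses <- c(planClasses, classes, rep("weak", nInfl))
  inflam <- c(rep(FALSE, planCount + length(classes)), rep(TRUE, nInfl))
  nAll <- length(allClasses)

  if (nAll == 0L) {
    img <- array(255L, dim = c(h, w, 3))
    truth <- new("GroundTruth",
                 nuclei = data.frame(id = integer(), x_um = numeric(),
                                     y_um = numeric(), radius_um = numeric(),
                                     planted_class = character(),
                                     planted_mean_intensity = numeric(),
                                     inflammatory = logical()),
                 summary = .metricsFromCounts(0L, 0L, 0L, 0L, roi@areaMm2,
                                              "synthetic"))
    return(list(image = img, truth = truth, roi = roi))
  }

  radii <- ifelse(inflam,
                  stats::runif(nAll, .inflRadiusUm[1], .inflRadiusUm[2]),
                  stats::runif(nAll, spec@nucleusRadiusUm[1],
                               spec@nucleusRadiusUm[2]))
  positive <- allClasses != "negative"

  planGeom <- NULL
  if (planCount > 0L) {
    side <- hotspotWindowSideUm()
    inset <- max(radii[seq_len(planCount)]) + 3
    planGeom <- list(count = planCount,
                     insetLo = plan$originUm + inset,
                     insetHi = plan$originUm + side - inset)
  }
  pos <- .placeNuclei(radii, positive, spec, excludeMask, plan = planGeom)
  if (is.null(pos))
    stop(sprintf(paste0("could not place %d non-overlapping nuclei within ",
                        "100 retries each: requested density exceeds the ",
                        "non-overlap limit for this image size"), nAll))

  bands <- spec@intensityBands
  intensity <- stats::runif(nAll, bands[allClasses, 1], bands[allClasses, 2])
  hemaOD <- stats::runif(nAll, 0.45, 0.65)

  ## composite OD planes
  hPlane <- matrix(0, h, w)
  dPlane <- matrix(0, h, w)
  for (i in seq_len(nAll)) {
    cx <- pos[i, 1] / mpp; cy <- pos[i, 2] / mpp
    rpx <- radii[i] / mpp
    ix <- max(0L, floor(cx - rpx - 1)):min(w - 1L, ceiling(cx + rpx + 1))
    iy <- max(0L, floor(cy - rpx - 1)):min(h - 1L, ceiling(cy + rpx + 1))
    dx2 <- (ix + 0.5 - cx)^2
    dy2 <- (iy + 0.5 - cy)^2
    disk <- outer(dy2, dx2, "+") <= rpx^2
    sel <- which(disk, arr.ind = TRUE)
    if (!nrow(sel)) next
    lin <- (iy[sel[, 1]]) + 1L + (ix[sel[, 2]]) * h
    hPlane[lin] <- hPlane[lin] + hemaOD[i]
    ## zero-mean per-pixel texture (+-1.5 intensity units) dithers the 8-bit
    ## quantisation so the rendered mean central pseudo-intensity stays
    ## within +-2 units of the planted value
    ipx <- pmax(1, intensity[i] + stats::runif(nrow(sel), -1.5, 1.5))
    dPlane[lin] <- dPlane[lin] - log10(ipx / 255)
  }

  basis <- hdabBasis()@vectors
  img <- array(0L, dim = c(h, w, 3))
  for (c in 1:3) {
    od <- hPlane * basis["hematoxylin", c] + dPlane * basis["dab", c]
    img[, , c] <- as.integer(pmax(0, pmin(255, round(256 * 10^(-od) - 1))))
  }
  rm(hPlane, dPlane)

  nuc <- data.frame(id = seq_len(nAll), x_um = pos[, 1], y_um = pos[, 2],
                    radius_um = radii, planted_class = allClasses,
                    planted_mean_intensity = intensity,
                    inflammatory = inflam)
  tal <- table(factor(allClasses, levels = .classNames))
  truth <- new("GroundTruth", nuclei = nuc,
               summary = .metricsFromCounts(tal[["negative"]], tal[["weak"]],
                                            tal[["moderate"]],
                                            tal[["strong"]], roi@areaMm2,
                                            "synthetic"))

  if (planCount > 0L) .verifyHotspotPlan(nuc, plan, spec)
  list(image = img, truth = truth, roi = roi)
}

## the planted window must beat every disjoint window strictly
.verifyHotspotPlan <- function(nuc, plan, spec) {
  side <- hotspotWindowSideUm()
  pos <- nuc[nuc$planted_class != "negative", ]
  o <- plan$originUm
  inWin <- pos$x_um >= o[1] & pos$x_um < o[1] + side &
    pos$y_um >= o[2] & pos$y_um < o[2] + side
  if (sum(inWin) < plan$count)
    stop("hotspot plan violated: planted window lost nuclei")
  out <- pos[!inWin, ]
  if (!nrow(out)) return(invisible(TRUE))
  ## max count over windows anchored at out-of-window nuclei, restricted to
  ## windows disjoint from the planted one
  for (i in seq_len(nrow(out))) {
    x0 <- out$x_um[i]
    for (y0 in out$y_um) {
      disjoint <- x0 + side <= o[1] || x0 >= o[1] + side ||
        y0 + side <= o[2] || y0 >= o[2] + side
      if (!disjoint) next
      cnt <- sum(out$x_um >= x0 & out$x_um < x0 + side &
                 out$y_um >= y0 & out$y_um < y0 + side)
      if (cnt >= plan$count)
        stop("hotspot plan violated: a disjoint window matches the planted count")
    }
  }
  invisible(TRUE)
}

#' Plant a hotspot into a slide specification
#'
#' Returns a spec whose generated slide contains at least
#' \code{windowPositiveCount} Ki-67-positive nuclei inside one fixed window
#' of area 0.3125 mm^2 (default: centred on the slide) and strictly fewer in
#' any disjoint window; the generator verifies the guarantee and errors if
#' the background violates it. A count of zero only annotates the plan.
#'
#' @param spec a [SlideSpec-class].
#' @param windowPositiveCount number of positives to plant in the window.
#' @param windowOriginUm optional window origin (x, y) in microns.
#' @return the modified [SlideSpec-class].
#' @export
plantHotspot <- function(spec, windowPositiveCount, windowOriginUm = NULL) {
  stopifnot(is(spec, "SlideSpec"))
  count <- as.integer(windowPositiveCount)
  if (count < 0L) stop("windowPositiveCount must be non-negative")
  side <- hotspotWindowSideUm()
  mpp <- spec@micronsPerPixel
  if (is.null(windowOriginUm)) {
    windowOriginUm <- c(spec@widthPx, spec@heightPx) * mpp / 2 - side / 2
  }
  if (any(windowOriginUm < 0) ||
      windowOriginUm[1] + side > spec@widthPx * mpp ||
      windowOriginUm[2] + side > spec@heightPx * mpp)
    stop("hotspot window does not fit inside the image")
  ## feasibility at the non-overlap density limit (conservative RSA bound)
  rmax <- spec@nucleusRadiusUm[2]
  capacity <- floor(0.4 * side^2 / (pi * (rmax + 1)^2))
  if (count > capacity)
    stop(sprintf("cannot place %d non-overlapping positives in one window (limit ~%d)",
                 count, capacity))
  spec@hotspotPlan <- list(originUm = as.numeric(windowOriginUm),
                           count = count)
  spec
}

#' Write a generated slide to disk
#'
#' Writes the image (PNG or TIFF by extension), the ground-truth nucleus
#' table (TSV with header) and the ROI (GeoJSON FeatureCollection).
#'
#' @param slide list from [generateSlide()].
#' @param imagePath path ending in .png or .tif/.tiff.
#' @param truthPath optional ground-truth TSV path.
#' @param roiPath optional GeoJSON path.
#' @return invisibly, \code{imagePath}.
#' @export
writeSlide <- function(slide, imagePath, truthPath = NULL, roiPath = NULL) {
  writeSlideImage(slide$image, imagePath)
  if (!is.null(truthPath)) {
    utils::write.table(truthNuclei(slide$truth), truthPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(roiPath)) writeROIGeoJSON(slide$roi, roiPath)
  invisible(imagePath)
}

#' Read / write slide images
#'
#' 8-bit RGB round trip through PNG or TIFF: values 0-255 map to the file's
#' [0, 1] scale exactly, so a written image reads back bit-identical.
#'
#' @param image integer array \code{[height, width, 3]}, values 0-255.
#' @param path file ending in .png, .tif or .tiff.
#' @return \code{writeSlideImage}: invisibly, the path;
#'   \code{readSlideImage}: integer array \code{[height, width, 3]}.
#' @export
writeSlideImage <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  arr <- image / 255
  if (ext == "png") png::writePNG(arr, path)
  else if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  else stop("unsupported image format: ", ext)
  invisible(path)
}

#' @rdname writeSlideImage
#' @export
readSlideImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image format: ", ext)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  array(as.integer(round(arr * 255)), dim = dim(arr))
}
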
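square <- function(x0, y0, side) {
  cbind(c(x0, x0 + side, x0 + side, x0), c(y0, y0, y0 + side, y0 + side))
}

test_that("assessed area follows the pixel-center rasterisation rule", {
  ## 1000 x 1000 px tumour square at 0.23 um/px: (230 um)^2 = 0.0529 mm2
  roi <- roiFromPolygons(square(0, 0, 1000), imageDim = c(1100, 1100),
                         micronsPerPixel = 0.23)
  expect_equal(sum(roiMask(roi)), 1000L * 1000L)
  expect_equal(area(roi), 0.0529)

  ## an exclusion fully inside reduces the area by exactly its raster area
  excl <- square(100, 100, 200)
  roi2 <- roiFromPolygons(square(0, 0, 1000), list(excl),
                          imageDim = c(1100, 1100), micronsPerPixel = 0.23)
  expect_equal(sum(roiMask(roi)) - sum(roiMask(roi2)), 200L * 200L)

  ## an exclusion fully outside leaves the area unchanged
  roi3 <- roiFromPolygons(square(0, 0, 500), list(square(600, 600, 100)),
                          imageDim = c(1100, 1100), micronsPerPixel = 0.23)
  expect_equal(area(roi3), area(roiFromPolygons(square(0, 0, 500),
                                                imageDim = c(1100, 1100),
                                                micronsPerPixel = 0.23)))
})

test_that("disjoint tumour polygons add; nested exclusions subtract once", {
  t1 <- square(0, 0, 100); t2 <- square(200, 200, 100)
  roi <- roiFromPolygons(list(t1, t2), imageDim = c(400, 400),
                         micronsPerPixel = 1)
  expect_equal(sum(roiMask(roi)), 2L * 100L * 100L)

  ## two overlapping exclusions are unioned before subtraction
  e1 <- square(10, 10, 40); e2 <- square(30, 30, 40)
  roi2 <- roiFromPolygons(t1, list(e1, e2), imageDim = c(400, 400),
                          micronsPerPixel = 1)
  unionArea <- 40 * 40 * 2 - 20 * 20
  expect_equal(sum(roiMask(roi2)), 100L * 100L - unionArea)
})

test_that("rasterisation agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(5)
  for (rep in 1:5) {
    ## random star-shaped (hence simple) polygon
    nv <- sample(5:12, 1)
    ang <- sort(runif(nv, 0, 2 * pi))
    rad <- runif(nv, 10, 45)
    poly <- cbind(50 + rad * cos(ang), 50 + rad * sin(ang))
    roi <- roiFromPolygons(poly, imageDim = c(100, 100), micronsPerPixel = 1)
    centers <- expand.grid(x = (0:99) + 0.5, y = (0:99) + 0.5)
    oracle <- mgcv::in.out(rbind(poly, poly[1, ]),
                           as.matrix(centers))
    got <- as.vector(t(roiMask(roi)))     # row y, col x -> x fastest
    ## boundary-grazing centers may differ by convention; require identity
    ## away from the outline (distance > 1 px from any vertex/edge sample)
    edgePts <- poly[rep(seq_len(nv), each = 30), ] +
      (rbind(poly[c(2:nv, 1), ] - poly)[rep(seq_len(nv), each = 30), ] *
         runif(nv * 30))
    dmin <- vapply(seq_len(nrow(centers)), function(i)
      min(abs(centers$x[i] - edgePts[, 1]) + abs(centers$y[i] - edgePts[, 2])),
      0)
    interior <- dmin > 2
    expect_equal(got[interior], oracle[interior])
  }
})

test_that("invalid annotations are rejected with informative errors", {
  bowtie <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_error(roiFromPolygons(bowtie, imageDim = c(20, 20),
                               micronsPerPixel = 1), "self-intersecting")
  expect_error(roiFromPolygons(list(), imageDim = c(20, 20),
                               micronsPerPixel = 1), "tumour")
  expect_error(roiFromPolygons(cbind(c(0, 1), c(0, 1)),
                               imageDim = c(20, 20), micronsPerPixel = 1),
               ">= 3")
})

test_that("nucleus ROI membership follows the centroid pixel-center rule", {
  roi <- roiFromPolygons(square(0, 0, 100), list(square(20, 20, 10)),
                         imageDim = c(200, 200), micronsPerPixel = 1)
  nuc <- data.frame(
    x_um = c(50.5, 25.0, 150.5, 20.5, 19.5, -5),
    y_um = c(50.5, 25.0, 150.5, 20.5, 19.5, 10))
  expect_warning(out <- filterNuclei(nuc, roi), "outside the image")
  expect_true(out$inside_roi[1])          # interior
  expect_false(out$inside_roi[2])         # inside excluded vessel
  expect_false(out$inside_roi[3])         # outside tumour
  expect_false(out$inside_roi[4])         # first excluded pixel (20, 20)
  expect_true(out$inside_roi[5])          # pixel (19, 19), still tumour
  expect_false(out$inside_roi[6])         # off the image
})

test_that("GeoJSON annotations round-trip through write and load", {
  roi <- roiFromPolygons(square(0, 0, 80),
                         list(square(10, 10, 20), square(40, 40, 10)),
                         imageDim = c(100, 100), micronsPerPixel = 0.5,
                         categories = c("vessel", "artefact"))
  path <- tempfile(fileext = ".geojson")
  writeROIGeoJSON(roi, path)
  back <- loadROI(path, imageDim = c(100, 100), micronsPerPixel = 0.5)
  expect_identical(roiMask(back), roiMask(roi))
  expect_equal(area(back), area(roi))
  expect_equal(back@exclusionCategories, c("vessel", "artefact"))
})
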
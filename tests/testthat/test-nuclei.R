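## build OD maps with planted disks directly (no generator involved)
diskMaps <- function(centersPx, radiusPx, dim, hemaOD = 0.5, dabOD = 0) {
  hema <- matrix(0, dim[1], dim[2])
  dab <- matrix(0, dim[1], dim[2])
  for (i in seq_len(nrow(centersPx))) {
    cx <- centersPx[i, 1]; cy <- centersPx[i, 2]
    ix <- floor(cx - radiusPx - 1):ceiling(cx + radiusPx + 1)
    iy <- floor(cy - radiusPx - 1):ceiling(cy + radiusPx + 1)
    ix <- ix[ix >= 0 & ix < dim[2]]; iy <- iy[iy >= 0 & iy < dim[1]]
    disk <- outer((iy + 0.5 - cy)^2, (ix + 0.5 - cx)^2, "+") <= radiusPx^2
    sel <- which(disk, arr.ind = TRUE)
    lin <- iy[sel[, 1]] + 1L + ix[sel[, 2]] * dim[1]
    hema[lin] <- hemaOD
    dab[lin] <- if (length(dabOD) > 1) dabOD[i] else dabOD
  }
  list(hema = hema, dab = dab)
}

test_that("classification bands are exhaustive, exclusive and honour the printed boundaries", {
  expect_equal(as.character(classifyNucleus(39)), "strong")
  expect_equal(as.character(classifyNucleus(89)), "moderate")
  expect_equal(as.character(classifyNucleus(200)), "negative")
  expect_equal(as.character(classifyNucleus(170)), "weak")
  expect_equal(as.character(classifyNucleus(70)), "moderate")
  expect_equal(as.character(classifyNucleus(120)), "weak")

  ## every value maps to exactly one class
  v <- seq(0, 255, by = 0.25)
  cls <- classifyNucleus(v)
  expect_false(any(is.na(cls)))
  expect_equal(as.character(unique(cls[v < 70])), "strong")
  expect_equal(as.character(unique(cls[v >= 70 & v < 120])), "moderate")
  expect_equal(as.character(unique(cls[v >= 120 & v <= 170])), "weak")
  expect_equal(as.character(unique(cls[v > 170])), "negative")

  expect_error(classifyNucleus(-1), "0, 255")
  expect_error(classifyNucleus(256), "0, 255")
})

test_that("central 25-75% selection follows the distance-rank definition", {
  ## 10x10 square: 100 pixels, ranks 26-75 kept -> exactly 50
  expect_equal(sum(centralPixels(matrix(TRUE, 10, 10))), 50L)

  ## small-object rule: <= 4 pixels kept whole
  m <- matrix(FALSE, 4, 4); m[2, 2:4] <- TRUE
  expect_equal(which(centralPixels(m)), which(m))

  expect_error(centralPixels(matrix(FALSE, 3, 3)), "empty")

  ## 5x5 square against a brute-force Euclidean distance oracle
  sq <- matrix(FALSE, 9, 9); sq[3:7, 3:7] <- TRUE
  got <- which(centralPixels(sq))
  fg <- which(sq, arr.ind = TRUE)
  bg <- which(!sq, arr.ind = TRUE)
  d <- vapply(seq_len(nrow(fg)), function(i)
    sqrt(min((bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2)), 0)
  idx <- which(sq)
  o <- order(d, seq_along(d))
  n <- length(idx)
  want <- sort(idx[o[(floor(0.25 * n) + 1):floor(0.75 * n)]])
  expect_equal(sort(got), want)
})

test_that("well-separated disks are detected with sub-pixel centroids", {
  mpp <- 0.23
  centers <- expand.grid(x = seq(60, 460, by = 100),
                         y = c(100, 300))[1:10, ]
  maps <- diskMaps(as.matrix(centers), radiusPx = 3 / mpp, dim = c(520, 520))
  nuc <- detectNuclei(maps$hema, maps$dab, micronsPerPixel = mpp)
  expect_equal(nrow(nuc), 10L)
  expect_true(all(as.character(nuc$class) == "negative"))  # no DAB planted
  for (i in seq_len(10)) {
    d <- sqrt(min((nuc$x_um - (centers$x[i] * mpp))^2 +
                  (nuc$y_um - (centers$y[i] * mpp))^2))
    expect_lt(d, mpp)                     # within 1 px of the planted center
  }
})

test_that("touching disks are split by the watershed", {
  mpp <- 0.23
  r <- 3 / mpp
  ## overlap of 20% of the radius: center distance 1.8 r
  centers <- rbind(c(100, 100), c(100 + 1.8 * r, 100))
  maps <- diskMaps(centers, radiusPx = r, dim = c(200, 260))
  nuc <- detectNuclei(maps$hema, maps$dab, micronsPerPixel = mpp)
  expect_equal(nrow(nuc), 2L)
})

test_that("blank input and empty ROI behave per contract", {
  blank <- matrix(0, 100, 100)
  expect_equal(nrow(detectNuclei(blank, blank)), 0L)

  roi <- roiFromPolygons(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                         imageDim = c(100, 100), micronsPerPixel = 0.23)
  roi@mask[] <- FALSE
  roi@areaMm2 <- 0
  expect_warning(out <- detectNuclei(blank, blank, roi), "empty ROI")
  expect_equal(nrow(out), 0L)
})

test_that("DAB intensity is measured on the central band, not the rim", {
  mpp <- 0.23
  r <- 4.5 / mpp
  centers <- rbind(c(80, 80), c(200, 80), c(80, 200), c(200, 200))
  planted <- c(40, 90, 140, 210)
  maps <- diskMaps(centers, radiusPx = r, dim = c(280, 280),
                   dabOD = -log10(planted / 255))
  nuc <- detectNuclei(maps$hema, maps$dab, micronsPerPixel = mpp)
  expect_equal(nrow(nuc), 4L)
  o <- order(nuc$y_um, nuc$x_um)
  got <- nuc$central_mean_dab[order(nuc$x_um + 1000 * nuc$y_um)]
  want <- planted[order(centers[, 1] + 1000 * centers[, 2])]
  expect_equal(got, want, tolerance = 2.5 / 40)
  expect_equal(as.character(classifyNucleus(got)),
               as.character(classifyNucleus(want)))
})
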
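## shared fixtures: small slides are generated in code, never stored

## a quick single-class slide spec for pipeline tests
quickSpec <- function(nNuclei = 40, quotas = c(negative = 0.86, weak = 0.06,
                                               moderate = 0.04,
                                               strong = 0.04),
                      widthPx = 1200, heightPx = 1200, seed = 42, ...) {
  slideSpec(widthPx, heightPx, nNuclei = nNuclei, classQuotas = quotas,
            inflammationFraction = 0, seed = seed, ...)
}

## run deconvolution + detection on a generated slide
analyzeSlide <- function(slide, mpp = 0.23) {
  od <- rgbToOD(slide$image)
  st <- separateStains(od)
  detectNuclei(st$hematoxylin, st$dab, slide$roi, micronsPerPixel = mpp)
}

## match detected nuclei to ground truth by nearest centroid; returns index
## into `nuc` for each truth row plus the match distance in um
matchToTruth <- function(truth, nuc) {
  tr <- truthNuclei(truth)
  stopifnot(nrow(nuc) > 0, nrow(tr) > 0)
  nn <- integer(nrow(tr)); dist <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    d2 <- (nuc$x_um - tr$x_um[i])^2 + (nuc$y_um - tr$y_um[i])^2
    nn[i] <- which.min(d2)
    dist[i] <- sqrt(min(d2))
  }
  list(idx = nn, dist = dist, truth = tr)
}

## brute-force hotspot oracle: counts for every anchored window pair,
## computed independently of the packaged sliding search
bruteHotspotMax <- function(x, y, bounds) {
  side <- hotspotWindowSideUm()
  clampAnchors <- function(v, lo, hi) {
    if (hi - lo <= side) return(lo)
    sort(unique(c(lo, pmin(pmax(v, lo), hi - side))))
  }
  xs <- clampAnchors(x, bounds[1], bounds[3])
  ys <- clampAnchors(y, bounds[2], bounds[4])
  best <- 0L
  for (x0 in xs) {
    inX <- x >= x0 & x < x0 + side
    if (!any(inX)) next
    ysub <- y[inX]
    cnt <- vapply(ys, function(y0) sum(ysub >= y0 & ysub < y0 + side), 0L)
    best <- max(best, max(cnt))
  }
  best
}
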
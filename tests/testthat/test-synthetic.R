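test_that("largest-remainder apportionment is exact on exact fractions", {
  expect_equal(unname(apportionCounts(200, c(0.6, 0.2, 0.15, 0.05))),
               c(120L, 40L, 30L, 10L))
  expect_equal(sum(apportionCounts(7, c(0.5, 0.25, 0.15, 0.1))), 7L)
  for (n in c(1, 13, 99)) {
    q <- c(0.37, 0.23, 0.4)
    expect_equal(sum(apportionCounts(n, q)), as.integer(n))
  }
  expect_error(apportionCounts(10, c(0.5, 0.4)), "sum to 1")
})

test_that("an empty spec yields a blank white slide", {
  s <- generateSlide(slideSpec(120, 90, nNuclei = 0,
                               inflammationFraction = 0, seed = 1))
  expect_true(all(s$image == 255L))
  expect_identical(dim(s$image), c(90L, 120L, 3L))
  expect_equal(nrow(truthNuclei(s$truth)), 0L)
  expect_equal(hScore(truthSummary(s$truth)), 0)
})

test_that("identical specs give bit-identical slides", {
  sp <- quickSpec(nNuclei = 30, widthPx = 900, heightPx = 900, seed = 9)
  a <- generateSlide(sp)
  b <- generateSlide(sp)
  expect_identical(a$image, b$image)
  expect_identical(truthNuclei(a$truth), truthNuclei(b$truth))
})

test_that("spec validation enforces recoverable intensity bands and quotas", {
  bands <- rbind(negative = c(185, 245), weak = c(130, 160),
                 moderate = c(80, 110), strong = c(30, 75))  # crosses 70
  expect_error(slideSpec(100, 100, 10, intensityBands = bands),
               "strictly inside")
  expect_error(slideSpec(100, 100, 10,
                         classQuotas = c(0.5, 0.3, 0.1, 0.2)), "sum to 1")
  expect_error(slideSpec(100, 100, 10, nucleusRadiusUm = c(6, 4)),
               "min <= max")
})

test_that("impossible densities fail with the density-limit error", {
  expect_error(generateSlide(quickSpec(nNuclei = 5000, widthPx = 500,
                                       heightPx = 500)),
               "density")
})

test_that("the planted summary equals summarizeSlide on the truth table", {
  s <- generateSlide(slideSpec(1500, 1500, nNuclei = 120,
                               inflammationFraction = 0.05, seed = 4))
  tr <- truthNuclei(s$truth)
  direct <- summarizeSlide(
    data.frame(class = tr$planted_class, inside_roi = TRUE),
    areaMm2 = area(s$roi), slideId = "synthetic")
  expect_identical(classCounts(truthSummary(s$truth)), classCounts(direct))
  expect_identical(piPercent(truthSummary(s$truth)), piPercent(direct))
  expect_identical(hScore(truthSummary(s$truth)), hScore(direct))
  ## inflammatory stand-ins exist and stain weakly
  expect_gt(sum(tr$inflammatory), 0)
  expect_true(all(tr$planted_class[tr$inflammatory] == "weak"))
})

test_that("nuclei avoid exclusion polygons", {
  excl <- cbind(c(200, 700, 700, 200), c(200, 200, 700, 700))
  s <- generateSlide(slideSpec(1500, 1500, nNuclei = 120,
                               inflammationFraction = 0,
                               exclusionPolygons = list(excl), seed = 6))
  tr <- truthNuclei(s$truth)
  mpp <- 0.23
  inExcl <- tr$x_um / mpp > 200 & tr$x_um / mpp < 700 &
    tr$y_um / mpp > 200 & tr$y_um / mpp < 700
  expect_equal(sum(inExcl), 0L)
  expect_lt(area(s$roi), 1500^2 * mpp^2 / 1e6)
})

test_that("planted hotspots are recovered exactly by the window search", {
  ## window side 559 um = 2430 px fits inside a 3000 px slide
  sp <- slideSpec(3000, 3000, nNuclei = 0, inflammationFraction = 0,
                  seed = 3)
  sp30 <- plantHotspot(sp, 30)
  s <- generateSlide(sp30)
  tr <- truthNuclei(s$truth)
  expect_equal(nrow(tr), 30L)
  hs <- findHotspot(data.frame(x_um = tr$x_um, y_um = tr$y_um,
                               class = tr$planted_class),
                    roiBoundsUm = c(0, 0, 3000, 3000) * 0.23)
  expect_equal(positiveCount(hs), 30L)

  ## Webster category flips just above the 23-cell cutoff
  s24 <- generateSlide(plantHotspot(sp, 24))
  tr24 <- truthNuclei(s24$truth)
  hs24 <- findHotspot(data.frame(x_um = tr24$x_um, y_um = tr24$y_um,
                                 class = tr24$planted_class),
                      roiBoundsUm = c(0, 0, 3000, 3000) * 0.23)
  expect_equal(hs24@websterCategory, "high")

  ## count 0 only annotates
  sp0 <- plantHotspot(sp, 0)
  expect_equal(sp0@hotspotPlan$count, 0L)
  expect_identical(generateSlide(sp0)$image, generateSlide(sp)$image)

  ## infeasible plant is refused
  expect_error(plantHotspot(sp, 100000), "cannot place")
})

test_that("synthetic cohorts honour the censoring contract", {
  co <- generateCohort(50, effect = 0, censorTime = 0, seed = 2)
  expect_true(all(co$event_flag == "alive"))
  expect_true(all(co$survival_days == 0))

  co2 <- generateCohort(300, effect = 0, censorTime = 2000, seed = 2)
  expect_gt(sum(co2$event_flag == "died-MCT"), 0)
  ## null effect: Cox estimate consistent with HR 1
  fit <- coxUnivariable(co2$ki67_metric, co2$survival_days, co2$event_flag)
  expect_gt(effectSize(fit), 0.8)
  expect_lt(effectSize(fit), 1.25)

  expect_error(generateCohort(1), ">= 2")
  expect_error(generateCohort(10, baselineHazard = 0), "baselineHazard")
  ## reproducible under seed, no global RNG pollution
  set.seed(123); before <- runif(1)
  set.seed(123)
  a <- generateCohort(10, seed = 5)
  expect_identical(runif(1), before)
  expect_identical(a, generateCohort(10, seed = 5))
})

test_that("a generated slide is recovered end-to-end by the pipeline", {
  s <- generateSlide(quickSpec(nNuclei = 80, widthPx = 1600,
                               heightPx = 1600, seed = 12))
  nuc <- analyzeSlide(s)
  expect_equal(nrow(nuc), nrow(truthNuclei(s$truth)))
  m <- summarizeSlide(nuc, area(s$roi))
  expect_lt(abs(piPercent(m) - piPercent(truthSummary(s$truth))), 2)
  mt <- matchToTruth(s$truth, nuc)
  expect_lt(max(mt$dist), 0.23)           # matched within 1 px
  expect_equal(as.character(nuc$class[mt$idx]),
               as.character(mt$truth$planted_class))
})
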
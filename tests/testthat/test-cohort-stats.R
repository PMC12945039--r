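test_that("inflammation exclusion keeps scores 1 and 2", {
  co <- data.frame(slide_id = 1:9,
                   q_inflammation = c(2, 2, 2, 1, 1, 0, 0, 0, NA))
  expect_equal(nrow(excludeInflamed(co)), 5L)
  all2 <- data.frame(q_inflammation = rep(2, 4))
  expect_equal(excludeInflamed(all2), all2)
  expect_equal(nrow(excludeInflamed(data.frame(q_inflammation = rep(0, 3)))),
               0L)
})

test_that("fold changes reproduce the printed cohort values", {
  expect_equal(foldChange(26, 21), -1.24)   # H-score
  expect_equal(foldChange(14, 11), -1.27)   # proliferation index
  expect_equal(foldChange(1056, 845), -1.25) # positive density
  expect_equal(foldChange(346, 305), -1.13) # strong density
  expect_equal(foldChange(5, 5), 1)
  ## antisymmetry: equal magnitude, opposite sign
  set.seed(2)
  for (i in 1:25) {
    a <- runif(1, 1, 100); b <- runif(1, 1, 100)
    if (a == b) next
    expect_equal(abs(foldChange(a, b)), abs(foldChange(b, a)))
    expect_equal(sign(foldChange(a, b)), -sign(foldChange(b, a)))
  }
  expect_warning(out <- foldChange(0, 5), "non-positive")
  expect_true(is.na(out))
})

test_that("category summaries use half-away-from-zero integer percentages", {
  co <- data.frame(manual_hotspot_category = rep(c("low", "high"),
                                                 c(149, 93)))
  ws <- websterSummary(co)
  expect_equal(ws$percent[ws$category == "low"], 62)
  expect_equal(ws$percent[ws$category == "high"], 38)
  expect_equal(sum(ws$n), 242L)

  ws2 <- websterSummary(data.frame(manual_hotspot_category = c("low",
                                                               "high")))
  expect_equal(ws2$percent, c(50, 50))
  ws3 <- websterSummary(
    data.frame(manual_hotspot_category = c("low", "low", "high")))
  expect_equal(ws3$percent, c(67, 33))
  expect_error(websterSummary(
    data.frame(manual_hotspot_category = NA_character_)), "no hotspot")

  ## percent summaries sum to 100 +- 1 under integer rounding
  set.seed(11)
  for (i in 1:20) {
    n <- sample(3:400, 2)
    w <- websterSummary(
      data.frame(manual_hotspot_category = rep(c("low", "high"), n)))
    expect_lte(abs(sum(w$percent) - 100), 1)
  }
})

test_that("PI categories match a direct tally on a synthetic cohort", {
  set.seed(9)
  pi <- c(runif(60, 0, 15), runif(25, 15.1, 29.9), runif(15, 30, 60))
  co <- data.frame(pi_percent = sample(pi),
                   q_inflammation = sample(0:2, 100, replace = TRUE))
  ps <- piCategorySummary(co)
  allRows <- ps[ps$subset == "all", ]
  expect_equal(allRows$n[allRows$category == "low"], sum(pi <= 15))
  expect_equal(allRows$n[allRows$category == "high"], sum(pi >= 30))
  sub <- excludeInflamed(co)
  exRows <- ps[ps$subset == "inflammation-excluded", ]
  expect_equal(exRows$n[exRows$category == "low"],
               sum(sub$pi_percent <= 15))
  expect_equal(exRows$total[1], nrow(sub))

  allZero <- piCategorySummary(data.frame(pi_percent = rep(0, 12)))
  expect_equal(allZero$percent[allZero$category == "low"], 100)
})

test_that("the rank-sum test uses exact enumeration for small groups", {
  r <- compareGroups(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(pValue(r), 1 / 3, tolerance = 1e-12)
  expect_match(r@test, "exact")

  ## identical groups: perfectly symmetric, p = 1
  r2 <- compareGroups(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(pValue(r2), 1)

  ## exact p agrees with an independent exact implementation for all
  ## tie-free group sizes up to 5
  set.seed(17)
  for (n1 in 2:5) for (n2 in 2:5) {
    x <- sample(seq_len(50), n1)
    y <- sample(setdiff(seq_len(50), x), n2)
    mine <- compareGroups(c(x, y), rep(c("a", "b"), c(n1, n2)))
    ref <- stats::wilcox.test(x, y, exact = TRUE)
    expect_equal(pValue(mine), ref$p.value, tolerance = 1e-12)
  }

  ## large groups fall back to the tie-corrected normal approximation
  set.seed(18)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  big <- compareGroups(c(x, y), rep(c("a", "b"), c(30, 25)))
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(pValue(big), ref$p.value)
  expect_match(big@test, "approximation")

  expect_error(compareGroups(1:4, factor(rep("a", 4), levels = c("a", "b"))),
               "non-empty")
})

test_that("three-group comparisons use Kruskal-Wallis", {
  r <- compareGroups(rep(c(1, 2, 3), 3), rep(c("I", "II", "III"), each = 3))
  expect_equal(r@statistic, 0)
  expect_match(r@test, "Kruskal")
  set.seed(3)
  v <- rnorm(30); g <- rep(c("I", "II", "III"), each = 10)
  expect_equal(pValue(compareGroups(v, g)),
               stats::kruskal.test(v, factor(g))$p.value)
})

test_that("Spearman correlation matches hand-ranked computation", {
  expect_equal(effectSize(spearmanCorrelation(1:6, 2 * (1:6) + 3)), 1)
  expect_equal(effectSize(spearmanCorrelation(1:6, -(1:6))), -1)
  ## 5-pair worked set: ranks y = (2,1,4,3,5), sum d^2 = 4,
  ## rho = 1 - 6*4 / (5*24) = 0.8
  expect_equal(effectSize(spearmanCorrelation(1:5, c(2, 1, 4, 3, 5))), 0.8)
  flagged <- spearmanCorrelation(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(effectSize(flagged)))
  expect_match(flagged@note, "constant")
})

test_that("Cox fits honour the censoring rules and symmetry", {
  co <- generateCohort(120, effect = log(2), seed = 77)
  fit <- coxUnivariable(co$ki67_metric, co$survival_days, co$event_flag)
  inv <- coxUnivariable(-co$ki67_metric, co$survival_days, co$event_flag)
  expect_equal(effectSize(inv), 1 / effectSize(fit), tolerance = 1e-6)

  flat <- coxUnivariable(rep(3, 120), co$survival_days, co$event_flag)
  expect_equal(effectSize(flat), 1)
  expect_match(flat@note, "constant")

  expect_error(coxUnivariable(co$ki67_metric, co$survival_days,
                              rep("alive", 120)), "2 events")

  ## died-other records are events under all-deaths, censored under mct-only
  flags <- c(rep("died-MCT", 5), rep("died-other", 10), rep("alive", 15))
  days <- seq_len(30)
  metric <- rnorm(30)
  a <- coxUnivariable(metric, days, flags, censorRule = "all-deaths")
  b <- coxUnivariable(metric, days, flags, censorRule = "mct-only")
  expect_equal(unname(a@n["events"]), 15L)
  expect_equal(unname(b@n["events"]), 5L)
})

test_that("Kaplan-Meier dichotomisation and product-limit steps are exact", {
  km <- kmDichotomize(c(1, 2, 3, 4), c(10, 20, 30, 40),
                      rep("died-MCT", 4))
  expect_equal(as.character(km$group), c("low", "low", "high", "high"))

  allEqual <- kmDichotomize(rep(2, 4), c(10, 20, 30, 40),
                            rep("died-MCT", 4))
  expect_match(allEqual$note, "degenerate")

  ## hand-computed product limit, one group with censoring:
  ## times 1,2,3,4,5,6; events 1,1,0,1,0,1
  ## S = 5/6, 2/3, 2/3, 4/9, 4/9, 0
  metric <- c(0, 0, 0, 1, 1, 1)           # low: first three
  km2 <- kmDichotomize(
    metric, c(1, 2, 3, 1, 2, 3),
    c("died-MCT", "died-MCT", "alive", "died-MCT", "alive", "died-MCT"),
    threshold = 0.5)
  lo <- km2$curve[km2$curve$group == "low", ]
  expect_equal(lo$survival, c(2/3, 1/3, 1/3))
  hi <- km2$curve[km2$curve$group == "high", ]
  expect_equal(hi$survival, c(2/3, 2/3, 0))

  ## no censoring: the curve equals the empirical survival function
  tt <- c(5, 1, 3, 2, 4)
  km3 <- kmDichotomize(c(rep(0, 5), 1), c(tt, 9), rep("died-MCT", 6),
                       threshold = 0.5)
  crv <- km3$curve[km3$curve$group == "low", ]
  expect_equal(crv$survival, 1 - ecdf(tt)(sort(tt)))
})

test_that("inter-laboratory comparison reports the mean intensity shift", {
  set.seed(55)
  a <- runif(5000, 60, 160)
  same <- interlabIntensityCompare(c(a, a),
                                   rep(c("DE", "CH"), each = 5000))
  expect_equal(same$meanDifference, 0)

  b <- a + 2                              # planted 2-unit protocol shift
  shift <- interlabIntensityCompare(c(a, b),
                                    rep(c("DE", "CH"), each = 5000))
  expect_equal(shift$meanDifference, 2, tolerance = 1e-9)
  expect_lt(pValue(shift$test), 0.05)

  tiny <- interlabIntensityCompare(c(1, 2, 3, 10, 11, 12),
                                   rep(c("DE", "CH"), each = 3))
  expect_match(tiny$test@test, "exact")
})
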
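## Cohort statistics layer: quality-stratified exclusion, fold changes,
## category summaries, rank tests (exact enumeration for small samples),
## Spearman correlation, univariable Cox regression and median-dichotomised
## Kaplan-Meier curves. No multiple-testing correction is applied by
## default; p-values are exploratory (Benjamini-Hochberg available via
## adjustP).

#' Exclude highly inflamed slides
#'
#' Retains records whose inflammation quality score is 1 or 2; score-0
#' (marked inflammation) slides are removed, as their metrics are confounded
#' by non-neoplastic Ki-67-positive cells.
#'
#' @param cohort data.frame with a \code{q_inflammation} column.
#' @return the filtered data.frame.
#' @export
excludeInflamed <- function(cohort) {
  if (!"q_inflammation" %in% names(cohort))
    stop("cohort lacks a q_inflammation column")
  cohort[!is.na(cohort$q_inflammation) &
           cohort$q_inflammation %in% c(1, 2), , drop = FALSE]
}

#' Signed fold change between two means
#'
#' Magnitude \code{max(a, b) / min(a, b)} rounded to 2 decimals; the sign is
#' negative when the excluded-subset mean is below the all-slides mean
#' (a decrease after exclusion), and +1.00 when the means are equal.
#'
#' @param meanAll mean over all slides (> 0).
#' @param meanExcluded mean over the inflammation-excluded subset (> 0).
#' @return signed fold change; \code{NA} with a warning when a mean is not
#'   positive.
#' @export
#' @examples
#' foldChange(26, 21)   # -1.24
#' foldChange(14, 11)   # -1.27
foldChange <- function(meanAll, meanExcluded) {
  if (is.na(meanAll) || is.na(meanExcluded) ||
      meanAll <= 0 || meanExcluded <= 0) {
    warning("fold change undefined for non-positive means")
    return(NA_real_)
  }
  if (meanAll == meanExcluded) return(1)
  mag <- roundHalfAway(max(meanAll, meanExcluded) /
                         min(meanAll, meanExcluded), 2)
  if (meanExcluded < meanAll) -mag else mag
}

#' Webster hotspot category summary
#'
#' Counts and integer percentages (rounded half away from zero) of records
#' in the low (<= 23) and high (> 23) manual hotspot categories.
#'
#' @param cohort data.frame with a \code{manual_hotspot_category} column
#'   (values \code{"low"} / \code{"high"}; NA ignored).
#' @return data.frame with columns \code{category}, \code{n},
#'   \code{percent}.
#' @export
#' @examples
#' co <- data.frame(manual_hotspot_category = rep(c("low", "high"),
#'                                                c(149, 93)))
#' websterSummary(co)
websterSummary <- function(cohort) {
  if (!"manual_hotspot_category" %in% names(cohort))
    stop("cohort lacks a manual_hotspot_category column")
  v <- cohort$manual_hotspot_category
  v <- v[!is.na(v)]
  if (!length(v)) stop("no hotspot categories present")
  tal <- table(factor(v, levels = c("low", "high")))
  data.frame(category = names(tal), n = as.integer(tal),
             percent = roundHalfAway(100 * as.integer(tal) / sum(tal)),
             stringsAsFactors = FALSE)
}

#' Proliferation-index category summary
#'
#' Counts and integer percentages of slides with low (PI <= \code{lowMax})
#' and high (PI >= \code{highMin}) proliferation indices, for all slides and
#' for the inflammation-excluded subset (when quality scores are present).
#'
#' @param cohort data.frame with \code{pi_percent} and optionally
#'   \code{q_inflammation}.
#' @param lowMax low-PI threshold (default 15).
#' @param highMin high-PI threshold (default 30).
#' @return data.frame with columns \code{subset}, \code{category},
#'   \code{n}, \code{total}, \code{percent}.
#' @export
piCategorySummary <- function(cohort, lowMax = 15, highMin = 30) {
  if (!"pi_percent" %in% names(cohort))
    stop("cohort lacks a pi_percent column")
  one <- function(df, label) {
    pi <- df$pi_percent
    data.frame(subset = label, category = c("low", "high"),
               n = c(sum(pi <= lowMax), sum(pi >= highMin)),
               total = length(pi),
               percent = roundHalfAway(
                 100 * c(sum(pi <= lowMax), sum(pi >= highMin)) /
                   length(pi)),
               stringsAsFactors = FALSE)
  }
  out <- one(cohort, "all")
  if ("q_inflammation" %in% names(cohort))
    out <- rbind(out, one(excludeInflamed(cohort), "inflammation-excluded"))
  out
}

## exact two-sided rank-sum p by full enumeration of group assignments;
## average ranks handle ties, so the null distribution conditions on the
## observed tie pattern
.rankSumExactP <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  wObs <- sum(r[seq_len(n1)])
  mu <- n1 * mean(r)
  combs <- utils::combn(n, n1)
  w <- colSums(matrix(r[combs], nrow = n1))
  list(statistic = wObs,
       p = mean(abs(w - mu) >= abs(wObs - mu) - 1e-9))
}

#' Compare a Ki-67 metric between groups
#'
#' Two groups: two-sided Wilcoxon rank-sum test -- exact enumeration of all
#' group assignments when both groups have at most 8 observations (valid
#' under ties via average ranks), normal approximation with tie correction
#' otherwise. Three or more groups: Kruskal-Wallis test.
#'
#' @param values numeric metric values.
#' @param groups group labels (coerced to factor).
#' @return a [TestResult-class].
#' @export
#' @examples
#' compareGroups(c(1, 2, 3, 4), c("a", "a", "b", "b"))
compareGroups <- function(values, groups) {
  g <- factor(groups)
  if (any(table(g) == 0L) || nlevels(g) < 2L)
    stop("need at least two non-empty groups")
  split_ <- split(values, g)
  ns <- vapply(split_, length, 1L)
  if (any(ns == 0L)) stop("empty group")
  if (nlevels(g) == 2L) {
    x <- split_[[1]]; y <- split_[[2]]
    if (length(x) <= 8L && length(y) <= 8L) {
      ex <- .rankSumExactP(x, y)
      .testResult("Wilcoxon rank-sum (exact enumeration)",
                  statistic = ex$statistic, pValue = ex$p, n = ns)
    } else {
      wt <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
      .testResult("Wilcoxon rank-sum (normal approximation)",
                  statistic = unname(wt$statistic), pValue = wt$p.value,
                  n = ns)
    }
  } else {
    kw <- stats::kruskal.test(values, g)
    stat <- unname(kw$statistic)
    if (is.nan(stat)) stat <- 0          # all values tied across groups
    .testResult("Kruskal-Wallis", statistic = stat,
                pValue = if (is.nan(kw$p.value)) 1 else kw$p.value, n = ns)
  }
}

#' Spearman correlation
#'
#' Spearman's rho from ranked data with average ranks for ties. A constant
#' input yields a flagged result with NA rho.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return a [TestResult-class] with rho as the effect.
#' @export
#' @examples
#' spearmanCorrelation(1:5, c(2, 1, 4, 3, 5))
spearmanCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(.testResult("Spearman correlation", n = length(x),
                       note = "constant input: rho undefined"))
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  .testResult("Spearman correlation", statistic = unname(ct$statistic),
              pValue = ct$p.value, effect = unname(ct$estimate),
              n = length(x))
}

## map event flags to 0/1 under the chosen censoring rule
.eventIndicator <- function(eventFlag,
                            censorRule = c("all-deaths", "mct-only")) {
  censorRule <- match.arg(censorRule)
  ok <- eventFlag %in% c("died-MCT", "died-other", "alive")
  if (any(!ok))
    stop("event_flag values must be 'died-MCT', 'died-other' or 'alive'")
  if (censorRule == "all-deaths") as.integer(eventFlag != "alive")
  else as.integer(eventFlag == "died-MCT")
}

#' Univariable Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Efron tie handling; reports the hazard ratio
#' per metric unit with a 95\% Wald interval. Two censoring rules are
#' available: all deaths are events, or only tumour-related deaths are
#' events (other deaths censored). A constant metric returns HR 1
#' (coefficient 0) flagged as uninformative.
#'
#' @param metric numeric Ki-67 metric per record.
#' @param survivalDays follow-up time in days.
#' @param eventFlag character: \code{"died-MCT"}, \code{"died-other"} or
#'   \code{"alive"}.
#' @param censorRule \code{"all-deaths"} or \code{"mct-only"}.
#' @return a [TestResult-class] with the HR as the effect.
#' @export
coxUnivariable <- function(metric, survivalDays, eventFlag,
                           censorRule = c("all-deaths", "mct-only")) {
  event <- .eventIndicator(eventFlag, censorRule)
  if (any(survivalDays < 0)) stop("survival_days must be non-negative")
  if (sum(event) < 2L) stop("need at least 2 events")
  n <- c(events = sum(event), censored = sum(event == 0L))
  if (stats::sd(metric) == 0)
    return(.testResult("Cox univariable (Efron ties)", statistic = 0,
                       pValue = NA_real_, effect = 1, n = n,
                       note = "constant metric: no information"))
  fit <- tryCatch(
    survival::coxph(survival::Surv(survivalDays, event) ~ metric,
                    ties = "efron"),
    warning = function(w) w)
  if (inherits(fit, "warning"))
    return(.testResult("Cox univariable (Efron ties)", n = n,
                       note = paste("fit flagged:",
                                    conditionMessage(fit))))
  sm <- summary(fit)
  .testResult("Cox univariable (Efron ties)",
              statistic = unname(sm$coefficients[1, "z"]),
              pValue = unname(sm$coefficients[1, "Pr(>|z|)"]),
              effect = unname(sm$conf.int[1, "exp(coef)"]),
              ciLower = unname(sm$conf.int[1, "lower .95"]),
              ciUpper = unname(sm$conf.int[1, "upper .95"]),
              n = n)
}

#' Median-dichotomised Kaplan-Meier curves
#'
#' Splits records at a threshold (default: the metric's median; values equal
#' to the threshold go to the low group, so "Ki-67-high" means strictly
#' above the median) and computes product-limit survival curves per group
#' with censoring. A degenerate split (all records on one side) is returned
#' flagged rather than raising.
#'
#' @param metric numeric Ki-67 metric per record.
#' @param survivalDays follow-up time in days.
#' @param eventFlag see [coxUnivariable()].
#' @param threshold split point; default \code{median(metric)}.
#' @param censorRule \code{"all-deaths"} or \code{"mct-only"}.
#' @return list with \code{threshold}, \code{group} (factor low/high),
#'   \code{curve} (data.frame time, n_risk, n_event, survival, group) and
#'   \code{note} (non-empty when degenerate).
#' @export
kmDichotomize <- function(metric, survivalDays, eventFlag, threshold = NULL,
                          censorRule = c("all-deaths", "mct-only")) {
  event <- .eventIndicator(eventFlag, censorRule)
  if (is.null(threshold)) threshold <- stats::median(metric)
  group <- factor(ifelse(metric > threshold, "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) == 0L)) {
    return(list(threshold = threshold, group = group,
                curve = data.frame(time = numeric(), n_risk = integer(),
                                   n_event = integer(),
                                   survival = numeric(),
                                   group = character()),
                note = "degenerate dichotomisation: all records in one group"))
  }
  sf <- survival::survfit(survival::Surv(survivalDays, event) ~ group)
  gl <- rep(sub("^group=", "", names(sf$strata)), sf$strata)
  curve <- data.frame(time = sf$time, n_risk = sf$n.risk,
                      n_event = sf$n.event, survival = sf$surv,
                      group = gl, stringsAsFactors = FALSE)
  list(threshold = threshold, group = group, curve = curve, note = "")
}

#' Inter-laboratory DAB intensity comparison
#'
#' Compares pooled per-nucleus central mean DAB pseudo-intensities of
#' Ki-67-positive nuclei between two staining protocol groups: Wilcoxon
#' rank-sum p-value (exact enumeration for tiny groups) plus the absolute
#' difference of group means in pseudo-intensity units.
#'
#' @param intensity per-nucleus pseudo-intensities pooled across slides.
#' @param protocolGroup two-level group label per nucleus.
#' @return list with \code{test} (a [TestResult-class]) and
#'   \code{meanDifference}.
#' @export
interlabIntensityCompare <- function(intensity, protocolGroup) {
  g <- factor(protocolGroup)
  if (nlevels(g) != 2L) stop("need exactly two protocol groups")
  tr <- compareGroups(intensity, g)
  m <- tapply(intensity, g, mean)
  list(test = tr, meanDifference = abs(unname(m[1] - m[2])))
}

#' Tidy one-row summary of a test result
#'
#' @param tr a [TestResult-class].
#' @return one-row data.frame with columns test, n, statistic, p, effect,
#'   ci_lower, ci_upper, note -- the tidy TSV row format used by the
#'   command-line report.
#' @export
testResultRow <- function(tr) {
  stopifnot(is(tr, "TestResult"))
  lbl <- if (is.null(names(tr@n))) as.character(tr@n)
         else sprintf("%s=%d", names(tr@n), tr@n)
  data.frame(test = tr@test,
             n = paste(lbl, collapse = ";"),
             statistic = tr@statistic, p = tr@pValue, effect = tr@effect,
             ci_lower = tr@ciLower, ci_upper = tr@ciUpper, note = tr@note,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment (off by default in reports)
#'
#' @param p numeric p-values.
#' @return adjusted p-values.
#' @export
adjustP <- function(p) stats::p.adjust(p, method = "BH")
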
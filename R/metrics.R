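## Per-slide Ki-67 metrics, the three-axis quality rubric and TSV export.

## single arithmetic path shared by summarizeSlide() and the synthetic
## generator's planted summary, so the plant/recover invariant is exact
.metricsFromCounts <- function(nNegative, nWeak, nModerate, nStrong,
                               areaMm2, slideId = "slide") {
  nTotal <- nNegative + nWeak + nModerate + nStrong
  nPositive <- nWeak + nModerate + nStrong
  if (nTotal == 0L) {
    pi <- 0; h <- 0
  } else {
    pi <- 100 * nPositive / nTotal
    h <- 1 * (100 * nWeak / nTotal) + 2 * (100 * nModerate / nTotal) +
      3 * (100 * nStrong / nTotal)
  }
  new("SlideMetrics", slideId = slideId, areaMm2 = areaMm2,
      nNegative = as.integer(nNegative), nWeak = as.integer(nWeak),
      nModerate = as.integer(nModerate), nStrong = as.integer(nStrong),
      nTotal = as.integer(nTotal), nPositive = as.integer(nPositive),
      piPercent = pi, hScore = h,
      positiveDensity = nPositive / areaMm2,
      strongDensity = nStrong / areaMm2)
}

#' Summarise a slide from its nucleus table
#'
#' Computes class counts over the in-ROI nuclei, the proliferation index
#' \code{100 * nPositive / nTotal}, the H-score
#' \code{1 * \%weak + 2 * \%moderate + 3 * \%strong} (percentages over all
#' assessed nuclei), and positive / strong densities per mm^2. An empty
#' nucleus table yields zero PI and H-score with a warning rather than an
#' error, so degenerate ROIs do not abort a batch.
#'
#' @param nuclei data.frame with columns \code{class} and (optionally)
#'   \code{inside_roi}; only in-ROI rows are assessed.
#' @param areaMm2 assessed tumour area in mm^2 (> 0).
#' @param slideId slide identifier.
#' @return a [SlideMetrics-class].
#' @export
#' @examples
#' nuc <- data.frame(class = rep(c("negative", "weak", "moderate", "strong"),
#'                               c(50, 20, 20, 10)))
#' summarizeSlide(nuc, areaMm2 = 0.1)
summarizeSlide <- function(nuclei, areaMm2, slideId = "slide") {
  .assertScalarNumber(areaMm2, "areaMm2", 0, strict.lower = TRUE)
  if (nrow(nuclei) && "inside_roi" %in% names(nuclei))
    nuclei <- nuclei[nuclei$inside_roi, , drop = FALSE]
  tal <- table(factor(nuclei$class,
                      levels = c("negative", "weak", "moderate", "strong")))
  if (sum(tal) == 0L)
    warning(sprintf("slide '%s': no assessed nuclei; PI and H-score set to 0",
                    slideId))
  .metricsFromCounts(tal[["negative"]], tal[["weak"]], tal[["moderate"]],
                     tal[["strong"]], areaMm2, slideId)
}

#' Quality rubric: tissue section completeness
#'
#' Score 2 when more than 90\% of the tumour tissue is assessable, 1 for
#' 50-90\%, 0 below 50\%. Boundary values (exactly 50\% or 90\%) belong to
#' the middle score, matching the strict inequalities of the outer classes.
#'
#' @param fractionAssessable fraction in [0, 1].
#' @return integer score 0, 1 or 2.
#' @export
#' @examples
#' scoreTissue(0.95); scoreTissue(0.9); scoreTissue(0.4)
scoreTissue <- function(fractionAssessable) {
  .assertFraction(fractionAssessable, "fractionAssessable")
  if (fractionAssessable > 0.90) 2L
  else if (fractionAssessable >= 0.50) 1L
  else 0L
}

#' Quality rubric: inflammation
#'
#' Score 2 (negligible) below 1\% inflammatory cells, 1 (mild) for 1-10\%,
#' 0 (marked) above 10\%. Boundaries (1\%, 10\%) belong to the middle score.
#'
#' @param fractionInflammatory fraction in [0, 1].
#' @return integer score 0, 1 or 2.
#' @export
#' @examples
#' scoreInflammation(0.005); scoreInflammation(0.05); scoreInflammation(0.2)
scoreInflammation <- function(fractionInflammatory) {
  .assertFraction(fractionInflammatory, "fractionInflammatory")
  if (fractionInflammatory < 0.01) 2L
  else if (fractionInflammatory <= 0.10) 1L
  else 0L
}

#' Quality rubric: nuclear segmentation
#'
#' Score 2 (good) below 1\% unlabelled nuclei, 1 (mildly reduced) for
#' 1-10\%, 0 (reduced) above 10\%.
#'
#' @param fractionUnlabelled fraction in [0, 1].
#' @return integer score 0, 1 or 2.
#' @export
#' @examples
#' scoreSegmentation(0); scoreSegmentation(0.02); scoreSegmentation(0.15)
scoreSegmentation <- function(fractionUnlabelled) {
  .assertFraction(fractionUnlabelled, "fractionUnlabelled")
  if (fractionUnlabelled < 0.01) 2L
  else if (fractionUnlabelled <= 0.10) 1L
  else 0L
}

#' Quality scores constructor
#'
#' @param tissue,inflammation,segmentation integer scores in \{0, 1, 2\}.
#' @return a [QualityScores-class].
#' @export
qualityScores <- function(tissue = 2L, inflammation = 2L, segmentation = 2L) {
  new("QualityScores", tissue = as.integer(tissue),
      inflammation = as.integer(inflammation),
      segmentation = as.integer(segmentation))
}

.slideTsvColumns <- c(
  "slide_id", "area_mm2", "n_negative", "n_weak", "n_moderate", "n_strong",
  "n_total", "n_positive", "pi_percent", "h_score",
  "positive_density_per_mm2", "strong_density_per_mm2",
  "q_tissue", "q_inflammation", "q_segmentation",
  "hotspot_count", "hotspot_density_per_mm2", "webster_category",
  "proliferation_factor")

#' Assemble one slide TSV row
#'
#' @param metrics a [SlideMetrics-class].
#' @param quality optional [QualityScores-class].
#' @param hotspot optional [HotspotResult-class].
#' @return one-row data.frame in the fixed slide-TSV column order. PI,
#'   H-score and densities are rounded to 1 decimal; area to 4 decimals;
#'   the proliferation factor to 3.
#' @export
slideTsvRow <- function(metrics, quality = NULL, hotspot = NULL) {
  stopifnot(is(metrics, "SlideMetrics"))
  row <- data.frame(
    slide_id = metrics@slideId,
    area_mm2 = round(metrics@areaMm2, 4),
    n_negative = metrics@nNegative, n_weak = metrics@nWeak,
    n_moderate = metrics@nModerate, n_strong = metrics@nStrong,
    n_total = metrics@nTotal, n_positive = metrics@nPositive,
    pi_percent = round(metrics@piPercent, 1),
    h_score = round(metrics@hScore, 1),
    positive_density_per_mm2 = round(metrics@positiveDensity, 1),
    strong_density_per_mm2 = round(metrics@strongDensity, 1),
    q_tissue = if (is.null(quality)) NA_integer_ else quality@tissue,
    q_inflammation = if (is.null(quality)) NA_integer_
                     else quality@inflammation,
    q_segmentation = if (is.null(quality)) NA_integer_
                     else quality@segmentation,
    hotspot_count = if (is.null(hotspot)) NA_integer_
                    else hotspot@positiveCount,
    hotspot_density_per_mm2 = if (is.null(hotspot)) NA_real_
                              else round(hotspot@hotspotDensity, 1),
    webster_category = if (is.null(hotspot)) NA_character_
                       else hotspot@websterCategory,
    proliferation_factor = if (is.null(hotspot)) NA_real_
                           else round(hotspot@proliferationFactor, 3),
    stringsAsFactors = FALSE)
  row[, .slideTsvColumns]
}

#' Write slide metrics to a TSV file
#'
#' One row per slide, tab-separated, fixed header and column order (stable
#' across runs).
#'
#' @param rows data.frame from [slideTsvRow()] (one or more rows bound
#'   together), or a [SlideMetrics-class] (then \code{quality} and
#'   \code{hotspot} may be given).
#' @param path output path.
#' @param quality,hotspot forwarded to [slideTsvRow()] when \code{rows} is a
#'   [SlideMetrics-class].
#' @return invisibly, the path.
#' @export
exportSlideTSV <- function(rows, path, quality = NULL, hotspot = NULL) {
  if (is(rows, "SlideMetrics")) rows <- slideTsvRow(rows, quality, hotspot)
  if (!identical(names(rows), .slideTsvColumns))
    stop("rows must carry the fixed slide TSV columns")
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write the per-nucleus table as TSV
#'
#' Columns: id, x_um, y_um, area_um2, central_mean_dab, class, inside_roi.
#'
#' @param nuclei data.frame from [detectNuclei()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
exportNucleiTSV <- function(nuclei, path) {
  cols <- c("id", "x_um", "y_um", "area_um2", "central_mean_dab", "class",
            "inside_roi")
  if (!all(cols %in% names(nuclei)))
    stop("nuclei table lacks the standard detection columns")
  utils::write.table(nuclei[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a slide TSV written by [exportSlideTSV()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readSlideTSV <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
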
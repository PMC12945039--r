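## Config-driven end-to-end orchestration: image + annotation in, slide TSV
## row out; batch processing with per-slide failure isolation; cohort-level
## summary and statistics.

#' Pipeline configuration
#'
#' All tunables of the per-slide pipeline in one flat list; every default is
#' the module default it feeds. The configuration round-trips unchanged
#' through [writePipelineConfig()] / [readPipelineConfig()].
#'
#' @param micronsPerPixel pixel pitch in microns (0.23 = the 40x scan
#'   resolution the workflow assumes).
#' @param background per-channel white reference for the OD transform.
#' @param stainVectors 3x3 stain matrix (rows hematoxylin, DAB, residual;
#'   row-normalised on use).
#' @param odThreshold,smoothSigmaUm,minAreaUm2,maxAreaUm2 detection
#'   parameters, see [nucleusDetectionParams()].
#' @param tNegative,tWeak,tStrong classification bands, see [classBands()].
#' @param hotspotStrideUm optional extra anchor grid stride for the hotspot
#'   search (NA = anchored candidates only, which is already exact).
#' @param censorRule survival censoring rule, \code{"all-deaths"} or
#'   \code{"mct-only"}.
#' @param seed integer seed for any stochastic step.
#' @return a named list with class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(micronsPerPixel = 0.23,
                           background = c(255, 255, 255),
                           stainVectors = NULL,
                           odThreshold = 0.15, smoothSigmaUm = 0.5,
                           minAreaUm2 = 8, maxAreaUm2 = 150,
                           tNegative = 170, tWeak = 120, tStrong = 70,
                           hotspotStrideUm = NA_real_,
                           censorRule = "all-deaths", seed = 1L) {
  if (is.null(stainVectors)) stainVectors <- hdabBasis()@vectors
  structure(list(
    micronsPerPixel = micronsPerPixel, background = background,
    stainVectors = matrix(as.numeric(stainVectors), 3, 3,
                          dimnames = list(c("hematoxylin", "dab",
                                            "residual"),
                                          c("r", "g", "b"))),
    odThreshold = odThreshold, smoothSigmaUm = smoothSigmaUm,
    minAreaUm2 = minAreaUm2, maxAreaUm2 = maxAreaUm2,
    tNegative = tNegative, tWeak = tWeak, tStrong = tStrong,
    hotspotStrideUm = hotspotStrideUm, censorRule = censorRule,
    seed = as.integer(seed)), class = "PipelineConfig")
}

#' Write / read a pipeline configuration file
#'
#' Flat \code{key = value} text format (vectors comma-separated,
#' full-precision), chosen for bit-exact reproducibility and diffability.
#'
#' @param config a [pipelineConfig()] list.
#' @param path file path.
#' @return \code{writePipelineConfig}: invisibly, the path;
#'   \code{readPipelineConfig}: a \code{PipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
  fmt <- function(v) paste(format(v, digits = 17, trim = TRUE),
                           collapse = ",")
  keys <- names(config)
  lines <- vapply(keys, function(k) {
    v <- config[[k]]
    if (is.matrix(v)) v <- as.numeric(v)
    sprintf("%s = %s", k, fmt(v))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- list()
  for (p in kv) {
    if (length(p) != 2L) next
    parts <- strsplit(p[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(parts))
    vals[[p[1]]] <- if (any(is.na(num) & parts != "NA")) parts else num
  }
  do.call(pipelineConfig, vals)
}

#' Run the full pipeline on one slide
#'
#' Executes stain separation, nucleus detection and classification, ROI
#' filtering, slide metrics, quality scoring and hotspot analysis; logs one
#' structured line per stage (slide id, wall time, object counts) and
#' returns the assembled results plus the slide TSV row. Deterministic for
#' a given image, annotation and configuration.
#'
#' @param imagePath PNG or TIFF image.
#' @param annotationPath optional GeoJSON ROI file; \code{NULL} assesses the
#'   whole image.
#' @param config a [pipelineConfig()] list.
#' @param slideId slide identifier (default: the image file stem).
#' @param qualityFractions named fractions \code{assessable},
#'   \code{inflammatory}, \code{unlabelled} feeding the three quality
#'   rubrics (review inputs; defaults assume a clean slide).
#' @param verbose emit per-stage log lines.
#' @return list with \code{nuclei}, \code{roi}, \code{metrics},
#'   \code{quality}, \code{hotspot}, \code{row} (one-row data.frame).
#' @export
runSlide <- function(imagePath, annotationPath = NULL,
                     config = pipelineConfig(), slideId = NULL,
                     qualityFractions = c(assessable = 1, inflammatory = 0,
                                          unlabelled = 0),
                     verbose = FALSE) {
  if (is.null(slideId))
    slideId <- tools::file_path_sans_ext(basename(imagePath))
  logline <- function(stage, t0, extra = "") {
    if (verbose)
      message(sprintf("[%s] %-12s %6.2fs %s", slideId, stage,
                      (proc.time() - t0)[["elapsed"]], extra))
  }
  mpp <- config$micronsPerPixel

  t0 <- proc.time()
  img <- readSlideImage(imagePath)
  logline("read", t0, sprintf("%dx%d px", ncol(img), nrow(img)))

  t0 <- proc.time()
  od <- rgbToOD(img, config$background)
  stains <- separateStains(od, stainBasis(config$stainVectors))
  rm(od)
  logline("deconvolve", t0)

  t0 <- proc.time()
  roi <- if (is.null(annotationPath)) {
    rect <- cbind(c(0, ncol(img), ncol(img), 0),
                  c(0, 0, nrow(img), nrow(img)))
    roiFromPolygons(rect, imageDim = dim(img)[1:2], micronsPerPixel = mpp)
  } else {
    loadROI(annotationPath, dim(img)[1:2], mpp)
  }
  logline("roi", t0, sprintf("%.4f mm2", area(roi)))

  t0 <- proc.time()
  params <- nucleusDetectionParams(config$odThreshold, config$smoothSigmaUm,
                                   config$minAreaUm2, config$maxAreaUm2)
  bands <- classBands(config$tNegative, config$tWeak, config$tStrong)
  nuclei <- detectNuclei(stains$hematoxylin, stains$dab, roi, params, mpp,
                         bands)
  logline("detect", t0, sprintf("%d objects (%d in ROI)", nrow(nuclei),
                                sum(nuclei$inside_roi)))

  t0 <- proc.time()
  metrics <- summarizeSlide(nuclei, area(roi), slideId)
  quality <- qualityScores(
    scoreTissue(qualityFractions[["assessable"]]),
    scoreInflammation(qualityFractions[["inflammatory"]]),
    scoreSegmentation(qualityFractions[["unlabelled"]]))
  bb <- c(0, 0, ncol(img), nrow(img)) * mpp
  stride <- config$hotspotStrideUm
  hotspot <- findHotspot(nuclei, roiBoundsUm = bb[c(1, 2, 3, 4)],
                         strideUm = if (is.na(stride)) NULL else stride,
                         globalStrongDensityPerMm2 =
                           strongDensity(metrics))
  logline("summarise", t0,
          sprintf("PI %.1f H %.1f hotspot %d", piPercent(metrics),
                  hScore(metrics), positiveCount(hotspot)))

  list(nuclei = nuclei, roi = roi, metrics = metrics, quality = quality,
       hotspot = hotspot, row = slideTsvRow(metrics, quality, hotspot))
}

#' Run a batch of slides
#'
#' Applies [runSlide()] to each image; a failing slide is recorded and the
#' batch continues. Rows of successful slides are bound into one slide TSV
#' table (written to \code{outTsv} when given).
#'
#' @param imagePaths character vector of image files.
#' @param annotationPaths optional character vector (or \code{NULL}),
#'   recycled NA entries mean whole-image ROI.
#' @param config a [pipelineConfig()] list.
#' @param outTsv optional output TSV path.
#' @param verbose forwarded to [runSlide()].
#' @return list with \code{rows} (data.frame) and \code{failures} (named
#'   character vector of error messages).
#' @export
runBatch <- function(imagePaths, annotationPaths = NULL,
                     config = pipelineConfig(), outTsv = NULL,
                     verbose = FALSE) {
  if (is.null(annotationPaths))
    annotationPaths <- rep(NA_character_, length(imagePaths))
  rows <- list(); failures <- character()
  for (i in seq_along(imagePaths)) {
    ann <- annotationPaths[i]
    res <- tryCatch(
      runSlide(imagePaths[i], if (is.na(ann)) NULL else ann, config,
               verbose = verbose),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[imagePaths[i]] <- conditionMessage(res)
      warning(sprintf("slide '%s' failed: %s", imagePaths[i],
                      conditionMessage(res)))
    } else {
      rows[[length(rows) + 1L]] <- res$row
    }
  }
  rows <- if (length(rows)) do.call(rbind, rows) else
    slideTsvRow(.metricsFromCounts(0L, 0L, 0L, 0L, 1, "none"))[0, ]
  if (!is.null(outTsv)) exportSlideTSV(rows, outTsv)
  list(rows = rows, failures = failures)
}

#' Cohort summary table (mean, range, SD; all vs inflammation-excluded)
#'
#' For each metric column: mean, min, max and SD over all slides and over
#' the subset excluding marked inflammation (quality score 0), plus the
#' signed fold change of the means after exclusion.
#'
#' @param cohort data.frame of slide rows (from [runBatch()] joined with
#'   metadata).
#' @param metrics character vector of metric column names.
#' @return data.frame with one row per metric and subset.
#' @export
cohortSummaryTable <- function(cohort,
                               metrics = c("h_score", "pi_percent",
                                           "positive_density_per_mm2",
                                           "strong_density_per_mm2")) {
  metrics <- intersect(metrics, names(cohort))
  if (!length(metrics)) stop("no metric columns found")
  hasQ <- "q_inflammation" %in% names(cohort) &&
    any(!is.na(cohort$q_inflammation))
  sub <- if (hasQ) excludeInflamed(cohort) else NULL
  rows <- lapply(metrics, function(m) {
    v <- cohort[[m]]
    r <- data.frame(metric = m, subset = "all", n = sum(!is.na(v)),
                    mean = mean(v, na.rm = TRUE),
                    min = suppressWarnings(min(v, na.rm = TRUE)),
                    max = suppressWarnings(max(v, na.rm = TRUE)),
                    sd = stats::sd(v, na.rm = TRUE),
                    fold_change = NA_real_, stringsAsFactors = FALSE)
    if (!is.null(sub)) {
      v2 <- sub[[m]]
      fc <- if (mean(v, na.rm = TRUE) > 0 && mean(v2, na.rm = TRUE) > 0)
        foldChange(mean(v, na.rm = TRUE), mean(v2, na.rm = TRUE))
      else NA_real_
      r <- rbind(r, data.frame(metric = m, subset = "inflammation-excluded",
                               n = sum(!is.na(v2)),
                               mean = mean(v2, na.rm = TRUE),
                               min = suppressWarnings(min(v2, na.rm = TRUE)),
                               max = suppressWarnings(max(v2, na.rm = TRUE)),
                               sd = stats::sd(v2, na.rm = TRUE),
                               fold_change = fc,
                               stringsAsFactors = FALSE))
    }
    r
  })
  do.call(rbind, rows)
}

#' Run the cohort statistics layer
#'
#' Joins slide rows to cohort metadata by \code{slide_id} (join failures are
#' logged with the offending ids) and produces the summary table plus the
#' available tests: Webster category summary, PI category summary, and --
#' when survival columns are present -- univariable Cox fits and
#' median-dichotomised Kaplan-Meier curves for H-score, PI and strong
#' density.
#'
#' @param slideRows data.frame of slide TSV rows.
#' @param metadata optional data.frame keyed by \code{slide_id}.
#' @param config a [pipelineConfig()] list (censoring rule).
#' @return list with \code{cohort}, \code{summary}, \code{webster},
#'   \code{piCategories}, \code{cox}, \code{km}.
#' @export
runCohort <- function(slideRows, metadata = NULL,
                      config = pipelineConfig()) {
  if (!nrow(slideRows)) stop("need at least one slide row")
  cohort <- slideRows
  if (!is.null(metadata)) {
    miss <- setdiff(slideRows$slide_id, metadata$slide_id)
    if (length(miss))
      warning("no metadata for slide id(s): ", paste(miss, collapse = ", "))
    cohort <- merge(slideRows, metadata, by = "slide_id", all.x = TRUE)
  }
  out <- list(cohort = cohort, summary = cohortSummaryTable(cohort))
  out$webster <- if ("manual_hotspot_category" %in% names(cohort) &&
                     any(!is.na(cohort$manual_hotspot_category)))
    websterSummary(cohort) else NULL
  out$piCategories <- if ("pi_percent" %in% names(cohort))
    piCategorySummary(cohort) else NULL
  if (all(c("survival_days", "event_flag") %in% names(cohort)) &&
      sum(.eventIndicator(cohort$event_flag, config$censorRule)) >= 2) {
    metrics <- intersect(c("h_score", "pi_percent",
                           "strong_density_per_mm2"), names(cohort))
    out$cox <- lapply(stats::setNames(metrics, metrics), function(m)
      tryCatch(coxUnivariable(cohort[[m]], cohort$survival_days,
                              cohort$event_flag, config$censorRule),
               error = function(e)
                 .testResult("Cox univariable (Efron ties)",
                             note = conditionMessage(e))))
    out$km <- lapply(stats::setNames(metrics, metrics), function(m)
      kmDichotomize(cohort[[m]], cohort$survival_days, cohort$event_flag,
                    censorRule = config$censorRule))
  }
  out
}
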
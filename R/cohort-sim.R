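## Synthetic cohort generator for the survival layer: a standardised Ki-67
## metric per record, exponential survival under a proportional-hazards law,
## administrative censoring.

#' Generate a synthetic cohort with known hazard structure
#'
#' Each record carries a standardised Ki-67 metric drawn from a standard
#' normal distribution; the survival time is exponential with hazard
#' \code{baselineHazard * exp(effect * metric)} and administrative censoring
#' at \code{censorTime} (deaths are recorded as tumour-related). A true
#' hazard ratio per metric unit of \code{exp(effect)} is therefore planted.
#'
#' @param n number of records (>= 2).
#' @param effect log hazard ratio per metric unit.
#' @param baselineHazard baseline hazard per day (> 0).
#' @param censorTime administrative censoring time in days (>= 0).
#' @param seed integer seed (private stream; no global RNG state touched).
#' @return data.frame with columns \code{slide_id}, \code{ki67_metric},
#'   \code{survival_days}, \code{event_flag} (\code{"died-MCT"} or
#'   \code{"alive"}).
#' @export
#' @examples
#' head(generateCohort(10, effect = log(2), seed = 1))
generateCohort <- function(n, effect = 0, baselineHazard = 1 / 500,
                           censorTime = 730, seed = 1L) {
  if (n < 2) stop("n must be >= 2")
  .assertScalarNumber(baselineHazard, "baselineHazard", 0,
                      strict.lower = TRUE)
  .assertScalarNumber(censorTime, "censorTime", 0)
  withLocalSeed(seed, {
    metric <- stats::rnorm(n)
    tt <- stats::rexp(n, rate = baselineHazard * exp(effect * metric))
    event <- tt <= censorTime
    data.frame(slide_id = sprintf("sim%04d", seq_len(n)),
               ki67_metric = metric,
               survival_days = pmin(tt, censorTime),
               event_flag = ifelse(event, "died-MCT", "alive"),
               stringsAsFactors = FALSE)
  })
}
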
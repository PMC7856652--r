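#' Rescale a raw 24-item BPRS total to a lowest score of zero
#'
#' The 24-item Brief Psychiatric Rating Scale total has a floor of 24 (one
#' point per item); analyses work on the rescaled scale where 24 maps to 0,
#' so that percent change is computed from a true zero.
#'
#' @param raw numeric raw total(s), each `>= 24`.
#' @return `raw - 24`.
#' @export
#' @examples
#' rescaleBprs(c(24, 29, 48))  # 0, 5, 24
rescaleBprs <- function(raw) {
  if (any(!is.na(raw) & raw < 24))
    stop("raw BPRS total below the 24-item scale minimum of 24", call. = FALSE)
  raw - 24
}

#' Label a subject Improver from baseline/follow-up BPRS totals
#'
#' Improver means a strictly greater than 20 percent decrease in the
#' rescaled total from baseline to follow-up. The boundary is strict: an
#' exactly-20 percent decrease is a non-Improver.
#'
#' @param baselineRaw,followupRaw raw BPRS totals (scale minimum 24).
#' @return logical; `TRUE` for Improver. Vectorized.
#' @export
#' @examples
#' labelImprover(44, 34)  # 20 -> 10, 50% decrease: TRUE
#' labelImprover(44, 40)  # 20 -> 16, exactly 20%: FALSE
labelImprover <- function(baselineRaw, followupRaw) {
  b <- rescaleBprs(baselineRaw)
  f <- rescaleBprs(followupRaw)
  if (any(!is.na(b) & b == 0))
    stop("percent decrease undefined for a rescaled baseline of 0",
         call. = FALSE)
  (b - f) / b > 0.20
}

#' Continuous BPRS change
#'
#' Follow-up minus baseline on the rescaled scale; negative values mean
#' improvement. The rescaling offset cancels, so this equals the raw change.
#'
#' @inheritParams labelImprover
#' @return numeric signed change.
#' @export
computeDelta <- function(baselineRaw, followupRaw) {
  rescaleBprs(followupRaw) - rescaleBprs(baselineRaw)
}

#' Build the outcome table for a cohort, applying the inclusion rule
#'
#' Patients enter the analysis only if their rescaled baseline total is at
#' least 5 (raw `>= 29`), ensuring a 20 percent improvement is resolvable.
#' Excluded patients and patients with missing follow-up are flagged, never
#' silently dropped; healthy controls are reference-only and marked not
#' included. Improver labels are defined only for included patients.
#'
#' @param cohort a [PsychosisCohort-class].
#' @return a [S4Vectors::DataFrame] with columns `subject_id`, `group`,
#'   `included`, `reason` (why a row is excluded, `NA` if included),
#'   `improver`, `delta_bprs`.
#' @export
outcomeTable <- function(cohort) {
  cd <- colData(cohort)
  pat <- cd$group == "psychosis"
  base <- cd$bprs_baseline_raw
  fol <- cd$bprs_followup_raw
  reason <- rep(NA_character_, nrow(cd))
  reason[!pat] <- "healthy control (reference only)"
  reason[pat & is.na(base)] <- "missing baseline BPRS"
  reason[pat & is.na(fol)] <- "missing follow-up BPRS"
  ok <- pat & !is.na(base) & !is.na(fol)
  lowres <- ok & rescaleBprs(base) < 5
  reason[lowres] <- "rescaled baseline below 5"
  included <- ok & !lowres
  improver <- rep(NA, nrow(cd))
  delta <- rep(NA_real_, nrow(cd))
  if (any(included)) {
    improver[included] <- labelImprover(base[included], fol[included])
    delta[included] <- computeDelta(base[included], fol[included])
  }
  DataFrame(subject_id = cd$subject_id, group = cd$group,
            included = included, reason = reason,
            improver = improver, delta_bprs = delta,
            row.names = rownames(cd))
}

#' Pooled improvement rate from subgroup sizes and rates
#'
#' Reconstructs integer Improver counts from diagnostic subgroup sizes and
#' their improvement proportions (rounding each subgroup count to the
#' nearest integer) and pools them into the overall percent improved.
#'
#' @param nPerGroup named integer subgroup sizes (default the published
#'   cohort: 65 schizophrenia, 17 bipolar I).
#' @param rates improvement proportions per subgroup, same order
#'   (default 0.60 and 0.47).
#' @return list with `improved` (integer counts per subgroup),
#'   `totalImproved`, `total`, and `percent` improved.
#' @export
#' @examples
#' pooledImprovementRate()$percent  # 57.3
pooledImprovementRate <- function(nPerGroup = c(SZ = 65L, BD = 17L),
                                  rates = c(SZ = 0.60, BD = 0.47)) {
  stopifnot(length(nPerGroup) == length(rates))
  improved <- round(nPerGroup * rates)
  list(improved = improved, totalImproved = sum(improved),
       total = sum(nPerGroup),
       percent = round(100 * sum(improved) / sum(nPerGroup), 1))
}
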
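## Inclusion/exclusion rules, index dates, pre-diagnostic windows and
## prevalence-ratio sampling.

#' Cohort construction configuration
#'
#' Defaults encode the study design: minimum age 40 at index, two diagnostic
#' codes at least 182 days (6 months) apart to accept a case, index date at
#' the first disease code or the earlier first disease-specific medication,
#' control index at last visit minus 182 days, exclusion of cases on
#' neuroleptic medication within 182 days before the first disease code, a
#' case:control training ratio of 572 per 100,000 (age-adjusted prevalence),
#' and pre-diagnostic horizons of 1, 3 and 5 years. All date arithmetic is in
#' fixed days (year = 365 d, 6 months = 182 d).
#'
#' @param minAgeYears minimum age (years) at index date.
#' @param pdCodeSet,pdMedSet,neurolepticSet character vectors of concept ids
#'   for the target-disease diagnosis codes, disease-specific medications and
#'   neuroleptic medications.
#' @param minCodeGapDays required gap between the index code and a later
#'   confirming code.
#' @param controlOffsetDays offset of control index dates before last visit.
#' @param prevalenceRatio numeric length-2, cases per population
#'   (default \code{c(572, 100000)}).
#' @param horizonsYears pre-diagnostic horizons in years.
#' @return a validated list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(minAgeYears = 40,
                         pdCodeSet = c("PD_CODE_1", "PD_CODE_2"),
                         pdMedSet = c("PD_MED_1", "PD_MED_2"),
                         neurolepticSet = c("NEUROLEPTIC_1", "NEUROLEPTIC_2"),
                         minCodeGapDays = 182L,
                         controlOffsetDays = 182L,
                         prevalenceRatio = c(572, 100000),
                         horizonsYears = c(1, 3, 5)) {
  stopifnot(minAgeYears > 0, minCodeGapDays > 0, controlOffsetDays > 0,
            length(prevalenceRatio) == 2, all(prevalenceRatio > 0),
            prevalenceRatio[1] <= prevalenceRatio[2],
            all(horizonsYears > 0))
  structure(list(minAgeYears = minAgeYears, pdCodeSet = pdCodeSet,
                 pdMedSet = pdMedSet, neurolepticSet = neurolepticSet,
                 minCodeGapDays = as.integer(minCodeGapDays),
                 controlOffsetDays = as.integer(controlOffsetDays),
                 prevalenceRatio = prevalenceRatio,
                 horizonsYears = horizonsYears),
            class = "CohortConfig")
}

#' Assign a case index date to one patient record, or reject
#'
#' The index date t0 is the day of the first disease diagnosis code, or the
#' day the first disease-specific medication was started if that precedes the
#' code. A case is accepted only if at least two diagnosis codes exist and
#' some other code falls at least \code{minCodeGapDays} after t0.
#'
#' @param events data.frame of the patient's events (from
#'   \code{\link{patientEvents}}).
#' @param config a \code{\link{cohortConfig}}.
#' @return list with \code{accepted} (logical), \code{t0} (integer or NA),
#'   \code{firstCodeDay} and \code{reason} (\code{"ok"}, \code{"no_pd_code"}
#'   or \code{"insufficient_codes"}). Rejection is a value, not an error.
#' @export
assignCaseIndex <- function(events, config) {
  codeDays <- sort(events$event_day[events$concept_id %in% config$pdCodeSet])
  medDays <- sort(events$event_day[events$concept_id %in% config$pdMedSet &
                                     events$domain == "medication"])
  if (!length(codeDays))
    return(list(accepted = FALSE, t0 = NA_integer_,
                firstCodeDay = NA_integer_, reason = "no_pd_code"))
  t0 <- codeDays[1]
  if (length(medDays) && medDays[1] < t0) t0 <- medDays[1]
  confirmed <- any(codeDays >= t0 + config$minCodeGapDays)
  if (length(codeDays) < 2 || !confirmed)
    return(list(accepted = FALSE, t0 = as.integer(t0),
                firstCodeDay = as.integer(codeDays[1]),
                reason = "insufficient_codes"))
  list(accepted = TRUE, t0 = as.integer(t0),
       firstCodeDay = as.integer(codeDays[1]), reason = "ok")
}

#' Index every patient in a cohort as case or control
#'
#' Patients with any disease code or disease-specific medication are treated
#' as case candidates and run through \code{\link{assignCaseIndex}};
#' candidates that fail the two-code rule are rejected (with reasons).
#' Patients with neither become controls with
#' \code{t0 = last_visit_day - controlOffsetDays}.
#'
#' @param cohort an \linkS4class{EHRCohort}.
#' @param config a \code{\link{cohortConfig}}.
#' @return list with \code{indexed} (data.frame: patient_id, label,
#'   index_day, age_at_index, first_code_day) and \code{rejected}
#'   (data.frame: patient_id, reason).
#' @export
indexCohort <- function(cohort, config) {
  pats <- cohortPatients(cohort)
  ev <- cohortEvents(cohort)
  if (anyNA(pats$birth_day)) kgStop("missing birth_day for some patients")
  pdConcepts <- c(config$pdCodeSet, config$pdMedSet)
  isCand <- pats$patient_id %in%
    unique(ev$patient_id[ev$concept_id %in% pdConcepts])
  rows <- vector("list", nrow(pats))
  rej <- list()
  for (i in seq_len(nrow(pats))) {
    pid <- pats$patient_id[i]
    if (isCand[i]) {
      res <- assignCaseIndex(ev[ev$patient_id == pid, , drop = FALSE], config)
      if (!res$accepted) {
        rej[[length(rej) + 1L]] <- data.frame(patient_id = pid,
                                              reason = res$reason)
        next
      }
      rows[[i]] <- data.frame(patient_id = pid, label = "case",
                              index_day = res$t0,
                              first_code_day = res$firstCodeDay)
    } else {
      t0 <- pats$last_visit_day[i] - config$controlOffsetDays
      rows[[i]] <- data.frame(patient_id = pid, label = "control",
                              index_day = as.integer(t0),
                              first_code_day = NA_integer_)
    }
  }
  indexed <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  bd <- setNames(pats$birth_day, pats$patient_id)
  indexed$age_at_index <- (indexed$index_day - bd[indexed$patient_id]) / 365
  rownames(indexed) <- NULL
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(patient_id = character(), reason = character())
  list(indexed = indexed, rejected = rejected)
}

#' Apply exclusion rules to indexed patients
#'
#' Removes (a) cases with any neuroleptic medication event in the half-open
#' window \code{(firstCode - 182 d, firstCode]} (drug-induced parkinsonism
#' guard; measured relative to the first disease diagnosis code) and (b) any
#' patient younger than \code{minAgeYears} at index. Each excluded patient
#' carries exactly one primary reason code (\code{"neuroleptic_window"}
#' checked first, then \code{"age"}), so exclusion counts partition the
#' rejected set.
#'
#' @param indexed data.frame from \code{\link{indexCohort}}.
#' @param cohort the \linkS4class{EHRCohort} with the full event history.
#' @param config a \code{\link{cohortConfig}}.
#' @return list with \code{kept} (filtered indexed data.frame) and
#'   \code{excluded} (data.frame: patient_id, reason).
#' @export
applyExclusions <- function(indexed, cohort, config) {
  ev <- cohortEvents(cohort)
  win <- config$controlOffsetDays
  reason <- rep(NA_character_, nrow(indexed))
  for (i in seq_len(nrow(indexed))) {
    pid <- indexed$patient_id[i]
    if (indexed$label[i] == "case") {
      ref <- indexed$first_code_day[i]
      nl <- ev$event_day[ev$patient_id == pid &
                           ev$concept_id %in% config$neurolepticSet]
      if (any(nl > ref - win & nl <= ref)) {
        reason[i] <- "neuroleptic_window"
        next
      }
    }
    if (indexed$age_at_index[i] < config$minAgeYears) reason[i] <- "age"
  }
  keep <- is.na(reason)
  list(kept = indexed[keep, , drop = FALSE],
       excluded = data.frame(patient_id = indexed$patient_id[!keep],
                             reason = reason[!keep]))
}

#' Restrict a cohort's events to a pre-diagnostic horizon
#'
#' Keeps, for each indexed patient, exactly the events strictly before
#' \code{t0 - horizonYears * 365}. Patients left with zero events are kept in
#' the patient table but flagged in the \code{"emptyPatients"} attribute;
#' modelling code drops them (and logs the count).
#'
#' @param cohort an \linkS4class{EHRCohort}.
#' @param indexed data.frame from \code{\link{indexCohort}} (after
#'   exclusions).
#' @param horizonYears a single horizon in years (1, 3 or 5 in the default
#'   design).
#' @return an \linkS4class{EHRCohort} containing only the indexed patients
#'   and their windowed events, with attribute \code{emptyPatients}.
#' @export
windowEvents <- function(cohort, indexed, horizonYears) {
  stopifnot(length(horizonYears) == 1, horizonYears > 0)
  pats <- cohortPatients(cohort)
  pats <- pats[pats$patient_id %in% indexed$patient_id, , drop = FALSE]
  ev <- cohortEvents(cohort)
  ev <- ev[ev$patient_id %in% indexed$patient_id, , drop = FALSE]
  cutoff <- setNames(indexed$index_day - round(horizonYears * 365),
                     indexed$patient_id)
  ev <- ev[ev$event_day < cutoff[ev$patient_id], , drop = FALSE]
  rownames(ev) <- NULL
  labs <- setNames(indexed$label, indexed$patient_id)[pats$patient_id]
  out <- new("EHRCohort", patients = pats, events = ev,
             labels = labs)
  attr(out, "emptyPatients") <-
    setdiff(pats$patient_id, unique(ev$patient_id))
  out
}

#' Subsample controls to the population prevalence ratio
#'
#' Retains all cases and draws, without replacement and deterministically
#' under \code{seed}, \code{floor(nCases * ratio[2] / ratio[1])} controls
#' (e.g. 10 cases at 572:100,000 keep 1,748 controls). Pass
#' \code{prevalenceRatio = c(1, 1)} in the config for a balanced design.
#'
#' @param indexed data.frame with \code{patient_id} and \code{label}.
#' @param config a \code{\link{cohortConfig}}.
#' @param seed integer seed for the control draw.
#' @return the filtered indexed data.frame (cases first, then sampled
#'   controls, in stable patient order).
#' @export
samplePrevalence <- function(indexed, config, seed) {
  cases <- indexed[indexed$label == "case", , drop = FALSE]
  controls <- indexed[indexed$label == "control", , drop = FALSE]
  nNeed <- floor(nrow(cases) * config$prevalenceRatio[2] /
                   config$prevalenceRatio[1])
  if (nrow(controls) < nNeed)
    kgStop("insufficient controls: need ", nNeed, ", have ", nrow(controls))
  set.seed(seed)
  pick <- sample(seq_len(nrow(controls)), nNeed, replace = FALSE)
  out <- rbind(cases, controls[sort(pick), , drop = FALSE])
  rownames(out) <- NULL
  out
}
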
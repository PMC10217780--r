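## Prodromal-criteria baseline: combine marker likelihood ratios with an
## age-based prior, via odds, into a per-patient posterior probability.

#' Read marker definitions for the prodromal-criteria calculator
#'
#' The table has columns \code{marker_id}, \code{lr_present},
#' \code{lr_absent}, \code{assessable} (TRUE when the marker can be asserted
#' from coded EHR data) and \code{concept_ids} (semicolon-separated EHR
#' concept ids asserting the marker). By convention
#' \code{lr_present >= 1 >= lr_absent > 0}; the convention is validated but
#' can be relaxed with \code{strict = FALSE}. A default table seeded with
#' likelihood ratios from the published prodromal research criteria ships in
#' \code{inst/extdata/mds_markers.tsv}; it is an editable configuration
#' default, not a reproduction of any specific study's marker set.
#'
#' @param path TSV path; default the shipped table.
#' @param strict enforce the LR ordering convention.
#' @return data.frame of marker definitions with a \code{concepts} list
#'   column.
#' @export
readMarkerDefinitions <- function(path = system.file("extdata",
                                                     "mds_markers.tsv",
                                                     package = "kgprodromal"),
                                  strict = TRUE) {
  defs <- read.delim(path, colClasses = "character")
  defs$lr_present <- as.numeric(defs$lr_present)
  defs$lr_absent <- as.numeric(defs$lr_absent)
  defs$assessable <- as.logical(defs$assessable)
  if (any(defs$lr_present <= 0) || any(defs$lr_absent <= 0))
    kgStop("likelihood ratios must be positive")
  if (strict && (any(defs$lr_present < 1) || any(defs$lr_absent > 1)))
    kgStop("expected lr_present >= 1 >= lr_absent; use strict = FALSE to override")
  defs$concept_ids[is.na(defs$concept_ids)] <- ""
  defs$concepts <- lapply(strsplit(defs$concept_ids, ";"),
                          function(x) x[!is.na(x) & nzchar(x)])
  defs
}

#' Read the age-band prior probability table
#'
#' Columns \code{age_lo}, \code{age_hi} (half-open bands \code{[lo, hi)} in
#' years) and \code{prior} in (0,1). Bands must tile an age range without
#' overlap and priors must be non-decreasing with age.
#'
#' @param path TSV path; default the shipped table.
#' @return data.frame of age bands.
#' @export
readAgePriors <- function(path = system.file("extdata",
                                             "mds_age_priors.tsv",
                                             package = "kgprodromal")) {
  pr <- read.delim(path)
  stopifnot(all(c("age_lo", "age_hi", "prior") %in% names(pr)))
  pr <- pr[order(pr$age_lo), , drop = FALSE]
  if (any(pr$age_hi <= pr$age_lo)) kgStop("empty age band in prior table")
  if (nrow(pr) > 1 && any(pr$age_lo[-1] != pr$age_hi[-nrow(pr)]))
    kgStop("age bands must tile the range without gaps or overlap")
  if (any(pr$prior <= 0 | pr$prior >= 1))
    kgStop("priors must lie in (0,1)")
  if (is.unsorted(pr$prior))
    kgStop("priors must be non-decreasing with age")
  pr
}

#' Look up the age-based prior for one age
#'
#' @param age age in years.
#' @param priors data.frame from \code{\link{readAgePriors}}.
#' @return prior probability.
#' @export
agePrior <- function(age, priors) {
  hit <- which(age >= priors$age_lo & age < priors$age_hi)
  if (!length(hit)) kgStop("age ", age, " outside the prior table range")
  priors$prior[hit[1]]
}

#' Marker presence/absence profile from a patient's coded events
#'
#' A marker is \code{present} when at least one event maps to its concept
#' set, \code{absent} when the marker is EHR-assessable but no event is
#' found, and \code{unknown} when the marker is declared non-assessable from
#' codes (its likelihood contribution is then neutral).
#'
#' @param events data.frame of one patient's (windowed) events.
#' @param defs marker definitions from \code{\link{readMarkerDefinitions}}.
#' @return named character vector, status per marker_id.
#' @export
profileFromEvents <- function(events, defs) {
  vapply(seq_len(nrow(defs)), function(i) {
    if (!isTRUE(defs$assessable[i])) return("unknown")
    if (any(events$concept_id %in% defs$concepts[[i]])) "present" else "absent"
  }, character(1)) |> setNames(defs$marker_id)
}

#' Total likelihood ratio of a marker profile
#'
#' Product over markers of \code{lr_present} for present markers,
#' \code{lr_absent} for absent markers, and 1 for unknown markers.
#'
#' @param profile named status vector from \code{\link{profileFromEvents}}.
#' @param defs marker definitions.
#' @return positive scalar.
#' @export
totalLR <- function(profile, defs) {
  if (any(defs$lr_present <= 0) || any(defs$lr_absent <= 0))
    kgStop("likelihood ratios must be positive")
  status <- profile[defs$marker_id]
  if (anyNA(status)) kgStop("profile missing markers: ",
                            paste(defs$marker_id[is.na(status)], collapse = ", "))
  lr <- ifelse(status == "present", defs$lr_present,
               ifelse(status == "absent", defs$lr_absent, 1))
  prod(lr)
}

#' Posterior probability from a prior and a total likelihood ratio
#'
#' Odds form of Bayes' rule: posterior odds = prior odds x LR, then mapped
#' back to a probability. The update is associative: applying LRs
#' sequentially equals applying their product.
#'
#' @param prior probability in (0,1).
#' @param lr positive likelihood ratio.
#' @return posterior probability.
#' @export
#' @examples
#' posteriorProbability(0.02, 10)   # ~0.1695
posteriorProbability <- function(prior, lr) {
  if (any(prior <= 0 | prior >= 1)) kgStop("prior must lie in (0,1)")
  if (any(lr <= 0)) kgStop("likelihood ratio must be positive")
  odds <- prior / (1 - prior) * lr
  odds / (1 + odds)
}

#' Posterior prodromal-disease scores for a cohort
#'
#' For each indexed patient: build the marker profile from the (windowed)
#' events, multiply the marker likelihood ratios, look up the age prior at
#' the index date and return the posterior probability. The scores serve
#' directly as the ranking statistic for ROC analysis. Patients whose
#' profile is all-unknown/absent still receive a score; set
#' \code{requireMarkers = TRUE} to restrict to patients with at least one
#' present marker (the comparison-cohort filter).
#'
#' @param cohort an \linkS4class{EHRCohort} (windowed events).
#' @param defs marker definitions.
#' @param priors age-prior table.
#' @param indexed data.frame with \code{patient_id} and \code{age_at_index}.
#' @param requireMarkers drop patients with no present marker.
#' @return named numeric vector of posterior probabilities.
#' @export
scoreCohort <- function(cohort, defs, priors, indexed,
                        requireMarkers = FALSE) {
  ev <- cohortEvents(cohort)
  scores <- numeric(0)
  for (i in seq_len(nrow(indexed))) {
    pid <- indexed$patient_id[i]
    pe <- ev[ev$patient_id == pid, , drop = FALSE]
    prof <- profileFromEvents(pe, defs)
    if (requireMarkers && !any(prof == "present")) next
    prior <- tryCatch(agePrior(indexed$age_at_index[i], priors),
                      error = function(e)
                        kgStop("patient ", pid, ": ", conditionMessage(e)))
    scores[pid] <- posteriorProbability(prior, totalLR(prof, defs))
  }
  scores
}

#' Derive synthetic marker definitions from a generated knowledge graph
#'
#' Assigns the shipped likelihood-ratio values to the first prodromal
#' concepts of a synthetic graph (recycled if there are more markers than
#' concepts are available), so the prodromal-criteria baseline can be scored
#' on synthetic cohorts. Non-assessable markers in the shipped table remain
#' non-assessable.
#'
#' @param kgGen list from \code{\link{generateKG}}.
#' @param defs marker definitions to re-target; default the shipped table.
#' @return marker definitions data.frame.
#' @export
syntheticMarkerDefinitions <- function(kgGen,
                                       defs = readMarkerDefinitions()) {
  assessIdx <- which(defs$assessable)
  concepts <- kgGen$prodromalConcepts
  for (j in seq_along(assessIdx)) {
    cid <- concepts[((j - 1) %% length(concepts)) + 1]
    defs$concepts[[assessIdx[j]]] <- cid
    defs$concept_ids[assessIdx[j]] <- cid
  }
  defs
}
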
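## Synthetic knowledge graphs and timestamped EHR cohorts with controllable
## planted signal. The generators are pure functions of their specs (seed
## included): identical spec implies identical output.

#' Specification of a synthetic knowledge graph
#'
#' The generated graph has five node types (Disease, Symptom, Gene, Compound,
#' SideEffect), a deterministic ring backbone over all nodes (guaranteeing
#' connectivity), planted edges from a designated target disease to
#' \code{nProdromalNeighbors} entry nodes, and independent background edges
#' with probability \code{backgroundEdgeProb} per node pair. Entry nodes (the
#' EHR-mappable concepts) are taken from the Symptom and Compound nodes;
#' prodromal entry nodes are spaced evenly among them.
#'
#' @param nDisease,nSymptom,nGene,nCompound,nSideEffect node counts per type.
#' @param nEntryConcepts number of EHR-mappable entry nodes (must not exceed
#'   nSymptom + nCompound).
#' @param nProdromalNeighbors number of entry nodes wired directly to the
#'   target disease.
#' @param targetDisease node id of the target disease; default the first
#'   disease node.
#' @param backgroundEdgeProb probability of a background edge per node pair.
#' @param seed integer seed.
#' @return a validated list of class \code{"SyntheticKGSpec"}.
#' @export
syntheticKGSpec <- function(nDisease = 10, nSymptom = 60, nGene = 30,
                            nCompound = 40, nSideEffect = 15,
                            nEntryConcepts = 80, nProdromalNeighbors = 8,
                            targetDisease = NULL,
                            backgroundEdgeProb = 0.01, seed = 1L) {
  counts <- c(nDisease, nSymptom, nGene, nCompound, nSideEffect)
  stopifnot(all(counts >= 1), nEntryConcepts >= 1,
            backgroundEdgeProb >= 0, backgroundEdgeProb <= 1)
  if (nProdromalNeighbors > nEntryConcepts)
    kgStop("nProdromalNeighbors must not exceed nEntryConcepts")
  if (nEntryConcepts > nSymptom + nCompound)
    kgStop("not enough Symptom + Compound nodes to host ", nEntryConcepts,
           " entry concepts")
  structure(list(nDisease = nDisease, nSymptom = nSymptom, nGene = nGene,
                 nCompound = nCompound, nSideEffect = nSideEffect,
                 nEntryConcepts = nEntryConcepts,
                 nProdromalNeighbors = nProdromalNeighbors,
                 targetDisease = targetDisease,
                 backgroundEdgeProb = backgroundEdgeProb,
                 seed = as.integer(seed)),
            class = "SyntheticKGSpec")
}

#' Generate a synthetic knowledge graph with planted prodromal wiring
#'
#' @param spec a \code{\link{syntheticKGSpec}}.
#' @return list with components \code{kg} (\linkS4class{KnowledgeGraph}),
#'   \code{mapping} (named character, concept_id -> node_id, covering every
#'   entry node), \code{targetDisease}, \code{entryNodes},
#'   \code{prodromalNodes} (entry nodes wired to the target) and
#'   \code{prodromalConcepts}.
#' @export
#' @examples
#' gen <- generateKG(syntheticKGSpec(seed = 7))
#' gen$kg
generateKG <- function(spec) {
  stopifnot(inherits(spec, "SyntheticKGSpec"))
  set.seed(spec$seed)
  mkIds <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  nodes <- rbind(
    data.frame(node_id = mkIds("DIS", spec$nDisease), node_type = "Disease"),
    data.frame(node_id = mkIds("SYM", spec$nSymptom), node_type = "Symptom"),
    data.frame(node_id = mkIds("GEN", spec$nGene), node_type = "Gene"),
    data.frame(node_id = mkIds("CMP", spec$nCompound), node_type = "Compound"),
    data.frame(node_id = mkIds("SID", spec$nSideEffect),
               node_type = "SideEffect"))
  nodes$name <- paste(nodes$node_type, nodes$node_id)
  target <- spec$targetDisease %||% "DIS001"
  if (!target %in% nodes$node_id) kgStop("targetDisease not in node set")

  entry <- c(mkIds("SYM", spec$nSymptom),
             mkIds("CMP", spec$nCompound))[seq_len(spec$nEntryConcepts)]
  prodromal <- entry[unique(round(seq(1, length(entry),
                                      length.out = spec$nProdromalNeighbors)))]
  if (length(prodromal) < spec$nProdromalNeighbors)
    prodromal <- entry[seq_len(spec$nProdromalNeighbors)]

  ids <- sort(nodes$node_id)
  ring <- data.frame(source = ids,
                     target = ids[c(2:length(ids), 1L)],
                     predicate = "ASSOCIATES")
  planted <- data.frame(source = target, target = prodromal,
                        predicate = "PRESENTS")
  # every entry node attaches round-robin to one non-target disease
  # (background clinical wiring: symptoms and compounds occur in many
  # diseases); prodromal entries carry their planted target edge on top, so
  # their embedding rows behave like any other entry row away from the
  # target's neighborhood
  decoyDiseases <- setdiff(mkIds("DIS", spec$nDisease), target)
  # the highest-id non-target disease is designated structurally unrelated:
  # it is kept clear of any wiring to the target or the prodromal entries so
  # it can serve as a negative-control feature in screening
  unrelated <- if (length(decoyDiseases)) decoyDiseases[length(decoyDiseases)]
               else NA_character_
  decoy <- if (length(decoyDiseases)) {
    dd <- rep(decoyDiseases, length.out = length(entry))
    clash <- entry %in% prodromal & dd == unrelated
    dd[clash] <- decoyDiseases[1]
    data.frame(source = dd, target = entry, predicate = "PRESENTS")
  } else NULL
  edges <- rbind(ring, planted, decoy)
  if (spec$backgroundEdgeProb > 0) {
    pair <- t(utils::combn(ids, 2))
    have <- paste(pmin(edges$source, edges$target),
                  pmax(edges$source, edges$target))
    free <- !(paste(pair[, 1], pair[, 2]) %in% have)
    if (!is.na(unrelated))   # the negative-control disease gets no random
      free <- free & pair[, 1] != unrelated & pair[, 2] != unrelated  # edges

    draw <- runif(sum(free)) < spec$backgroundEdgeProb
    bg <- pair[free, , drop = FALSE][draw, , drop = FALSE]
    if (nrow(bg))
      edges <- rbind(edges, data.frame(source = bg[, 1], target = bg[, 2],
                                       predicate = "ASSOCIATES"))
  }
  kg <- knowledgeGraph(nodes, edges)
  mapping <- setNames(entry, paste0("C_", entry))
  list(kg = kg, mapping = mapping, targetDisease = target,
       entryNodes = entry, prodromalNodes = prodromal,
       prodromalConcepts = paste0("C_", prodromal),
       unrelatedDisease = unrelated, spec = spec)
}

#' Specification of a synthetic EHR cohort
#'
#' Case patients receive a planted index day (uniform within the central 60%
#' of the observation span), two target-disease diagnosis codes at least 182
#' days apart from the index, optionally a disease-specific medication
#' preceding the first code, background events at \code{baseRate} events per
#' patient-year spread uniformly over the mapped entry concepts, and extra
#' prodromal-concept events whose rate is multiplied according to the time
#' before the index day: \code{signalMultipliers["1"]} within the final year,
#' \code{["3"]} between 1 and 3 years, and \code{["5"]} beyond 3 years.
#' Multipliers must be non-increasing with distance from the index
#' (prodromal symptoms grow more numerous as diagnosis nears). Controls draw
#' background events only.
#'
#' @param nCases,nControls cohort arm sizes (must be positive).
#' @param obsDays observation span in days (default 12 years).
#' @param baseRate mean mapped events per patient-year (default 4).
#' @param signalMultipliers named numeric \code{c("1"=,"3"=,"5"=)}, rate
#'   multipliers for prodromal concepts among cases; 1 = no signal.
#' @param ageRange age range (years) at the start of observation.
#' @param fracNeuroleptic fraction of cases tagged with a neuroleptic
#'   medication within 182 days before their first disease code (these are
#'   later removed by the exclusion rules).
#' @param fracMedFirst fraction of cases whose disease-specific medication
#'   precedes their first diagnosis code (index date then comes from the
#'   medication).
#' @param seed integer seed.
#' @return a validated list of class \code{"SyntheticCohortSpec"}.
#' @export
syntheticCohortSpec <- function(nCases = 200, nControls = 200,
                                obsDays = 12 * 365, baseRate = 1.5,
                                signalMultipliers = c("1" = 6, "3" = 4,
                                                      "5" = 3),
                                ageRange = c(35, 85),
                                fracNeuroleptic = 0.05,
                                fracMedFirst = 0.2, seed = 1L) {
  if (nCases <= 0 || nControls <= 0)
    kgStop("nCases and nControls must be positive")
  stopifnot(obsDays > 365, baseRate >= 0,
            all(c("1", "3", "5") %in% names(signalMultipliers)),
            all(signalMultipliers >= 0),
            length(ageRange) == 2, ageRange[1] < ageRange[2],
            fracNeuroleptic >= 0, fracNeuroleptic <= 1,
            fracMedFirst >= 0, fracMedFirst <= 1)
  m <- signalMultipliers[c("1", "3", "5")]
  if (m[["1"]] < m[["3"]] || m[["3"]] < m[["5"]])
    kgStop("signal multipliers must be non-increasing from horizon -1 to -5")
  structure(list(nCases = as.integer(nCases),
                 nControls = as.integer(nControls),
                 obsDays = as.integer(obsDays), baseRate = baseRate,
                 signalMultipliers = m, ageRange = ageRange,
                 fracNeuroleptic = fracNeuroleptic,
                 fracMedFirst = fracMedFirst, seed = as.integer(seed)),
            class = "SyntheticCohortSpec")
}

## internal: uniform background events over a concept pool
drawBackground <- function(pool, rate, lastVisit) {
  n <- rpois(1, rate * (lastVisit + 1) / 365)
  if (n == 0) return(NULL)
  data.frame(concept_id = sample(pool, n, replace = TRUE),
             domain = "diagnosis",
             event_day = sample(0:lastVisit, n, replace = TRUE))
}

## internal: extra prodromal events for one case in the pre-index bands.
## Band b of [lo, hi) days before t0 gets per-concept yearly rate
## `mult * perConcept` (on top of background when addToBackground, i.e. the
## extra rate is (mult-1) * perConcept; when the concepts are excluded from
## the background pool the full mult * perConcept is drawn here).
drawProdromal <- function(concepts, perConcept, t0, mults, extraOnly) {
  bands <- list(c(0, 365), c(365, 3 * 365), c(3 * 365, t0))
  mult <- c(mults[["1"]], mults[["3"]], mults[["5"]])
  out <- list()
  for (b in seq_along(bands)) {
    lo <- bands[[b]][1]; hi <- min(bands[[b]][2], t0)
    if (hi <= lo) next
    rate <- (if (extraOnly) mult[b] - 1 else mult[b]) * perConcept
    if (rate <= 0) next
    lambda <- rate * (hi - lo) / 365
    for (cid in concepts) {
      k <- rpois(1, lambda)
      if (k > 0)
        out[[length(out) + 1L]] <-
          data.frame(concept_id = cid, domain = "diagnosis",
                     event_day = t0 - sample(seq.int(lo + 1L, hi), k,
                                             replace = TRUE))
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

## internal shared generator; folds only used in relayed mode
generateCohortImpl <- function(spec, kgGen, relayed = FALSE) {
  stopifnot(inherits(spec, "SyntheticCohortSpec"))
  set.seed(spec$seed)
  mapping <- kgGen$mapping
  prodromalConcepts <- kgGen$prodromalConcepts
  allConcepts <- names(mapping)
  backgroundPool <- if (relayed) setdiff(allConcepts, prodromalConcepts)
                    else allConcepts
  perConcept <- spec$baseRate / length(allConcepts)
  bgRate <- perConcept * length(backgroundPool)

  folds <- NULL
  caseConcepts <- rep(list(prodromalConcepts), spec$nCases)
  if (relayed) {
    if (length(prodromalConcepts) < 2)
      kgStop("relayed design needs at least 2 prodromal concepts")
    half <- ceiling(length(prodromalConcepts) / 2)
    setA <- prodromalConcepts[seq_len(half)]
    setB <- prodromalConcepts[-seq_len(half)]
    nTrain <- round(0.8 * spec$nCases)
    caseFold <- c(rep("train", nTrain), rep("test", spec$nCases - nTrain))
    caseConcepts <- lapply(caseFold, function(f)
      if (f == "train") setA else setB)
    nTrainCtrl <- round(0.8 * spec$nControls)
    folds <- c(setNames(caseFold, sprintf("CASE%04d", seq_len(spec$nCases))),
               setNames(c(rep("train", nTrainCtrl),
                          rep("test", spec$nControls - nTrainCtrl)),
                        sprintf("CTRL%04d", seq_len(spec$nControls))))
  }

  pats <- list(); evs <- list()
  nNeuro <- round(spec$fracNeuroleptic * spec$nCases)
  for (i in seq_len(spec$nCases)) {
    pid <- sprintf("CASE%04d", i)
    ageAtIndex <- runif(1, spec$ageRange[1], spec$ageRange[2])
    t0 <- round(runif(1, 0.2, 0.8) * spec$obsDays)
    medFirst <- runif(1) < spec$fracMedFirst
    if (medFirst) {
      medDay <- t0
      firstCode <- t0 + sample(30:120, 1)
    } else {
      medDay <- NA_integer_
      firstCode <- t0
    }
    secondCode <- max(firstCode, t0 + 182L) + sample(1:90, 1)
    lastVisit <- secondCode + sample(30:365, 1)
    ev <- list(drawBackground(backgroundPool, bgRate, lastVisit),
               drawProdromal(caseConcepts[[i]], perConcept, t0,
                             spec$signalMultipliers, extraOnly = !relayed),
               data.frame(concept_id = "PD_CODE_1", domain = "diagnosis",
                          event_day = c(firstCode, secondCode)))
    if (medFirst)
      ev[[length(ev) + 1L]] <- data.frame(concept_id = "PD_MED_1",
                                          domain = "medication",
                                          event_day = medDay)
    if (i <= nNeuro)
      ev[[length(ev) + 1L]] <- data.frame(concept_id = "NEUROLEPTIC_1",
                                          domain = "medication",
                                          event_day = firstCode -
                                            sample(1:182, 1))
    ev <- do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
    ev$patient_id <- pid
    evs[[length(evs) + 1L]] <- ev
    # age is drawn at the index date so both arms share one age distribution
    pats[[length(pats) + 1L]] <-
      data.frame(patient_id = pid,
                 birth_day = as.integer(t0 - round(ageAtIndex * 365)),
                 last_visit_day = as.integer(max(lastVisit, ev$event_day)))
  }
  for (i in seq_len(spec$nControls)) {
    pid <- sprintf("CTRL%04d", i)
    ageAtIndex <- runif(1, spec$ageRange[1], spec$ageRange[2])
    # control index dates follow the same distribution as case index dates so
    # the two arms have comparable pre-index exposure time
    t0 <- round(runif(1, 0.2, 0.8) * spec$obsDays)
    lastVisit <- t0 + 182L   # control index = last visit - 182 d
    ev <- drawBackground(backgroundPool, bgRate, lastVisit)
    if (is.null(ev))
      ev <- data.frame(concept_id = sample(backgroundPool, 1),
                       domain = "diagnosis",
                       event_day = sample(0:lastVisit, 1))
    ev$patient_id <- pid
    evs[[length(evs) + 1L]] <- ev
    pats[[length(pats) + 1L]] <-
      data.frame(patient_id = pid,
                 birth_day = as.integer(t0 - round(ageAtIndex * 365)),
                 last_visit_day = as.integer(lastVisit))
  }
  patients <- do.call(rbind, pats)
  events <- do.call(rbind, evs)[, c("patient_id", "concept_id", "domain",
                                    "event_day")]
  events$event_day <- as.integer(events$event_day)
  events <- events[order(events$patient_id, events$event_day), , drop = FALSE]
  rownames(events) <- rownames(patients) <- NULL
  labels <- setNames(ifelse(grepl("^CASE", patients$patient_id),
                            "case", "control"),
                     patients$patient_id)
  cohort <- new("EHRCohort", patients = patients, events = events,
                labels = labels)
  list(cohort = cohort, labels = labels, folds = folds, spec = spec)
}

#' Generate a synthetic case/control EHR cohort
#'
#' See \code{\link{syntheticCohortSpec}} for the event model. Cases carry the
#' reserved concepts \code{PD_CODE_1} (diagnosis codes), optionally
#' \code{PD_MED_1} (disease-specific medication preceding the code) and, for
#' the first \code{round(fracNeuroleptic * nCases)} cases,
#' \code{NEUROLEPTIC_1} within 182 days before the first code; these reserved
#' ids match the defaults of \code{\link{cohortConfig}}.
#'
#' @param spec a \code{\link{syntheticCohortSpec}}.
#' @param kgGen the list returned by \code{\link{generateKG}} (supplies the
#'   concept mapping and the planted prodromal concept set).
#' @return list with \code{cohort} (an \linkS4class{EHRCohort}),
#'   \code{labels} (named character) and \code{spec}.
#' @export
generateCohort <- function(spec, kgGen) {
  generateCohortImpl(spec, kgGen, relayed = FALSE)
}

#' Generate a relayed-signal cohort with disjoint train/test prodromal codes
#'
#' Constructs the scenario in which graph enrichment is necessary: training
#' cases express one half (A) of the prodromal concepts, test cases the
#' disjoint other half (B), and prodromal concepts never appear as background
#' noise, so raw binary vectors of test cases have zero mass on the concepts
#' a classifier sees among training cases. Both halves are graph neighbors of
#' the target disease, so propagated signatures of both folds load on the
#' same target-disease feature.
#'
#' @inheritParams generateCohort
#' @return as \code{\link{generateCohort}}, plus \code{folds}: a named
#'   character vector assigning every patient to \code{"train"} (80\%) or
#'   \code{"test"} (20\%).
#' @export
generateRelayedCohort <- function(spec, kgGen) {
  generateCohortImpl(spec, kgGen, relayed = TRUE)
}

## ---------------------------------------------------------------------------
## TSV I/O for cohorts and mappings
## ---------------------------------------------------------------------------

#' Write / read a cohort as TSV tables
#'
#' \code{writeCohort} emits \code{events.tsv}, \code{patients.tsv} and (when
#' labels are present) \code{labels.tsv} into \code{dir}; \code{readCohort}
#' reloads them.
#'
#' @param cohort an \linkS4class{EHRCohort}.
#' @param dir directory path.
#' @return \code{writeCohort}: invisibly \code{dir}; \code{readCohort}: an
#'   \linkS4class{EHRCohort}.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(cohortEvents(cohort), file.path(dir, "events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohortPatients(cohort), file.path(dir, "patients.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  labs <- cohortLabels(cohort)
  if (length(labs))
    write.table(data.frame(patient_id = names(labs), label = unname(labs)),
                file.path(dir, "labels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  ev <- read.delim(file.path(dir, "events.tsv"),
                   colClasses = c(event_day = "integer"))
  pats <- read.delim(file.path(dir, "patients.tsv"),
                     colClasses = c(patient_id = "character"))
  ev$patient_id <- as.character(ev$patient_id)
  ev$concept_id <- as.character(ev$concept_id)
  labPath <- file.path(dir, "labels.tsv")
  labs <- if (file.exists(labPath)) {
    lt <- read.delim(labPath, colClasses = "character")
    setNames(lt$label, lt$patient_id)
  } else character()
  new("EHRCohort", patients = pats,
      events = ev[order(ev$patient_id, ev$event_day), , drop = FALSE],
      labels = labs)
}

#' Write / read a concept-to-node mapping table
#'
#' @param mapping named character vector, concept_id -> node_id.
#' @param path TSV path with columns concept_id, node_id.
#' @export
writeMapping <- function(mapping, path) {
  write.table(data.frame(concept_id = names(mapping),
                         node_id = unname(mapping)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMapping
#' @export
readMapping <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  setNames(tab$node_id, tab$concept_id)
}
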
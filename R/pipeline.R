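## End-to-end orchestration: one config, seeded stages, per-horizon
## experiments, method comparison report.

.configKeys <- c("kgSpec", "cohortSpec", "relayed", "prevalenceRatio",
                 "damping", "tol", "model", "nBoot", "bootSize",
                 "trainFraction", "numTrees", "horizons", "seed",
                 "compareLogistic")

#' Experiment configuration
#'
#' Bundles the synthetic-data specs, cohort rules, propagation parameters,
#' model choice and evaluation parameters for \code{\link{runExperiment}}.
#' Unknown keys are rejected. A single global \code{seed} fans out to
#' per-stage seeds via \code{\link{stageSeed}} so stages are independently
#' reproducible.
#'
#' @param kgSpec a \code{\link{syntheticKGSpec}}.
#' @param cohortSpec a \code{\link{syntheticCohortSpec}}.
#' @param relayed use \code{\link{generateRelayedCohort}} and its fixed
#'   train/test folds (default FALSE).
#' @param prevalenceRatio case:population ratio for control subsampling;
#'   default \code{c(1, 1)} (balanced arms at desk scale; the epidemiological
#'   default of \code{\link{cohortConfig}} is \code{c(572, 100000)}).
#' @param damping,tol propagation parameters.
#' @param model primary classifier, \code{"forest"} or \code{"logistic"}.
#' @param nBoot,bootSize bootstrap replicates and per-replicate sample size.
#' @param trainFraction train split fraction.
#' @param numTrees forest size.
#' @param horizons pre-diagnostic horizons (years) to analyse.
#' @param compareLogistic also fit the logistic model on signatures for the
#'   algorithm comparison (default TRUE).
#' @param seed global integer seed.
#' @return a validated list of class \code{"ExperimentConfig"}.
#' @export
experimentConfig <- function(kgSpec = syntheticKGSpec(),
                             cohortSpec = syntheticCohortSpec(),
                             relayed = FALSE,
                             prevalenceRatio = c(1, 1),
                             damping = 0.85, tol = 1e-8,
                             model = "forest", nBoot = 100L, bootSize = 50L,
                             trainFraction = 0.8, numTrees = 500L,
                             horizons = c(1, 3, 5),
                             compareLogistic = TRUE, seed = 1L) {
  cfg <- list(kgSpec = kgSpec, cohortSpec = cohortSpec, relayed = relayed,
              prevalenceRatio = prevalenceRatio, damping = damping,
              tol = tol, model = model, nBoot = as.integer(nBoot),
              bootSize = as.integer(bootSize),
              trainFraction = trainFraction, numTrees = as.integer(numTrees),
              horizons = horizons, compareLogistic = compareLogistic,
              seed = as.integer(seed))
  validateExperimentConfig(cfg)
}

validateExperimentConfig <- function(cfg) {
  unknown <- setdiff(names(cfg), .configKeys)
  if (length(unknown))
    kgStop("unknown config keys: ", paste(unknown, collapse = ", "))
  stopifnot(inherits(cfg$kgSpec, "SyntheticKGSpec"),
            inherits(cfg$cohortSpec, "SyntheticCohortSpec"),
            is.logical(cfg$relayed), length(cfg$prevalenceRatio) == 2,
            cfg$damping > 0, cfg$damping < 1, cfg$tol > 0,
            cfg$model %in% c("forest", "logistic"),
            cfg$nBoot >= 1, cfg$bootSize >= 2,
            cfg$trainFraction > 0, cfg$trainFraction < 1,
            all(cfg$horizons > 0))
  structure(cfg, class = "ExperimentConfig")
}

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys mirror the arguments of \code{\link{experimentConfig}};
#' \code{kgSpec} and \code{cohortSpec} are nested maps passed to the
#' respective spec constructors. Unknown keys anywhere are rejected.
#'
#' @param path YAML file path.
#' @return an \code{"ExperimentConfig"}.
#' @export
readExperimentConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), .configKeys)
  if (length(unknown))
    kgStop("unknown config keys: ", paste(unknown, collapse = ", "))
  args <- raw
  if (!is.null(raw$kgSpec)) {
    if (!is.null(raw$kgSpec$signalMultipliers))
      kgStop("signalMultipliers belongs to cohortSpec")
    args$kgSpec <- do.call(syntheticKGSpec, raw$kgSpec)
  }
  if (!is.null(raw$cohortSpec)) {
    cs <- raw$cohortSpec
    if (!is.null(cs$signalMultipliers))
      cs$signalMultipliers <- unlist(cs$signalMultipliers)
    args$cohortSpec <- do.call(syntheticCohortSpec, cs)
  }
  do.call(experimentConfig, args)
}

## internal: summarize an AUCDistribution as plain numbers
aucSummary <- function(dist) {
  ci <- aucCI(dist)
  list(mean = aucMean(dist), sd = aucSD(dist),
       ci_lo = ci[1], ci_hi = ci[2], values = aucValues(dist))
}

#' The disease node least related to the planted signal
#'
#' Returns the generator's designated structurally unrelated disease (kept
#' clear of wiring to the target and the prodromal entries); if none is
#' designated, falls back to the non-target Disease node at maximal hop
#' distance from the target (ties broken by node id). Used as the
#' negative-control feature in signature screening.
#'
#' @param kgGen list from \code{\link{generateKG}}.
#' @return a node id.
#' @export
unrelatedDiseaseNode <- function(kgGen) {
  if (!is.null(kgGen$unrelatedDisease) && !is.na(kgGen$unrelatedDisease))
    return(kgGen$unrelatedDisease)
  kg <- kgGen$kg
  dis <- setdiff(kgNodes(kg)$node_id[kgNodes(kg)$node_type == "Disease"],
                 kgGen$targetDisease)
  d <- hopDistances(kg, kgGen$targetDisease)[dis]
  dis[order(-d, dis)][1]
}

#' Run the full synthetic replica experiment
#'
#' For each configured horizon: generate graph and cohort, derive index
#' dates, apply exclusions, subsample controls to the prevalence ratio,
#' window events, build PSEVs and patient signatures, score the three
#' methods (graph signatures, raw binary EHR vectors, prodromal-criteria
#' posteriors), split train/test, train weighted classifiers, bootstrap the
#' test AUC and compare methods. Fully deterministic under
#' \code{config$seed}.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @param verbose emit stage messages to stderr.
#' @return an \code{"ExperimentReport"}: list with \code{accounting},
#'   \code{horizons} (per-horizon results: AUC summaries per method, feature
#'   screen, importance top lists, comparisons) and \code{config} echoes.
#' @export
runExperiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "ExperimentConfig"))
  say <- function(...) if (verbose) message("[kgprodromal] ", ...)
  seed <- config$seed

  kgSpec <- config$kgSpec
  kgSpec$seed <- stageSeed(seed, "kg")
  kgGen <- generateKG(kgSpec)
  say("graph: ", numNodes(kgGen$kg), " nodes, ", numEdges(kgGen$kg), " edges")

  cohortSpec <- config$cohortSpec
  cohortSpec$seed <- stageSeed(seed, "cohort")
  gen <- if (config$relayed) generateRelayedCohort(cohortSpec, kgGen)
         else generateCohort(cohortSpec, kgGen)
  cohort <- gen$cohort

  cfg <- cohortConfig(prevalenceRatio = config$prevalenceRatio)
  idx <- indexCohort(cohort, cfg)
  excl <- applyExclusions(idx$indexed, cohort, cfg)
  kept <- excl$kept
  # if exclusions leave too few controls for the requested ratio, trim cases
  # (seeded) to the feasible count rather than aborting the experiment
  maxCases <- floor(sum(kept$label == "control") *
                      config$prevalenceRatio[1] / config$prevalenceRatio[2])
  nCasesTrimmed <- 0L
  if (sum(kept$label == "case") > maxCases) {
    caseIds <- kept$patient_id[kept$label == "case"]
    set.seed(stageSeed(seed, "trim"))
    keepIds <- sort(sample(caseIds, maxCases))
    nCasesTrimmed <- length(caseIds) - maxCases
    kept <- kept[kept$label == "control" | kept$patient_id %in% keepIds, ,
                 drop = FALSE]
  }
  sampled <- samplePrevalence(kept, cfg, stageSeed(seed, "sample"))
  accounting <- list(
    n_input = numPatients(cohort),
    n_index_rejected = nrow(idx$rejected),
    index_reject_reasons = as.list(table(idx$rejected$reason)),
    n_excluded = nrow(excl$excluded),
    exclusion_reasons = as.list(table(excl$excluded$reason)),
    n_after_exclusions = nrow(excl$kept),
    n_cases_trimmed = nCasesTrimmed,
    n_cases_sampled = sum(sampled$label == "case"),
    n_controls_sampled = sum(sampled$label == "control"))
  say("cohort: ", accounting$n_cases_sampled, " cases / ",
      accounting$n_controls_sampled, " controls after sampling")

  markerDefs <- syntheticMarkerDefinitions(kgGen)
  priors <- readAgePriors()

  horizons <- lapply(config$horizons, function(h) {
    hs <- function(stage) stageSeed(seed, paste0(stage, "_h", h))
    win <- windowEvents(cohort, sampled, h)
    psev <- buildPSEVMatrix(kgGen$kg, win, kgGen$mapping,
                            damping = config$damping, tol = config$tol)
    sig <- buildSpokeSigMatrix(win, psev, kgGen$mapping)
    raw <- buildRawMatrix(win, kgGen$mapping)
    ids <- rownames(as.matrix(sig))          # patients with mapped events
    raw <- raw[ids, , drop = FALSE]
    labs <- setNames(sampled$label, sampled$patient_id)[ids]
    nDropped <- length(attr(sig, "dropped"))
    if (length(unique(labs)) < 2)
      kgStop("horizon ", h, ": a class vanished after windowing")

    if (config$relayed && !is.null(gen$folds)) {
      fold <- gen$folds[ids]
      split <- list(train = ids[fold == "train"], test = ids[fold == "test"])
    } else {
      split <- splitTrainTest(ids, labs, config$trainFraction, hs("split"))
    }
    trainIds <- split$train; testIds <- split$test
    sigMat <- as.matrix(sig)

    scoreMethod <- function(mat, stage) {
      clf <- trainClassifier(mat[trainIds, , drop = FALSE], labs[trainIds],
                             model = config$model, seed = hs(stage),
                             numTrees = config$numTrees)
      scores <- predict(clf, mat[testIds, , drop = FALSE])
      list(clf = clf,
           dist = bootstrapAuc(scores, labs[testIds], config$nBoot,
                               config$bootSize, hs(paste0("boot_", stage))),
           full_auc = rocAuc(scores, labs[testIds]))
    }
    spoke <- scoreMethod(sigMat, "spokesig")
    rawRes <- scoreMethod(raw, "raw")

    mdsScores <- scoreCohort(win, markerDefs, priors,
                             sampled[sampled$patient_id %in% testIds, ,
                                     drop = FALSE])
    mds <- list(dist = bootstrapAuc(mdsScores, labs[names(mdsScores)],
                                    config$nBoot, config$bootSize,
                                    hs("boot_mds")),
                full_auc = rocAuc(mdsScores, labs[names(mdsScores)]))

    features <- featureMannWhitney(sig, labs, nodeTypes(kgGen$kg))
    imp <- importancePercentiles(spoke$clf, nodeTypes(kgGen$kg))

    out <- list(
      horizon = h,
      n_modelled = length(ids), n_empty_dropped = nDropped,
      n_train = length(trainIds), n_test = length(testIds),
      auc = list(spokesig = aucSummary(spoke$dist),
                 raw = aucSummary(rawRes$dist),
                 mds = aucSummary(mds$dist)),
      full_auc = list(spokesig = spoke$full_auc, raw = rawRes$full_auc,
                      mds = mds$full_auc),
      comparisons = list(
        spokesig_vs_raw_t = compareAucDistributions(spoke$dist, rawRes$dist,
                                                    "t"),
        spokesig_vs_raw_ks = compareAucDistributions(spoke$dist,
                                                     rawRes$dist, "ks"),
        spokesig_vs_mds_t = compareAucDistributions(spoke$dist, mds$dist,
                                                    "t")),
      feature_screen = features,
      importance_top = lapply(imp$top, function(d)
        d[, c("node_id", "importance", "percentile")]))

    if (isTRUE(config$compareLogistic)) {
      logit <- trainClassifier(sigMat[trainIds, , drop = FALSE],
                               labs[trainIds], model = "logistic",
                               seed = hs("logit"))
      lScores <- predict(logit, sigMat[testIds, , drop = FALSE])
      lDist <- bootstrapAuc(lScores, labs[testIds], config$nBoot,
                            config$bootSize, hs("boot_logit"))
      out$auc$logistic <- aucSummary(lDist)
      out$comparisons$forest_vs_logistic_ks <-
        compareAucDistributions(spoke$dist, lDist, "ks")
    }
    say("horizon -", h, ": spokesig AUC ",
        round(out$auc$spokesig$mean, 3), ", raw ",
        round(out$auc$raw$mean, 3), ", mds ", round(out$auc$mds$mean, 3))
    out
  })
  names(horizons) <- paste0("h", config$horizons)

  structure(list(accounting = accounting, horizons = horizons,
                 targetDisease = kgGen$targetDisease,
                 unrelatedDisease = unrelatedDiseaseNode(kgGen),
                 seed = seed),
            class = "ExperimentReport")
}

#' Write an experiment report as JSON
#'
#' Data frames become row-oriented records; numbers keep full precision.
#' Re-running \code{\link{runExperiment}} with the same config yields a
#' byte-identical file.
#'
#' @param report an \code{"ExperimentReport"}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeReportJSON <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' @export
print.ExperimentReport <- function(x, ...) {
  cat("ExperimentReport (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  cohort: %d input, %d sampled (%d cases / %d controls)\n",
              x$accounting$n_input,
              x$accounting$n_cases_sampled + x$accounting$n_controls_sampled,
              x$accounting$n_cases_sampled, x$accounting$n_controls_sampled))
  for (h in x$horizons)
    cat(sprintf("  horizon -%s: AUC spokesig %.3f, raw %.3f, mds %.3f\n",
                h$horizon, h$auc$spokesig$mean, h$auc$raw$mean,
                h$auc$mds$mean))
  invisible(x)
}
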
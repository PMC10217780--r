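test_that("graph generation is a pure function of its spec", {
  spec <- syntheticKGSpec(seed = 42)
  g1 <- generateKG(spec); g2 <- generateKG(spec)
  dir <- withr::local_tempdir()
  writeGraph(g1$kg, file.path(dir, "n1.tsv"), file.path(dir, "e1.tsv"))
  writeGraph(g2$kg, file.path(dir, "n2.tsv"), file.path(dir, "e2.tsv"))
  expect_identical(readLines(file.path(dir, "e1.tsv")),
                   readLines(file.path(dir, "e2.tsv")))
  expect_identical(g1$mapping, g2$mapping)
})

test_that("planted wiring, connectivity and mapping coverage hold", {
  gen <- generateKG(syntheticKGSpec(seed = 1))
  kg <- gen$kg
  # target degree at least the number of prodromal neighbors
  expect_gte(length(kgNeighbors(kg, gen$targetDisease)),
             length(gen$prodromalNodes))
  # prodromal entry nodes all adjacent to the target
  expect_true(all(gen$prodromalNodes %in%
                    kgNeighbors(kg, gen$targetDisease)))
  # connected
  ig <- igraph::graph_from_data_frame(kgEdges(kg)[, 1:2], directed = FALSE,
                                      vertices = nodeIds(kg))
  expect_true(igraph::is_connected(ig))
  # mapping covers every entry node
  expect_setequal(unname(gen$mapping), gen$entryNodes)
  # negative-control disease touches neither target nor prodromal entries
  nb <- kgNeighbors(kg, gen$unrelatedDisease)
  expect_false(gen$targetDisease %in% nb)
  expect_false(any(gen$prodromalNodes %in% nb))
})

test_that("zero background probability leaves only deterministic wiring", {
  spec <- syntheticKGSpec(backgroundEdgeProb = 0, seed = 8)
  gen <- generateKG(spec)
  ed <- kgEdges(gen$kg)
  nRing <- numNodes(gen$kg)
  nPlanted <- length(gen$prodromalNodes)
  nDecoy <- length(gen$entryNodes)   # one decoy disease per entry node
  expect_equal(nrow(ed), nRing + nPlanted + nDecoy)
})

test_that("generator rejects infeasible wiring requests", {
  expect_error(syntheticKGSpec(nEntryConcepts = 10, nProdromalNeighbors = 11),
               "nProdromalNeighbors")
  expect_error(syntheticKGSpec(nSymptom = 3, nCompound = 2,
                               nEntryConcepts = 10), "entry")
  expect_error(syntheticCohortSpec(nCases = 0), "positive")
  expect_error(syntheticCohortSpec(
    signalMultipliers = c("1" = 1, "3" = 2, "5" = 3)), "non-increasing")
})

test_that("neuroleptic tagging hits exactly the configured fraction", {
  kgGen <- generateKG(syntheticKGSpec(seed = 3))
  gen <- generateCohort(syntheticCohortSpec(nCases = 100, nControls = 10,
                                            fracNeuroleptic = 0.1, seed = 3),
                        kgGen)
  ev <- cohortEvents(gen$cohort)
  tagged <- unique(ev$patient_id[ev$concept_id == "NEUROLEPTIC_1"])
  expect_length(tagged, 10L)
  expect_true(all(grepl("^CASE", tagged)))
})

test_that("cases carry a valid planted index with confirming codes", {
  kgGen <- generateKG(syntheticKGSpec(seed = 6))
  gen <- generateCohort(syntheticCohortSpec(nCases = 50, nControls = 10,
                                            fracNeuroleptic = 0, seed = 6),
                        kgGen)
  idx <- indexCohort(gen$cohort, cohortConfig())
  # every generated case passes the two-code rule; no controls have codes
  expect_equal(sum(idx$indexed$label == "case"), 50L)
  expect_equal(nrow(idx$rejected), 0L)
  expect_equal(sum(idx$indexed$label == "control"), 10L)
})

test_that("a unit multiplier yields indistinguishable pre-index rates", {
  kgGen <- generateKG(syntheticKGSpec(seed = 5))
  gen <- generateCohort(
    syntheticCohortSpec(signalMultipliers = c("1" = 1, "3" = 1, "5" = 1),
                        fracNeuroleptic = 0, seed = 5), kgGen)
  idx <- indexCohort(gen$cohort, cohortConfig())
  ev <- cohortEvents(gen$cohort)
  t0 <- setNames(idx$indexed$index_day, idx$indexed$patient_id)
  pre <- ev[ev$concept_id %in% names(kgGen$mapping) &
              ev$event_day < t0[ev$patient_id], ]
  # per-patient pre-index mapped event rate (events per day of exposure)
  n <- table(factor(pre$patient_id, levels = names(t0)))
  rate <- as.numeric(n) / as.numeric(t0)
  lab <- idx$indexed$label
  p <- wilcox.test(rate[lab == "case"], rate[lab == "control"])$p.value
  expect_gt(p, 0.01)
})

test_that("elevated multipliers raise case prodromal-concept rates", {
  kgGen <- generateKG(syntheticKGSpec(seed = 7))
  gen <- generateCohort(
    syntheticCohortSpec(signalMultipliers = c("1" = 5, "3" = 5, "5" = 5),
                        fracNeuroleptic = 0, seed = 7), kgGen)
  idx <- indexCohort(gen$cohort, cohortConfig())
  ev <- cohortEvents(gen$cohort)
  t0 <- setNames(idx$indexed$index_day, idx$indexed$patient_id)
  pro <- ev[ev$concept_id %in% kgGen$prodromalConcepts &
              ev$event_day < t0[ev$patient_id], ]
  n <- table(factor(pro$patient_id, levels = names(t0)))
  rate <- as.numeric(n) / as.numeric(t0) * 365
  lab <- idx$indexed$label
  expect_gt(mean(rate[lab == "case"]), mean(rate[lab == "control"]))
})

test_that("relayed cohorts keep train and test prodromal codes disjoint", {
  kgGen <- generateKG(syntheticKGSpec(seed = 2))
  gen <- generateRelayedCohort(syntheticCohortSpec(nCases = 40,
                                                   nControls = 40,
                                                   fracNeuroleptic = 0,
                                                   seed = 2), kgGen)
  ev <- cohortEvents(gen$cohort)
  folds <- gen$folds
  caseIds <- names(folds)[grepl("^CASE", names(folds))]
  conceptsOf <- function(ids)
    unique(ev$concept_id[ev$patient_id %in% ids &
                           ev$concept_id %in% kgGen$prodromalConcepts])
  A <- conceptsOf(caseIds[folds[caseIds] == "train"])
  B <- conceptsOf(caseIds[folds[caseIds] == "test"])
  expect_gt(length(A), 0); expect_gt(length(B), 0)
  expect_length(intersect(A, B), 0)

  # raw binary vectors of test cases have zero mass on train-case concepts
  raw <- buildRawMatrix(gen$cohort, kgGen$mapping)
  testCases <- caseIds[folds[caseIds] == "test"]
  expect_true(all(raw[testCases, A] == 0))

  # but their propagated signatures still load on the target disease
  idx <- indexCohort(gen$cohort, cohortConfig())
  win <- windowEvents(gen$cohort, idx$indexed, 1)
  psev <- buildPSEVMatrix(kgGen$kg, win, kgGen$mapping)
  tc <- intersect(testCases, unique(cohortEvents(win)$patient_id))
  sig <- buildSpokeSig(patientEvents(win, tc[1]), psev, kgGen$mapping)
  expect_gt(sig[[kgGen$targetDisease]], 0)
})

test_that("cohort TSV output round-trips through read/write", {
  kgGen <- generateKG(syntheticKGSpec(seed = 4))
  gen <- generateCohort(syntheticCohortSpec(nCases = 5, nControls = 5,
                                            seed = 4), kgGen)
  dir <- withr::local_tempdir()
  writeCohort(gen$cohort, dir)
  back <- readCohort(dir)
  expect_equal(cohortPatients(back), cohortPatients(gen$cohort))
  expect_equal(cohortEvents(back), cohortEvents(gen$cohort),
               ignore_attr = TRUE)
  expect_identical(cohortLabels(back), cohortLabels(gen$cohort))
  p <- file.path(dir, "mapping.tsv")
  writeMapping(kgGen$mapping, p)
  expect_identical(readMapping(p), kgGen$mapping)
})
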
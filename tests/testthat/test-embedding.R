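test_that("restart vectors weight entry nodes by cohort co-occurrence", {
  kg <- pathGraphABC()
  mapping <- c(c1 = "A", c2 = "B")

  # single patient with only concept c1: unit mass on A
  co1 <- miniCohort(data.frame(patient_id = "p1", concept_id = "c1",
                               domain = "diagnosis", event_day = 10L))
  r <- buildRestartVector("c1", co1, mapping, nodeIds(kg))
  expect_equal(r, c(A = 1, B = 0, C = 0))

  # two carriers of c1 who both also carry c2: mass 1/2 on A and B
  ev <- rbind(
    data.frame(patient_id = "p1", concept_id = c("c1", "c2"),
               domain = "diagnosis", event_day = c(1L, 2L)),
    data.frame(patient_id = "p2", concept_id = c("c1", "c2"),
               domain = "diagnosis", event_day = c(3L, 4L)))
  co2 <- miniCohort(ev)
  r2 <- buildRestartVector("c1", co2, mapping, nodeIds(kg))
  expect_equal(r2, c(A = 0.5, B = 0.5, C = 0))

  # concept with no carriers falls back to its own node
  r3 <- buildRestartVector("c2", co1, mapping, nodeIds(kg))
  expect_equal(r3, c(A = 0, B = 1, C = 0))

  expect_error(buildRestartVector("zzz", co1, mapping, nodeIds(kg)),
               "not mapped")
})

test_that("propagation matches closed forms on degenerate inputs", {
  one <- knowledgeGraph(
    data.frame(node_id = "A", node_type = "Disease", name = "a"),
    data.frame(source = character(), target = character(),
               predicate = character()))
  tm1 <- buildTransition(one)
  expect_equal(computePSEV(tm1, c(A = 1)), c(A = 1))

  # damping -> 0 collapses to the restart distribution
  tm <- buildTransition(pathGraphABC())
  r <- c(A = 0.2, B = 0.5, C = 0.3)
  v <- computePSEV(tm, r, damping = 1e-9)
  expect_equal(v, r, tolerance = 1e-6)

  expect_error(computePSEV(tm, r, damping = 0.85, maxIter = 1L),
               "did not converge")
  expect_error(computePSEV(tm, c(A = 0.7, B = 0.7, C = -0.4)), "negative")
})

test_that("propagation agrees with a dense power-iteration oracle", {
  kg4 <- knowledgeGraph(
    data.frame(node_id = c("A", "B", "C", "D"), node_type = "Gene",
               name = "n"),
    data.frame(source = c("A", "B", "C"), target = c("B", "C", "D"),
               predicate = "E"))
  tm <- buildTransition(kg4)
  restart <- c(A = 1, B = 0, C = 0, D = 0)
  v <- computePSEV(tm, restart, damping = 0.85, tol = 1e-12)
  o <- densePageRankOracle(nodeIds(kg4), kgEdges(kg4), restart, 0.85)
  expect_lt(sum(abs(v - o)), 1e-8)
  expect_equal(sum(v), 1, tolerance = 1e-12)
})

test_that("PSEV matrices have one unit-sum row per observed mapped concept", {
  kg <- pathGraphABC()
  mapping <- c(c1 = "A", c2 = "B", c3 = "C")
  ev <- data.frame(
    patient_id = c("p1", "p1", "p2", "p2"),
    concept_id = c("c1", "c2", "c3", "unmapped_concept"),
    domain = "diagnosis", event_day = c(1L, 2L, 1L, 5L))
  co <- miniCohort(ev)
  psev <- buildPSEVMatrix(kg, co, mapping)
  expect_identical(rownames(as.matrix(psev)), c("c1", "c2", "c3"))
  expect_true(all(abs(rowSums(as.matrix(psev)) - 1) <= 1e-9))

  # permuting patient order leaves the matrix unchanged
  ev2 <- ev[c(3, 4, 1, 2), ]
  psev2 <- buildPSEVMatrix(kg, miniCohort(ev2), mapping)
  expect_identical(as.matrix(psev), as.matrix(psev2))
})

test_that("patient signatures combine PSEV rows as stated", {
  kg <- pathGraphABC()
  mapping <- c(c1 = "A", c2 = "B")
  ev <- rbind(
    data.frame(patient_id = "p1", concept_id = "c1", domain = "diagnosis",
               event_day = 1L),
    data.frame(patient_id = "p2", concept_id = "c2", domain = "diagnosis",
               event_day = 1L))
  psev <- buildPSEVMatrix(kg, miniCohort(ev), mapping)
  pm <- as.matrix(psev)

  # one concept: exactly that PSEV row
  sig1 <- buildSpokeSig(data.frame(concept_id = "c1"), psev, mapping)
  expect_equal(as.numeric(sig1), unname(pm["c1", ]))

  # two concepts: elementwise mean of the two unit-sum rows
  sig2 <- buildSpokeSig(data.frame(concept_id = c("c1", "c2")), psev,
                        mapping)
  expect_equal(as.numeric(sig2), unname((pm["c1", ] + pm["c2", ]) / 2))

  # duplicate events count once by default
  sig3 <- buildSpokeSig(data.frame(concept_id = c("c1", "c1", "c1")), psev,
                        mapping)
  expect_equal(as.numeric(sig3), as.numeric(sig1))

  # but weight the row under the count-weighted flag
  sig4 <- buildSpokeSig(data.frame(concept_id = c("c1", "c1", "c2")), psev,
                        mapping, countWeighted = TRUE)
  expect_equal(as.numeric(sig4),
               unname((2 * pm["c1", ] + pm["c2", ]) / 3))

  expect_error(buildSpokeSig(data.frame(concept_id = "unmapped"), psev,
                             mapping), "empty signature")
})

test_that("raw binary matrices restrict to mapped concepts", {
  mapping <- c(c1 = "A", c2 = "B", c3 = "C")
  ev <- data.frame(patient_id = c("p1", "p1", "p1", "p2"),
                   concept_id = c("c1", "c1", "c3", "zz"),
                   domain = "diagnosis", event_day = c(1L, 2L, 3L, 1L))
  raw <- buildRawMatrix(miniCohort(ev), mapping)
  expect_identical(colnames(raw), c("c1", "c2", "c3"))
  expect_equal(raw["p1", ], c(c1 = 1, c2 = 0, c3 = 1))
  expect_equal(unname(raw["p2", ]), c(0, 0, 0))
  expect_identical(attr(raw, "emptyRows"), "p2")
  expect_true(all(raw %in% c(0, 1)))
})

test_that("signal reaches the target disease through planted wiring", {
  gen <- generateKG(syntheticKGSpec(seed = 2))
  kg <- gen$kg
  mapping <- gen$mapping
  proConcept <- gen$prodromalConcepts[1]
  # a background concept at least 3 hops from the target
  d <- igraph::distances(
    igraph::graph_from_data_frame(kgEdges(kg)[, 1:2], directed = FALSE,
                                  vertices = nodeIds(kg)),
    v = gen$targetDisease)[1, ]
  farEntry <- names(which(d[gen$entryNodes] >= 3))
  farConcepts <- names(mapping)[mapping %in% farEntry]
  expect_gte(length(farConcepts), 2)
  ev <- rbind(
    data.frame(patient_id = "pro", concept_id = proConcept,
               domain = "diagnosis", event_day = 1L),
    data.frame(patient_id = "far", concept_id = farConcepts[1:2],
               domain = "diagnosis", event_day = 1L))
  co <- miniCohort(ev)
  psev <- buildPSEVMatrix(kg, co, mapping)
  sigPro <- buildSpokeSig(data.frame(concept_id = proConcept), psev, mapping)
  sigFar <- buildSpokeSig(data.frame(concept_id = farConcepts[1:2]), psev,
                          mapping)
  expect_gt(sigPro[gen$targetDisease], sigFar[gen$targetDisease])
})

test_that("adding an edge to the target never lowers its signature value", {
  gen <- generateKG(syntheticKGSpec(seed = 4))
  entry <- setdiff(gen$entryNodes, gen$prodromalNodes)[1]
  cid <- names(gen$mapping)[gen$mapping == entry]
  ev <- data.frame(patient_id = "p", concept_id = cid, domain = "diagnosis",
                   event_day = 1L)
  co <- miniCohort(ev)
  psev0 <- buildPSEVMatrix(gen$kg, co, gen$mapping)
  v0 <- buildSpokeSig(ev, psev0, gen$mapping)[gen$targetDisease]
  kg2 <- knowledgeGraph(kgNodes(gen$kg),
                        rbind(kgEdges(gen$kg),
                              data.frame(source = entry,
                                         target = gen$targetDisease,
                                         predicate = "PRESENTS")))
  psev1 <- buildPSEVMatrix(kg2, co, gen$mapping)
  v1 <- buildSpokeSig(ev, psev1, gen$mapping)[gen$targetDisease]
  expect_gte(v1, v0)
})

test_that("embedding matrices round-trip bit-exactly through MatrixMarket", {
  emb <- signalEmbedding()
  pm <- as.matrix(emb$psev)[1:5, , drop = FALSE]
  dir <- withr::local_tempdir()
  p <- file.path(dir, "psev.mtx")
  writeEmbedding(pm, p)
  back <- readEmbedding(p)
  expect_identical(back, pm)
})
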
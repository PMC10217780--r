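test_that("stratified splits are exact, disjoint and seeded", {
  ids <- sprintf("s%03d", 1:100)
  labels <- c(rep("case", 10), rep("control", 90))
  sp <- splitTrainTest(ids, labels, 0.8, seed = 3)
  expect_length(sp$train, 80)
  expect_equal(sum(sp$train %in% ids[1:10]), 8)   # 8 of 10 cases in train
  expect_setequal(c(sp$train, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  sp2 <- splitTrainTest(ids, labels, 0.8, seed = 3)
  expect_identical(sp, sp2)
  expect_error(splitTrainTest(ids[1:3], c("case", "control", "control")),
               "at least 2")
})

test_that("class weights are balanced inverse frequencies", {
  w <- classWeights(c(rep("case", 10), rep("control", 990)))
  expect_equal(w[["case"]], 50)
  expect_equal(w[["control"]], 1000 / 1980)
  wb <- classWeights(rep(c("case", "control"), 50))
  expect_equal(unname(wb), c(1, 1))
  # invariant to encoding order
  w2 <- classWeights(c(rep("control", 990), rep("case", 10)))
  expect_equal(w[sort(names(w))], w2[sort(names(w2))])
  expect_error(classWeights(rep("case", 5)), "both classes")
})

test_that("both classifier backends honor the scorer contract", {
  set.seed(42)
  n <- 120
  x <- cbind(f1 = c(rnorm(n / 2, 0), rnorm(n / 2, 3)),
             f2 = rnorm(n))
  rownames(x) <- sprintf("p%03d", 1:n)
  labels <- rep(c("control", "case"), each = n / 2)
  for (m in c("forest", "logistic")) {
    clf <- trainClassifier(x, labels, model = m, seed = 1)
    sc <- predict(clf, x)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_named(sc, rownames(x))
    # linearly separable toy data is learned (near-)perfectly in-sample
    expect_gte(rocAuc(sc, labels), 0.99)
  }
  # reproducible under a fixed seed
  s1 <- predict(trainClassifier(x, labels, model = "forest", seed = 9), x)
  s2 <- predict(trainClassifier(x, labels, model = "forest", seed = 9), x)
  expect_identical(s1, s2)
  expect_error(trainClassifier(cbind(x, f3 = NA), labels), "NA")
})

test_that("label-permuted training yields chance-level test AUC", {
  set.seed(7)
  n <- 200
  x <- matrix(rnorm(n * 8), n, 8,
              dimnames = list(sprintf("p%03d", 1:n), paste0("f", 1:8)))
  labels <- setNames(sample(rep(c("case", "control"), each = n / 2)),
                     rownames(x))
  sp <- splitTrainTest(rownames(x), labels[rownames(x)], 0.8, seed = 7)
  clf <- trainClassifier(x[sp$train, ], labels[sp$train], seed = 7,
                         numTrees = 300)
  auc <- rocAuc(predict(clf, x[sp$test, ]), labels[sp$test])
  expect_gte(auc, 0.35); expect_lte(auc, 0.65)
})

test_that("rank-based AUC matches pair counting, including ties", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.1, 0.2),
                      c("case", "case", "control", "control")), 1.0)
  expect_equal(rocAuc(rep(0.5, 6), rep(c("case", "control"), 3)), 0.5)
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8),
                      c("control", "control", "case", "case")), 0.75)
  set.seed(123)
  for (i in 1:25) {
    n <- sample(4:30, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    labels <- sample(c("case", "control"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(rocAuc(scores, labels), pairCountAucOracle(scores, labels))
  }
  expect_error(rocAuc(1:3, rep("case", 3)), "both classes")
})

test_that("AUC symmetry and the Mann-Whitney relation hold on tie-free data", {
  set.seed(5)
  for (i in 1:20) {
    scores <- sample(seq_len(50), 20)   # distinct -> tie-free
    labels <- sample(rep(c("case", "control"), 10))
    a <- rocAuc(scores, labels)
    expect_equal(a, 1 - rocAuc(-scores, labels))
    u <- unname(wilcox.test(scores[labels == "case"],
                            scores[labels == "control"])$statistic)
    expect_equal(a, u / 100)
  }
})

test_that("rank-based AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  scores <- runif(60)
  labels <- sample(c("case", "control"), 60, replace = TRUE, prob = c(.4, .6))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("control", "case"),
    direction = "<", quiet = TRUE)))
  expect_equal(rocAuc(scores, labels), ref, tolerance = 1e-12)
})

test_that("bootstrap AUC distributions behave at the extremes", {
  labels <- rep(c("case", "control"), each = 30)
  perfect <- c(runif(30, 0.8, 1), runif(30, 0, 0.2))
  d <- bootstrapAuc(perfect, labels, nBoot = 50, sampleSize = 40, seed = 1)
  expect_equal(aucValues(d), rep(1, 50))
  expect_equal(aucCI(d), c(1, 1))

  flat <- rep(0.5, 60)
  d2 <- bootstrapAuc(flat, labels, nBoot = 50, sampleSize = 40, seed = 1)
  expect_equal(aucValues(d2), rep(0.5, 50))

  set.seed(2)
  noisy <- c(rnorm(30, 1), rnorm(30, 0))
  d3 <- bootstrapAuc(noisy, labels, nBoot = 100, sampleSize = 50, seed = 3)
  expect_lt(abs(aucMean(d3) - rocAuc(noisy, labels)), 0.05)
  ci <- aucCI(d3)
  expect_gte(ci[1], min(aucValues(d3)))
  expect_lte(ci[2], max(aucValues(d3)))
  expect_error(bootstrapAuc(1:5, rep("case", 5)), "both classes")
})

test_that("feature screening recovers separation and flags constants", {
  mat <- cbind(
    sep = c(1, 2, 3, 10, 11, 12),
    same = c(1, 2, 3, 1, 2, 3),
    const = rep(7, 6),
    lab = c(0, 0, 0, 1, 1, 1))
  rownames(mat) <- paste0("p", 1:6)
  labels <- setNames(c(rep("control", 3), rep("case", 3)), rownames(mat))
  res <- featureMannWhitney(mat, labels)
  row <- function(id) res[res$node_id == id, ]
  # fully separated 3v3: U = 9 for the case-first orientation, exact p = 0.1
  expect_equal(row("sep")$p_value, 0.1)
  expect_true(row("sep")$u_statistic %in% c(0, 9))
  # identical class distributions: U = n1 n2 / 2
  expect_equal(row("same")$u_statistic, 4.5)
  # constant column: p = 1 by convention, flagged
  expect_equal(row("const")$p_value, 1)
  expect_true(row("const")$constant)
  # a column equal to the label separates maximally
  expect_equal(min(res$p_value), row("lab")$p_value)
  # ranks permute within type
  expect_setequal(res$rank, seq_len(nrow(res)))
})

test_that("importance percentiles use the midrank convention", {
  clf <- list(importance = setNames(rep(2, 10), paste0("f", 1:10)))
  class(clf) <- "kgClassifier"
  rep1 <- importancePercentiles(clf)
  expect_true(all(rep1$report$percentile == 50))

  imp <- setNames(c(rep(1, 9), 5), paste0("f", 1:10))
  clf2 <- structure(list(importance = imp), class = "kgClassifier")
  rep2 <- importancePercentiles(clf2)
  expect_equal(rep2$report$percentile[rep2$report$node_id == "f10"],
               100 * (10 - 0.5) / 10)
  # top lists are sorted and truncated
  types <- setNames(rep(c("Gene", "Disease"), 5), paste0("f", 1:10))
  rep3 <- importancePercentiles(clf2, types, topK = 3)
  expect_true(all(vapply(rep3$top, nrow, 1L) <= 3))
  expect_true(all(vapply(rep3$top, function(d)
    !is.unsorted(rev(d$importance)), TRUE)))
})

test_that("AUC distribution comparisons are symmetric and calibrated", {
  a <- new("AUCDistribution", values = rep(c(0.7, 0.72, 0.74), length.out = 100),
           sampleSize = 50L)
  same <- compareAucDistributions(a, a, "ks")
  expect_equal(same$statistic, 0)

  set.seed(8)
  v1 <- pmin(pmax(rnorm(100, 0.6, 0.05), 0), 1)
  b1 <- new("AUCDistribution", values = v1, sampleSize = 50L)
  b2 <- new("AUCDistribution", values = pmin(v1 + 0.2, 1), sampleSize = 50L)
  shifted <- compareAucDistributions(b1, b2, "t")
  expect_lt(shifted$p_value, 0.001)
  expect_equal(compareAucDistributions(b2, b1, "t")$p_value,
               shifted$p_value)
  expect_error(compareAucDistributions(
    b1, new("AUCDistribution", values = v1[1:50], sampleSize = 50L)),
    "replicate counts")
})
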
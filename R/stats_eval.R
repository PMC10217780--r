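## Classifier training contract, ROC-AUC, bootstrap confidence intervals,
## per-feature Mann-Whitney screening, importance percentiles and AUC
## distribution comparisons.

#' Stratified train/test split
#'
#' Splits samples by label with \code{trainFraction} (per class,
#' \code{floor}) going to the training set; deterministic under \code{seed};
#' the partitions are disjoint and exhaustive.
#'
#' @param ids character vector of sample ids.
#' @param labels factor or character vector aligned with \code{ids}
#'   (two classes).
#' @param trainFraction fraction in (0,1); default 0.8.
#' @param seed integer seed.
#' @return list with character vectors \code{train} and \code{test}.
#' @export
splitTrainTest <- function(ids, labels, trainFraction = 0.8, seed = 1L) {
  stopifnot(length(ids) == length(labels),
            trainFraction > 0, trainFraction < 1)
  tab <- table(labels)
  if (any(tab < 2))
    kgStop("every class needs at least 2 samples; got ",
           paste(names(tab), tab, sep = "=", collapse = ", "))
  set.seed(seed)
  train <- character(0)
  for (cl in names(tab)) {
    members <- ids[labels == cl]
    nTrain <- min(max(floor(trainFraction * length(members)), 1L),
                  length(members) - 1L)
    train <- c(train, sample(members, nTrain))
  }
  list(train = ids[ids %in% train], test = setdiff(ids, train))
}

#' Balanced inverse-frequency class weights
#'
#' \code{weight(class) = nTotal / (2 * nClass)}, so the minority class is
#' weighted up: 10 cases among 1,000 samples gives case weight 50 and
#' control weight ~0.505. Invariant to label encoding order.
#'
#' @param labels two-class label vector.
#' @return named numeric vector of per-class weights.
#' @export
classWeights <- function(labels) {
  tab <- table(labels)
  if (length(tab) < 2) kgStop("class weights need both classes present")
  setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
}

#' Train a weighted classifier on a feature matrix
#'
#' \code{model = "forest"} fits a probability random forest (ranger) with
#' per-sample weights derived from the class weights; \code{"logistic"} fits
#' a ridge-penalized logistic regression (glmnet, alpha = 0, small fixed
#' lambda chosen for numerical stability because signature columns are
#' collinear -- every row sums to 1). Both return the same scorer contract: a
#' \code{predict} method mapping a feature matrix to case probabilities in
#' [0,1]. Fixed seed implies a reproducible scorer.
#'
#' @param x numeric feature matrix (rows = samples) with rownames; no NAs.
#' @param labels vector of \code{"case"} / \code{"control"} aligned with
#'   rows.
#' @param weights named per-class weights from \code{\link{classWeights}};
#'   computed from \code{labels} when NULL.
#' @param model \code{"forest"} or \code{"logistic"}.
#' @param seed integer seed.
#' @param numTrees forest size (default 500).
#' @return an object of class \code{"kgClassifier"} with a \code{predict}
#'   method; feature importances are exposed via
#'   \code{\link{importancePercentiles}}.
#' @export
trainClassifier <- function(x, labels, weights = NULL,
                            model = c("forest", "logistic"), seed = 1L,
                            numTrees = 500L) {
  model <- match.arg(model)
  if (anyNA(x) || any(!is.finite(x))) kgStop("feature matrix contains NA/Inf")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) kgStop("training needs both classes")
  if (is.null(weights)) weights <- classWeights(labels)
  w <- unname(weights[labels])
  y <- factor(labels, levels = c("control", "case"))
  if (model == "forest") {
    df <- as.data.frame(x)
    colnames(df) <- paste0("f", seq_len(ncol(x)))  # syntactic names
    df$.y <- y
    set.seed(seed)
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = df, probability = TRUE,
      num.trees = numTrees, case.weights = w, importance = "impurity",
      seed = seed, num.threads = 1L)
    imp <- setNames(ranger::importance(fit), colnames(x))
    predictFun <- function(newx) {
      nd <- as.data.frame(newx)
      colnames(nd) <- paste0("f", seq_len(ncol(newx)))
      p <- predict(fit, data = nd, num.threads = 1L)$predictions[, "case"]
      setNames(p, rownames(newx))
    }
  } else {
    set.seed(seed)
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = 1e-3, weights = w, standardize = TRUE)
    coefs <- as.numeric(stats::coef(fit))[-1]
    sds <- apply(x, 2, sd)
    imp <- setNames(abs(coefs) * ifelse(sds > 0, sds, 0), colnames(x))
    predictFun <- function(newx) {
      p <- as.numeric(predict(fit, newx = newx, type = "response"))
      setNames(p, rownames(newx))
    }
  }
  structure(list(model = model, fit = fit, importance = imp,
                 predictFun = predictFun, features = colnames(x)),
            class = "kgClassifier")
}

#' @export
predict.kgClassifier <- function(object, newx, ...) {
  if (!is.null(object$features) && !is.null(colnames(newx)))
    newx <- newx[, object$features, drop = FALSE]
  object$predictFun(newx)
}

#' @export
print.kgClassifier <- function(x, ...) {
  cat("kgClassifier (", x$model, "), ", length(x$features),
      " features\n", sep = "")
  invisible(x)
}

#' Rank-based ROC-AUC
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control, ties counted one half; computed from midranks, so it equals the
#' normalized Mann-Whitney U statistic.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels aligned \code{"case"} / \code{"control"} labels.
#' @return AUC in [0,1].
#' @export
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c("control", "control", "case", "case"))
rocAuc <- function(scores, labels) {
  labels <- as.character(labels)
  n1 <- sum(labels == "case"); n0 <- sum(labels == "control")
  if (n1 == 0 || n0 == 0) kgStop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == "case"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap distribution of test-set AUC
#'
#' Draws \code{nBoot} replicates of \code{sampleSize} patients with
#' replacement from the test set (redrawing any replicate that does not
#' contain both classes), computes the AUC of each, and summarizes the
#' distribution; the 95\% CI is the 2.5th/97.5th percentile pair.
#'
#' @param scores named numeric test-set scores.
#' @param labels aligned labels.
#' @param nBoot number of replicates (default 100).
#' @param sampleSize patients per replicate (default 50).
#' @param seed integer seed.
#' @return an \linkS4class{AUCDistribution}.
#' @export
bootstrapAuc <- function(scores, labels, nBoot = 100L, sampleSize = 50L,
                         seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) kgStop("test set needs both classes")
  set.seed(seed)
  n <- length(scores)
  vals <- numeric(nBoot)
  for (b in seq_len(nBoot)) {
    repeat {
      idx <- sample.int(n, sampleSize, replace = TRUE)
      if (length(unique(labels[idx])) == 2) break
    }
    vals[b] <- rocAuc(scores[idx], labels[idx])
  }
  new("AUCDistribution", values = vals, sampleSize = as.integer(sampleSize))
}

#' Per-feature Mann-Whitney screening of a signature matrix
#'
#' Two-sided Mann-Whitney U test comparing case and control distributions at
#' every feature column (exact enumeration for small tie-free samples,
#' normal approximation with tie correction otherwise, as in
#' \code{stats::wilcox.test}). Constant columns get p = 1 by convention and
#' are flagged. Features are ranked by p-value within each node type and
#' Benjamini-Hochberg FDR values are reported alongside raw p.
#'
#' @param sig a \linkS4class{SpokeSigMatrix} or plain matrix (rows =
#'   patients).
#' @param labels named or aligned \code{"case"}/\code{"control"} labels.
#' @param nodeTypes optional named vector node_id -> node_type used for
#'   within-type ranking; a single type is assumed when NULL.
#' @return data.frame with node_id, node_type, u_statistic, p_value, fdr,
#'   direction (sign of case-minus-control median difference), constant
#'   flag, and rank within node_type.
#' @export
featureMannWhitney <- function(sig, labels, nodeTypes = NULL) {
  mat <- if (is(sig, "SpokeSigMatrix")) as.matrix(sig) else sig
  labels <- as.character(if (!is.null(names(labels)))
    labels[rownames(mat)] else labels)
  if (length(unique(labels)) < 2) kgStop("both classes required")
  case <- labels == "case"
  types <- if (is.null(nodeTypes)) setNames(rep("feature", ncol(mat)),
                                            colnames(mat))
           else nodeTypes
  res <- lapply(colnames(mat), function(nid) {
    x <- mat[case, nid]; y <- mat[!case, nid]
    const <- length(unique(c(x, y))) == 1L
    if (const) {
      u <- length(x) * length(y) / 2; p <- 1
    } else {
      wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
      u <- unname(wt$statistic); p <- wt$p.value
    }
    data.frame(node_id = nid, node_type = unname(types[nid]),
               u_statistic = u, p_value = p,
               direction = sign(median(x) - median(y)), constant = const)
  })
  res <- do.call(rbind, res)
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res$rank <- ave(res$p_value, res$node_type,
                  FUN = function(p) rank(p, ties.method = "first"))
  res[order(res$node_type, res$rank), c("node_id", "node_type",
                                        "u_statistic", "p_value", "fdr",
                                        "direction", "constant", "rank")]
}

#' Feature-importance percentiles and per-type top lists
#'
#' Converts a trained classifier's per-feature importances (impurity
#' importance for the forest; absolute standardized coefficients for the
#' logistic model) into percentile scores within the full importance
#' distribution, using the midrank convention
#' \code{100 * (rank - 0.5) / N} (all-equal importances therefore score
#' exactly 50), and extracts the top-\code{k} features per node type.
#'
#' @param classifier a \code{"kgClassifier"} from
#'   \code{\link{trainClassifier}}.
#' @param nodeTypes optional named vector feature -> node_type.
#' @param topK per-type top-list length (default 15).
#' @return list with \code{report} (data.frame: node_id, node_type,
#'   importance, percentile) and \code{top} (named list of per-type
#'   data.frames, descending importance, length <= topK).
#' @export
importancePercentiles <- function(classifier, nodeTypes = NULL, topK = 15L) {
  imp <- classifier$importance
  if (is.null(imp)) kgStop("classifier exposes no importances")
  n <- length(imp)
  pct <- 100 * (rank(imp, ties.method = "average") - 0.5) / n
  types <- if (is.null(nodeTypes)) setNames(rep("feature", n), names(imp))
           else nodeTypes
  report <- data.frame(node_id = names(imp),
                       node_type = unname(types[names(imp)]),
                       importance = unname(imp), percentile = unname(pct))
  report <- report[order(-report$importance, report$node_id), , drop = FALSE]
  rownames(report) <- NULL
  top <- lapply(split(report, report$node_type),
                function(d) utils::head(d, topK))
  list(report = report, top = top)
}

#' Compare two bootstrap AUC distributions
#'
#' Two-sided Welch t-test or two-sample Kolmogorov-Smirnov test between
#' replicate AUC values; replicate counts must match.
#'
#' @param a,b \linkS4class{AUCDistribution} objects with equal replicate
#'   counts.
#' @param test \code{"t"} (Welch) or \code{"ks"}.
#' @return list with \code{statistic}, \code{p_value}, \code{test},
#'   \code{meanDiff} (mean(a) - mean(b)).
#' @export
compareAucDistributions <- function(a, b, test = c("t", "ks")) {
  test <- match.arg(test)
  va <- aucValues(a); vb <- aucValues(b)
  if (length(va) != length(vb))
    kgStop("replicate counts differ: ", length(va), " vs ", length(vb))
  res <- if (test == "t") t.test(va, vb, var.equal = FALSE)
         else suppressWarnings(ks.test(va, vb))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       test = test, meanDiff = mean(va) - mean(vb))
}
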
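## PSEV propagation (personalized PageRank with cohort-weighted restart),
## patient signature assembly, and the raw binary EHR representation.

#' Cohort-weighted restart distribution for one EHR concept
#'
#' The restart (teleport) distribution of the propagation walk for concept
#' \code{conceptId} places mass on each entry node in proportion to the number
#' of cohort patients who carry the concept \emph{and} have at least one event
#' mapping to that entry node. Patients carrying the concept always contribute
#' to the concept's own node, so that node always receives mass. If no cohort
#' patient carries the concept the restart falls back to unit mass on the
#' concept's own node.
#'
#' @param conceptId a mapped EHR concept id.
#' @param cohort an \linkS4class{EHRCohort} (typically already restricted to a
#'   pre-diagnostic window).
#' @param mapping named character vector, concept_id -> node_id.
#' @param nodeOrder character vector of graph node ids defining the vector
#'   layout (use \code{nodeIds(kg)}).
#' @return named numeric probability vector over \code{nodeOrder}.
#' @export
buildRestartVector <- function(conceptId, cohort, mapping, nodeOrder) {
  if (!conceptId %in% names(mapping))
    kgStop("concept not mapped to any graph node: ", conceptId)
  own <- unname(mapping[[conceptId]])
  if (!own %in% nodeOrder) kgStop("mapped node absent from graph: ", own)
  ev <- cohortEvents(cohort)
  carriers <- unique(ev$patient_id[ev$concept_id == conceptId])
  v <- setNames(numeric(length(nodeOrder)), nodeOrder)
  if (!length(carriers)) {           # fallback: unit mass on own node
    v[own] <- 1
    return(v)
  }
  ce <- ev[ev$patient_id %in% carriers & ev$concept_id %in% names(mapping), ,
           drop = FALSE]
  pn <- unique(data.frame(patient = ce$patient_id,
                          node = unname(mapping[ce$concept_id])))
  counts <- table(pn$node)
  v[names(counts)] <- as.numeric(counts)
  v / sum(v)
}

#' Personalized PageRank propagation of a restart distribution
#'
#' Iterates \deqn{v \leftarrow d\,(T v + m_{dangling}\, r) + (1-d)\, r} where
#' \eqn{T} is the column-stochastic transition operator, \eqn{r} the restart
#' distribution, \eqn{d} the damping factor and \eqn{m_{dangling}} the mass
#' currently sitting on dangling nodes (redistributed to the restart
#' distribution, the standard PageRank convention), until the L1 change falls
#' below \code{tol}. The result is a probability vector over graph nodes.
#'
#' @param transition a \linkS4class{TransitionModel}.
#' @param restart numeric probability vector over the model's nodes (named or
#'   in node order).
#' @param damping damping factor in (0,1); default 0.85.
#' @param tol L1 convergence tolerance; default 1e-8.
#' @param maxIter iteration cap; non-convergence is an error reporting the
#'   last residual.
#' @return named numeric vector summing to 1.
#' @export
#' @examples
#' kg <- knowledgeGraph(
#'   data.frame(node_id = c("A", "B", "C"), node_type = "Symptom",
#'              name = c("A", "B", "C")),
#'   data.frame(source = c("A", "B"), target = c("B", "C"),
#'              predicate = "ASSOCIATES"))
#' tm <- buildTransition(kg)
#' computePSEV(tm, c(A = 1, B = 0, C = 0))
computePSEV <- function(transition, restart, damping = 0.85, tol = 1e-8,
                        maxIter = 1000L) {
  stopifnot(is(transition, "TransitionModel"))
  if (damping <= 0 || damping >= 1) kgStop("damping must lie in (0,1)")
  ids <- transition@nodeIds
  n <- length(ids)
  if (!is.null(names(restart))) {
    if (!setequal(names(restart), ids))
      kgStop("restart names must match the graph's nodes")
    restart <- restart[ids]
  } else if (length(restart) != n) {
    kgStop("restart length must equal the number of nodes")
  }
  assertProb(restart, what = "restart vector")
  T <- transition@matrix
  dang <- transition@dangling
  v <- as.numeric(restart)
  r <- as.numeric(restart)
  for (it in seq_len(maxIter)) {
    mDang <- if (any(dang)) sum(v[dang]) else 0
    vNew <- damping * (as.numeric(T %*% v) + mDang * r) + (1 - damping) * r
    delta <- sum(abs(vNew - v))
    v <- vNew
    if (delta < tol) {
      v <- v / sum(v)               # guard against drift at machine precision
      return(setNames(v, ids))
    }
  }
  kgStop("propagation did not converge within ", maxIter,
         " iterations (last L1 residual ", format(delta), ")")
}

#' Build the PSEV matrix for a cohort
#'
#' One propagated entry vector per distinct mapped concept observed in the
#' cohort's events (rows sorted by concept id). Rows are independent: the
#' result is identical regardless of computation order or patient order.
#'
#' @param kg a \linkS4class{KnowledgeGraph}.
#' @param cohort an \linkS4class{EHRCohort} (windowed to the horizon of
#'   interest).
#' @param mapping named character vector concept_id -> node_id.
#' @param damping,tol,maxIter propagation parameters, see
#'   \code{\link{computePSEV}}.
#' @param orientation edge traversal mode for the transition operator.
#' @return a \linkS4class{PSEVMatrix}.
#' @export
buildPSEVMatrix <- function(kg, cohort, mapping, damping = 0.85, tol = 1e-8,
                            maxIter = 1000L,
                            orientation = c("undirected", "directed")) {
  orientation <- match.arg(orientation)
  tm <- buildTransition(kg, orientation)
  ids <- nodeIds(kg)
  ev <- cohortEvents(cohort)
  concepts <- intersect(unique(ev$concept_id), names(mapping))
  concepts <- concepts[orderC(concepts)]
  if (!length(concepts))
    kgStop("no mapped concepts observed in the cohort")
  rows <- vapply(concepts, function(cid) {
    r <- buildRestartVector(cid, cohort, mapping, ids)
    tryCatch(computePSEV(tm, r, damping = damping, tol = tol,
                         maxIter = maxIter),
             error = function(e) kgStop("PSEV for concept ", cid, ": ",
                                        conditionMessage(e)))
  }, numeric(length(ids)))
  mat <- t(rows)
  dimnames(mat) <- list(concepts, ids)
  new("PSEVMatrix", mat = mat, damping = damping, tol = tol)
}

#' Patient signature vector (SPOKEsig) from PSEV rows
#'
#' Sums the PSEV rows of the patient's distinct mapped concepts and
#' L1-normalizes the result onto the probability simplex. Each concept
#' contributes once regardless of how many events carry it
#' (\code{countWeighted = TRUE} weights rows by event counts instead).
#' Unmapped concepts are ignored; their ids are attached as the
#' \code{"unmapped"} attribute for coverage logging.
#'
#' @param events data.frame of one patient's events (columns
#'   \code{concept_id}, ...), e.g. from \code{\link{patientEvents}}.
#' @param psev a \linkS4class{PSEVMatrix}.
#' @param mapping named character vector concept_id -> node_id.
#' @param countWeighted weight concepts by event multiplicity (default FALSE).
#' @return named numeric probability vector over graph nodes, with attribute
#'   \code{unmapped}.
#' @export
buildSpokeSig <- function(events, psev, mapping, countWeighted = FALSE) {
  pm <- as.matrix(psev)
  present <- unique(events$concept_id)
  usable <- intersect(present, intersect(names(mapping), rownames(pm)))
  if (!length(usable))
    kgStop("empty signature: patient has no mapped concepts with PSEV rows")
  if (countWeighted) {
    w <- table(factor(events$concept_id, levels = usable))
    sig <- as.numeric(as.numeric(w) %*% pm[usable, , drop = FALSE])
  } else {
    sig <- colSums(pm[usable, , drop = FALSE])
  }
  sig <- sig / sum(sig)
  structure(setNames(sig, colnames(pm)),
            unmapped = setdiff(present, names(mapping)))
}

#' Signature matrix for a whole cohort
#'
#' Applies \code{\link{buildSpokeSig}} to every patient; patients with no
#' mapped concepts in the window are dropped and listed in the
#' \code{"dropped"} attribute of the result (the caller decides policy).
#'
#' @inheritParams buildSpokeSig
#' @param cohort an \linkS4class{EHRCohort}.
#' @return a \linkS4class{SpokeSigMatrix} with attribute \code{dropped}.
#' @export
buildSpokeSigMatrix <- function(cohort, psev, mapping, countWeighted = FALSE) {
  pm <- as.matrix(psev)
  ev <- cohortEvents(cohort)
  pats <- cohortPatients(cohort)$patient_id
  rows <- lapply(pats, function(p) {
    pe <- ev[ev$patient_id == p, , drop = FALSE]
    tryCatch(as.numeric(buildSpokeSig(pe, psev, mapping,
                                      countWeighted = countWeighted)),
             error = function(e) NULL)
  })
  ok <- !vapply(rows, is.null, logical(1))
  mat <- do.call(rbind, rows[ok])
  if (is.null(mat)) kgStop("no patient has a non-empty signature")
  dimnames(mat) <- list(pats[ok], colnames(pm))
  out <- new("SpokeSigMatrix", mat = mat)
  attr(out, "dropped") <- pats[!ok]
  out
}

#' Raw binary EHR representation restricted to mapped concepts
#'
#' Entry (p, c) is 1 iff patient p has at least one event of mapped concept c
#' in the cohort's (windowed) events. Columns are exactly the mapped concepts
#' (sorted), mirroring the restriction of the comparison to graph-mappable
#' EHR concepts; all-zero rows are listed in the \code{"emptyRows"} attribute.
#'
#' @param cohort an \linkS4class{EHRCohort}.
#' @param mapping named character vector concept_id -> node_id.
#' @return binary numeric matrix, rows = patients, cols = mapped concept ids.
#' @export
buildRawMatrix <- function(cohort, mapping) {
  concepts <- names(mapping)[orderC(names(mapping))]
  pats <- cohortPatients(cohort)$patient_id
  ev <- cohortEvents(cohort)
  ev <- ev[ev$concept_id %in% concepts, , drop = FALSE]
  mat <- matrix(0, nrow = length(pats), ncol = length(concepts),
                dimnames = list(pats, concepts))
  if (nrow(ev)) {
    idx <- cbind(match(ev$patient_id, pats), match(ev$concept_id, concepts))
    mat[unique(idx, MARGIN = 1)] <- 1
  }
  attr(mat, "emptyRows") <- pats[rowSums(mat) == 0]
  mat
}

## ---------------------------------------------------------------------------
## Matrix Market I/O with sidecar label files (bit-exact round trip)
## ---------------------------------------------------------------------------

#' Write / read an embedding matrix as Matrix Market with label sidecars
#'
#' Writes a dense real MatrixMarket \code{array} file plus \code{<path>.rows}
#' and \code{<path>.cols} label files. Values are written with 17 significant
#' digits so the reload is bit-exact.
#'
#' @param mat numeric matrix with dimnames (or a PSEVMatrix/SpokeSigMatrix).
#' @param path output \code{.mtx} path.
#' @return \code{writeEmbedding}: invisibly the path; \code{readEmbedding}:
#'   the labelled matrix.
#' @export
writeEmbedding <- function(mat, path) {
  if (is(mat, "PSEVMatrix") || is(mat, "SpokeSigMatrix")) mat <- as.matrix(mat)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix array real general", con)
  writeLines(paste(nrow(mat), ncol(mat)), con)
  writeLines(sprintf("%.17g", as.numeric(mat)), con)  # column-major
  writeLines(rownames(mat), paste0(path, ".rows"))
  writeLines(colnames(mat), paste0(path, ".cols"))
  invisible(path)
}

#' @rdname writeEmbedding
#' @export
readEmbedding <- function(path) {
  lines <- readLines(path)
  stopifnot(grepl("^%%MatrixMarket matrix array real", lines[1]))
  body <- lines[!grepl("^%", lines)]
  dims <- as.integer(strsplit(trimws(body[1]), "\\s+")[[1]])
  vals <- as.numeric(body[-1])
  mat <- matrix(vals, nrow = dims[1], ncol = dims[2])
  dimnames(mat) <- list(readLines(paste0(path, ".rows")),
                        readLines(paste0(path, ".cols")))
  mat
}
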
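#' @import methods
NULL

## ---------------------------------------------------------------------------
## KnowledgeGraph
## ---------------------------------------------------------------------------

#' KnowledgeGraph: a typed heterogeneous biomedical knowledge graph
#'
#' Holds a validated node table (\code{node_id}, \code{node_type},
#' \code{name}), an edge table (\code{source}, \code{target},
#' \code{predicate}) and a dense 0-based node index. Nodes are kept sorted
#' lexicographically by \code{node_id} so that all derived matrices are
#' reproducible across runs.
#'
#' @slot nodes data.frame with columns node_id, node_type, name.
#' @slot edges data.frame with columns source, target, predicate.
#' @slot nodeIndex named integer vector mapping node_id to 0..N-1.
#' @slot allowSelfLoops logical, whether self-loop edges are permitted.
#' @aliases KnowledgeGraph
#' @exportClass KnowledgeGraph
setClass("KnowledgeGraph",
  slots = c(
    nodes = "data.frame",
    edges = "data.frame",
    nodeIndex = "integer",
    allowSelfLoops = "logical"
  )
)

setValidity("KnowledgeGraph", function(object) {
  nd <- object@nodes; ed <- object@edges
  msgs <- character()
  need <- c("node_id", "node_type", "name")
  if (!all(need %in% names(nd)))
    return(paste("nodes must have columns:", paste(need, collapse = ", ")))
  if (!all(c("source", "target", "predicate") %in% names(ed)))
    return("edges must have columns: source, target, predicate")
  dup <- nd$node_id[duplicated(nd$node_id)]
  if (length(dup))
    msgs <- c(msgs, paste0("duplicate node_id: ", paste(unique(dup), collapse = ", ")))
  if (any(!nzchar(nd$node_type)) || anyNA(nd$node_type))
    msgs <- c(msgs, "node_type must be non-empty")
  if (is.unsorted(nd$node_id, strictly = TRUE))
    msgs <- c(msgs, "nodes must be strictly sorted by node_id")
  unknown <- setdiff(c(ed$source, ed$target), nd$node_id)
  if (length(unknown))
    msgs <- c(msgs, paste0("edges reference unknown nodes: ",
                           paste(unique(unknown), collapse = ", ")))
  if (!isTRUE(object@allowSelfLoops) && nrow(ed) && any(ed$source == ed$target))
    msgs <- c(msgs, "self-loop edges present but not allowed")
  idx <- object@nodeIndex
  if (length(idx) != nrow(nd) ||
      !identical(names(idx), nd$node_id) ||
      !identical(unname(idx), seq_len(nrow(nd)) - 1L))
    msgs <- c(msgs, "nodeIndex must map sorted node ids to 0..N-1")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

## ---------------------------------------------------------------------------
## TransitionModel
## ---------------------------------------------------------------------------

#' TransitionModel: column-stochastic transition operator over a graph
#'
#' Sparse N x N operator in which column j distributes probability mass
#' uniformly over the neighbors of node j. Columns with no out-edges under the
#' chosen orientation are flagged dangling; their mass is redistributed to the
#' restart distribution during propagation.
#'
#' @slot matrix a \code{Matrix::dgCMatrix}, column-stochastic on non-dangling
#'   columns.
#' @slot dangling named logical vector, TRUE for dangling nodes.
#' @slot nodeIds character vector of node ids in matrix order.
#' @slot orientation \code{"undirected"} or \code{"directed"}.
#' @exportClass TransitionModel
setClass("TransitionModel",
  slots = c(
    matrix = "Matrix",
    dangling = "logical",
    nodeIds = "character",
    orientation = "character"
  )
)

setValidity("TransitionModel", function(object) {
  m <- object@matrix
  n <- length(object@nodeIds)
  if (!all(dim(m) == c(n, n))) return("matrix dimension must match nodeIds")
  if (length(object@dangling) != n) return("dangling mask length must be N")
  if (any(m@x < 0)) return("transition entries must be non-negative")
  cs <- Matrix::colSums(m)
  bad <- which(!object@dangling & abs(cs - 1) > 1e-12)
  if (length(bad))
    return(paste0("non-dangling columns not stochastic: ",
                  paste(object@nodeIds[head(bad, 5)], collapse = ", ")))
  if (any(object@dangling & cs != 0)) return("dangling columns must be zero")
  TRUE
})

## ---------------------------------------------------------------------------
## EHRCohort
## ---------------------------------------------------------------------------

#' EHRCohort: timestamped EHR event tables for a patient cohort
#'
#' Container for a patient table (\code{patient_id}, \code{birth_day},
#' \code{last_visit_day}), an event table (\code{patient_id},
#' \code{concept_id}, \code{domain}, \code{event_day}) and optional case /
#' control labels. Dates are integer day offsets from an arbitrary epoch;
#' events are stored sorted by patient then day.
#'
#' @slot patients data.frame with one row per patient.
#' @slot events data.frame of timestamped events.
#' @slot labels named character vector (\code{"case"} / \code{"control"}),
#'   possibly empty when labels are not yet known.
#' @exportClass EHRCohort
setClass("EHRCohort",
  slots = c(
    patients = "data.frame",
    events = "data.frame",
    labels = "character"
  )
)

setValidity("EHRCohort", function(object) {
  p <- object@patients; e <- object@events
  if (!all(c("patient_id", "birth_day", "last_visit_day") %in% names(p)))
    return("patients must have columns patient_id, birth_day, last_visit_day")
  if (!all(c("patient_id", "concept_id", "domain", "event_day") %in% names(e)))
    return("events must have columns patient_id, concept_id, domain, event_day")
  if (anyDuplicated(p$patient_id)) return("duplicate patient_id in patients")
  if (nrow(e)) {
    if (length(setdiff(unique(e$patient_id), p$patient_id)))
      return("events reference unknown patients")
    mx <- tapply(e$event_day, e$patient_id, max)
    lv <- setNames(p$last_visit_day, p$patient_id)
    if (any(mx > lv[names(mx)]))
      return("event_day after last_visit_day for some patients")
    o <- order(e$patient_id, e$event_day)
    if (!identical(o, seq_len(nrow(e))))
      return("events must be sorted by patient_id then event_day")
  }
  if (length(object@labels)) {
    if (length(setdiff(names(object@labels), p$patient_id)))
      return("labels reference unknown patients")
    if (!all(object@labels %in% c("case", "control")))
      return("labels must be 'case' or 'control'")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Embedding matrices
## ---------------------------------------------------------------------------

#' PSEVMatrix: propagated entry vectors, one per EHR concept
#'
#' Rows are mapped EHR concepts, columns are graph nodes (in the graph's sorted
#' node order), and each row is the stationary distribution of a personalized
#' PageRank walk whose restart distribution is weighted by the cohort carrying
#' that concept. Every row is a probability vector.
#'
#' @slot mat numeric matrix, rows = concepts, cols = nodes; each row sums to 1.
#' @slot damping damping factor used (probability of following an edge).
#' @slot tol L1 convergence tolerance used.
#' @exportClass PSEVMatrix
setClass("PSEVMatrix",
  slots = c(mat = "matrix", damping = "numeric", tol = "numeric")
)

setValidity("PSEVMatrix", function(object) {
  m <- object@mat
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("PSEV matrix must have concept rownames and node colnames")
  if (any(m < 0)) return("PSEV values must be non-negative")
  rs <- rowSums(m)
  if (any(abs(rs - 1) > 1e-9))
    return(paste0("PSEV rows must sum to 1; worst |sum-1| = ",
                  format(max(abs(rs - 1)))))
  if (object@damping <= 0 || object@damping >= 1)
    return("damping must lie in (0,1)")
  TRUE
})

#' SpokeSigMatrix: patient signature vectors over graph nodes
#'
#' Rows are patients, columns are graph nodes (identical order and labels as
#' the generating \linkS4class{PSEVMatrix}); each row is the L1-normalized sum
#' of the PSEV rows of the patient's distinct mapped concepts.
#'
#' @slot mat numeric matrix, rows = patients, cols = nodes; each row sums to 1.
#' @exportClass SpokeSigMatrix
setClass("SpokeSigMatrix", slots = c(mat = "matrix"))

setValidity("SpokeSigMatrix", function(object) {
  m <- object@mat
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("signature matrix must have patient rownames and node colnames")
  if (any(m < 0)) return("signature values must be non-negative")
  rs <- rowSums(m)
  if (nrow(m) && any(abs(rs - 1) > 1e-9))
    return("signature rows must sum to 1")
  TRUE
})

## ---------------------------------------------------------------------------
## AUCDistribution
## ---------------------------------------------------------------------------

#' AUCDistribution: bootstrap distribution of ROC-AUC values
#'
#' @slot values numeric vector of per-replicate AUC values in [0,1].
#' @slot sampleSize patients drawn (with replacement) per replicate.
#' @exportClass AUCDistribution
setClass("AUCDistribution",
  slots = c(values = "numeric", sampleSize = "integer")
)

setValidity("AUCDistribution", function(object) {
  v <- object@values
  if (!length(v)) return("empty AUC distribution")
  if (any(v < 0 | v > 1)) return("AUC values must lie in [0,1]")
  TRUE
})

## ---------------------------------------------------------------------------
## PatientSubnetwork
## ---------------------------------------------------------------------------

#' PatientSubnetwork: explanatory subgraph for one patient's prediction
#'
#' Nodes are tagged by role: \code{entry} (the patient's mapped EHR concepts),
#' \code{focus} (the disease of interest) and \code{relay} (nodes on short
#' paths between the two, ranked by the patient's signature value).
#'
#' @slot focus node_id of the focus node.
#' @slot nodes data.frame with columns node_id, node_type, role,
#'   spokesig_value.
#' @slot edges data.frame with columns source, target, predicate.
#' @exportClass PatientSubnetwork
setClass("PatientSubnetwork",
  slots = c(focus = "character", nodes = "data.frame", edges = "data.frame")
)
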
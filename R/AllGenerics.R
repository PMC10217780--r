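#' @importClassesFrom Matrix Matrix dgCMatrix
NULL

## ---- KnowledgeGraph accessors ---------------------------------------------

#' Accessors for KnowledgeGraph objects
#'
#' \code{kgNodes} / \code{kgEdges} return the node and edge tables;
#' \code{nodeIds} the sorted node ids; \code{nodeIndex} the named 0-based
#' dense index; \code{nodeTypes} a named vector of node types;
#' \code{numNodes} / \code{numEdges} the counts.
#'
#' @param x a \linkS4class{KnowledgeGraph}.
#' @return see individual descriptions.
#' @name kg-accessors
#' @aliases kgNodes kgEdges nodeIds nodeIndex nodeTypes numNodes numEdges
NULL

#' @rdname kg-accessors
#' @export
setGeneric("kgNodes", function(x) standardGeneric("kgNodes"))
#' @rdname kg-accessors
#' @export
setGeneric("kgEdges", function(x) standardGeneric("kgEdges"))
#' @rdname kg-accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
#' @rdname kg-accessors
#' @export
setGeneric("nodeIndex", function(x) standardGeneric("nodeIndex"))
#' @rdname kg-accessors
#' @export
setGeneric("nodeTypes", function(x) standardGeneric("nodeTypes"))
#' @rdname kg-accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))
#' @rdname kg-accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname kg-accessors
setMethod("kgNodes", "KnowledgeGraph", function(x) x@nodes)
#' @rdname kg-accessors
setMethod("kgEdges", "KnowledgeGraph", function(x) x@edges)
#' @rdname kg-accessors
setMethod("nodeIds", "KnowledgeGraph", function(x) x@nodes$node_id)
#' @rdname kg-accessors
setMethod("nodeIndex", "KnowledgeGraph", function(x) x@nodeIndex)
#' @rdname kg-accessors
setMethod("nodeTypes", "KnowledgeGraph",
          function(x) setNames(x@nodes$node_type, x@nodes$node_id))
#' @rdname kg-accessors
setMethod("numNodes", "KnowledgeGraph", function(x) nrow(x@nodes))
#' @rdname kg-accessors
setMethod("numEdges", "KnowledgeGraph", function(x) nrow(x@edges))

setMethod("show", "KnowledgeGraph", function(object) {
  tab <- table(object@nodes$node_type)
  cat("KnowledgeGraph with", nrow(object@nodes), "nodes and",
      nrow(object@edges), "edges\n")
  cat("  node types:",
      paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "), "\n")
})

## ---- EHRCohort accessors ---------------------------------------------------

#' Accessors for EHRCohort objects
#'
#' @param x an \linkS4class{EHRCohort}.
#' @param patientId a single patient id (for \code{patientEvents}).
#' @name cohort-accessors
#' @aliases cohortPatients cohortEvents cohortLabels patientEvents numPatients
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("cohortPatients", function(x) standardGeneric("cohortPatients"))
#' @rdname cohort-accessors
#' @export
setGeneric("cohortEvents", function(x) standardGeneric("cohortEvents"))
#' @rdname cohort-accessors
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))
#' @rdname cohort-accessors
#' @export
setGeneric("numPatients", function(x) standardGeneric("numPatients"))
#' @rdname cohort-accessors
#' @export
setGeneric("patientEvents",
           function(x, patientId) standardGeneric("patientEvents"))

#' @rdname cohort-accessors
setMethod("cohortPatients", "EHRCohort", function(x) x@patients)
#' @rdname cohort-accessors
setMethod("cohortEvents", "EHRCohort", function(x) x@events)
#' @rdname cohort-accessors
setMethod("cohortLabels", "EHRCohort", function(x) x@labels)
#' @rdname cohort-accessors
setMethod("numPatients", "EHRCohort", function(x) nrow(x@patients))
#' @rdname cohort-accessors
setMethod("patientEvents", "EHRCohort", function(x, patientId) {
  if (!patientId %in% x@patients$patient_id)
    kgStop("unknown patient: ", patientId)
  x@events[x@events$patient_id == patientId, , drop = FALSE]
})

setMethod("show", "EHRCohort", function(object) {
  cat("EHRCohort with", nrow(object@patients), "patients and",
      nrow(object@events), "events\n")
  if (length(object@labels)) {
    tab <- table(object@labels)
    cat("  labels:", paste0(names(tab), " (", as.integer(tab), ")",
                            collapse = ", "), "\n")
  }
})

## ---- Matrix wrappers -------------------------------------------------------

#' @describeIn PSEVMatrix-class extract the underlying numeric matrix.
#' @param x,object a \code{PSEVMatrix}.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "PSEVMatrix", function(x, ...) x@mat)

#' @describeIn SpokeSigMatrix-class extract the underlying numeric matrix.
#' @param x,object a \code{SpokeSigMatrix}.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "SpokeSigMatrix", function(x, ...) x@mat)

setMethod("show", "PSEVMatrix", function(object) {
  cat("PSEVMatrix:", nrow(object@mat), "concepts x", ncol(object@mat),
      "graph nodes (damping ", object@damping, ")\n", sep = " ")
})

setMethod("show", "SpokeSigMatrix", function(object) {
  cat("SpokeSigMatrix:", nrow(object@mat), "patients x", ncol(object@mat),
      "graph nodes\n")
})

#' Dimensions of embedding matrices
#' @param x a PSEVMatrix or SpokeSigMatrix.
#' @export
setMethod("dim", "PSEVMatrix", function(x) dim(x@mat))
#' @rdname dim-PSEVMatrix-method
#' @export
setMethod("dim", "SpokeSigMatrix", function(x) dim(x@mat))

## ---- AUCDistribution -------------------------------------------------------

#' Summaries of a bootstrap AUC distribution
#'
#' \code{aucValues} returns the raw replicate values, \code{aucMean} /
#' \code{aucSD} their mean and standard deviation, and \code{aucCI} the 95%
#' bootstrap confidence interval taken as the 2.5th and 97.5th percentiles of
#' the distribution.
#'
#' @param x an \linkS4class{AUCDistribution}.
#' @name auc-accessors
#' @aliases aucValues aucMean aucSD aucCI
NULL

#' @rdname auc-accessors
#' @export
setGeneric("aucValues", function(x) standardGeneric("aucValues"))
#' @rdname auc-accessors
#' @export
setGeneric("aucMean", function(x) standardGeneric("aucMean"))
#' @rdname auc-accessors
#' @export
setGeneric("aucSD", function(x) standardGeneric("aucSD"))
#' @rdname auc-accessors
#' @export
setGeneric("aucCI", function(x) standardGeneric("aucCI"))

#' @rdname auc-accessors
setMethod("aucValues", "AUCDistribution", function(x) x@values)
#' @rdname auc-accessors
setMethod("aucMean", "AUCDistribution", function(x) mean(x@values))
#' @rdname auc-accessors
setMethod("aucSD", "AUCDistribution", function(x) sd(x@values))
#' @rdname auc-accessors
setMethod("aucCI", "AUCDistribution", function(x)
  unname(quantile(x@values, c(0.025, 0.975))))

setMethod("show", "AUCDistribution", function(object) {
  ci <- aucCI(object)
  cat(sprintf("AUCDistribution: %d replicates, mean %.3f +/- %.3f, 95%% CI (%.3f, %.3f)\n",
              length(object@values), aucMean(object), aucSD(object),
              ci[1], ci[2]))
})

setMethod("show", "PatientSubnetwork", function(object) {
  cat("PatientSubnetwork around", object@focus, ":",
      nrow(object@nodes), "nodes,", nrow(object@edges), "edges\n")
  cat("  roles:", paste(names(table(object@nodes$role)),
                        as.integer(table(object@nodes$role)),
                        sep = "=", collapse = ", "), "\n")
})
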
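## Knowledge-graph construction, I/O and the stochastic transition operator
## used by propagation.

#' Construct a KnowledgeGraph from node and edge tables
#'
#' Nodes are sorted lexicographically by \code{node_id} (C locale) so that all
#' derived matrices have a reproducible column order; the dense node index is
#' 0-based.
#'
#' @param nodes data.frame with columns \code{node_id}, \code{node_type},
#'   \code{name}.
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{predicate}.
#' @param allowSelfLoops permit edges with source == target (default FALSE).
#' @return a validated \linkS4class{KnowledgeGraph}.
#' @export
#' @examples
#' kg <- knowledgeGraph(
#'   nodes = data.frame(node_id = c("A", "B"), node_type = "Symptom",
#'                      name = c("a", "b")),
#'   edges = data.frame(source = "A", target = "B", predicate = "ASSOCIATES")
#' )
#' numNodes(kg)
knowledgeGraph <- function(nodes, edges, allowSelfLoops = FALSE) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  for (cn in c("node_id", "node_type", "name"))
    nodes[[cn]] <- as.character(nodes[[cn]])
  if (nrow(edges))
    for (cn in c("source", "target", "predicate"))
      edges[[cn]] <- as.character(edges[[cn]])
  dup <- unique(nodes$node_id[duplicated(nodes$node_id)])
  if (length(dup))
    kgStop("duplicate node_id in node table: ", paste(dup, collapse = ", "))
  unknown <- setdiff(c(edges$source, edges$target), nodes$node_id)
  if (length(unknown)) {
    bad <- edges$source %in% unknown | edges$target %in% unknown
    kgStop("edges reference unknown nodes: ",
           paste(unknown, collapse = ", "),
           " (", sum(bad), " offending rows)")
  }
  o <- orderC(nodes$node_id)
  nodes <- nodes[o, , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  idx <- setNames(seq_len(nrow(nodes)) - 1L, nodes$node_id)
  new("KnowledgeGraph", nodes = nodes, edges = edges, nodeIndex = idx,
      allowSelfLoops = allowSelfLoops)
}

## locale-independent lexicographic order
orderC <- function(x) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(suppressWarnings(Sys.setlocale("LC_COLLATE", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_COLLATE", "C"))
  order(x)
}

#' Load a knowledge graph from TSV node and edge lists
#'
#' Expects tab-separated files with header rows: nodes with columns
#' \code{node_id}, \code{node_type}, \code{name}; edges with \code{source},
#' \code{target}, \code{predicate}. Validation rejects duplicate node ids and
#' edges referencing unknown nodes, naming the offenders.
#'
#' @param nodesPath,edgesPath file paths.
#' @param allowSelfLoops passed to \code{\link{knowledgeGraph}}.
#' @return a \linkS4class{KnowledgeGraph}.
#' @export
loadGraph <- function(nodesPath, edgesPath, allowSelfLoops = FALSE) {
  nodes <- read.delim(nodesPath, colClasses = "character")
  edges <- read.delim(edgesPath, colClasses = "character")
  knowledgeGraph(nodes, edges, allowSelfLoops = allowSelfLoops)
}

#' Write a knowledge graph to TSV node and edge lists
#'
#' Inverse of \code{\link{loadGraph}}: writing then loading round-trips the
#' node and edge multisets exactly.
#'
#' @param kg a \linkS4class{KnowledgeGraph}.
#' @param nodesPath,edgesPath output file paths.
#' @return invisibly, the paths.
#' @export
writeGraph <- function(kg, nodesPath, edgesPath) {
  write.table(kgNodes(kg), nodesPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(kgEdges(kg), edgesPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(nodesPath, edgesPath))
}

#' Neighbors of a node under the undirected view
#'
#' @param kg a \linkS4class{KnowledgeGraph}.
#' @param nodeId a single node id.
#' @return character vector of neighboring node ids (sorted, no duplicates).
#' @export
kgNeighbors <- function(kg, nodeId) {
  if (!nodeId %in% nodeIds(kg)) kgStop("unknown node: ", nodeId)
  ed <- kgEdges(kg)
  nb <- c(ed$target[ed$source == nodeId], ed$source[ed$target == nodeId])
  nb <- setdiff(unique(nb), nodeId)
  nb[orderC(nb)]
}

#' Build the column-stochastic transition operator of a graph
#'
#' Column j of the operator distributes mass uniformly over the (unique)
#' neighbors of node j. Under \code{orientation = "undirected"} every edge is
#' traversable both ways; under \code{"directed"} only source-to-target.
#' Columns with no out-neighbors are flagged dangling and left as zero
#' columns; \code{\link{computePSEV}} redistributes their mass to the restart
#' distribution.
#'
#' @param kg a \linkS4class{KnowledgeGraph}; must be non-empty.
#' @param orientation edge traversal mode, \code{"undirected"} (default) or
#'   \code{"directed"}.
#' @return a \linkS4class{TransitionModel}.
#' @export
buildTransition <- function(kg, orientation = c("undirected", "directed")) {
  orientation <- match.arg(orientation)
  n <- numNodes(kg)
  if (n == 0L) kgStop("cannot build a transition model for an empty graph")
  ids <- nodeIds(kg)
  ed <- kgEdges(kg)
  ed <- ed[ed$source != ed$target, , drop = FALSE]  # self-loops carry no step
  if (nrow(ed)) {
    src <- match(ed$source, ids)
    tgt <- match(ed$target, ids)
    if (orientation == "undirected") {
      from <- c(src, tgt); to <- c(tgt, src)
    } else {
      from <- src; to <- tgt
    }
    pairs <- unique(cbind(from, to))   # parallel edges count once
    from <- pairs[, 1]; to <- pairs[, 2]
    deg <- tabulate(from, nbins = n)
    mat <- Matrix::sparseMatrix(i = to, j = from, x = 1 / deg[from],
                                dims = c(n, n), dimnames = list(ids, ids))
  } else {
    deg <- integer(n)
    mat <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n), dimnames = list(ids, ids))
  }
  new("TransitionModel", matrix = methods::as(mat, "CsparseMatrix"),
      dangling = setNames(deg == 0L, ids), nodeIds = ids,
      orientation = orientation)
}
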
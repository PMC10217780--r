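## Patient-specific explanatory subnetworks around a focus (disease) node.

## internal: BFS hop distances from a set of source nodes (undirected view)
hopDistances <- function(kg, sources) {
  ig <- igraph::graph_from_data_frame(
    kgEdges(kg)[, c("source", "target")], directed = FALSE,
    vertices = kgNodes(kg)$node_id)
  d <- igraph::distances(ig, v = sources, to = igraph::V(ig))
  out <- apply(d, 2, min)
  setNames(as.numeric(out), igraph::V(ig)$name)[nodeIds(kg)]
}

#' Extract a patient-specific subnetwork explaining a prediction
#'
#' Collects the patient's entry nodes (graph nodes mapped from the concepts
#' in the record), the focus node, and relay candidates lying on paths of at
#' most \code{maxHops} hops between an entry node and the focus. Relays are
#' ranked by the patient's signature value (a deterministic pruning rule
#' replacing manual curation) and truncated to \code{topK}, ties broken by
#' node id. Edges are the graph edges among included nodes that lie on a
#' qualifying path. If the focus is unreachable within \code{maxHops} from
#' every entry node the relay set is empty and a warning is raised.
#'
#' @param kg a \linkS4class{KnowledgeGraph}.
#' @param events data.frame of the patient's (windowed) events.
#' @param mapping named character vector concept_id -> node_id.
#' @param focus focus node id (e.g. the target disease).
#' @param spokesig named numeric signature vector for the patient (from
#'   \code{\link{buildSpokeSig}}).
#' @param maxHops maximum entry-to-focus path length (default 2).
#' @param topK maximum number of relay nodes retained (default 25).
#' @return a \linkS4class{PatientSubnetwork}.
#' @export
extractSubnetwork <- function(kg, events, mapping, focus, spokesig,
                              maxHops = 2L, topK = 25L) {
  if (!focus %in% nodeIds(kg)) kgStop("unknown focus node: ", focus)
  entry <- unique(unname(mapping[intersect(unique(events$concept_id),
                                           names(mapping))]))
  entry <- setdiff(intersect(entry, nodeIds(kg)), focus)
  if (!length(entry)) kgStop("patient has no entry nodes in the graph")
  dEntry <- hopDistances(kg, entry)
  dFocus <- hopDistances(kg, focus)
  onPath <- names(dEntry)[dEntry + dFocus <= maxHops]
  relays <- setdiff(onPath, c(entry, focus))
  if (min(dFocus[entry]) > maxHops) {
    warning("focus unreachable within ", maxHops,
            " hops from all entry nodes; relay set empty")
    relays <- character(0)
  }
  if (length(relays)) {
    val <- spokesig[relays]
    ord <- order(-val, relays)
    relays <- relays[ord][seq_len(min(topK, length(relays)))]
  }
  keepEntry <- entry[dFocus[entry] <= maxHops]
  included <- c(keepEntry, relays, focus)
  roles <- c(rep("entry", length(keepEntry)),
             rep("relay", length(relays)), "focus")
  types <- nodeTypes(kg)
  nodes <- data.frame(node_id = included, node_type = unname(types[included]),
                      role = roles,
                      spokesig_value = unname(spokesig[included]))
  nodes <- nodes[orderC(nodes$node_id), , drop = FALSE]
  rownames(nodes) <- NULL
  ed <- kgEdges(kg)
  keep <- ed$source %in% included & ed$target %in% included
  ed <- ed[keep, , drop = FALSE]
  # retain only edges on a qualifying entry -> focus path
  onEdge <- (dEntry[ed$source] + 1 + dFocus[ed$target] <= maxHops) |
            (dEntry[ed$target] + 1 + dFocus[ed$source] <= maxHops)
  ed <- ed[onEdge, , drop = FALSE]
  rownames(ed) <- NULL
  new("PatientSubnetwork", focus = focus, nodes = nodes, edges = ed)
}

#' Export a patient subnetwork as GraphML
#'
#' Node attributes \code{role}, \code{node_type} and \code{spokesig_value}
#' and the edge attribute \code{predicate} are carried through for rendering
#' in standard graph viewers.
#'
#' @param subnet a \linkS4class{PatientSubnetwork}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeSubnetworkGraphML <- function(subnet, path) {
  ig <- igraph::graph_from_data_frame(
    subnet@edges[, c("source", "target", "predicate")], directed = FALSE,
    vertices = subnet@nodes)
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}
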
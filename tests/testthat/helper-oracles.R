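# Independent oracles, kept deliberately naive and separate from the package
# implementations they check.

# Dense personalized-PageRank power iteration built straight from the edge
# list (no sparse algebra, no package transition code).
densePageRankOracle <- function(nodes, edges, restart, damping,
                                iters = 20000, tol = 1e-14) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    A[edges$target[i], edges$source[i]] <- 1
    A[edges$source[i], edges$target[i]] <- 1
  }
  deg <- colSums(A)
  T <- A
  for (j in seq_len(n)) if (deg[j] > 0) T[, j] <- A[, j] / deg[j]
  v <- restart
  for (k in seq_len(iters)) {
    vNew <- damping * (T %*% v + sum(v[deg == 0]) * restart) +
      (1 - damping) * restart
    if (sum(abs(vNew - v)) < tol) break
    v <- vNew
  }
  drop(v)
}

# Brute-force AUC: explicit pair counting with half-credit for ties.
pairCountAucOracle <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# A random undirected graph guaranteed connected via a random spanning tree.
randomConnectedGraph <- function(n, extraEdgeProb = 0.1) {
  ids <- sprintf("N%02d", seq_len(n))
  nodes <- data.frame(node_id = ids, node_type = "Generic", name = ids)
  edges <- NULL
  if (n > 1) {
    perm <- sample(ids)
    attach_to <- vapply(2:n, function(i) perm[sample.int(i - 1, 1)],
                        character(1))
    edges <- data.frame(source = attach_to, target = perm[-1],
                        predicate = "E")
    pairs <- t(combn(ids, 2))
    extra <- pairs[runif(nrow(pairs)) < extraEdgeProb, , drop = FALSE]
    if (nrow(extra))
      edges <- unique(rbind(edges,
                            data.frame(source = extra[, 1],
                                       target = extra[, 2], predicate = "E")))
  }
  list(nodes = nodes, edges = edges)
}
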
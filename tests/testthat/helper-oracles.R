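# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementation.

# All-pairs shortest hop counts by BFS over an explicit adjacency list.
oracle_distances <- function(nodes, edges) {
  n <- length(nodes)
  adj <- lapply(nodes, function(v) edges$to[edges$from == v])
  names(adj) <- nodes
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- nodes[s]
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(d[s, nxt])]
      d[s, nxt] <- depth
      frontier <- nxt
    }
  }
  d
}

# Largest strongly connected component via pairwise mutual reachability.
oracle_lscc <- function(nodes, edges) {
  if (!length(nodes)) return(0L)
  d <- oracle_distances(nodes, edges)
  reach <- is.finite(d)
  best <- 1L
  for (i in seq_along(nodes)) {
    comp <- sum(reach[i, ] & reach[, i])
    best <- max(best, comp)
  }
  as.integer(best)
}

oracle_metrics <- function(graph) {
  nodes <- graph$nodes; edges <- graph$edges
  nn <- length(nodes); ne <- nrow(edges)
  if (nn == 0L) {
    return(list(nn = 0, ne = 0, diameter = 0, aspl = 0, awd = 0,
                density = 0, lscc = 0))
  }
  d <- oracle_distances(nodes, edges)
  finite <- d[is.finite(d) & d > 0]
  list(nn = nn, ne = ne,
       diameter = if (length(finite)) max(finite) else 0,
       aspl = if (length(finite)) mean(finite) else 0,
       awd = 2 * sum(edges$weight) / nn,
       density = if (nn >= 2) ne / (nn * (nn - 1)) else 0,
       lscc = oracle_lscc(nodes, edges))
}

# Uniform random simple digraph as a speech_graph, with random weights.
random_speech_graph <- function(max_nodes = 8L) {
  nn <- sample.int(max_nodes, 1L)
  pairs <- expand.grid(from = seq_len(nn), to = seq_len(nn))
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  ne <- sample.int(nrow(pairs) + 1L, 1L) - 1L
  nodes <- paste0("w", seq_len(nn))
  edges <- if (ne > 0L) {
    sel <- pairs[sample.int(nrow(pairs), ne), , drop = FALSE]
    data.frame(from = nodes[sel$from], to = nodes[sel$to],
               weight = sample.int(3L, ne, replace = TRUE),
               stringsAsFactors = FALSE)
  } else NULL
  speech_graph(edges, nodes, "structural")
}

# Brute-force U1 and rank-biserial by explicit pair counting.
oracle_u_rbc <- function(x, y) {
  u1 <- 0
  for (a in x) for (b in y) u1 <- u1 + (a > b) + 0.5 * (a == b)
  list(u1 = u1, rbc = 2 * u1 / (length(x) * length(y)) - 1)
}

# VIF by an explicit normal-equations solve.
oracle_vif <- function(x) {
  x <- as.matrix(x)
  vapply(seq_len(ncol(x)), function(i) {
    yi <- x[, i]
    Xi <- cbind(1, x[, -i, drop = FALSE])
    beta <- solve(t(Xi) %*% Xi, t(Xi) %*% yi)
    res <- yi - Xi %*% beta
    r2 <- 1 - sum(res^2) / sum((yi - mean(yi))^2)
    1 / (1 - r2)
  }, numeric(1))
}

# All simple digraphs with nn nodes and ne edges, enumerated by edge subset.
enumerate_gnm <- function(nn, ne) {
  pairs <- expand.grid(from = seq_len(nn), to = seq_len(nn))
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  sets <- utils::combn(nrow(pairs), ne, simplify = FALSE)
  nodes <- paste0("w", seq_len(nn))
  lapply(sets, function(idx) {
    sel <- pairs[idx, , drop = FALSE]
    speech_graph(data.frame(from = nodes[sel$from], to = nodes[sel$to],
                            weight = 1L, stringsAsFactors = FALSE),
                 nodes, "structural")
  })
}
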
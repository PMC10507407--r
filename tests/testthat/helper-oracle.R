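# Independent oracles used across the suite.
#
# The topology oracle never touches the package's BFS/Brandes code path:
# hop distances and geodesic counts come from powers of the adjacency
# matrix (the number of length-d walks between two nodes at hop distance
# d equals the number of shortest paths), triangles from diag(A^3).

# Build a ppi_network from an adjacency matrix (upper triangle).
net_from_adjacency <- function(am, score = 0.95, ids = NULL) {
  n <- nrow(am)
  if (is.null(ids)) ids <- sprintf("v%02d", seq_len(n))
  ij <- which(upper.tri(am) & am == 1, arr.ind = TRUE)
  edges <- if (nrow(ij)) {
    data.frame(node1 = ids[ij[, 1]], node2 = ids[ij[, 2]],
               combined_score = score, stringsAsFactors = FALSE)
  } else {
    data.frame(node1 = character(), node2 = character(),
               combined_score = numeric())
  }
  ppi_network(edges, nodes = ids)
}

random_adjacency <- function(n, p) {
  am <- matrix(0L, n, n)
  am[upper.tri(am)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  am + t(am)
}

# All indices of a small simple graph by exhaustive walk counting.
oracle_topology <- function(am) {
  n <- nrow(am)
  ids <- sprintf("v%02d", seq_len(n))
  # hop distances and geodesic counts from matrix powers
  dist <- matrix(Inf, n, n); diag(dist) <- 0
  sigma <- matrix(0, n, n); diag(sigma) <- 1
  pw <- vector("list", n)
  P <- diag(n)
  for (d in seq_len(n - 1)) {
    P <- P %*% am
    pw[[d]] <- P
    newly <- is.infinite(dist) & P > 0
    dist[newly] <- d
    sigma[newly] <- P[newly]
  }
  k <- rowSums(am)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || is.infinite(dist[s, t])) next
        d1 <- dist[s, v]; d2 <- dist[v, t]
        if (is.finite(d1) && is.finite(d2) && d1 + d2 == dist[s, t]) {
          n1 <- if (d1 == 0) 1 else pw[[d1]][s, v]
          n2 <- if (d2 == 0) 1 else pw[[d2]][v, t]
          bc[v] <- bc[v] + n1 * n2 / sigma[s, t]
        }
      }
    }
  }
  ecc <- apply(dist, 1, function(row) {
    r <- row[is.finite(row)]
    max(r)
  })
  cc <- vapply(seq_len(n), function(v) {
    d <- dist[v, ]
    d <- d[is.finite(d)]
    if (length(d) <= 1) return(0)
    (length(d) - 1) / sum(d[d > 0])
  }, numeric(1))
  tri <- diag(am %*% am %*% am)   # closed 3-walks = 2 * triangles at v
  clo <- ifelse(k < 2, 0, tri / (k * (k - 1)))
  list(ids = ids, k = k, bc = bc, ecc = ecc, cc = cc,
       clustering = clo, acc = mean(clo),
       mean_degree = sum(k) / n)
}

# Connected check by reachability (matrix powers, independent of BFS).
oracle_connected <- function(am) {
  n <- nrow(am)
  if (n == 1) return(TRUE)
  R <- diag(n) + am
  for (i in seq_len(ceiling(log2(n)) + 1)) R <- sign(R %*% R)
  all(R > 0)
}

# Adjacency matrix of a ppi_network (node order = sorted identifiers).
adjacency_of <- function(net) {
  ids <- net$nodes$identifier
  am <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    i <- match(net$edges$node1, ids); j <- match(net$edges$node2, ids)
    am[cbind(i, j)] <- 1L
    am[cbind(j, i)] <- 1L
  }
  am
}
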
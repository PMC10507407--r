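# Per-node and global topological indices of a simple undirected PPI
# graph. Distances are hop counts: the combined score is a confidence,
# not a length, so edges are unweighted here.

#' Degree of a single node
#'
#' @param net a [ppi_network].
#' @param node node identifier.
#' @return integer number of incident edges.
#' @export
node_degree <- function(net, node) {
  stopifnot(inherits(net, "ppi_network"))
  if (!node %in% net$nodes$identifier) stop("unknown node: ", node)
  sum(net$edges$node1 == node) + sum(net$edges$node2 == node)
}

#' Betweenness centrality of every node
#'
#' Fraction of shortest paths passing through each node, summed over
#' unordered source-target pairs (endpoints excluded). Computed with the
#' standard single-source accumulation algorithm on unit-length edges;
#' pairs in different components contribute zero. Values are unnormalized
#' pair fractions; divide by `(n-1)(n-2)/2` for the normalized variant.
#'
#' @param net a [ppi_network].
#' @return named numeric vector (one entry per node).
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  adj <- adjacency_list(net)
  n <- length(adj)
  bc <- numeric(n)
  if (n == 0L) return(stats::setNames(bc, character()))
  for (s in seq_len(n)) {
    # Brandes' accumulation from source s
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_out <- integer(n)
    queue <- integer(n); queue[1L] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      order_out[head - 1L] <- v
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L; queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (i in rev(seq_len(tail))) {
      w <- order_out[i]
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  stats::setNames(bc / 2, names(adj))   # each unordered pair counted twice
}

#' Eccentricity of every node
#'
#' Maximum hop distance from each node to any other node of its connected
#' component; 0 for an isolated node.
#'
#' @param net a [ppi_network].
#' @return named integer vector.
#' @export
eccentricity <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  adj <- adjacency_list(net)
  ecc <- vapply(seq_along(adj), function(s) {
    d <- bfs_distances(adj, s)
    max(d, na.rm = TRUE)
  }, integer(1))
  stats::setNames(ecc, names(adj))
}

#' Closeness centrality of every node
#'
#' Inverse of the mean hop distance from each node to the other nodes of
#' its component: `(n_c - 1) / sum(d)` with `n_c` the component size.
#' Defined as 0 for an isolated node.
#'
#' @param net a [ppi_network].
#' @return named numeric vector in \[0, 1\].
#' @export
closeness_centrality <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  adj <- adjacency_list(net)
  cc <- vapply(seq_along(adj), function(s) {
    d <- bfs_distances(adj, s)
    d <- d[!is.na(d)]
    if (length(d) <= 1L) return(0)
    (length(d) - 1) / sum(d)
  }, numeric(1))
  stats::setNames(cc, names(adj))
}

#' Local clustering coefficient of every node
#'
#' `C(v) = 2 T(v) / (k(v) (k(v)-1))` with `T(v)` the number of edges among
#' the neighbours of `v`; 0 when `k(v) < 2`.
#'
#' @param net a [ppi_network].
#' @return named numeric vector in \[0, 1\].
#' @export
local_clustering <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  adj <- adjacency_list(net)
  cl <- vapply(seq_along(adj), function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2L) return(0)
    t <- 0L
    for (i in seq_len(k - 1L)) {
      t <- t + sum(adj[[nb[i]]] %in% nb[(i + 1L):k])
    }
    2 * t / (k * (k - 1))
  }, numeric(1))
  stats::setNames(cl, names(adj))
}

#' Average clustering coefficient of the network
#'
#' Mean over all nodes of the local clustering coefficient (nodes of
#' degree < 2 contribute 0, which lowers the mean; this matches the
#' default of the common network tools).
#'
#' @param net a [ppi_network].
#' @return a single value in \[0, 1\].
#' @export
average_clustering <- function(net) {
  mean(local_clustering(net))
}

#' Full topological report of a network
#'
#' Computes every per-node index (degree k, betweenness BC with its
#' normalized variant, eccentricity Ecc, closeness CC, local clustering,
#' component membership) plus the global mean degree and average
#' clustering coefficient. The result is independent of node insertion
#' order (rows are sorted by identifier).
#'
#' @param net a non-empty [ppi_network].
#' @return object of class `topology_report`: a list with `per_node`
#'   (data.frame), `n_nodes`, `n_edges`, `mean_degree`, `avg_clustering`.
#' @export
compute_topology <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  n <- nrow(net$nodes)
  if (n == 0L) stop("empty network")
  adj <- adjacency_list(net)
  k <- vapply(adj, length, integer(1))
  bc <- betweenness_centrality(net)
  norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  per_node <- data.frame(
    identifier = names(adj),
    k = as.integer(k),
    BC = as.numeric(bc),
    BC_normalized = as.numeric(bc) / norm,
    Ecc = as.integer(eccentricity(net)),
    CC = as.numeric(closeness_centrality(net)),
    clustering = as.numeric(local_clustering(net)),
    component = component_labels(adj),
    stringsAsFactors = FALSE
  )
  rownames(per_node) <- NULL
  structure(
    list(per_node = per_node,
         n_nodes = n,
         n_edges = nrow(net$edges),
         mean_degree = 2 * nrow(net$edges) / n,
         avg_clustering = mean(per_node$clustering)),
    class = "topology_report"
  )
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("<topology_report> %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("  mean degree <k> = %.4g   avg clustering Acc = %.4g\n",
              x$mean_degree, x$avg_clustering))
  top <- x$per_node[order(-x$per_node$k), , drop = FALSE]
  cat("  highest-degree nodes: ",
      paste(utils::head(top$identifier, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write the per-node index table as CSV
#'
#' @param report a `topology_report`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_topology_csv <- function(report, path) {
  stopifnot(inherits(report, "topology_report"))
  utils::write.csv(report$per_node, path, row.names = FALSE)
  invisible(path)
}

#' Write the global index block as JSON
#'
#' @param report a `topology_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(report, path) {
  stopifnot(inherits(report, "topology_report"))
  jsonlite::write_json(
    list(n_nodes = report$n_nodes, n_edges = report$n_edges,
         mean_degree = report$mean_degree,
         avg_clustering = report$avg_clustering),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
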
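# ---- ppi_network class -------------------------------------------------

#' Construct a scored protein-protein interaction network
#'
#' An `ppi_network` is a simple undirected graph: a node table with
#' provenance (`seed` vs `predicted_partner`) and an edge table with a
#' STRING-style combined confidence score in \[0, 1\]. Self-loops are
#' forbidden and duplicate unordered pairs are collapsed keeping the
#' maximum score.
#'
#' @param edges data.frame with columns `node1`, `node2`, `combined_score`.
#' @param seeds character vector of identifiers to mark with origin
#'   `"seed"`; all other nodes get origin `"predicted_partner"`.
#' @param nodes optional character vector of node identifiers; defaults to
#'   the union of edge endpoints. Extra identifiers become isolated nodes.
#' @return An object of class `ppi_network` with elements `nodes`
#'   (data.frame: `identifier`, `origin`) and `edges` (data.frame:
#'   `node1`, `node2`, `combined_score`; `node1 < node2` lexicographically).
#' @export
ppi_network <- function(edges, seeds = character(), nodes = NULL) {
  stopifnot(is.data.frame(edges))
  need <- c("node1", "node2", "combined_score")
  if (!all(need %in% names(edges))) {
    stop("edge table must have columns node1, node2, combined_score")
  }
  a <- trimws(as.character(edges$node1))
  b <- trimws(as.character(edges$node2))
  s <- as.numeric(edges$combined_score)
  keep <- a != b
  if (any(!keep)) {
    warning(sprintf("dropping %d self-loop edge row(s)", sum(!keep)))
    a <- a[keep]; b <- b[keep]; s <- s[keep]
  }
  if (length(s) && (any(!is.finite(s)) || any(s < 0) || any(s > 1))) {
    bad <- which(!is.finite(s) | s < 0 | s > 1)[1L]
    stop(sprintf("combined_score outside [0,1] at edge row %d", bad))
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  if (length(lo)) {
    key <- paste(lo, hi, sep = "\r")
    # collapse duplicate unordered pairs, keep max score
    o <- order(key, -s)
    first <- !duplicated(key[o])
    lo <- lo[o][first]; hi <- hi[o][first]; s <- s[o][first]
    o2 <- order(lo, hi)
    lo <- lo[o2]; hi <- hi[o2]; s <- s[o2]
  }
  ids <- sort(unique(c(lo, hi, trimws(as.character(nodes)), trimws(seeds))))
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stop("network has no nodes")
  origin <- ifelse(ids %in% trimws(seeds), "seed", "predicted_partner")
  net <- structure(
    list(
      nodes = data.frame(identifier = ids, origin = origin,
                         stringsAsFactors = FALSE),
      edges = data.frame(node1 = lo, node2 = hi, combined_score = s,
                         stringsAsFactors = FALSE)
    ),
    class = "ppi_network"
  )
  net
}

#' @export
print.ppi_network <- function(x, ...) {
  iso <- isolated_nodes(x)
  cat(sprintf("<ppi_network> %d nodes (%d seeds), %d edges%s\n",
              nrow(x$nodes), sum(x$nodes$origin == "seed"),
              nrow(x$edges),
              if (length(iso)) sprintf(", %d isolated", length(iso)) else ""))
  if (nrow(x$edges)) {
    cat(sprintf("  combined_score in [%.3f, %.3f]\n",
                min(x$edges$combined_score), max(x$edges$combined_score)))
  }
  invisible(x)
}

#' Nodes with no incident edge
#'
#' @param net a `ppi_network`.
#' @return character vector of isolated node identifiers.
#' @export
isolated_nodes <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  setdiff(net$nodes$identifier, c(net$edges$node1, net$edges$node2))
}

# Internal: adjacency list as integer vectors indexed by position in
# net$nodes$identifier (sorted). Used by all first-principles traversals.
adjacency_list <- function(net) {
  ids <- net$nodes$identifier
  n <- length(ids)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  if (nrow(net$edges)) {
    i1 <- match(net$edges$node1, ids)
    i2 <- match(net$edges$node2, ids)
    for (e in seq_along(i1)) {
      adj[[i1[e]]] <- c(adj[[i1[e]]], i2[e])
      adj[[i2[e]]] <- c(adj[[i2[e]]], i1[e])
    }
    adj <- lapply(adj, sort)
  }
  names(adj) <- ids
  adj
}

# Internal: BFS hop distances from source index; NA_integer_ = unreachable.
bfs_distances <- function(adj, s) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[s] <- 0L
  queue <- integer(n)
  queue[1L] <- s
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        tail <- tail + 1L
        queue[tail] <- w
      }
    }
  }
  dist
}

# Internal: connected-component labels (integers, 1-based, ordered by
# smallest member index).
component_labels <- function(adj) {
  n <- length(adj)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    reach <- !is.na(bfs_distances(adj, s))
    comp[reach & is.na(comp)] <- k
  }
  comp
}

# ---- I/O ---------------------------------------------------------------

#' Read a STRING-style scored edge list
#'
#' Accepts the tab-separated export dialect of the STRING database: a
#' header row naming at least `node1`, `node2` and `combined_score`
#' (extra columns are ignored). Scores may use either the 0-1 or the
#' integer 0-1000 convention; the latter is normalised by 1000. Duplicate
#' unordered pairs are collapsed keeping the maximum score; self-loop rows
#' are skipped with a warning.
#'
#' @param path path to a TSV file.
#' @param seeds optional character vector marking seed-protein origins.
#' @return a [ppi_network].
#' @export
read_string_tsv <- function(path, seeds = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#")
  need <- c("node1", "node2", "combined_score")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  s <- suppressWarnings(as.numeric(tab$combined_score))
  if (any(is.na(s))) {
    stop(sprintf("unparseable combined_score at line %d",
                 which(is.na(s))[1L] + 1L))
  }
  # 0-1000 integer dialect: integral values with at least one > 1
  if (length(s) && max(s) > 1 && all(abs(s - round(s)) < 1e-9)) {
    s <- s / 1000
  }
  bad <- which(s < 0 | s > 1)
  if (length(bad)) {
    stop(sprintf("combined_score outside [0,1] after normalization at line %d",
                 bad[1L] + 1L))
  }
  ppi_network(data.frame(node1 = tab$node1, node2 = tab$node2,
                         combined_score = s, stringsAsFactors = FALSE),
              seeds = seeds)
}

#' Write a network in the STRING TSV dialect
#'
#' Writes `node1<TAB>node2<TAB>combined_score` with a header row.
#' Isolated nodes are appended as comment lines (`# node <id>`) so that a
#' read/write round trip reproduces the node set as well as the edge set.
#'
#' @param net a [ppi_network].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("node1\tnode2\tcombined_score", con)
  if (nrow(net$edges)) {
    writeLines(sprintf("%s\t%s\t%.17g", net$edges$node1, net$edges$node2,
                       net$edges$combined_score), con)
  }
  for (id in isolated_nodes(net)) writeLines(paste("# node", id), con)
  invisible(path)
}

#' Read a node roster (one identifier per line)
#'
#' Lines starting with `#` and blank lines are skipped; entries are
#' whitespace-trimmed and case-sensitive. Duplicates are removed with a
#' warning.
#'
#' @param path path to a plain-text roster file.
#' @return character vector of identifiers.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stop("empty roster: ", path)
  if (anyDuplicated(x)) {
    warning("duplicate roster entries removed: ",
            paste(unique(x[duplicated(x)]), collapse = ", "))
    x <- unique(x)
  }
  x
}

# ---- filtering and core reduction -------------------------------------

#' Keep only edges at or above a confidence threshold
#'
#' Retains edges with `combined_score >= min_score` (inclusive, so the
#' conventional "very high confidence" level 0.9 keeps a 0.90-scored
#' edge). Nodes isolated by the filter are retained; use
#' [isolated_nodes()] to list them.
#'
#' @param net a [ppi_network].
#' @param min_score confidence threshold in \[0, 1\]; default 0.9.
#' @return filtered [ppi_network] on the same node set.
#' @export
filter_by_confidence <- function(net, min_score = 0.9) {
  stopifnot(inherits(net, "ppi_network"))
  if (!is.numeric(min_score) || length(min_score) != 1L ||
      is.na(min_score) || min_score < 0 || min_score > 1) {
    stop("min_score must be a single value in [0,1]")
  }
  keep <- net$edges$combined_score >= min_score
  out <- net
  out$edges <- net$edges[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  out
}

#' Reduce a network to a connected seed-anchored core
#'
#' Deterministic replacement for the interactive practice of re-running a
#' STRING query at progressively fewer interactors until the graph forms
#' an uninterrupted chain of connections: non-seed nodes are greedily
#' removed in increasing-degree order (ties broken lexicographically by
#' identifier) as long as the remaining induced subgraph stays a single
#' connected component containing every seed, stopping once at most
#' `max_partners` non-seed nodes remain or no further removal preserves
#' connectivity.
#'
#' @param net a [ppi_network] (typically confidence-filtered already).
#' @param seeds character vector of seed identifiers; must all lie in one
#'   connected component of `net`.
#' @param max_partners maximum number of non-seed nodes to retain (>= 0).
#' @return connected [ppi_network] containing every seed.
#' @export
reduce_to_connected_core <- function(net, seeds, max_partners) {
  stopifnot(inherits(net, "ppi_network"))
  seeds <- unique(trimws(seeds))
  if (!length(seeds)) stop("at least one seed required")
  if (!all(seeds %in% net$nodes$identifier)) {
    stop("seeds not in network: ",
         paste(setdiff(seeds, net$nodes$identifier), collapse = ", "))
  }
  if (!is.numeric(max_partners) || max_partners < 0) {
    stop("max_partners must be >= 0")
  }
  ids <- net$nodes$identifier
  adj <- adjacency_list(net)
  comp <- component_labels(adj)
  seed_idx <- match(seeds, ids)
  if (length(unique(comp[seed_idx])) > 1L) {
    main <- as.integer(names(which.max(table(comp[seed_idx]))))
    stop("seeds are not all in one connected component; disconnected: ",
         paste(seeds[comp[seed_idx] != main], collapse = ", "))
  }
  keep <- comp == comp[seed_idx[1L]]   # other components are trivially removable
  is_seed <- seq_along(ids) %in% seed_idx

  connected_with_seeds <- function(keep) {
    sub <- lapply(seq_along(adj), function(i) {
      if (!keep[i]) integer() else adj[[i]][keep[adj[[i]]]]
    })
    d <- bfs_distances(sub, seed_idx[1L])
    all(!is.na(d[keep]))
  }

  repeat {
    partners <- which(keep & !is_seed)
    if (length(partners) <= max_partners) break
    deg <- vapply(partners, function(i) sum(keep[adj[[i]]]), integer(1))
    ord <- partners[order(deg, ids[partners])]
    removed <- FALSE
    for (v in ord) {
      trial <- keep
      trial[v] <- FALSE
      if (connected_with_seeds(trial)) {
        keep <- trial
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  kept_ids <- ids[keep]
  e <- net$edges
  e <- e[e$node1 %in% kept_ids & e$node2 %in% kept_ids, , drop = FALSE]
  ppi_network(e, seeds = seeds, nodes = kept_ids)
}
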
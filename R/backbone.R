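# Hub / bottleneck / backbone / upstream-signal role calls from a
# topology report. Hubs are the top decile by degree, bottlenecks the top
# decile by betweenness; their union forms the network backbone. A
# hub-grade node with peripheral placement (low BC, high Ecc, low CC) is
# flagged as an upstream/early signal instead - the pattern of a protein
# that feeds the backbone rather than belonging to it.

#' Top-fraction nodes of a named value vector
#'
#' Returns the `ceiling(fraction * N)` highest-valued nodes, expanded to
#' include every node tied with the cutoff value. Rounding is upward so
#' that, e.g., the top 10\% of 24 nodes is 3 nodes.
#'
#' @param values named numeric vector (one value per node).
#' @param fraction fraction of nodes to keep, in (0, 1\]; default 0.10.
#' @return character vector of node identifiers (sorted).
#' @export
top_decile <- function(values, fraction = 0.10) {
  if (!length(values)) stop("empty value map")
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("values must be named by node identifier")
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  m <- ceiling(fraction * length(values))
  cutoff <- sort(values, decreasing = TRUE)[m]
  sort(names(values)[values >= cutoff])
}

#' Classify hub, bottleneck, backbone and upstream-signal roles
#'
#' Hubs are the top `fraction` of nodes by degree, bottlenecks the top
#' `fraction` by betweenness (both with tie expansion). The backbone is
#' their union, minus any node flagged as an upstream signal when
#' `exclude_upstream_from_backbone` is `TRUE` (the default): a node can
#' carry hub-grade degree yet sit upstream of the information flow, and
#' such a node is reported as an early activator rather than part of the
#' backbone. Ranks use competition ranking (ties share the better rank).
#'
#' @param report a `topology_report` from [compute_topology()].
#' @param fraction decile fraction; default 0.10.
#' @param exclude_upstream_from_backbone drop upstream-signal nodes from
#'   the backbone set (default `TRUE`).
#' @return object of class `role_assignment`: a data.frame with columns
#'   `identifier`, `k`, `BC`, `Ecc`, `CC`, `rank_k`, `rank_BC`, `is_hub`,
#'   `is_bottleneck`, `is_upstream_signal`, `is_backbone`.
#' @export
classify_roles <- function(report, fraction = 0.10,
                           exclude_upstream_from_backbone = TRUE) {
  stopifnot(inherits(report, "topology_report"))
  pn <- report$per_node
  k <- stats::setNames(as.numeric(pn$k), pn$identifier)
  bc <- stats::setNames(pn$BC, pn$identifier)
  hubs <- top_decile(k, fraction)
  bottlenecks <- top_decile(bc, fraction)
  up <- vapply(pn$identifier, function(id) {
    upstream_signal_flag(report, id, fraction = fraction, hubs = hubs)
  }, logical(1))
  is_hub <- pn$identifier %in% hubs
  is_bot <- pn$identifier %in% bottlenecks
  is_bb <- is_hub | is_bot
  if (exclude_upstream_from_backbone) is_bb <- is_bb & !up
  out <- data.frame(
    identifier = pn$identifier,
    k = pn$k, BC = pn$BC, Ecc = pn$Ecc, CC = pn$CC,
    rank_k = as.integer(rank(-k, ties.method = "min")),
    rank_BC = as.integer(rank(-bc, ties.method = "min")),
    is_hub = is_hub,
    is_bottleneck = is_bot,
    is_upstream_signal = unname(up),
    is_backbone = is_bb,
    stringsAsFactors = FALSE
  )
  class(out) <- c("role_assignment", "data.frame")
  out
}

#' Upstream/early-signal test for a single node
#'
#' `TRUE` when the node carries hub-grade degree (top `fraction` by k) but
#' peripheral information flow: betweenness below the network median,
#' eccentricity strictly above the median, closeness strictly below the
#' median. This is the topological signature of an initiating signal that
#' feeds the backbone from upstream.
#'
#' @param report a `topology_report`.
#' @param node node identifier.
#' @param fraction decile fraction used for the hub-grade criterion.
#' @param hubs optional precomputed hub set (internal use).
#' @return logical flag.
#' @export
upstream_signal_flag <- function(report, node, fraction = 0.10, hubs = NULL) {
  stopifnot(inherits(report, "topology_report"))
  pn <- report$per_node
  i <- match(node, pn$identifier)
  if (is.na(i)) stop("unknown node: ", node)
  if (is.null(hubs)) {
    hubs <- top_decile(stats::setNames(as.numeric(pn$k), pn$identifier),
                       fraction)
  }
  (node %in% hubs) &&
    pn$BC[i] < stats::median(pn$BC) &&
    pn$Ecc[i] > stats::median(pn$Ecc) &&
    pn$CC[i] < stats::median(pn$CC)
}

#' @export
print.role_assignment <- function(x, ...) {
  cat(sprintf("<role_assignment> %d nodes\n", nrow(x)))
  cat("  hubs:        ", paste(x$identifier[x$is_hub], collapse = ", "), "\n")
  cat("  bottlenecks: ", paste(x$identifier[x$is_bottleneck], collapse = ", "), "\n")
  cat("  backbone:    ", paste(x$identifier[x$is_backbone], collapse = ", "), "\n")
  up <- x$identifier[x$is_upstream_signal]
  if (length(up)) cat("  upstream signal:", paste(up, collapse = ", "), "\n")
  invisible(x)
}

#' Write role assignments as CSV plus a JSON role summary
#'
#' @param roles a `role_assignment`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, a list naming the hub/bottleneck/backbone/upstream
#'   sets.
#' @export
write_roles <- function(roles, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(roles, "role_assignment"))
  sets <- list(
    hubs = roles$identifier[roles$is_hub],
    bottlenecks = roles$identifier[roles$is_bottleneck],
    backbone = roles$identifier[roles$is_backbone],
    upstream_signal = roles$identifier[roles$is_upstream_signal]
  )
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(roles), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(sets, json_path, auto_unbox = FALSE)
  }
  invisible(sets)
}
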
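# Seeded generators for offline testing: scored PPI graphs with a planted
# hub (strict maximum degree) and a planted bottleneck (the unique bridge
# node between two blocks, hence the dominant betweenness), culture-image
# fields with known colony ground truth, and normal group data for the
# statistical calibration runs. All generators take an explicit seed and
# restore the caller's RNG state.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a scored PPI graph with planted hub and bottleneck
#'
#' The graph is built from two blocks joined only through a single
#' bottleneck node `X`: every cross-block shortest path runs through `X`,
#' giving it the dominant betweenness by construction. `X` attaches to
#' several nodes spread across each block so that no single neighbour
#' funnels the relayed traffic and `X` stays the strict betweenness
#' maximum. Inside the first block one hub node is wired to every block
#' member (the strict degree maximum); random within-block edges are
#' added, capped below the hub degree, until the requested edge count is
#' reached. Edge scores are drawn uniformly over `score_range`.
#' Deterministic for a fixed seed.
#'
#' @param n_nodes number of nodes (>= 12).
#' @param n_edges number of edges; must be feasible for the construction.
#' @param n_seeds how many nodes to mark as seed proteins.
#' @param score_range length-2 numeric range for combined scores.
#' @param seed RNG seed.
#' @return list with `network` (a [ppi_network]) and `truth` (list:
#'   `hub`, `bottleneck`, `seeds`, `partners`).
#' @export
gen_planted_graph <- function(n_nodes = 24, n_edges = 42, n_seeds = 14,
                              score_range = c(0.9, 1), seed = 0) {
  if (n_nodes < 12) stop("n_nodes must be >= 12 for the planted construction")
  if (n_seeds < 1 || n_seeds > n_nodes) stop("n_seeds must be in 1..n_nodes")
  if (any(score_range < 0) || any(score_range > 1) ||
      score_range[1] > score_range[2]) {
    stop("score_range must be an increasing range within [0,1]")
  }
  w <- max(2L, nchar(as.character(n_nodes)))
  ids <- sprintf(paste0("N%0", w, "d"), seq_len(n_nodes))
  x <- ids[1L]                       # bottleneck bridge
  a <- ceiling((n_nodes - 1) / 2)    # block A size (includes the hub)
  A <- ids[2:(1 + a)]
  B <- ids[(2 + a):n_nodes]
  hub <- A[1L]
  b <- length(B)
  # bridge attachments: spread across each block, total degree kept below
  # the hub degree (a - 1) so the hub stays the strict degree maximum
  k_xa <- max(2L, min(floor(a / 2), a - 4L))
  k_xb <- max(2L, min(floor(b / 3), a - 2L - k_xa))
  xa <- A[-1L][round(seq(1L, a - 1L, length.out = k_xa))]
  xb <- B[round(seq(1L, b, length.out = k_xb))]
  base <- rbind(
    cbind(hub, A[-1L]),                         # hub wired to all of A
    cbind(B[-b], B[-1L]),                       # spanning path through B
    cbind(x, c(xa, xb))                         # bridge attachments
  )
  extra <- n_edges - nrow(base)
  if (extra < 0) {
    stop(sprintf("infeasible edge count: need at least %d edges", nrow(base)))
  }
  with_seed(seed, {
    deg <- stats::setNames(integer(n_nodes), ids)
    for (i in seq_len(nrow(base))) {
      deg[base[i, 1]] <- deg[base[i, 1]] + 1L
      deg[base[i, 2]] <- deg[base[i, 2]] + 1L
    }
    cap <- deg[hub] - 1L               # keep the hub the strict maximum
    cand_a <- if (length(A) > 2) t(utils::combn(A[-1L], 2)) else
      matrix(character(), 0, 2)
    cand_b <- t(utils::combn(B, 2))
    path_key <- paste(pmin(B[-length(B)], B[-1L]),
                      pmax(B[-length(B)], B[-1L]))
    cand_b <- cand_b[!(paste(pmin(cand_b[, 1], cand_b[, 2]),
                             pmax(cand_b[, 1], cand_b[, 2])) %in% path_key), ,
                     drop = FALSE]
    cand <- rbind(cand_a, cand_b)
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
    added <- matrix(character(), 0, 2)
    i <- 1L
    while (extra > 0 && i <= nrow(cand)) {
      u <- cand[i, 1]; v <- cand[i, 2]
      if (deg[u] < cap && deg[v] < cap) {
        added <- rbind(added, c(u, v))
        deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
        extra <- extra - 1L
      }
      i <- i + 1L
    }
    if (extra > 0) stop("infeasible edge count under the hub-degree cap")
    edges <- rbind(base, added)
    scores <- stats::runif(nrow(edges), score_range[1], score_range[2])
    seeds <- sort(sample(ids, n_seeds))
    net <- ppi_network(
      data.frame(node1 = edges[, 1], node2 = edges[, 2],
                 combined_score = scores, stringsAsFactors = FALSE),
      seeds = seeds)
    stopifnot(nrow(net$edges) == n_edges)   # construction never duplicates
    list(network = net,
         truth = list(hub = hub, bottleneck = x, seeds = seeds,
                      partners = setdiff(ids, seeds)))
  })
}

#' Write a generated planted graph as a STRING-dialect TSV fixture
#'
#' The seed is recorded in a leading comment line; [read_string_tsv()]
#' skips comments, so the fixture round-trips.
#'
#' @param path output TSV path.
#' @inheritParams gen_planted_graph
#' @return `path` invisibly, with the generator `truth` attached as
#'   attribute `"truth"`.
#' @export
gen_string_tsv <- function(path, n_nodes = 24, n_edges = 42, n_seeds = 14,
                           score_range = c(0.9, 1), seed = 0) {
  g <- gen_planted_graph(n_nodes, n_edges, n_seeds, score_range, seed)
  tmp <- tempfile()
  write_network(g$network, tmp)
  ok <- file.create(path)
  if (!ok) stop("cannot write: ", path)
  writeLines(c(sprintf("# generator seed: %d", seed), readLines(tmp)), path)
  unlink(tmp)
  invisible(structure(path, truth = g$truth))
}

# Internal: numeric isoperimetric quotient of a polar curve r(theta).
polar_circularity <- function(rfun, ngrid = 4096) {
  th <- seq(0, 2 * pi, length.out = ngrid + 1L)[-1L]
  r <- rfun(th)
  dth <- 2 * pi / ngrid
  area <- sum(r^2) / 2 * dth
  dr <- (rfun(th + 1e-6) - rfun(th - 1e-6)) / 2e-6
  perim <- sum(sqrt(r^2 + dr^2)) * dth
  4 * pi * area / perim^2
}

#' Generate a synthetic culture-image field with colony ground truth
#'
#' Emulates a grayscale micrograph of stromal-cell colonies on a dark
#' background: bright colony regions (dense colonies as near-confluent
#' uniform texture, sparse colonies as a dimmer carpet with resolvable
#' bright nuclei), small bright speckles below any reasonable `min_area`,
#' and Gaussian background noise. The two condition presets differ in
#' colony geometry: `"control"` colonies are larger and more irregular
#' (elongated ellipses and lobed blobs), `"differentiated"` colonies are
#' smaller and rounder, reproducing the direction of the morphometric
#' effect the package is designed to quantify.
#'
#' @param n_colonies colonies to place (non-overlapping by default).
#' @param image_size c(rows, cols) of the field; default 512 x 512.
#' @param condition `"control"` or `"differentiated"`.
#' @param sparse_fraction probability a colony is sparse (countable
#'   nuclei); default 0.5.
#' @param noise_sd background noise standard deviation; default 0.02.
#' @param n_speckles number of 1-4 px bright speckles; default 10.
#' @param allow_overlap allow colonies to overlap (default `FALSE`).
#' @param seed RNG seed.
#' @param field_id label stored in the truth table.
#' @return list with `image` (matrix in \[0,1\]), `truth` (data.frame:
#'   `field_id`, `colony_id`, `cx`, `cy`, `shape`, `area_px`,
#'   `ideal_circularity`, `cell_count`, `nuclei_countable`, `class`,
#'   `condition`, `seed`), and `params`.
#' @export
gen_colony_field <- function(n_colonies = 6, image_size = c(512, 512),
                             condition = c("control", "differentiated"),
                             sparse_fraction = 0.5, noise_sd = 0.02,
                             n_speckles = 10, allow_overlap = FALSE,
                             seed = 0, field_id = NULL) {
  condition <- match.arg(condition)
  nr <- image_size[1]; nc <- image_size[2]
  if (is.null(field_id)) field_id <- sprintf("%s_s%d", condition, seed)
  with_seed(seed, {
    img <- matrix(pmin(abs(stats::rnorm(nr * nc, 0, noise_sd)), 0.25), nr, nc)
    placed <- matrix(numeric(), 0, 3)   # cy, cx, bounding radius
    truth <- list()
    for (i in seq_len(n_colonies)) {
      if (condition == "control") {
        r0 <- stats::runif(1, 18, 32)
        shape <- sample(c("ellipse", "blob"), 1)
        aspect <- stats::runif(1, 1.5, 2.6)
      } else {
        r0 <- stats::runif(1, 9, 18)
        shape <- sample(c("disk", "ellipse"), 1)
        aspect <- stats::runif(1, 1.0, 1.25)
      }
      amp <- stats::runif(1, 0.15, 0.30)
      lobes <- sample(3:6, 1)
      phase <- stats::runif(1, 0, 2 * pi)
      ang <- stats::runif(1, 0, pi)
      rmax <- switch(shape,
                     disk = r0,
                     ellipse = r0 * sqrt(aspect),
                     blob = r0 * (1 + amp))
      ok <- FALSE
      for (attempt in seq_len(1e4)) {
        cy <- stats::runif(1, rmax + 2, nr - rmax - 2)
        cx <- stats::runif(1, rmax + 2, nc - rmax - 2)
        if (allow_overlap || !nrow(placed) ||
            all(sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2) >
                placed[, 3] + rmax + 3)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("cannot place colonies without overlap; reduce n_colonies")
      placed <- rbind(placed, c(cy, cx, rmax))
      # rasterize over the bounding box
      rows <- max(1, floor(cy - rmax - 1)):min(nr, ceiling(cy + rmax + 1))
      cols <- max(1, floor(cx - rmax - 1)):min(nc, ceiling(cx + rmax + 1))
      yy <- outer(rows - cy, rep(1, length(cols)))
      xx <- outer(rep(1, length(rows)), cols - cx)
      if (shape == "disk") {
        inside <- yy^2 + xx^2 <= r0^2
        ideal_circ <- 1
      } else if (shape == "ellipse") {
        rx <- r0 * sqrt(aspect); ry <- r0 / sqrt(aspect)
        u <- xx * cos(ang) + yy * sin(ang)
        v <- -xx * sin(ang) + yy * cos(ang)
        inside <- (u / rx)^2 + (v / ry)^2 <= 1
        h <- ((rx - ry) / (rx + ry))^2
        per <- pi * (rx + ry) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
        ideal_circ <- 4 * pi * (pi * rx * ry) / per^2
      } else {
        th <- atan2(yy, xx)
        rad <- r0 * (1 + amp * cos(lobes * th + phase))
        inside <- yy^2 + xx^2 <= rad^2
        ideal_circ <- polar_circularity(
          function(t) r0 * (1 + amp * cos(lobes * t + phase)))
      }
      sparse <- stats::runif(1) < sparse_fraction
      area_px <- sum(inside)
      if (sparse) {
        cell_count <- sample(15:60, 1)
        patch <- img[rows, cols]
        patch[inside] <- 0.55
        # resolvable nuclei: bright dots at random interior pixels
        pix <- which(inside, arr.ind = TRUE)
        nn <- min(cell_count, nrow(pix))
        sel <- pix[sample.int(nrow(pix), nn), , drop = FALSE]
        patch[sel] <- 0.95
        img[rows, cols] <- patch
      } else {
        cell_count <- sample(60:250, 1)
        patch <- img[rows, cols]
        patch[inside] <- pmin(0.8 + stats::rnorm(sum(inside), 0, 0.03), 1)[
          seq_len(sum(inside))]
        img[rows, cols] <- patch
      }
      truth[[i]] <- data.frame(
        field_id = field_id, colony_id = i, cx = cx, cy = cy, shape = shape,
        area_px = area_px, ideal_circularity = ideal_circ,
        cell_count = cell_count, nuclei_countable = sparse,
        class = classify_colony(cell_count, sparse),
        condition = condition, seed = seed, stringsAsFactors = FALSE)
    }
    # sub-min_area speckles on free background
    spk <- 0L
    for (attempt in seq_len(1e4)) {
      if (spk >= n_speckles) break
      sy <- sample.int(nr - 2L, 1) + 1L
      sx <- sample.int(nc - 2L, 1) + 1L
      if (!nrow(placed) ||
          all(sqrt((placed[, 1] - sy)^2 + (placed[, 2] - sx)^2) >
              placed[, 3] + 6)) {
        sz <- sample.int(4L, 1)
        dy <- c(0L, 1L, 0L, 1L)[seq_len(sz)]
        dx <- c(0L, 0L, 1L, 1L)[seq_len(sz)]
        img[cbind(sy + dy, sx + dx)] <- 0.9
        spk <- spk + 1L
      }
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    list(image = img,
         truth = do.call(rbind, truth),
         params = list(n_colonies = n_colonies, image_size = image_size,
                       condition = condition,
                       sparse_fraction = sparse_fraction,
                       noise_sd = noise_sd, n_speckles = n_speckles,
                       seed = seed, field_id = field_id))
  })
}

#' Generate normal group data for calibration runs
#'
#' @param means group means.
#' @param sds group standard deviations (recycled).
#' @param n per-group sample size (recycled).
#' @param seed RNG seed.
#' @param labels optional group labels.
#' @return named list of numeric vectors.
#' @export
gen_group_data <- function(means, sds = 1, n = 10, seed = 0, labels = NULL) {
  k <- length(means)
  sds <- rep_len(sds, k)
  n <- rep_len(n, k)
  if (is.null(labels)) labels <- paste0("g", seq_len(k))
  with_seed(seed, {
    stats::setNames(
      lapply(seq_len(k), function(i) stats::rnorm(n[i], means[i], sds[i])),
      labels)
  })
}
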
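# End-to-end orchestration: a validated run configuration, the network
# pipeline (read -> confidence filter -> connected core -> topology ->
# roles) and the morphometry pipeline (segment -> measure -> classify ->
# CFE/proportions -> tests), each writing machine-readable reports plus a
# run log. Reports carry the resolved configuration and its MD5 hash and
# contain no timestamps, so a rerun on the same inputs is bit-identical.

#' Build and validate a run configuration
#'
#' Defaults follow the analysis settings the package is built around:
#' confidence threshold 0.9, role decile 0.10, alpha 0.05.
#'
#' @param x a named list of settings, or a path to a YAML or JSON file.
#' @param mode `"network"` or `"morphometry"`.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(x = list(), mode = c("network", "morphometry")) {
  if (is.character(x) && length(x) == 1L) {
    x <- if (grepl("\\.ya?ml$", x)) yaml::read_yaml(x)
         else jsonlite::read_json(x, simplifyVector = TRUE)
  }
  stopifnot(is.list(x))
  if (!is.null(x$mode)) mode <- x$mode
  mode <- match.arg(mode)
  defaults <- list(
    mode = mode,
    min_score = 0.9,
    decile_fraction = 0.10,
    alpha = 0.05,
    max_partners = 10,
    intensity_threshold = 0.3,
    min_area = 50,
    pixel_size = NULL,
    seed = 1
  )
  cfg <- utils::modifyList(defaults, x[setdiff(names(x), "mode")])
  cfg$mode <- mode
  if (cfg$min_score < 0 || cfg$min_score > 1) stop("min_score must be in [0,1]")
  if (cfg$decile_fraction <= 0 || cfg$decile_fraction > 1) {
    stop("decile_fraction must be in (0,1]")
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0,1)")
  for (f in c("edges", "seeds_roster", "partners_roster")) {
    if (!is.null(cfg[[f]]) && is.character(cfg[[f]]) &&
        !file.exists(cfg[[f]])) {
      stop("config path does not exist: ", f, " = ", cfg[[f]])
    }
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

# Internal: write the run log (resolved config + its hash + versions).
write_run_log <- function(cfg, out_dir, stages) {
  cfg_path <- file.path(out_dir, "config.json")
  plain <- unclass(cfg)
  plain <- plain[!vapply(plain, is.null, logical(1))]
  jsonlite::write_json(plain, cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  log <- list(
    package = "osteonet",
    package_version = as.character(utils::packageVersion("osteonet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    stages = stages
  )
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(log)
}

# Internal: run a stage, tagging errors with the stage name; on error the
# caller removes partial outputs.
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the network analysis pipeline
#'
#' Reads a scored edge list and seed/partner rosters, filters edges at the
#' configured confidence, reduces to a connected seed-anchored core,
#' computes all topological indices and classifies hub / bottleneck /
#' backbone / upstream-signal roles. Writes `nodes.csv` (indices + roles),
#' `global.json` (node and edge counts, mean degree, average clustering,
#' role sets), `config.json` and `run_log.json` into `out_dir`. On error,
#' partial outputs are removed.
#'
#' @param config a [run_config()] (or list/path coercible to one) with
#'   entries `edges` (TSV path), `seeds_roster` (roster path), optional
#'   `partners_roster`, `min_score`, `max_partners`, `decile_fraction`,
#'   `out_dir`.
#' @return invisibly, a list with the `topology_report`, the
#'   `role_assignment` and the paths written.
#' @export
run_network_pipeline <- function(config) {
  cfg <- run_config(config, mode = "network")
  if (is.null(cfg$edges) || is.null(cfg$seeds_roster)) {
    stop("network config needs 'edges' and 'seeds_roster'")
  }
  out_dir <- cfg$out_dir %||% stop("config needs 'out_dir'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("nodes.csv", "global.json", "config.json",
                                "run_log.json"))
  on_fail <- function(e) { unlink(paths); stop(e) }
  tryCatch({
    seeds <- run_stage("read_roster", read_roster(cfg$seeds_roster))
    net <- run_stage("read_edges", read_string_tsv(cfg$edges, seeds = seeds))
    net <- run_stage("confidence_filter",
                     filter_by_confidence(net, cfg$min_score))
    core <- run_stage("connected_core",
                      reduce_to_connected_core(net, seeds, cfg$max_partners))
    report <- run_stage("topology", compute_topology(core))
    roles <- run_stage("roles",
                       classify_roles(report, cfg$decile_fraction))
    tab <- merge(report$per_node,
                 as.data.frame(roles)[, c("identifier", "rank_k", "rank_BC",
                                          "is_hub", "is_bottleneck",
                                          "is_upstream_signal",
                                          "is_backbone")],
                 by = "identifier", sort = TRUE)
    utils::write.csv(tab, paths[1], row.names = FALSE)
    jsonlite::write_json(
      list(n_nodes = report$n_nodes, n_edges = report$n_edges,
           mean_degree = report$mean_degree,
           avg_clustering = report$avg_clustering,
           hubs = roles$identifier[roles$is_hub],
           bottlenecks = roles$identifier[roles$is_bottleneck],
           backbone = roles$identifier[roles$is_backbone],
           upstream_signal = roles$identifier[roles$is_upstream_signal]),
      paths[2], auto_unbox = TRUE, digits = NA)
    write_run_log(cfg, out_dir,
                  c("read_roster", "read_edges", "confidence_filter",
                    "connected_core", "topology", "roles"))
    invisible(list(topology = report, roles = roles, paths = paths))
  }, error = on_fail)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the morphometry analysis pipeline
#'
#' Segments and measures colonies in one or more fields, summarises per
#' condition, computes colony-forming efficiency from count tables when
#' supplied, and compares conditions (one-way ANOVA with SNK post hoc on
#' colony area and circularity) when at least two conditions have two or
#' more colonies. Writes `colonies.csv`, `summary.json`, `config.json`
#' and `run_log.json` into `out_dir`.
#'
#' @param config a [run_config()] (list or path) with entries `fields`
#'   (a list of lists, each with `image` — a matrix, or `path` to a
#'   grayscale PNG — plus `condition` and optional `field_id`), optional
#'   `counts` (data.frame: `condition`, `n_colonies`, `n_seeded`),
#'   segmentation settings and `out_dir`.
#' @return invisibly, a list with `colonies` (data.frame), `summary`
#'   (list) and the paths written.
#' @export
run_morphometry_pipeline <- function(config) {
  cfg <- run_config(config, mode = "morphometry")
  if (is.null(cfg$fields) || !length(cfg$fields)) {
    stop("morphometry config needs a non-empty 'fields' list")
  }
  out_dir <- cfg$out_dir %||% stop("config needs 'out_dir'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("colonies.csv", "summary.json",
                                "config.json", "run_log.json"))
  on_fail <- function(e) { unlink(paths); stop(e) }
  tryCatch({
    per_field <- lapply(seq_along(cfg$fields), function(i) {
      f <- cfg$fields[[i]]
      img <- f$image
      if (is.null(img)) {
        if (is.null(f$path)) stop("field ", i, " has neither image nor path")
        img <- run_stage("read_image", read_gray_image(f$path))
      }
      fid <- f$field_id %||% sprintf("field%02d", i)
      tab <- run_stage("segment_measure",
                       analyze_colony_image(img, cfg$intensity_threshold,
                                            cfg$min_area, cfg$pixel_size,
                                            field_id = fid))
      tab$condition <- rep(f$condition %||% "unspecified", nrow(tab))
      tab
    })
    colonies <- do.call(rbind, per_field)
    summary <- list(n_colonies_total = if (is.null(colonies)) 0L
                                       else nrow(colonies))
    if (!is.null(colonies) && nrow(colonies)) {
      by_cond <- split(colonies, colonies$condition)
      summary$conditions <- lapply(by_cond, function(d) {
        list(n_colonies = nrow(d),
             mean_area_px = mean(d$area_px),
             mean_circularity = mean(d$circularity))
      })
      two_plus <- names(by_cond)[vapply(by_cond, nrow, integer(1)) >= 2]
      if (length(two_plus) >= 2) {
        sub <- colonies[colonies$condition %in% two_plus, ]
        for (var in c("area_px", "circularity")) {
          grp <- split(as.numeric(sub[[var]]), sub$condition)
          an <- run_stage("anova", one_way_anova(grp))
          snk <- run_stage("snk", snk_test(grp, alpha = cfg$alpha))
          summary[[paste0("test_", var)]] <- list(
            F = an$F, df_between = an$df_between,
            df_within = an$df_within, p = an$p,
            snk_significant_pairs = if (nrow(snk$pairs))
              paste(snk$pairs$group_lo, snk$pairs$group_hi, sep = " vs ")
              else character())
        }
      }
    } else {
      summary$conditions <- list()
    }
    if (!is.null(cfg$counts)) {
      ct <- as.data.frame(cfg$counts)
      summary$cfe <- stats::setNames(
        as.list(colony_forming_efficiency(ct$n_colonies, ct$n_seeded)),
        ct$condition)
    }
    if (is.null(colonies)) {
      colonies <- analyze_colony_image(matrix(0.0, 2, 2) + 0)  # empty schema
    }
    utils::write.csv(colonies, paths[1], row.names = FALSE)
    jsonlite::write_json(summary, paths[2], auto_unbox = TRUE, digits = NA,
                         force = TRUE)
    write_run_log(cfg, out_dir, c("segment_measure", "summarise", "tests"))
    invisible(list(colonies = colonies, summary = summary, paths = paths))
  }, error = on_fail)
}

#' Read a grayscale image file as an intensity matrix
#'
#' PNG via the `png` package, TIFF via `tiff` when installed; multi-channel
#' images are averaged to grayscale.
#'
#' @param path image path.
#' @return numeric matrix in \[0, 1\].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lower <- tolower(path)
  img <- if (grepl("\\.png$", lower)) {
    if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' needed")
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", lower)) {
    if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' needed")
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format (png/tiff expected): ", path)
  }
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}
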
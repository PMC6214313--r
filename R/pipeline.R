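#' Run configuration for the ranking pipeline
#'
#' Validated container of every knob the pipeline accepts. Unknown fields are
#' rejected so that a typo in a config file fails before any computation.
#'
#' @param graph a [patch_graph()], or a path to an edge-list CSV / GraphML
#'   file (format inferred from the extension)
#' @param layer,sites optional [patch_layer()] / [site_set()] objects or
#'   GeoJSON paths; when `graph` is absent the graph is derived from `layer`
#' @param distances optional named numeric vector or two-column CSV path
#'   (node_id, distance); computed from `layer` + `sites` when those are given
#' @param adjacency_rule `"rook"` or `"queen"` — used when deriving the graph
#'   from polygons
#' @param metric_set metrics summed into the combined score; see
#'   [build_ranking()]
#' @param scope betweenness normalization scope, `"component"` or `"global"`
#' @param digits report rounding digits (display only)
#' @param drop_noise drop cut nodes with second-size 1 before ranking?
#' @param seed integer seed echoed into the run log
#' @param output_dir directory for [write_reports()]
#' @return a `run_config`
#' @export
run_config <- function(graph = NULL, layer = NULL, sites = NULL,
                       distances = NULL, adjacency_rule = "rook",
                       metric_set = c("additional_count", "second_size",
                                      "site_distance"),
                       scope = "component", digits = 2, drop_noise = FALSE,
                       seed = 1L, output_dir = NULL) {
  adjacency_rule <- match.arg(adjacency_rule, c("rook", "queen"))
  scope <- match.arg(scope, c("component", "global"))
  allowed <- c("additional_count", "second_size", "site_distance",
               "betweenness")
  bad <- setdiff(metric_set, allowed)
  if (length(bad) > 0) stop("unknown metric(s) in metric_set: ",
                            paste(bad, collapse = ", "))
  if (is.null(graph) && is.null(layer)) {
    stop("configuration needs a graph or a polygon layer")
  }
  if ("site_distance" %in% metric_set && is.null(distances) &&
      (is.null(layer) || is.null(sites))) {
    stop("metric set includes site_distance but the configuration has ",
         "neither distances nor a layer + site set to derive them from")
  }
  structure(list(graph = graph, layer = layer, sites = sites,
                 distances = distances, adjacency_rule = adjacency_rule,
                 metric_set = metric_set, scope = scope,
                 digits = as.integer(digits), drop_noise = drop_noise,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map one-to-one onto [run_config()] arguments; `graph`,
#' `layer`, `sites` and `distances` are interpreted as file paths. Unknown
#' keys are rejected.
#'
#' @param path YAML file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0) stop("unknown configuration key(s): ",
                            paste(bad, collapse = ", "))
  do.call(run_config, cfg)
}

load_graph_input <- function(x, rule = "rook") {
  if (is_patch_graph(x)) return(x)
  if (is.character(x) && length(x) == 1) {
    if (grepl("\\.graphml$", x, ignore.case = TRUE)) {
      return(read_patch_graphml(x))
    }
    return(read_edge_csv(x))
  }
  stop("cannot interpret graph input")
}

load_layer_input <- function(x, as_sites = FALSE) {
  if (inherits(x, "patch_layer")) {
    if (as_sites && !inherits(x, "site_set")) {
      return(site_set(x$geometry, id = x$id, crs = x$crs))
    }
    return(x)
  }
  if (is.character(x) && length(x) == 1) {
    layer <- read_geojson(x)
    if (as_sites) return(site_set(layer$geometry, id = layer$id,
                                  crs = layer$crs))
    return(layer)
  }
  stop("cannot interpret layer input")
}

load_distance_input <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  if (is.character(x) && length(x) == 1) {
    df <- utils::read.csv(x, stringsAsFactors = FALSE)
    return(setNames(as.numeric(df[[2]]), as.character(df[[1]])))
  }
  stop("distances must be a named numeric vector or a two-column CSV path")
}

#' Run the full cut-node ranking pipeline
#'
#' Executes the five ranking stages: (1) build or load the patch-adjacency
#' graph, (2) identify connected components, (3) find cut nodes and attach
#' site distances, (4) simulate each removal recording the additional
#' component count and second-size, (5) score by strictly-less percentiles
#' and rank by combined score, with normalized betweenness as comparison.
#'
#' @param config a [run_config()] (or YAML path)
#' @return a `corridor_ranking`: list with `graph`, `components`,
#'   `cut_nodes`, `metrics`, `betweenness`, `ranking`, `histograms`,
#'   `correlation`, `config`
#' @export
run_rank <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  layer <- if (!is.null(config$layer)) load_layer_input(config$layer)
  sites <- if (!is.null(config$sites)) load_layer_input(config$sites,
                                                        as_sites = TRUE)
  g <- if (!is.null(config$graph)) {
    load_graph_input(config$graph)
  } else {
    polygons_to_graph(layer, rule = config$adjacency_rule)
  }
  comps <- patch_components(g)
  cut <- find_cut_nodes(g)

  distances <- NULL
  if ("site_distance" %in% config$metric_set) {
    distances <- if (!is.null(config$distances)) {
      load_distance_input(config$distances)
    } else {
      min_site_distance(layer, sites)
    }
  }

  if (length(cut) == 0) {
    warning("no cut nodes found: the network has no critical patches")
    empty <- data.frame(node_id = character(0))
    return(structure(list(graph = g, components = comps,
                          cut_nodes = character(0),
                          metrics = removal_metrics(g, character(0)),
                          betweenness = betweenness_table(g, config$scope),
                          ranking = empty, histograms = list(),
                          correlation = NULL, layer = layer, config = config),
                     class = "corridor_ranking"))
  }

  metrics <- removal_metrics(g, cut)
  btw <- betweenness_table(g, scope = config$scope)
  ranking <- build_ranking(metrics, distances = distances, betweenness = btw,
                           metric_set = config$metric_set,
                           drop_noise = config$drop_noise)
  histograms <- list(
    additional_count = metric_histogram(ranking$additional_count),
    second_size = metric_histogram(ranking$second_size)
  )
  correlation <- if (nrow(ranking) >= 3) {
    correlation_report(ranking$combined, ranking$betweenness)
  }
  structure(list(graph = g, components = comps, cut_nodes = cut,
                 metrics = metrics, betweenness = btw, ranking = ranking,
                 histograms = histograms, correlation = correlation,
                 layer = layer, config = config),
            class = "corridor_ranking")
}

#' @export
print.corridor_ranking <- function(x, ...) {
  cat(sprintf(paste0("<corridor_ranking> %d patches, %d links, ",
                     "%d component(s), %d cut node(s)\n"),
              n_patches(x$graph), n_links(x$graph),
              length(x$components$blocks), length(x$cut_nodes)))
  if (nrow(x$ranking) > 0) {
    cat("top of ranking:\n")
    print(utils::head(format_ranking(x$ranking, x$config$digits), 5))
  }
  invisible(x)
}

format_ranking <- function(ranking, digits = 2) {
  out <- ranking
  num <- vapply(out, is.numeric, logical(1)) &
    !(names(out) %in% c("rank", "betweenness_rank", "additional_count",
                        "second_size", "host_component_size"))
  for (cl in names(out)[num]) out[[cl]] <- round(out[[cl]], digits)
  if ("betweenness" %in% names(out)) {
    out$betweenness <- round(ranking$betweenness, 5)
  }
  out
}

#' Write pipeline reports
#'
#' Emits the ranking table, the per-metric occurrence histograms, the
#' correlation report and a run log with stage counts, all with deterministic
#' column order and rounding so reruns are byte-identical. When the run had a
#' polygon layer, a GeoJSON layer joined with the ranking attributes is also
#' written for map styling.
#'
#' @param result a `corridor_ranking` from [run_rank()]
#' @param dir output directory (created if needed); defaults to the
#'   configuration's `output_dir`
#' @return invisible character vector of written paths
#' @export
write_reports <- function(result, dir = result$config$output_dir) {
  stopifnot(inherits(result, "corridor_ranking"))
  if (is.null(dir)) stop("no output directory configured")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  digits <- result$config$digits
  paths <- character(0)

  p <- file.path(dir, "ranking.csv")
  utils::write.csv(format_ranking(result$ranking, digits), p,
                   row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  for (m in names(result$histograms)) {
    p <- file.path(dir, sprintf("histogram_%s.csv", m))
    h <- result$histograms[[m]]
    h$percentile <- round(h$percentile, 5)
    utils::write.csv(h, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }

  p <- file.path(dir, "correlation.json")
  jsonlite::write_json(
    if (is.null(result$correlation)) {
      list(note = "fewer than 3 cut nodes; correlation undefined")
    } else {
      result$correlation
    },
    p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)

  if (!is.null(result$layer)) {
    p <- file.path(dir, "ranking.geojson")
    write_geojson(result$layer, p,
                  attributes = format_ranking(result$ranking, digits))
    paths <- c(paths, p)
  }

  p <- file.path(dir, "run_log.txt")
  cfg <- result$config
  writeLines(c(
    "corridorcut run log",
    sprintf("nodes: %d", n_patches(result$graph)),
    sprintf("edges: %d", n_links(result$graph)),
    sprintf("components: %d", length(result$components$blocks)),
    sprintf("cut nodes: %d (%.2f%%)", length(result$cut_nodes),
            100 * length(result$cut_nodes) / max(1, n_patches(result$graph))),
    sprintf("ranked: %d", nrow(result$ranking)),
    "config:",
    sprintf("  metric_set: %s", paste(cfg$metric_set, collapse = ", ")),
    sprintf("  adjacency_rule: %s", cfg$adjacency_rule),
    sprintf("  scope: %s", cfg$scope),
    sprintf("  digits: %d", cfg$digits),
    sprintf("  drop_noise: %s", cfg$drop_noise),
    sprintf("  seed: %d", cfg$seed)
  ), p)
  paths <- c(paths, p)
  invisible(paths)
}
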
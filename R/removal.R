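#' Simulate the removal of a single node
#'
#' Deletes one node from its host component (the graph itself is untouched)
#' and records how the component breaks apart. For a cut node the split
#' produces `n >= 2` pieces; the two fragmentation metrics are
#'
#' * **additional component count** `C_A = n - 1`, the number of components
#'   added to the graph total by the removal, and
#' * **second-size** `C_S`, the size of the second-largest piece. `C_S = 1`
#'   means the removal only detaches leaf nodes — in land-cover data these
#'   leaves are usually enclaves (patches surrounded by another patch), so a
#'   second-size of 1 flags a likely noise cut node.
#'
#' @param g a [patch_graph()]
#' @param v a node id present in `g`
#' @return A `split_result`: list with `node_id`, `host_component_size`,
#'   `split_sizes` (descending), `additional_count`, `second_size` (`NA` with
#'   `is_cut = FALSE` for a non-cut node), `is_cut`.
#' @examples
#' g <- patch_graph(data.frame(c("a", "b", "c", "d"), c("b", "c", "d", "e")))
#' simulate_removal(g, "c")
#' @export
simulate_removal <- function(g, v) {
  stopifnot(is_patch_graph(g))
  v <- as.character(v)
  if (!(v %in% igraph::V(g)$name)) stop("node not in graph: ", v)
  comp <- igraph::components(g)
  host <- names(comp$membership)[comp$membership == comp$membership[v]]
  host_size <- length(host)
  rest <- setdiff(host, v)
  if (length(rest) == 0) {
    sizes <- integer(0)
  } else {
    sub <- igraph::induced_subgraph(g, rest)
    sizes <- sort(as.integer(igraph::components(sub)$csize), decreasing = TRUE)
  }
  n <- length(sizes)
  structure(list(
    node_id = v,
    host_component_size = host_size,
    split_sizes = sizes,
    additional_count = max(n - 1L, 0L),
    second_size = if (n >= 2) sizes[2] else NA_integer_,
    is_cut = n >= 2
  ), class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> node %s: host size %d -> pieces [%s], C_A = %d, C_S = %s\n",
              x$node_id, x$host_component_size,
              paste(x$split_sizes, collapse = ", "),
              x$additional_count,
              ifelse(is.na(x$second_size), "NA (not a cut node)",
                     x$second_size)))
  invisible(x)
}

#' Fragmentation metrics for every cut node
#'
#' Runs [simulate_removal()] for each cut node and tabulates the metrics.
#' Non-cut nodes are rejected rather than silently scored, so they can never
#' enter the percentile populations used for ranking.
#'
#' @param g a [patch_graph()]
#' @param cut_nodes ids to analyse; defaults to [find_cut_nodes()]. Must be a
#'   subset of the graph's cut nodes.
#' @return data frame with columns `node_id`, `host_component_size`,
#'   `additional_count`, `second_size`, one row per cut node, sorted by id.
#' @export
removal_metrics <- function(g, cut_nodes = find_cut_nodes(g)) {
  stopifnot(is_patch_graph(g))
  cut_nodes <- sort(as.character(cut_nodes))
  actual <- find_cut_nodes(g)
  extra <- setdiff(cut_nodes, actual)
  if (length(extra) > 0) {
    stop("not cut nodes: ", paste(extra, collapse = ", "))
  }
  rows <- lapply(cut_nodes, function(v) {
    s <- simulate_removal(g, v)
    data.frame(node_id = s$node_id,
               host_component_size = s$host_component_size,
               additional_count = s$additional_count,
               second_size = s$second_size,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    return(data.frame(node_id = character(0),
                      host_component_size = integer(0),
                      additional_count = integer(0),
                      second_size = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Occurrence histogram of a fragmentation metric
#'
#' Tabulates a metric column into the value / occurrences layout used to
#' report the distribution of `C_A` and `C_S` across all cut nodes, plus the
#' strictly-less percentile of each distinct value.
#'
#' @param values integer or numeric metric values over the cut-node population
#' @return data frame with columns `value`, `occurrences`, `percentile`
#' @export
metric_histogram <- function(values) {
  values <- values[!is.na(values)]
  tb <- table(values)
  val <- as.numeric(names(tb))
  occ <- as.integer(tb)
  ord <- order(val)
  val <- val[ord]
  occ <- occ[ord]
  dist <- metric_distribution(histogram = data.frame(value = val,
                                                     occurrences = occ))
  data.frame(value = val, occurrences = occ,
             percentile = vapply(val, function(x) percentile_score(dist, x),
                                 numeric(1)))
}
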
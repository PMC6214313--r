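#' Betweenness centrality with pair-count normalization
#'
#' Computes the unweighted betweenness centrality of every node,
#' \deqn{C_B(v) = \sum_{s \ne v \ne t} \sigma_{st}(v) / \sigma_{st},}
#' where \eqn{\sigma_{st}} counts shortest paths between the unordered pair
#' (s, t) and \eqn{\sigma_{st}(v)} those passing through v, and normalizes it
#' to [0, 1] by the number of node pairs excluding v, \eqn{(N-1)(N-2)/2}.
#'
#' In a corridor network the graph is disconnected by construction (one
#' component per candidate corridor), and no shortest path crosses
#' components, so by default `N` is the size of the node's own connected
#' component: the score then measures how central the patch is within its
#' corridor. `scope = "global"` uses `N = |V|` of the whole graph instead,
#' for sensitivity checks; it deflates every score by a constant factor per
#' component. Nodes in components smaller than 3 have no eligible pair and
#' get a normalized score of 0.
#'
#' @param g a [patch_graph()]
#' @param scope `"component"` (default) or `"global"` — the population whose
#'   pair count divides the raw score
#' @return data frame with columns `node_id`, `raw`, `normalized`,
#'   `component_size`, sorted by `node_id`
#' @examples
#' betweenness_table(patch_graph(data.frame(c("a", "b"), c("b", "c"))))
#' @export
betweenness_table <- function(g, scope = c("component", "global")) {
  stopifnot(is_patch_graph(g))
  scope <- match.arg(scope)
  ids <- igraph::V(g)$name
  raw <- igraph::betweenness(g, directed = FALSE, weights = NULL,
                             normalized = FALSE)
  comp <- igraph::components(g)
  csize <- as.integer(comp$csize[comp$membership])
  n_pop <- if (scope == "global") rep(igraph::vcount(g), length(ids)) else csize
  denom <- (n_pop - 1) * (n_pop - 2) / 2
  normalized <- ifelse(n_pop >= 3, as.numeric(raw) / denom, 0)
  out <- data.frame(node_id = ids, raw = as.numeric(raw),
                    normalized = normalized, component_size = csize,
                    stringsAsFactors = FALSE)
  out <- out[order(out$node_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
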
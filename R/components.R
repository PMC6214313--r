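#' Connected components of a patch graph
#'
#' Partitions the patch graph into connected components. Blocks are returned
#' in descending size order, ties broken by the smallest contained id, and the
#' ids inside each block are sorted — the partition is therefore a pure
#' function of the graph, not of input order.
#'
#' @param g a [patch_graph()]
#' @return A `component_partition`: list with `blocks` (list of sorted
#'   character id vectors), `sizes` (integer), and `membership` (named integer
#'   vector, block index per node).
#' @examples
#' g <- patch_graph(data.frame(c("a", "b"), c("b", "c")),
#'                  nodes = data.frame(id = c("a", "b", "c", "d")))
#' patch_components(g)$sizes
#' @export
patch_components <- function(g) {
  stopifnot(is_patch_graph(g))
  comp <- igraph::components(g)
  ids <- igraph::V(g)$name
  blocks <- split(ids, comp$membership)
  blocks <- lapply(blocks, sort)
  sizes <- vapply(blocks, length, integer(1))
  first_id <- vapply(blocks, function(b) b[1], character(1))
  ord <- order(-sizes, first_id)
  blocks <- unname(blocks[ord])
  sizes <- unname(sizes[ord])
  membership <- integer(length(ids))
  names(membership) <- ids
  for (k in seq_along(blocks)) membership[blocks[[k]]] <- k
  structure(list(blocks = blocks, sizes = sizes, membership = membership),
            class = "component_partition")
}

#' @export
print.component_partition <- function(x, ...) {
  cat(sprintf("<component_partition> %d block(s); sizes: %s\n",
              length(x$blocks),
              paste(utils::head(x$sizes, 20), collapse = ", ")))
  invisible(x)
}

#' Find cut nodes (articulation points)
#'
#' A cut node is a node whose removal splits its connected component into two
#' or more smaller components. Cut nodes are where a corridor network is
#' vulnerable: losing the corresponding habitat patch interrupts every
#' migration path that crossed it.
#'
#' @param g a [patch_graph()]
#' @return sorted character vector of cut-node ids (possibly empty)
#' @examples
#' find_cut_nodes(patch_graph(data.frame(c("a", "b"), c("b", "c"))))
#' @export
find_cut_nodes <- function(g) {
  stopifnot(is_patch_graph(g))
  ap <- igraph::articulation_points(g)
  sort(as.character(ap$name))
}
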
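#' Build a patch-adjacency graph
#'
#' Constructs an undirected simple graph in which each node is a homogeneous
#' land patch and each edge records spatial adjacency between two patches.
#' Duplicate edges (in either orientation) are collapsed, node ids are stored
#' as character strings, and the internal vertex order is sorted by id so that
#' all downstream outputs are reproducible regardless of input order.
#'
#' @param edges two-column data frame, matrix, or list of length-2 vectors
#'   giving the adjacent id pairs. May be empty.
#' @param nodes optional data frame of node attributes; the first column (or a
#'   column named `id`) holds the node id. Declares isolated nodes and carries
#'   per-patch attributes such as land-use codes or site distances.
#' @return A `patch_graph` object (an [igraph::graph] with sorted named
#'   vertices, class `c("patch_graph", "igraph")`).
#' @examples
#' g <- patch_graph(data.frame(from = c("a", "b"), to = c("b", "c")))
#' n_patches(g)
#' @export
patch_graph <- function(edges = NULL, nodes = NULL) {
  ed <- normalize_edges(edges)
  node_df <- NULL
  if (!is.null(nodes)) {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
    id_col <- if ("id" %in% names(nodes)) "id" else names(nodes)[1]
    ids <- as.character(nodes[[id_col]])
    if (anyDuplicated(ids)) {
      stop("duplicate node ids in node records: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    missing <- setdiff(unique(c(ed$from, ed$to)), ids)
    if (length(missing) > 0) {
      stop("edge endpoints not declared as nodes: ",
           paste(sort(missing), collapse = ", "))
    }
    node_df <- data.frame(name = ids, stringsAsFactors = FALSE)
    extra <- setdiff(names(nodes), id_col)
    for (cl in extra) node_df[[cl]] <- nodes[[cl]]
    node_df <- node_df[order(node_df$name), , drop = FALSE]
  } else {
    ids <- sort(unique(c(ed$from, ed$to)))
    node_df <- data.frame(name = ids, stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = node_df)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
  class(g) <- unique(c("patch_graph", class(g)))
  g
}

# Coerce edge input to a deduplicated two-column character data frame,
# rejecting self-loops with the offending id.
normalize_edges <- function(edges) {
  if (is.null(edges) || (is.data.frame(edges) && nrow(edges) == 0) ||
      (is.matrix(edges) && nrow(edges) == 0) || length(edges) == 0) {
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) {
      if (length(e) != 2) stop("malformed edge record: ", deparse(e))
      as.character(e)
    }))
  }
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2) stop("edge records need two id columns")
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  bad <- is.na(from) | is.na(to) | from == "" | to == ""
  if (any(bad)) {
    stop("malformed edge record at line ", which(bad)[1])
  }
  loops <- from == to
  if (any(loops)) {
    stop("self-loop edge on node: ",
         paste(unique(from[loops]), collapse = ", "))
  }
  a <- pmin(from, to)
  b <- pmax(from, to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE)
}

#' @rdname patch_graph
#' @param g a `patch_graph`
#' @export
n_patches <- function(g) igraph::vcount(g)

#' @rdname patch_graph
#' @export
n_links <- function(g) igraph::ecount(g)

#' @rdname patch_graph
#' @export
node_ids <- function(g) igraph::V(g)$name

#' Test whether an object is a patch graph
#' @param x an object
#' @return logical
#' @export
is_patch_graph <- function(x) inherits(x, "patch_graph") && inherits(x, "igraph")

#' @export
print.patch_graph <- function(x, ...) {
  comp <- igraph::components(x)
  cat(sprintf("<patch_graph> %d patches, %d adjacency links, %d component(s)\n",
              igraph::vcount(x), igraph::ecount(x), comp$no))
  invisible(x)
}

#' Read and write patch graphs
#'
#' `read_edge_csv()` reads a two-column edge list (optional header, extra
#' columns ignored); `write_edge_csv()` writes the canonical sorted edge list.
#' `read_patch_graphml()` / `write_patch_graphml()` exchange GraphML through
#' igraph.
#'
#' @param path file path
#' @param header does the CSV carry a header row? Default `TRUE`.
#' @return a `patch_graph` (readers) or the path, invisibly (writers).
#' @export
read_edge_csv <- function(path, header = TRUE) {
  df <- utils::read.csv(path, header = header, colClasses = "character",
                        strip.white = TRUE)
  patch_graph(df[, 1:2])
}

#' @rdname read_edge_csv
#' @param g a `patch_graph`
#' @export
write_edge_csv <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) > 0) {
    a <- pmin(el[, 1], el[, 2])
    b <- pmax(el[, 1], el[, 2])
    el <- cbind(a, b)[order(a, b), , drop = FALSE]
  }
  df <- data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_edge_csv
#' @export
read_patch_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  ids <- if ("name" %in% igraph::vertex_attr_names(g)) {
    igraph::V(g)$name
  } else {
    as.character(seq_len(igraph::vcount(g)))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  patch_graph(data.frame(from = ids[el[, 1]], to = ids[el[, 2]],
                         stringsAsFactors = FALSE),
              nodes = data.frame(id = ids, stringsAsFactors = FALSE))
}

#' @rdname read_edge_csv
#' @export
write_patch_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
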
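#' Specification of a synthetic corridor landscape
#'
#' Parameters of the seeded generator that emulates the topology of
#' corridor-network graphs: each connected component is a chain of corridor
#' patches (the backbone) linking an anchor clique at either end (the patches
#' bordering a protected site, internally well-connected and therefore
#' biconnected), decorated with leaf "enclave" nodes and, optionally, a
#' redundant cycle-forming edge.
#'
#' @param n_components number of components to generate
#' @param backbone_length corridor chain length per component (>= 1)
#' @param cluster_size anchor clique size; 0 (no anchors) or >= 3, so that an
#'   anchor minus its junction stays connected
#' @param enclave_prob probability that a backbone patch carries one enclave
#'   leaf
#' @param redundancy_prob probability that a component receives a redundant
#'   edge closing the backbone into a cycle
#' @param seed integer seed; the same spec and seed always reproduce the same
#'   landscape
#' @return a validated `synthetic_spec`
#' @export
synthetic_spec <- function(n_components = 3, backbone_length = 8,
                           cluster_size = 3, enclave_prob = 0.25,
                           redundancy_prob = 0, seed = 1) {
  stopifnot(n_components >= 1, backbone_length >= 1,
            cluster_size == 0 || cluster_size >= 3,
            enclave_prob >= 0, enclave_prob <= 1,
            redundancy_prob >= 0, redundancy_prob <= 1)
  structure(list(n_components = as.integer(n_components),
                 backbone_length = as.integer(backbone_length),
                 cluster_size = as.integer(cluster_size),
                 enclave_prob = enclave_prob,
                 redundancy_prob = redundancy_prob,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_spec_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a corridor-like graph with ground truth
#'
#' Builds the graph described by a [synthetic_spec()] and, alongside it, the
#' exact set of cut nodes with their expected fragmentation metrics, derived
#' from the construction itself (no graph algorithm involved): with no
#' redundant edge, every backbone patch and both anchor junctions are cut
#' nodes; a redundant edge turns the backbone into a cycle so that only
#' junctions and enclave hosts remain cut; each enclave leaf adds a size-1
#' piece to its host's split. Enclaves hosted by non-junction clique members
#' detach nothing else, so those hosts carry the noise signature `C_S = 1`.
#'
#' @param spec a [synthetic_spec()]
#' @return list with `graph` (a [patch_graph()]) and `truth` (list:
#'   `cut_nodes` data frame with node_id / additional_count / second_size /
#'   component, `shortcut` logical per component)
#' @export
generate_corridor_graph <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_spec_seed(spec$seed, {
    from <- character(0); to <- character(0)
    nodes <- character(0)
    truth <- list()
    shortcut_flags <- logical(spec$n_components)
    for (ci in seq_len(spec$n_components)) {
      p <- sprintf("c%02d", ci)
      L <- spec$backbone_length
      cs <- spec$cluster_size
      bb <- sprintf("%s_b%03d", p, seq_len(L))
      leaves <- stats::rbinom(L, 1L, spec$enclave_prob)
      # enclaves also occur inside the anchor areas, where the surrounding
      # patch does not separate the corridor: one leaf per non-junction
      # clique member with the same probability
      aleaves1 <- if (cs > 1) stats::rbinom(cs - 1L, 1L, spec$enclave_prob)
                  else integer(0)
      aleaves2 <- if (cs > 1) stats::rbinom(cs - 1L, 1L, spec$enclave_prob)
                  else integer(0)
      shortcut <- stats::runif(1) < spec$redundancy_prob
      # a 2-node ring is a duplicate edge; keep the graph simple
      if (cs == 0 && L < 3) shortcut <- FALSE
      shortcut_flags[ci] <- shortcut

      nodes <- c(nodes, bb)
      if (L >= 2) {
        from <- c(from, bb[-L]); to <- c(to, bb[-1])
      }
      j1 <- j2 <- NULL
      if (cs > 0) {
        a1 <- sprintf("%s_s1n%02d", p, seq_len(cs))
        a2 <- sprintf("%s_s2n%02d", p, seq_len(cs))
        nodes <- c(nodes, a1, a2)
        for (anc in list(a1, a2)) {
          pr <- utils::combn(anc, 2)
          from <- c(from, pr[1, ]); to <- c(to, pr[2, ])
        }
        j1 <- a1[1]; j2 <- a2[1]
        from <- c(from, j1, bb[L]); to <- c(to, bb[1], j2)
        for (side in 1:2) {
          members <- (if (side == 1) a1 else a2)[-1]
          flags <- if (side == 1) aleaves1 else aleaves2
          for (k in seq_along(members)) {
            if (flags[k] == 1) {
              lid <- sprintf("%s_e%s", members[k], "a")
              nodes <- c(nodes, lid)
              from <- c(from, members[k]); to <- c(to, lid)
            }
          }
        }
      }
      leaf_ids <- character(L)
      for (k in seq_len(L)) {
        if (leaves[k] == 1) {
          leaf_ids[k] <- sprintf("%s_e%03d", p, k)
          nodes <- c(nodes, leaf_ids[k])
          from <- c(from, bb[k]); to <- c(to, leaf_ids[k])
        }
      }
      if (shortcut) {
        if (cs > 0) {
          from <- c(from, j1); to <- c(to, j2)
        } else {
          from <- c(from, bb[1]); to <- c(to, bb[L])
        }
      }

      la1 <- sum(aleaves1); la2 <- sum(aleaves2)
      total <- 2 * cs + L + sum(leaves) + la1 + la2
      add_truth <- function(id, pieces) {
        pieces <- sort(pieces[pieces > 0], decreasing = TRUE)
        if (length(pieces) < 2) return(NULL)
        data.frame(node_id = id, additional_count = length(pieces) - 1L,
                   second_size = pieces[2], component = ci,
                   stringsAsFactors = FALSE)
      }
      rows <- list()
      if (cs > 0) {
        # junction split: clique remainder (with its enclaves) vs the rest
        rows <- c(rows, list(
          add_truth(j1, c(cs - 1L + la1, total - cs - la1)),
          add_truth(j2, c(cs - 1L + la2, total - cs - la2))))
        # a clique member hosting an enclave detaches only that leaf
        for (side in 1:2) {
          members <- (if (side == 1) a1 else a2)[-1]
          flags <- if (side == 1) aleaves1 else aleaves2
          for (k in seq_along(members)) {
            if (flags[k] == 1) {
              rows <- c(rows, list(add_truth(members[k], c(total - 2L, 1L))))
            }
          }
        }
      }
      for (k in seq_len(L)) {
        pieces <- if (shortcut) {
          c(total - 1L - leaves[k], rep(1L, leaves[k]))
        } else {
          left <- cs + la1 + (k - 1L) + sum(leaves[seq_len(k - 1)])
          right <- cs + la2 + (L - k) +
            if (k < L) sum(leaves[(k + 1):L]) else 0L
          c(left, right, rep(1L, leaves[k]))
        }
        rows <- c(rows, list(add_truth(bb[k], pieces)))
      }
      truth <- c(truth, rows)
    }
    truth <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
    if (is.null(truth)) {
      truth <- data.frame(node_id = character(0),
                          additional_count = integer(0),
                          second_size = integer(0), component = integer(0),
                          stringsAsFactors = FALSE)
    }
    truth <- truth[order(truth$node_id), , drop = FALSE]
    rownames(truth) <- NULL
    g <- patch_graph(data.frame(from = from, to = to,
                                stringsAsFactors = FALSE),
                     nodes = data.frame(id = nodes, stringsAsFactors = FALSE))
    list(graph = g, truth = list(cut_nodes = truth,
                                 shortcut = shortcut_flags, spec = spec))
  })
}

#' Generate a toy grid landscape with sites and exact ground truth
#'
#' Produces unit-square patches between two rectangular protected sites, plus
#' the rook adjacency and boundary distances known exactly from construction,
#' so the spatial adapter can be validated end to end.
#'
#' In strip mode (default) the landscape is a 1-cell-wide corridor of
#' `backbone_length` squares whose ends touch the sites. With `rows` and
#' `cols` given, a rows x cols grid is generated and each cell is kept with
#' probability `keep_prob` (seeded); sites span the full grid height at both
#' vertical edges.
#'
#' @param spec a [synthetic_spec()] (supplies length and seed)
#' @param rows,cols optional grid dimensions (grid mode)
#' @param keep_prob cell retention probability in grid mode
#' @return list with `layer` ([patch_layer()]), `sites` ([site_set()]) and
#'   `truth` (list: `adjacency` data frame, `distances` named vector, and in
#'   strip mode `cut_nodes`)
#' @export
generate_grid_landscape <- function(spec, rows = NULL, cols = NULL,
                                    keep_prob = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_spec_seed(spec$seed, {
    if (is.null(rows) != is.null(cols)) stop("give both rows and cols, or neither")
    if (is.null(rows)) {
      L <- spec$backbone_length
      ids <- sprintf("p%03d", seq_len(L))
      geoms <- lapply(seq_len(L), function(i) rect_ring(i - 1, 0, i, 1))
      sites <- site_set(list(rect_ring(-2, -0.5, 0, 1.5),
                             rect_ring(L, -0.5, L + 2, 1.5)),
                        id = c("siteA", "siteB"))
      adjacency <- if (L >= 2) {
        data.frame(from = ids[-L], to = ids[-1], stringsAsFactors = FALSE)
      } else {
        data.frame(from = character(0), to = character(0))
      }
      distances <- setNames(pmin(seq_len(L) - 1, L - seq_len(L)), ids)
      cut <- if (L >= 3) {
        k <- 2:(L - 1)
        data.frame(node_id = ids[k], additional_count = 1L,
                   second_size = pmin(k - 1L, L - k),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(node_id = character(0), additional_count = integer(0),
                   second_size = integer(0), stringsAsFactors = FALSE)
      }
      layer <- patch_layer(geoms, id = ids)
      return(list(layer = layer, sites = sites,
                  truth = list(adjacency = adjacency, distances = distances,
                               cut_nodes = cut)))
    }
    stopifnot(rows >= 1, cols >= 1, keep_prob > 0, keep_prob <= 1)
    cells <- expand.grid(r = seq_len(rows), c = seq_len(cols))
    keep <- stats::runif(nrow(cells)) < keep_prob
    cells <- cells[keep, , drop = FALSE]
    if (nrow(cells) == 0) cells <- data.frame(r = 1L, c = 1L)
    ids <- sprintf("r%02dc%02d", cells$r, cells$c)
    geoms <- lapply(seq_len(nrow(cells)), function(i) {
      rect_ring(cells$c[i] - 1, cells$r[i] - 1, cells$c[i], cells$r[i])
    })
    key <- paste(cells$r, cells$c)
    from <- character(0); to <- character(0)
    for (i in seq_len(nrow(cells))) {
      for (d in list(c(0, 1), c(1, 0))) {
        nb <- paste(cells$r[i] + d[1], cells$c[i] + d[2])
        j <- match(nb, key)
        if (!is.na(j)) {
          from <- c(from, ids[i]); to <- c(to, ids[j])
        }
      }
    }
    sites <- site_set(list(rect_ring(-2, 0, 0, rows),
                           rect_ring(cols, 0, cols + 2, rows)),
                      id = c("siteA", "siteB"))
    distances <- setNames(pmin(cells$c - 1, cols - cells$c), ids)
    list(layer = patch_layer(geoms, id = ids), sites = sites,
         truth = list(adjacency = data.frame(from = from, to = to,
                                             stringsAsFactors = FALSE),
                      distances = distances))
  })
}
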
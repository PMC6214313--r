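# Independent oracles, written against plain adjacency lists so they share no
# code path with the package (which delegates graph algorithms to igraph).

oracle_adj <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# Flood-fill component labelling.
oracle_components <- function(nodes, edges) {
  adj <- oracle_adj(nodes, edges)
  label <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cur <- 0L
  for (v in nodes) {
    if (!is.na(label[v])) next
    cur <- cur + 1L
    queue <- v
    label[v] <- cur
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (w in adj[[u]]) {
        if (is.na(label[w])) {
          label[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  label
}

oracle_n_components <- function(nodes, edges) {
  if (length(nodes) == 0) return(0L)
  max(oracle_components(nodes, edges))
}

# Delete-each-node-and-recount articulation oracle: v is a cut node iff the
# component count among the remaining nodes exceeds the original count.
oracle_cut_nodes <- function(nodes, edges) {
  base <- oracle_n_components(nodes, edges)
  cut <- character(0)
  for (v in nodes) {
    rest <- setdiff(nodes, v)
    keep <- edges[edges[, 1] != v & edges[, 2] != v, , drop = FALSE]
    if (oracle_n_components(rest, keep) > base) cut <- c(cut, v)
  }
  sort(cut)
}

oracle_bfs_dist <- function(adj, src, nodes) {
  d <- setNames(rep(Inf, length(nodes)), nodes)
  d[src] <- 0
  queue <- src
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    for (w in adj[[u]]) {
      if (is.infinite(d[w])) {
        d[w] <- d[u] + 1
        queue <- c(queue, w)
      }
    }
  }
  d
}

# Shortest-path counts by dynamic programming over BFS layers.
oracle_sigma <- function(adj, src, nodes, d) {
  sigma <- setNames(rep(0, length(nodes)), nodes)
  sigma[src] <- 1
  finite <- nodes[is.finite(d)]
  for (u in finite[order(d[finite])]) {
    if (u == src) next
    preds <- adj[[u]][d[adj[[u]]] == d[u] - 1]
    sigma[u] <- sum(sigma[preds])
  }
  sigma
}

# Raw betweenness from the pair-sum definition: for every unordered pair
# (s, t) with s != v != t, add sigma_sv * sigma_vt / sigma_st when v lies on
# a shortest s-t path.
oracle_betweenness <- function(nodes, edges) {
  adj <- oracle_adj(nodes, edges)
  dmat <- lapply(setNames(nodes, nodes), function(s)
    oracle_bfs_dist(adj, s, nodes))
  smat <- lapply(setNames(nodes, nodes), function(s)
    oracle_sigma(adj, s, nodes, dmat[[s]]))
  btw <- setNames(rep(0, length(nodes)), nodes)
  n <- length(nodes)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      s <- nodes[i]; t <- nodes[j]
      if (is.infinite(dmat[[s]][t])) next
      for (v in nodes) {
        if (v == s || v == t) next
        if (dmat[[s]][v] + dmat[[v]][t] == dmat[[s]][t]) {
          btw[v] <- btw[v] + smat[[s]][v] * smat[[v]][t] / smat[[s]][t]
        }
      }
    }
  }
  btw
}

# Uniform random simple graph as a plain edge data frame.
random_edge_df <- function(n, m, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  all_pairs <- t(utils::combn(ids, 2))
  pick <- sample(nrow(all_pairs), min(m, nrow(all_pairs)))
  data.frame(from = all_pairs[pick, 1], to = all_pairs[pick, 2],
             stringsAsFactors = FALSE)
}

random_patch_graph <- function(n, m, seed) {
  ed <- random_edge_df(n, m, seed)
  patch_graph(ed, nodes = data.frame(id = sprintf("n%02d", seq_len(n))))
}

# Textbook product-moment correlation.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
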
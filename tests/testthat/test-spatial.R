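sq <- function(x, y, s = 1) rect_ring(x, y, x + s, y + s)

test_that("overlay intersection clips cells against land cover", {
  cells <- patch_layer(list(sq(0, 0)), id = "cell1")
  lc <- patch_layer(list(sq(0, 0)), id = "lc1", land_use = "forest")
  out <- overlay_intersection(cells, lc)
  expect_equal(length(out), 1)
  expect_equal(poly_area(out$geometry[[1]]), 1)
  expect_equal(out$land_use, "forest")

  # cell straddling two land-cover halves splits into two pieces
  lc2 <- patch_layer(list(rect_ring(0, 0, 0.5, 1), rect_ring(0.5, 0, 1, 1)),
                     id = c("w", "e"), land_use = c("forest", "scrub"))
  out2 <- overlay_intersection(cells, lc2)
  expect_equal(length(out2), 2)
  expect_equal(sort(vapply(out2$geometry, poly_area, numeric(1))),
               c(0.5, 0.5))
  expect_setequal(out2$land_use, c("forest", "scrub"))
  expect_equal(out2$id, c("1", "2"))

  # disjoint layers intersect to an empty (valid) layer
  far <- patch_layer(list(sq(10, 10)), id = "far")
  expect_equal(length(overlay_intersection(cells, far)), 0)
})

test_that("overlay area equals the analytic rectangle-overlap oracle", {
  set.seed(8)
  rect_df <- function(n) {
    data.frame(x = runif(n, 0, 10), y = runif(n, 0, 10),
               w = runif(n, 0.5, 3), h = runif(n, 0.5, 3))
  }
  a <- rect_df(6); b <- rect_df(5)
  cells <- patch_layer(lapply(seq_len(6), function(i)
    rect_ring(a$x[i], a$y[i], a$x[i] + a$w[i], a$y[i] + a$h[i])))
  lc <- patch_layer(lapply(seq_len(5), function(i)
    rect_ring(b$x[i], b$y[i], b$x[i] + b$w[i], b$y[i] + b$h[i])))
  out <- overlay_intersection(cells, lc)
  oracle <- 0
  for (i in 1:6) {
    for (j in 1:5) {
      ox <- max(0, min(a$x[i] + a$w[i], b$x[j] + b$w[j]) - max(a$x[i], b$x[j]))
      oy <- max(0, min(a$y[i] + a$h[i], b$y[j] + b$h[j]) - max(a$y[i], b$y[j]))
      oracle <- oracle + ox * oy
    }
  }
  expect_equal(sum(vapply(out$geometry, poly_area, numeric(1))), oracle,
               tolerance = 1e-9)
})

test_that("CRS mismatch and invalid geometry are rejected", {
  a <- patch_layer(list(sq(0, 0)), crs = "EPSG:32632")
  b <- patch_layer(list(sq(0, 0)), crs = "EPSG:4326")
  expect_error(overlay_intersection(a, b), "EPSG:32632.*EPSG:4326")
  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(patch_layer(list(bowtie), id = "bt"), "invalid geometry.*bt")
})

test_that("rook and queen contiguity on unit grids", {
  grid22 <- patch_layer(list(sq(0, 0), sq(1, 0), sq(0, 1), sq(1, 1)),
                        id = c("sw", "se", "nw", "ne"))
  rook <- polygons_to_graph(grid22, rule = "rook")
  expect_equal(n_links(rook), 4)
  queen <- polygons_to_graph(grid22, rule = "queen")
  expect_equal(n_links(queen), 6)

  # 5x5 grid with centre removed: hand-enumerated rook adjacency
  cells <- expand.grid(cx = 0:4, cy = 0:4)
  cells <- cells[!(cells$cx == 2 & cells$cy == 2), ]
  ids <- sprintf("c%d_%d", cells$cx, cells$cy)
  layer <- patch_layer(lapply(seq_len(nrow(cells)), function(i)
    sq(cells$cx[i], cells$cy[i])), id = ids)
  g <- polygons_to_graph(layer, rule = "rook")
  expected <- 0
  for (i in seq_len(nrow(cells))) {
    for (j in seq_len(nrow(cells))) {
      if (j <= i) next
      dx <- abs(cells$cx[i] - cells$cx[j])
      dy <- abs(cells$cy[i] - cells$cy[j])
      if (dx + dy == 1) expected <- expected + 1
    }
  }
  expect_equal(n_links(g), expected)
  # queen adds the diagonal contacts, a superset of rook
  gq <- polygons_to_graph(layer, rule = "queen")
  rook_edges <- apply(igraph::as_edgelist(g), 1, paste, collapse = "|")
  queen_edges <- apply(igraph::as_edgelist(gq), 1, paste, collapse = "|")
  expect_true(all(rook_edges %in% queen_edges))
})

test_that("minimum site distance is boundary-to-boundary with zero on contact", {
  sites <- site_set(list(rect_ring(0, 0, 1, 1)), id = "s1")
  inside <- patch_layer(list(rect_ring(0.25, 0.25, 0.75, 0.75)), id = "in")
  expect_equal(unname(min_site_distance(inside, sites)), 0)

  apart <- patch_layer(list(rect_ring(2, 0, 3, 1)), id = "p")
  expect_equal(unname(min_site_distance(apart, sites)), 1)

  expect_error(min_site_distance(apart, site_set(list())), "empty site set")

  # diagonal offset: corner-to-corner distance
  diag <- patch_layer(list(rect_ring(2, 2, 3, 3)), id = "d")
  expect_equal(unname(min_site_distance(diag, sites)), sqrt(2))
})

test_that("boundary distance agrees with a dense boundary-sampling oracle", {
  set.seed(14)
  sample_boundary <- function(p, k = 400) {
    pc <- close_ring(p)
    pts <- NULL
    for (i in seq_len(nrow(pc) - 1)) {
      t <- seq(0, 1, length.out = k)
      pts <- rbind(pts, cbind(pc[i, 1] + t * (pc[i + 1, 1] - pc[i, 1]),
                              pc[i, 2] + t * (pc[i + 1, 2] - pc[i, 2])))
    }
    pts
  }
  for (rep in 1:5) {
    a <- rect_ring(runif(1, 0, 3), runif(1, 0, 3),
                   runif(1, 4, 6), runif(1, 4, 6))
    b <- rect_ring(runif(1, 7, 9), runif(1, 0, 3),
                   runif(1, 10, 12), runif(1, 4, 6))
    pa <- sample_boundary(a); pb <- sample_boundary(b)
    oracle <- min(sqrt(outer(pa[, 1], pb[, 1], "-")^2 +
                         outer(pa[, 2], pb[, 2], "-")^2))
    layer <- patch_layer(list(a), id = "a")
    sites <- site_set(list(b), id = "b")
    expect_equal(unname(min_site_distance(layer, sites)), oracle,
                 tolerance = 1e-3)
  }
})

test_that("GeoJSON round-trips a layer with attributes", {
  layer <- patch_layer(list(sq(0, 0), sq(1, 0)), id = c("p1", "p2"),
                       land_use = c("forest", "scrub"))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(layer, path,
                attributes = data.frame(id = c("p1", "p2"),
                                        combined = c(10.5, 0)))
  back <- read_geojson(path)
  expect_equal(back$id, layer$id)
  expect_equal(back$land_use, layer$land_use)
  expect_equal(vapply(back$geometry, poly_area, numeric(1)), c(1, 1))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(doc$features[[1]]$properties$combined, 10.5)
})
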
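#' Patch layer: polygons with attributes
#'
#' A lightweight vector layer on projected planar coordinates: one exterior
#' ring per feature, with a unique id and an optional land-use code. Every
#' geometry goes through a repair pass (duplicate-vertex removal) and a
#' validity check (non-self-intersecting ring with positive area) at
#' construction; invalid features are reported by id.
#'
#' @param geometry list of coordinate matrices (columns x, y; one exterior
#'   ring each, open or closed)
#' @param id character ids, unique; defaults to `"1" ... "n"`
#' @param land_use optional land-use codes, recycled if length 1
#' @param crs optional CRS label (free string); compared verbatim between
#'   layers in overlay and distance operations
#' @return a `patch_layer`
#' @export
patch_layer <- function(geometry, id = NULL, land_use = NULL, crs = NULL) {
  stopifnot(is.list(geometry))
  n <- length(geometry)
  if (is.null(id)) id <- as.character(seq_len(n))
  id <- as.character(id)
  stopifnot(length(id) == n)
  if (anyDuplicated(id)) {
    stop("duplicate patch ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  geometry <- lapply(geometry, repair_ring)
  ok <- vapply(geometry, ring_valid, logical(1))
  if (!all(ok)) {
    stop("invalid geometry for patch id(s): ", paste(id[!ok], collapse = ", "))
  }
  if (is.null(land_use)) land_use <- rep(NA_character_, n)
  if (length(land_use) == 1 && n > 1) land_use <- rep(land_use, n)
  structure(list(id = id, land_use = as.character(land_use),
                 geometry = geometry, crs = crs),
            class = "patch_layer")
}

#' @export
print.patch_layer <- function(x, ...) {
  cat(sprintf("<patch_layer> %d polygon(s)%s\n", length(x$id),
              if (is.null(x$crs)) "" else paste0(", crs: ", x$crs)))
  invisible(x)
}

#' @export
length.patch_layer <- function(x) length(x$id)

#' Protected-site set
#'
#' The polygons of the nature-protection sites that anchor the minimum
#' distance metric (in the European context, Natura 2000 sites).
#'
#' @inheritParams patch_layer
#' @return a `site_set`
#' @export
site_set <- function(geometry, id = NULL, crs = NULL) {
  layer <- patch_layer(geometry, id = id, crs = crs)
  class(layer) <- c("site_set", "patch_layer")
  layer
}

check_crs <- function(a, b, what = "layers") {
  if (!is.null(a$crs) && !is.null(b$crs) && !identical(a$crs, b$crs)) {
    stop(sprintf("CRS mismatch between %s: '%s' vs '%s'", what, a$crs, b$crs))
  }
}

#' Intersect corridor cells with land-cover patches
#'
#' Overlays the candidate-corridor cells with the land-cover map so that the
#' resulting patches are homogeneous in land-use code: each output polygon is
#' the positive-area intersection of one corridor cell and one land-cover
#' patch, carries the land-use code of its land-cover parent, and receives a
#' fresh sequential id. Clipping uses Sutherland–Hodgman, which requires one
#' polygon of each intersecting pair to be convex (either side may play the
#' convex role); land-cover maps of rectangles or other convex patches are
#' handled exactly.
#'
#' @param corridor_cells a [patch_layer()] of corridor cells
#' @param landcover a [patch_layer()] of land-cover patches with land-use codes
#' @param min_area drop output slivers with area below this threshold
#'   (default 0: keep every positive-area piece)
#' @return a [patch_layer()] with columns id, land_use and parent bookkeeping
#'   in attributes `cell_id` and `parent_id`
#' @export
overlay_intersection <- function(corridor_cells, landcover, min_area = 0) {
  stopifnot(inherits(corridor_cells, "patch_layer"),
            inherits(landcover, "patch_layer"))
  check_crs(corridor_cells, landcover, "corridor cells and land cover")
  cell_bb <- lapply(corridor_cells$geometry, polygon_bbox)
  lc_bb <- lapply(landcover$geometry, polygon_bbox)
  geoms <- list(); land_use <- character(0)
  cell_id <- character(0); parent_id <- character(0)
  for (i in seq_along(corridor_cells$id)) {
    for (j in seq_along(landcover$id)) {
      if (!bboxes_overlap(cell_bb[[i]], lc_bb[[j]])) next
      cg <- corridor_cells$geometry[[i]]
      lg <- landcover$geometry[[j]]
      piece <- if (is_convex_poly(lg)) {
        clip_polygon_convex(cg, lg)
      } else if (is_convex_poly(cg)) {
        clip_polygon_convex(lg, cg)
      } else {
        stop(sprintf(
          "cannot intersect two non-convex polygons (cell %s, patch %s)",
          corridor_cells$id[i], landcover$id[j]))
      }
      if (nrow(piece) >= 3 && poly_area(piece) > max(min_area, 1e-12)) {
        geoms[[length(geoms) + 1]] <- piece
        land_use <- c(land_use, landcover$land_use[j])
        cell_id <- c(cell_id, corridor_cells$id[i])
        parent_id <- c(parent_id, landcover$id[j])
      }
    }
  }
  out <- patch_layer(geoms, id = as.character(seq_along(geoms)),
                     land_use = if (length(geoms)) land_use else NULL,
                     crs = corridor_cells$crs)
  out$cell_id <- cell_id
  out$parent_id <- parent_id
  out
}

#' Derive the patch-adjacency graph from a polygon layer
#'
#' Links two patches when they are adjacent on the map. Under the default
#' rook rule, adjacency requires a shared boundary segment of positive
#' length; under the queen rule, any shared boundary point (including a
#' single corner) suffices. Every patch becomes a node even if isolated.
#'
#' @param layer a [patch_layer()]
#' @param rule `"rook"` (default) or `"queen"`
#' @param tol coordinate tolerance for shared-boundary tests
#' @return a [patch_graph()] whose nodes carry the layer's land-use codes
#' @export
polygons_to_graph <- function(layer, rule = c("rook", "queen"), tol = 1e-9) {
  stopifnot(inherits(layer, "patch_layer"))
  rule <- match.arg(rule)
  n <- length(layer$id)
  bb <- lapply(layer$geometry, polygon_bbox)
  from <- character(0); to <- character(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (!bboxes_overlap(bb[[i]], bb[[j]], tol = tol)) next
        if (polys_adjacent(layer$geometry[[i]], layer$geometry[[j]],
                           rule, tol)) {
          from <- c(from, layer$id[i])
          to <- c(to, layer$id[j])
        }
      }
    }
  }
  patch_graph(data.frame(from = from, to = to, stringsAsFactors = FALSE),
              nodes = data.frame(id = layer$id, land_use = layer$land_use,
                                 stringsAsFactors = FALSE))
}

polys_adjacent <- function(a, b, rule, tol = 1e-9) {
  ac <- close_ring(open_ring(a)); bc <- close_ring(open_ring(b))
  shared <- 0
  touch <- FALSE
  for (i in seq_len(nrow(ac) - 1)) {
    for (j in seq_len(nrow(bc) - 1)) {
      d <- seg_seg_dist(ac[i, ], ac[i + 1, ], bc[j, ], bc[j + 1, ])
      if (d <= tol) {
        touch <- TRUE
        shared <- shared +
          collinear_overlap_length(ac[i, ], ac[i + 1, ], bc[j, ], bc[j + 1, ],
                                   tol = tol)
        if (shared > tol) return(TRUE)
      }
    }
  }
  rule == "queen" && touch
}

#' Minimum boundary distance to a protected site
#'
#' For each patch, the smallest Euclidean boundary-to-boundary distance to
#' any site polygon: `D(v) = min_s d(s, v)`, computed on the projected plane.
#' A patch touching or intersecting a site has distance 0.
#'
#' @param layer a [patch_layer()]
#' @param sites a [site_set()] (non-empty)
#' @return named numeric vector of distances, one per patch id
#' @export
min_site_distance <- function(layer, sites) {
  stopifnot(inherits(layer, "patch_layer"), inherits(sites, "patch_layer"))
  if (length(sites$id) == 0) {
    stop("empty site set: exclude the distance metric from the combined score")
  }
  check_crs(layer, sites, "patch layer and site set")
  d <- vapply(layer$geometry, function(g) {
    min(vapply(sites$geometry, function(s) polygon_boundary_distance(g, s),
               numeric(1)))
  }, numeric(1))
  names(d) <- layer$id
  d
}
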
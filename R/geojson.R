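#' Read a polygon layer from GeoJSON
#'
#' Reads a FeatureCollection of Polygon features into a [patch_layer()].
#' Only the exterior ring of each polygon is used; interior rings (holes) are
#' dropped with a warning. Feature ids come from a property named by
#' `id_property` (default `"id"`), falling back to sequential numbers.
#'
#' @param path GeoJSON file
#' @param id_property property holding the feature id
#' @param land_use_property property holding the land-use code
#' @param crs optional CRS label to attach
#' @return a [patch_layer()]
#' @export
read_geojson <- function(path, id_property = "id",
                         land_use_property = "land_use", crs = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection, got: ", doc$type)
  }
  geoms <- list(); ids <- character(0); lu <- character(0)
  holes <- FALSE
  for (k in seq_along(doc$features)) {
    f <- doc$features[[k]]
    gt <- f$geometry$type
    if (!identical(gt, "Polygon")) {
      stop(sprintf("feature %d: unsupported geometry type '%s' (Polygon only)",
                   k, gt))
    }
    rings <- f$geometry$coordinates
    if (length(rings) > 1) holes <- TRUE
    ring <- do.call(rbind, lapply(rings[[1]], function(pt) {
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
    }))
    colnames(ring) <- c("x", "y")
    geoms[[length(geoms) + 1]] <- ring
    props <- f$properties
    ids <- c(ids, if (!is.null(props[[id_property]])) {
      as.character(props[[id_property]])
    } else {
      as.character(k)
    })
    lu <- c(lu, if (!is.null(props[[land_use_property]])) {
      as.character(props[[land_use_property]])
    } else {
      NA_character_
    })
  }
  if (holes) warning("interior rings (holes) were dropped")
  patch_layer(geoms, id = ids, land_use = if (length(lu)) lu else NULL,
              crs = crs)
}

#' Write a polygon layer to GeoJSON
#'
#' Writes a [patch_layer()] as a FeatureCollection of Polygon features.
#' Extra per-patch attributes (for example the ranking table) can be joined
#' on id and emitted as feature properties, for downstream map styling.
#'
#' @param layer a [patch_layer()]
#' @param path output file
#' @param attributes optional data frame with a `node_id` or `id` column to
#'   join on the layer ids; remaining columns become properties
#' @return the path, invisibly
#' @export
write_geojson <- function(layer, path, attributes = NULL) {
  stopifnot(inherits(layer, "patch_layer"))
  join <- NULL
  if (!is.null(attributes)) {
    key <- if ("node_id" %in% names(attributes)) "node_id" else "id"
    join <- attributes[match(layer$id, attributes[[key]]), , drop = FALSE]
  }
  features <- lapply(seq_along(layer$id), function(i) {
    ring <- close_ring(layer$geometry[[i]])
    coords <- list(lapply(seq_len(nrow(ring)), function(r) {
      c(ring[r, 1], ring[r, 2])
    }))
    props <- list(id = layer$id[i])
    if (!is.na(layer$land_use[i])) props$land_use <- layer$land_use[i]
    if (!is.null(join)) {
      for (cl in names(join)) {
        val <- join[i, cl]
        if (!is.na(val)) props[[cl]] <- val
      }
    }
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = coords))
  })
  doc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}
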
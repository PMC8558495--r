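#' Catchment tables
#'
#' Catchments are represented as a tibble with one row per hydrologic unit:
#' a `huc_id` character column (hierarchical code, unique) and a `geometry`
#' list-column holding an n x 2 matrix of polygon vertices
#' (longitude, latitude, WGS84). Only single-ring polygons are supported.
#'
#' @param huc_id character vector of unique catchment codes.
#' @param geometry list of n x 2 numeric matrices (lon, lat vertex rings).
#' @return A tibble of class `aqrisk_catchments`.
#' @export
catchments <- function(huc_id, geometry) {
  stopifnot(length(huc_id) == length(geometry))
  if (anyDuplicated(huc_id)) {
    abort("catchment huc_id values must be unique")
  }
  geometry <- lapply(geometry, function(g) {
    g <- as.matrix(g)
    if (ncol(g) != 2 || nrow(g) < 3 || !is.numeric(g)) {
      abort("each catchment geometry must be an n x 2 numeric matrix with n >= 3")
    }
    colnames(g) <- c("lon", "lat")
    g
  })
  out <- tibble::tibble(huc_id = as.character(huc_id), geometry = geometry)
  class(out) <- c("aqrisk_catchments", class(out))
  out
}

#' Read catchments from a GeoJSON FeatureCollection
#'
#' Expects Polygon features with a `huc_id` property; only the outer ring is
#' used. Multi-ring or MultiPolygon geometries are rejected.
#'
#' @param path path to a GeoJSON file.
#' @return An [catchments()] tibble.
#' @export
read_catchments <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) abort("not a GeoJSON FeatureCollection")
  ids <- character(0)
  geoms <- list()
  for (f in gj$features) {
    id <- f$properties$huc_id
    if (is.null(id)) abort("feature missing 'huc_id' property")
    if (!identical(f$geometry$type, "Polygon")) {
      abort(paste0("feature ", id, ": only Polygon geometries are supported"))
    }
    rings <- f$geometry$coordinates
    if (length(rings) != 1) {
      abort(paste0("feature ", id, ": polygons with holes are not supported"))
    }
    ring <- do.call(rbind, lapply(rings[[1]], function(xy) c(xy[[1]], xy[[2]])))
    ids <- c(ids, as.character(id))
    geoms <- c(geoms, list(ring))
  }
  catchments(ids, geoms)
}

#' Write catchments (plus optional per-catchment attributes) as GeoJSON
#'
#' @param x an [catchments()] tibble.
#' @param path output path.
#' @param properties optional data frame of extra per-row properties
#'   (e.g. predicted suitability) joined by `huc_id`.
#' @return `path`, invisibly.
#' @export
write_catchments <- function(x, path, properties = NULL) {
  feats <- lapply(seq_len(nrow(x)), function(i) {
    ring <- x$geometry[[i]]
    # close the ring for GeoJSON validity
    if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
    props <- list(huc_id = x$huc_id[i])
    if (!is.null(properties)) {
      row <- properties[properties$huc_id == x$huc_id[i], , drop = FALSE]
      if (nrow(row) == 1) {
        for (nm in setdiff(names(row), "huc_id")) props[[nm]] <- row[[nm]][1]
      }
    }
    list(
      type = "Feature",
      properties = props,
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(j) {
          c(ring[j, 1], ring[j, 2])
        }))
      )
    )
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Assign points to catchments.
#
# Interior points get their containing catchment; points lying exactly on a
# shared edge or vertex are assigned to the catchment with the
# lexicographically smallest huc_id among those whose boundary contains them
# (a deterministic stand-in for a half-open pixel convention). Points inside
# no catchment get NA.
assign_catchment <- function(lon, lat, catch) {
  n <- length(lon)
  bb <- t(vapply(catch$geometry, function(g) {
    c(min(g[, 1]), max(g[, 1]), min(g[, 2]), max(g[, 2]))
  }, numeric(4)))
  out <- rep(NA_character_, n)
  ord <- order(catch$huc_id)
  for (k in ord) {
    g <- catch$geometry[[k]]
    cand <- which(is.na(out) &
      lon >= bb[k, 1] & lon <= bb[k, 2] &
      lat >= bb[k, 3] & lat <= bb[k, 4])
    if (!length(cand)) next
    hit <- sp::point.in.polygon(lon[cand], lat[cand], g[, 1], g[, 2])
    out[cand[hit > 0]] <- catch$huc_id[k]
  }
  out
}
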
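#' Read polygon features from a GeoJSON file
#'
#' Loads a GeoJSON (RFC 7946) `FeatureCollection` of named `Polygon` or
#' `MultiPolygon` features describing geographic features of interest —
#' islands, trails, parks, mountains — to annotate sampling sites with.
#' Coordinates are WGS84 decimal degrees, `[longitude, latitude]` per GeoJSON
#' convention. Each feature must carry a `name` property; non-polygon
#' geometries are skipped with a warning. Rings may be explicitly closed
#' (first vertex repeated last) or implicitly closed, and need at least three
#' distinct vertices.
#'
#' @param path Path to a `.geojson`/`.json` file.
#' @return A list of class `geo_features`; each element has `name`,
#'   `polygons` (a list of polygons, each a list of rings, each ring a
#'   two-column lon/lat matrix with the exterior ring first), and
#'   `properties`.
#' @export
read_features <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else if (identical(gj$type, "Feature")) list(gj)
           else abort("Expected a GeoJSON Feature or FeatureCollection.",
                      class = "sampleflow_invalid_feature")
  out <- list()
  for (f in feats) {
    geom <- f$geometry
    name <- f$properties$name
    if (is.null(name) || !nzchar(name)) {
      abort("Every feature needs a non-empty `name` property.",
            class = "sampleflow_invalid_feature")
    }
    if (is.null(geom) || !geom$type %in% c("Polygon", "MultiPolygon")) {
      warn(paste0("Skipping non-polygon feature: ", name))
      next
    }
    coords <- geom$coordinates
    polys <- if (geom$type == "Polygon") list(coords) else coords
    polys <- lapply(polys, function(poly) lapply(poly, as_ring))
    for (poly in polys) {
      for (ring in poly) validate_ring(ring, name)
    }
    out[[length(out) + 1]] <- list(
      name = name, polygons = polys,
      properties = f$properties
    )
  }
  structure(out, class = "geo_features")
}

as_ring <- function(ring) {
  m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
  storage.mode(m) <- "double"
  # drop explicit closure; the containment test closes implicitly
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

validate_ring <- function(ring, name) {
  if (nrow(unique(ring)) < 3) {
    abort(paste0("Degenerate ring (<3 distinct vertices) in feature ", name),
          class = "sampleflow_invalid_feature")
  }
  if (any(abs(ring[, 1]) > 180) || any(abs(ring[, 2]) > 90)) {
    abort(paste0("Coordinates out of WGS84 range in feature ", name),
          class = "sampleflow_invalid_feature")
  }
  invisible(ring)
}

# TRUE when (x, y) lies on the segment (x1,y1)-(x2,y2).
on_segment <- function(x, y, x1, y1, x2, y2, eps = 1e-12) {
  cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
  if (abs(cross) > eps * max(1, abs(x2 - x1), abs(y2 - y1))) return(FALSE)
  x >= min(x1, x2) - eps && x <= max(x1, x2) + eps &&
    y >= min(y1, y2) - eps && y <= max(y1, y2) + eps
}

# Even-odd ray-casting parity of one ring; boundary handled by the caller.
ring_parity <- function(lon, lat, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > lat) != (yj > lat)) {
      x_int <- xi + (lat - yi) / (yj - yi) * (xj - xi)
      if (lon < x_int) inside <- !inside
    }
    j <- i
  }
  inside
}

ring_boundary <- function(lon, lat, ring) {
  n <- nrow(ring)
  j <- n
  for (i in seq_len(n)) {
    if (on_segment(lon, lat, ring[j, 1], ring[j, 2], ring[i, 1], ring[i, 2])) {
      return(TRUE)
    }
    j <- i
  }
  FALSE
}

#' Test whether a point lies inside a geographic feature
#'
#' Even-odd ray-casting containment in WGS84 decimal degrees. A point exactly
#' on any ring boundary counts as inside (a sample taken on a trail edge
#' annotates to the trail); a point in a hole ring is outside. Polygons
#' crossing the antimeridian are not supported.
#'
#' @param lon,lat Point coordinates in decimal degrees.
#' @param feature One element of a [read_features()] list (or an equivalent
#'   list with a `polygons` field).
#' @return `TRUE` if the point is inside (or on the boundary of) any polygon
#'   of the feature.
#' @examples
#' square <- list(name = "unit", polygons = list(list(
#'   matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
#' )))
#' point_in_feature(0.5, 0.5, square)
#' point_in_feature(2, 2, square)
#' @export
point_in_feature <- function(lon, lat, feature) {
  stopifnot(length(lon) == 1, length(lat) == 1)
  if (is.na(lon) || is.na(lat)) return(FALSE)
  stopifnot(is.numeric(lon), is.numeric(lat))
  for (poly in feature$polygons) {
    for (ring in poly) {
      if (ring_boundary(lon, lat, ring)) return(TRUE)
    }
    parity <- FALSE
    for (ring in poly) {
      if (ring_parity(lon, lat, ring)) parity <- !parity
    }
    if (parity) return(TRUE)
  }
  FALSE
}

#' Annotate collections with containing geographic features
#'
#' Adds two columns to the joined collection table based on each row's final
#' (resolved) location: `location`, the name of the first feature in file
#' order that contains the point (`NA` if none), and `locations_all`, the
#' semicolon-joined names of every containing feature (overlapping features
#' are all retained). Rows without a resolved location (`location_source ==
#' "none"`) are left `NA`. Row count and order are preserved, and the
#' operation is idempotent for a fixed feature set.
#'
#' @param joined A `joined_collection` from [join_fulcrum()].
#' @param features A `geo_features` list from [read_features()], or `NULL`
#'   for no annotation (columns are still added, all `NA`).
#' @return The input with `location` and `locations_all` columns.
#' @export
annotate_fulcrum <- function(joined, features = NULL) {
  stopifnot(inherits(joined, "joined_collection"))
  n <- nrow(joined)
  location <- rep(NA_character_, n)
  locations_all <- rep(NA_character_, n)
  if (!is.null(features) && length(features) > 0) {
    # containment is per unique location, not per row
    key <- paste(joined$longitude, joined$latitude)
    for (k in unique(key[joined$location_source != "none"])) {
      rows <- which(key == k & joined$location_source != "none")
      lon <- joined$longitude[rows[1]]
      lat <- joined$latitude[rows[1]]
      hits <- purrr::map_lgl(features, ~ point_in_feature(lon, lat, .x))
      if (any(hits)) {
        matched <- purrr::map_chr(features[hits], "name")
        location[rows] <- matched[1]
        locations_all[rows] <- paste(matched, collapse = ";")
      }
    }
  }
  joined$location <- location
  joined$locations_all <- locations_all
  joined
}
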
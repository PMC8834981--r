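#' Read line features from GeoJSON
#'
#' Accepts a FeatureCollection of LineString / MultiLineString features in a
#' planar metric CRS. Each LineString becomes one coordinate matrix; a
#' MultiLineString contributes one matrix per part.
#'
#' @param path path to a GeoJSON file.
#' @return list of two-column coordinate matrices (x, y in meters).
#' @export
read_geojson_lines <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- geojson_features(gj)
  out <- list()
  for (i in seq_along(feats)) {
    geom <- feats[[i]]$geometry
    if (is.null(geom)) stop("feature ", i, " has no geometry", call. = FALSE)
    if (geom$type == "LineString") {
      out[[length(out) + 1]] <- coords_to_matrix(geom$coordinates)
    } else if (geom$type == "MultiLineString") {
      for (part in geom$coordinates)
        out[[length(out) + 1]] <- coords_to_matrix(part)
    } else {
      stop(sprintf("feature %d: expected LineString/MultiLineString, got %s",
                   i, geom$type), call. = FALSE)
    }
  }
  out
}

#' Read point features from GeoJSON
#'
#' @param path path to a GeoJSON FeatureCollection of Point features.
#' @return data.frame with columns `x`, `y` and one column per property.
#' @export
read_geojson_points <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- geojson_features(gj)
  if (length(feats) == 0)
    return(data.frame(x = numeric(0), y = numeric(0)))
  rows <- lapply(seq_along(feats), function(i) {
    geom <- feats[[i]]$geometry
    if (is.null(geom) || geom$type != "Point")
      stop(sprintf("feature %d: expected Point geometry, got %s",
                   i, if (is.null(geom)) "none" else geom$type), call. = FALSE)
    props <- feats[[i]]$properties
    c(list(x = as.numeric(geom$coordinates[[1]]),
           y = as.numeric(geom$coordinates[[2]])),
      lapply(props, function(p) if (is.null(p)) NA else p))
  })
  keys <- unique(unlist(lapply(rows, names)))
  df <- as.data.frame(
    lapply(keys, function(k)
      unlist(lapply(rows, function(r) if (is.null(r[[k]])) NA else r[[k]]))),
    stringsAsFactors = FALSE)
  names(df) <- keys
  df
}

geojson_features <- function(gj) {
  if (!is.list(gj) || is.null(gj$type))
    stop("not a GeoJSON object", call. = FALSE)
  if (gj$type == "FeatureCollection") return(gj$features)
  if (gj$type == "Feature") return(list(gj))
  # bare geometry
  list(list(geometry = gj, properties = list()))
}

coords_to_matrix <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(pt)
    c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
  colnames(m) <- c("x", "y")
  m
}

#' Write line features to GeoJSON
#'
#' @param lines list of two-column coordinate matrices.
#' @param path output path.
#' @param properties optional data.frame of per-feature properties.
#' @return `path`, invisibly.
#' @export
write_geojson_lines <- function(lines, path, properties = NULL) {
  feats <- lapply(seq_along(lines), function(i) {
    m <- lines[[i]]
    list(type = "Feature",
         properties = feature_props(properties, i),
         geometry = list(
           type = "LineString",
           coordinates = lapply(seq_len(nrow(m)), function(k) as.numeric(m[k, 1:2]))))
  })
  write_feature_collection(feats, path)
}

#' Write point features to GeoJSON
#'
#' @param df data.frame with `x`, `y` columns; all other columns become
#'   feature properties.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(df, path) {
  props <- df[setdiff(names(df), c("x", "y"))]
  feats <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         properties = feature_props(props, i),
         geometry = list(type = "Point",
                         coordinates = c(df$x[i], df$y[i])))
  })
  write_feature_collection(feats, path)
}

feature_props <- function(properties, i) {
  if (is.null(properties) || ncol(as.data.frame(properties)) == 0)
    return(structure(list(), names = character(0)))
  as.list(as.data.frame(properties)[i, , drop = FALSE])
}

write_feature_collection <- function(feats, path) {
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}
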
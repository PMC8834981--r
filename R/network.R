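#' Build a pedestrian network from line features
#'
#' Turns polyline records into an undirected graph: each record becomes one
#' edge whose endpoints are the polyline's first and last vertices, with the
#' full geometry retained for point snapping. Endpoints closer than the snap
#' tolerance are merged into a single node, so records digitized with
#' sub-centimeter gaps still connect.
#'
#' Coordinates must be planar meters (any metric projected CRS). If every
#' coordinate lies within [-360, 360] the input is almost certainly
#' geographic degrees and an error asks for reprojection.
#'
#' @param lines list of two-column coordinate matrices (x, y in meters), as
#'   returned by [read_geojson_lines()].
#' @param snap_tolerance endpoint merge tolerance (m), default 0.05.
#' @return an object of class `pedestrian_network` with `$nodes`
#'   (data.frame: id, x, y, elev) and `$edges` (data.frame: id, from, to,
#'   length, gradient, walkable, plus a `geom` list column).
#' @export
build_network <- function(lines, snap_tolerance = 0.05) {
  if (length(lines) == 0) stop("no line records", call. = FALSE)
  lines <- lapply(lines, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m[, 1:2, drop = FALSE]
  })
  allxy <- do.call(rbind, lines)
  if (all(abs(allxy) <= 360))
    stop("coordinates look like geographic degrees (all |x|,|y| <= 360); ",
         "reproject to a metric CRS before building the network", call. = FALSE)

  lens <- vapply(lines, polyline_length, numeric(1))
  zero <- which(lens <= 0)
  if (length(zero) > 0)
    stop("zero-length edge at record index ", zero[1], call. = FALSE)

  # merge endpoints within tolerance (greedy, via rounded spatial hashing +
  # exact distance check against accepted nodes in the same neighbourhood)
  ends <- do.call(rbind, lapply(lines, function(m) m[c(1, nrow(m)), ]))
  node_xy <- matrix(numeric(0), ncol = 2)
  node_of_end <- integer(nrow(ends))
  for (k in seq_len(nrow(ends))) {
    p <- ends[k, ]
    hit <- 0L
    if (nrow(node_xy) > 0) {
      d2 <- (node_xy[, 1] - p[1])^2 + (node_xy[, 2] - p[2])^2
      j <- which.min(d2)
      if (d2[j] <= snap_tolerance^2) hit <- j
    }
    if (hit == 0L) {
      node_xy <- rbind(node_xy, p)
      hit <- nrow(node_xy)
    }
    node_of_end[k] <- hit
  }
  from <- node_of_end[seq_along(lines) * 2 - 1]
  to   <- node_of_end[seq_along(lines) * 2]
  bad <- which(from == to)
  if (length(bad) > 0 && any(lens[bad] <= snap_tolerance))
    stop("zero-length edge at record index ", bad[which(lens[bad] <= snap_tolerance)][1],
         call. = FALSE)

  nodes <- data.frame(id = seq_len(nrow(node_xy)),
                      x = node_xy[, 1], y = node_xy[, 2], elev = NA_real_)
  edges <- data.frame(id = seq_along(lines), from = from, to = to,
                      length = lens, gradient = 0, walkable = TRUE)
  edges$geom <- lines
  structure(list(nodes = nodes, edges = edges), class = "pedestrian_network")
}

#' @export
print.pedestrian_network <- function(x, ...) {
  cat(sprintf("<pedestrian_network> %d nodes, %d edges, total length %.1f m\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length)))
  invisible(x)
}

polyline_length <- function(m) {
  if (nrow(m) < 2) return(0)
  sum(sqrt(diff(m[, 1])^2 + diff(m[, 2])^2))
}

#' Attach slope gradients to network edges from a DTM
#'
#' Samples node elevations bilinearly from the DTM, then sets each edge's
#' gradient to `|elev(to) - elev(from)| / length * 100`. Gradients are
#' unsigned: pedestrian travel is modeled as symmetric, so a single slope
#' magnitude per edge covers both directions.
#'
#' @param net a `pedestrian_network`.
#' @param dtm an [elev_raster()] covering every node.
#' @return the network with `$nodes$elev` and `$edges$gradient` filled in.
#' @export
assign_gradients <- function(net, dtm) {
  stopifnot(inherits(net, "pedestrian_network"))
  ext <- raster_extent(dtm)
  out <- net$nodes$x < ext["xmin"] | net$nodes$x > ext["xmax"] |
         net$nodes$y < ext["ymin"] | net$nodes$y > ext["ymax"]
  if (any(out))
    stop("node ", net$nodes$id[which(out)[1]], " lies outside the DTM extent",
         call. = FALSE)
  net$nodes$elev <- bilinear_sample(dtm, net$nodes$x, net$nodes$y)
  dz <- abs(net$nodes$elev[net$edges$to] - net$nodes$elev[net$edges$from])
  net$edges$gradient <- dz / net$edges$length * 100
  net
}

#' Two-regime walking speed model
#'
#' Older-adult walking speed as a step function of path gradient: a moderate
#' speed up to the gradient threshold and a reduced speed on steeper paths.
#' The default (4.3 km/h up to tan(9 deg) ~ 15.84%, 4.0 km/h beyond) averages
#' published sex-specific speed profiles into two regimes split at a 9-degree
#' slope.
#'
#' @param moderate_speed speed on gentle gradients (km/h).
#' @param steep_speed speed beyond the threshold (km/h); must not exceed
#'   `moderate_speed`.
#' @param gradient_threshold regime boundary in percent slope.
#' @return an object of class `speed_model`.
#' @export
speed_model <- function(moderate_speed = 4.3, steep_speed = 4.0,
                        gradient_threshold = tan(9 * pi / 180) * 100) {
  if (moderate_speed <= 0 || steep_speed <= 0)
    stop("speeds must be > 0", call. = FALSE)
  if (moderate_speed < steep_speed)
    stop("moderate_speed must be >= steep_speed", call. = FALSE)
  if (gradient_threshold <= 0)
    stop("gradient_threshold must be > 0", call. = FALSE)
  structure(list(moderate_speed = moderate_speed, steep_speed = steep_speed,
                 gradient_threshold = gradient_threshold),
            class = "speed_model")
}

#' Walking speed at a given gradient
#'
#' @param gradient percent slope magnitude, `>= 0` (vectorized).
#' @param model a [speed_model()].
#' @return speed in km/h: the moderate speed where
#'   `gradient <= gradient_threshold`, the steep speed beyond.
#' @export
walking_speed <- function(gradient, model = speed_model()) {
  if (any(gradient < 0, na.rm = TRUE))
    stop("gradient must be >= 0 (callers pass the slope magnitude)", call. = FALSE)
  ifelse(gradient <= model$gradient_threshold,
         model$moderate_speed, model$steep_speed)
}

#' Time to traverse a path segment
#'
#' @param length segment length (m), `>= 0`.
#' @param gradient percent slope magnitude.
#' @param model a [speed_model()].
#' @return traversal time in minutes.
#' @export
traversal_time <- function(length, gradient, model = speed_model()) {
  if (any(length < 0, na.rm = TRUE))
    stop("length must be >= 0", call. = FALSE)
  length / (walking_speed(gradient, model) * 1000) * 60
}

#' Snap a point to the nearest network edge
#'
#' Projects the point onto every edge polyline and returns the closest
#' position within the radius. Ties between edges are broken by the lowest
#' edge id, so results are deterministic.
#'
#' @param net a `pedestrian_network`.
#' @param p length-2 numeric (x, y).
#' @param radius maximum snap distance (m), default 25.
#' @return `NULL` when nothing lies within the radius; otherwise a list with
#'   `edge` (edge id), `offset` (m along the polyline), `point` (snapped
#'   coordinate) and `dist` (snap distance).
#' @export
snap_point <- function(net, p, radius = 25) {
  stopifnot(length(p) >= 2, radius > 0)
  best <- NULL
  for (i in seq_len(nrow(net$edges))) {
    cand <- project_on_polyline(net$edges$geom[[i]], p)
    if (cand$dist <= radius &&
        (is.null(best) || cand$dist < best$dist - 1e-12)) {
      best <- c(cand, list(edge = net$edges$id[i]))
    }
  }
  if (is.null(best)) return(NULL)
  list(edge = best$edge, offset = best$offset, point = best$point, dist = best$dist)
}

# nearest point on a polyline; returns dist, offset along line, coordinates
project_on_polyline <- function(m, p) {
  best_d2 <- Inf; best_off <- 0; best_pt <- m[1, ]
  cum <- 0
  for (s in seq_len(nrow(m) - 1)) {
    a <- m[s, ]; b <- m[s + 1, ]
    ab <- b - a
    L2 <- sum(ab^2)
    t <- if (L2 == 0) 0 else max(0, min(1, sum((p[1:2] - a) * ab) / L2))
    q <- a + t * ab
    d2 <- sum((p[1:2] - q)^2)
    if (d2 < best_d2 - 1e-15) {
      best_d2 <- d2
      best_off <- cum + t * sqrt(L2)
      best_pt <- q
    }
    cum <- cum + sqrt(L2)
  }
  list(dist = sqrt(best_d2), offset = best_off, point = unname(best_pt))
}

#' Multi-source network distance field (service-area substrate)
#'
#' Computes, for every network node, the shortest-path cost to the nearest of
#' a set of source points (multi-source Dijkstra). Sources are snapped to the
#' nearest edge; a source landing mid-edge splits that edge proportionally,
#' so distances are exact rather than rounded to the nearest node. With
#' `metric = "minutes"` edge costs are traversal times under the speed model
#' instead of meters.
#'
#' Nodes not connected to any source keep the value `Inf` (explicitly
#' unreachable).
#'
#' @param net a `pedestrian_network`.
#' @param sources two-column matrix or data.frame of source coordinates.
#' @param metric `"meters"` (default) or `"minutes"`.
#' @param model [speed_model()] used when `metric = "minutes"`.
#' @param snap_radius source snap radius (m), default 25.
#' @return an object of class `distance_field`: data.frame (`node`, `x`,
#'   `y`, `distance`) plus the metric as an attribute.
#' @export
distance_field <- function(net, sources, metric = c("meters", "minutes"),
                           model = speed_model(), snap_radius = 25) {
  metric <- match.arg(metric)
  sources <- as.matrix(as.data.frame(sources)[, 1:2])
  if (nrow(sources) == 0) stop("empty source set", call. = FALSE)
  snaps <- lapply(seq_len(nrow(sources)), function(i)
    snap_point(net, sources[i, ], radius = snap_radius))
  miss <- vapply(snaps, is.null, logical(1))
  if (all(miss))
    stop("no source within snap radius (", snap_radius, " m) of the network",
         call. = FALSE)
  if (any(miss))
    stop(sum(miss), " source(s) beyond the snap radius (",
         snap_radius, " m); first at index ", which(miss)[1], call. = FALSE)

  n_nodes <- nrow(net$nodes)
  ew <- edge_costs(net, metric, model)

  # augmented graph: one virtual vertex per mid-edge source, tied to the
  # split edge's endpoints with proportional costs (original edges kept;
  # extra parallel paths cannot shorten any shortest path)
  efrom <- net$edges$from; eto <- net$edges$to; ecost <- ew
  src_vids <- integer(length(snaps))
  extra <- n_nodes
  for (i in seq_along(snaps)) {
    sn <- snaps[[i]]
    e <- which(net$edges$id == sn$edge)
    L <- net$edges$length[e]
    frac <- min(max(sn$offset / L, 0), 1)
    if (frac <= 1e-12) { src_vids[i] <- net$edges$from[e]; next }
    if (frac >= 1 - 1e-12) { src_vids[i] <- net$edges$to[e]; next }
    extra <- extra + 1L
    src_vids[i] <- extra
    efrom <- c(efrom, net$edges$from[e], extra)
    eto <- c(eto, extra, net$edges$to[e])
    ecost <- c(ecost, ew[e] * frac, ew[e] * (1 - frac))
  }
  g <- igraph::make_graph(as.vector(rbind(efrom, eto)), n = extra, directed = FALSE)
  D <- igraph::distances(g, v = unique(src_vids), to = seq_len(n_nodes),
                         weights = ecost, algorithm = "dijkstra")
  d <- apply(D, 2, min)
  structure(
    data.frame(node = net$nodes$id, x = net$nodes$x, y = net$nodes$y,
               distance = as.numeric(d)),
    metric = metric, class = c("distance_field", "data.frame"))
}

edge_costs <- function(net, metric, model) {
  if (metric == "meters") net$edges$length
  else traversal_time(net$edges$length, net$edges$gradient, model)
}

#' Write a distance field to CSV
#'
#' @param field a [distance_field()] result.
#' @param path output CSV path (`node_id`, `x`, `y`, `distance_m`;
#'   unreachable nodes are written as empty cells).
#' @return `path`, invisibly.
#' @export
write_distance_field_csv <- function(field, path) {
  df <- data.frame(node_id = field$node, x = field$x, y = field$y,
                   distance_m = ifelse(is.finite(field$distance),
                                       field$distance, NA))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a distance field as point GeoJSON
#'
#' @param field a [distance_field()] result.
#' @param path output GeoJSON path.
#' @return `path`, invisibly.
#' @export
write_distance_field_geojson <- function(field, path) {
  df <- data.frame(x = field$x, y = field$y, node_id = field$node,
                   distance_m = ifelse(is.finite(field$distance),
                                       field$distance, NA))
  write_geojson_points(df, path)
}
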
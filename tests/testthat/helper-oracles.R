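# Independent oracles and fixture builders. Everything here is deliberately
# naive (loops, relaxation to a fixed point) and shares no code with the
# package's shortest-path or overlay implementations.

# multi-source Bellman-Ford on an undirected weighted edge list
bf_distances <- function(n_nodes, from, to, w, sources) {
  d <- rep(Inf, n_nodes)
  d[sources] <- 0
  for (iter in seq_len(n_nodes + 1)) {
    changed <- FALSE
    for (k in seq_along(from)) {
      if (is.finite(d[from[k]]) && d[from[k]] + w[k] < d[to[k]] - 1e-12) {
        d[to[k]] <- d[from[k]] + w[k]; changed <- TRUE
      }
      if (is.finite(d[to[k]]) && d[to[k]] + w[k] < d[from[k]] - 1e-12) {
        d[from[k]] <- d[to[k]] + w[k]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  d
}

# random connected planar-ish test network: a random tree plus extra chords,
# realized as straight-line records so build_network reconstructs it
random_test_network <- function(n_nodes, extra_edges = n_nodes %/% 2) {
  pts <- cbind(x = 1000 + runif(n_nodes, 0, 2000),
               y = 1000 + runif(n_nodes, 0, 2000))
  from <- integer(0); to <- integer(0)
  for (i in 2:n_nodes) {
    from <- c(from, sample.int(i - 1, 1)); to <- c(to, i)
  }
  for (k in seq_len(extra_edges)) {
    pair <- sample.int(n_nodes, 2)
    from <- c(from, pair[1]); to <- c(to, pair[2])
  }
  keep <- !duplicated(cbind(pmin(from, to), pmax(from, to))) & from != to
  from <- from[keep]; to <- to[keep]
  lines <- lapply(seq_along(from), function(k)
    rbind(pts[from[k], ], pts[to[k], ]))
  list(lines = lines, pts = pts, from = from, to = to)
}

# direct band lookups, written as plain if-chains
oracle_bench_level <- function(d) {
  if (!is.finite(d)) return(1L)
  if (d < 100) 5L else if (d < 300) 4L else if (d < 500) 3L
  else if (d < 700) 2L else 1L
}
oracle_service_level <- function(d) {
  if (!is.finite(d)) return(1L)
  if (d < 100) 5L else if (d < 300) 4L else if (d < 600) 3L
  else if (d < 800) 2L else 1L
}
oracle_slope_level <- function(s) {
  if (s <= 3) 5L else if (s <= 5) 4L else if (s <= 8) 3L
  else if (s <= 12) 2L else 1L
}

# a hand-made square-grid town: streets every `spacing` m over a square
# extent, offset so coordinates are unambiguously metric
square_town_lines <- function(n_blocks = 4, spacing = 100, origin = c(2000, 2000)) {
  xs <- origin[1] + spacing * 0:n_blocks
  ys <- origin[2] + spacing * 0:n_blocks
  lines <- list()
  for (x in xs) for (i in seq_len(n_blocks))
    lines[[length(lines) + 1]] <- cbind(x = c(x, x), y = ys[c(i, i + 1)])
  for (y in ys) for (i in seq_len(n_blocks))
    lines[[length(lines) + 1]] <- cbind(x = xs[c(i, i + 1)], y = c(y, y))
  lines
}

# flat DTM comfortably covering a town built by square_town_lines
flat_dtm <- function(value = 200, origin = c(2000, 2000), size = 500,
                     cellsize = 25) {
  n <- ceiling(size / cellsize) + 2
  elev_raster(matrix(value, n, n), xll = origin[1] - cellsize,
              yll = origin[2] - cellsize, cellsize = cellsize)
}

# inventory fixture reproducing the published two-neighborhood facility
# census (zone A: 2/3/8/10/4 = 27 sites; zone B: 7/7/6/20/5 = 45)
census_fixture_inventory <- function() {
  counts <- list(
    A = c(health_services = 2, municipal = 3, social_cultural = 8,
          shopping = 10, schools_childcare = 4),
    B = c(health_services = 7, municipal = 7, social_cultural = 6,
          shopping = 20, schools_childcare = 5))
  rows <- list()
  for (z in names(counts)) for (g in names(counts[[z]]))
    if (counts[[z]][g] > 0)
      rows[[length(rows) + 1]] <- data.frame(
        x = 1000 + seq_len(counts[[z]][g]), y = 1000, group = g, zone = z)
  fac <- do.call(rbind, rows)
  fac$id <- seq_len(nrow(fac))
  load_inventory(fac, data.frame(x = 1000, y = 1000, kind = "formal",
                                 zone = "A", id = 1))
}
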
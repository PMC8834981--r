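#' Ordinal accessibility levels
#'
#' @return named character vector mapping levels 1..5 to their labels
#'   (Very Low .. Very High).
#' @export
level_labels <- function() {
  c(`1` = "Very Low", `2` = "Low", `3` = "Moderate", `4` = "High",
    `5` = "Very High")
}

#' Reclassification table for one model variable
#'
#' An ordered set of contiguous value bands mapping a continuous variable
#' (network distance in meters, or percent slope) onto the common five-level
#' ordinal scale, levels strictly decreasing from 5 (Very High accessibility)
#' to 1 (Very Low).
#'
#' Band closure follows the printed convention of each variable: distance
#' bands are half-open `[lo, hi)` (a 100 m distance falls in the 100-300
#' band), slope bands are upper-closed `(lo, hi]` (5.00% is still High,
#' 5.01% is Moderate). Values beyond the last band take level 1.
#'
#' @param variable variable name (free text, e.g. `"benches"`).
#' @param bands data.frame with columns `lower`, `upper`, `level`.
#' @param units `"m"` or `"%"`.
#' @param closure `"left"` for `[lo, hi)` bands, `"right"` for `(lo, hi]`.
#' @return an object of class `reclass_table`.
#' @export
reclass_table <- function(variable, bands, units = c("m", "%"),
                          closure = c("left", "right")) {
  units <- match.arg(units); closure <- match.arg(closure)
  bands <- as.data.frame(bands)[c("lower", "upper", "level")]
  o <- order(bands$lower)
  bands <- bands[o, ]
  if (bands$lower[1] != 0)
    stop("bands must start at 0", call. = FALSE)
  if (nrow(bands) > 1 &&
      any(abs(bands$lower[-1] - bands$upper[-nrow(bands)]) > 1e-9))
    stop("bands must be contiguous and non-overlapping", call. = FALSE)
  if (any(diff(bands$level) >= 0))
    stop("levels must strictly decrease across bands", call. = FALSE)
  if (!all(bands$level %in% 1:5))
    stop("levels must be in 1..5", call. = FALSE)
  structure(list(variable = variable, bands = bands, units = units,
                 closure = closure),
            class = "reclass_table")
}

#' Built-in reclassification tables
#'
#' The distance and slope bands of the accessibility model. Bench distances:
#' 0-100 m Very High, 100-300 High, 300-500 Moderate, 500-700 Low, beyond
#' 700 Very Low. Service distances: 0-100, 100-300, 300-600, 600-800, beyond
#' 800. Slope: 0-3.00% Very High, 3.01-5.00 High, 5.01-8.00 Moderate,
#' 8.01-12.00 Low, >= 12.01 Very Low. The same service bands apply to the
#' health-services and other-services split used by the chronic-disease
#' profile.
#'
#' @return named list of [reclass_table()] objects: `benches`,
#'   `health_services`, `other_services`, `all_services`, `slope`.
#' @export
builtin_reclass_tables <- function() {
  bench_bands <- data.frame(lower = c(0, 100, 300, 500, 700),
                            upper = c(100, 300, 500, 700, 1000),
                            level = 5:1)
  svc_bands <- data.frame(lower = c(0, 100, 300, 600, 800),
                          upper = c(100, 300, 600, 800, 1000),
                          level = 5:1)
  slope_bands <- data.frame(lower = c(0, 3, 5, 8, 12),
                            upper = c(3, 5, 8, 12, Inf),
                            level = 5:1)
  list(
    benches = reclass_table("benches", bench_bands, "m", "left"),
    health_services = reclass_table("health_services", svc_bands, "m", "left"),
    other_services = reclass_table("other_services", svc_bands, "m", "left"),
    all_services = reclass_table("all_services", svc_bands, "m", "left"),
    slope = reclass_table("slope", slope_bands, "%", "right")
  )
}

#' Profile weights for the weighted linear combination
#'
#' A named weight vector over the model variables, summing to 1. Profiles
#' that split services into health vs other (the chronic-disease profile)
#' carry `health_services` and `other_services` keys; unsplit profiles carry
#' `all_services`.
#'
#' @param name profile name.
#' @param weights named numeric vector; must include `benches` and `slope`,
#'   plus either `all_services` or both `health_services` and
#'   `other_services`; non-negative, summing to 1 within 1e-9.
#' @return an object of class `profile_weights`.
#' @export
profile_weights <- function(name, weights) {
  weights <- unlist(weights)
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", sum(weights), ")", call. = FALSE)
  split <- all(c("health_services", "other_services") %in% names(weights))
  if (split && "all_services" %in% names(weights))
    stop("give either all_services or the health/other split, not both",
         call. = FALSE)
  if (!split && !"all_services" %in% names(weights))
    stop("weights need all_services, or both health_services and other_services",
         call. = FALSE)
  needed <- c("benches", "slope")
  if (!all(needed %in% names(weights)))
    stop("weights need keys: ", paste(setdiff(needed, names(weights)),
                                      collapse = ", "), call. = FALSE)
  structure(list(name = name, weights = weights, split_services = split),
            class = "profile_weights")
}

#' The three built-in older-adult profiles
#'
#' Weightings of the model variables per population profile:
#' * `healthy` - benches 45%, all services 45%, slope 10%;
#' * `chronic_disease` - benches 30%, health services 40%, other services
#'   10%, slope 20% (services split so that recurrent-care destinations
#'   dominate);
#' * `reduced_mobility` - benches 30%, all services 30%, slope 40%.
#'
#' @return named list of three [profile_weights()] objects.
#' @export
builtin_profiles <- function() {
  list(
    healthy = profile_weights("healthy",
      c(benches = 0.45, all_services = 0.45, slope = 0.10)),
    chronic_disease = profile_weights("chronic_disease",
      c(benches = 0.30, health_services = 0.40, other_services = 0.10,
        slope = 0.20)),
    reduced_mobility = profile_weights("reduced_mobility",
      c(benches = 0.30, all_services = 0.30, slope = 0.40))
  )
}

resolve_profile <- function(profile) {
  if (inherits(profile, "profile_weights")) return(profile)
  if (is.character(profile) && length(profile) == 1) {
    p <- builtin_profiles()[[profile]]
    if (is.null(p))
      stop("unknown profile \"", profile, "\"; built-in profiles are: ",
           paste(names(builtin_profiles()), collapse = ", "), call. = FALSE)
    return(p)
  }
  stop("profile must be a profile_weights object or a built-in profile name",
       call. = FALSE)
}

#' Rasterize a node distance field onto the analysis grid
#'
#' Each cell takes the field value of the nearest network node within the
#' off-network radius, plus the straight-line distance from the cell center
#' to that node (the walk to reach the network). Cells with no node within
#' the radius are marked unreached (`Inf`) and later reclassify to level 1.
#'
#' @param field a [distance_field()] result computed on `net`.
#' @param net the `pedestrian_network` the field was computed on.
#' @param grid an [analysis_grid()].
#' @param off_network_radius maximum cell-to-network distance (m), default
#'   100 (one Very-High band width).
#' @param cost_per_meter factor converting the off-network straight-line
#'   meters into the field's cost units (1 for a meters field).
#' @return an `elev_raster` of distances (m) on the grid header; unreached
#'   cells are `Inf`.
#' @export
distance_raster <- function(field, net, grid, off_network_radius = 100,
                            cost_per_meter = 1) {
  nx <- net$nodes$x; ny <- net$nodes$y
  gx_rng <- c(grid$xll, grid$xll + grid$ncol * grid$cellsize)
  gy_rng <- c(grid$yll, grid$yll + grid$nrow * grid$cellsize)
  if (max(nx) < gx_rng[1] || min(nx) > gx_rng[2] ||
      max(ny) < gy_rng[1] || min(ny) > gy_rng[2])
    stop("network and grid bounding boxes are disjoint; ",
         "check that both are in the same projected CRS", call. = FALSE)
  xy <- expand_centers(grid)
  n_cells <- length(xy$x)
  vals <- numeric(n_cells)
  fvals <- field$distance
  chunk <- max(1L, floor(2e6 / max(1, length(nx))))
  for (s in seq(1, n_cells, by = chunk)) {
    idx <- s:min(s + chunk - 1, n_cells)
    D2 <- outer(xy$x[idx], nx, "-")^2 + outer(xy$y[idx], ny, "-")^2
    k <- max.col(-D2, ties.method = "first")
    dmin <- sqrt(D2[cbind(seq_along(idx), k)])
    v <- fvals[k] + dmin * cost_per_meter
    v[dmin > off_network_radius] <- Inf
    vals[idx] <- v
  }
  grid_raster(grid, matrix(vals, nrow = grid$nrow, ncol = grid$ncol))
}

#' Reclassify a value raster onto the five-level scale
#'
#' Looks every cell up in the band table. Unreached cells (`Inf`) take level
#' 1; `NA` cells stay `NA` (masked). Negative values are an error: both
#' distances and slope magnitudes are non-negative by construction.
#'
#' @param values an `elev_raster` (or bare matrix) of variable values.
#' @param table a [reclass_table()] in the same units.
#' @return a `level_layer`: list with `$values` (integer matrix in 1..5),
#'   `$variable`, and the grid header fields.
#' @export
reclassify <- function(values, table) {
  stopifnot(inherits(table, "reclass_table"))
  hdr <- if (inherits(values, "elev_raster")) values else NULL
  m <- if (inherits(values, "elev_raster")) values$values else as.matrix(values)
  if (any(m < 0, na.rm = TRUE))
    stop("negative value passed to reclassify (", table$variable, ")",
         call. = FALSE)
  lv <- band_lookup(as.vector(m), table)
  out <- matrix(lv, nrow = nrow(m), ncol = ncol(m))
  structure(list(values = out, variable = table$variable,
                 xll = if (is.null(hdr)) 0 else hdr$xll,
                 yll = if (is.null(hdr)) 0 else hdr$yll,
                 cellsize = if (is.null(hdr)) 1 else hdr$cellsize),
            class = "level_layer")
}

band_lookup <- function(v, table) {
  b <- table$bands
  lv <- rep(NA_integer_, length(v))
  fin <- is.finite(v)
  if (table$closure == "left") {
    idx <- findInterval(v[fin], b$lower)                 # [lo, hi)
  } else {
    cuts <- b$upper[-nrow(b)]
    idx <- 1 + findInterval(v[fin], cuts, left.open = TRUE)  # (lo, hi]
  }
  idx[idx < 1] <- 1
  idx[idx > nrow(b)] <- nrow(b)   # beyond the last band: worst level
  lv[fin] <- b$level[idx]
  lv[is.infinite(v)] <- min(b$level)  # unreached
  lv
}

#' Weighted linear combination of level layers
#'
#' The overlay core: per-cell potential accessibility
#' `PA = sum_i w_i * r_i` over the reclassified layers, with the profile's
#' weights. Layer names must match the weight keys exactly and all layers
#' must share one grid header.
#'
#' @param layers named list of `level_layer` objects (names = variables).
#' @param weights a [profile_weights()] object.
#' @return an `accessibility_surface`: `$pa` (continuous matrix in `[1,5]`),
#'   `$class` (integer matrix, [quantize()]d), `$profile`, grid header.
#' @export
weighted_sum <- function(layers, weights) {
  stopifnot(inherits(weights, "profile_weights"))
  wk <- names(weights$weights)
  if (!setequal(names(layers), wk)) {
    missing <- setdiff(wk, names(layers))
    extra <- setdiff(names(layers), wk)
    stop("layer/weight mismatch",
         if (length(missing)) paste0("; missing layer(s): ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unweighted layer(s): ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  }
  ref <- layers[[1]]
  for (ly in layers[-1])
    if (!same_grid_header(as_header(ref), as_header(ly)) ||
        !identical(dim(ly$values), dim(ref$values)))
      stop("layers are not on the same grid", call. = FALSE)
  pa <- matrix(0, nrow = nrow(ref$values), ncol = ncol(ref$values))
  for (v in wk) pa <- pa + weights$weights[[v]] * layers[[v]]$values
  structure(list(pa = pa, class = quantize(pa), profile = weights$name,
                 xll = ref$xll, yll = ref$yll, cellsize = ref$cellsize),
            class = "accessibility_surface")
}

as_header <- function(ly) {
  list(xll = ly$xll, yll = ly$yll, cellsize = ly$cellsize,
       nrow = nrow(ly$values), ncol = ncol(ly$values))
}

#' @export
print.accessibility_surface <- function(x, ...) {
  cat(sprintf("<accessibility_surface> profile \"%s\", %d x %d cells\n",
              x$profile, nrow(x$pa), ncol(x$pa)))
  cat(sprintf("  PA mean %.3f, range [%.3f, %.3f]\n",
              mean(x$pa, na.rm = TRUE), min(x$pa, na.rm = TRUE),
              max(x$pa, na.rm = TRUE)))
  invisible(x)
}

#' Quantize continuous accessibility onto the five classes
#'
#' Nearest-integer rule with halves rounding up (PA 2.5 becomes class 3), so
#' the continuous weighted sum maps back onto the Very Low .. Very High
#' scale it was built from.
#'
#' @param pa numeric matrix/vector of PA values in `[1, 5]`.
#' @return integer matrix/vector of classes 1..5 (NA preserved).
#' @export
quantize <- function(pa) {
  eps <- 1e-9
  if (any(pa < 1 - eps | pa > 5 + eps, na.rm = TRUE))
    stop("PA values must lie in [1, 5]", call. = FALSE)
  cl <- floor(pmin(pmax(pa, 1), 5) + 0.5)
  storage.mode(cl) <- "integer"
  cl
}

#' Share of area per accessibility class
#'
#' Percentage of the (optionally masked) grid area in each of the five
#' classes. All five classes are always reported; absent classes get 0.
#'
#' @param classes integer matrix of classes 1..5, or an
#'   `accessibility_surface`.
#' @param grid the [analysis_grid()] (its mask, if any, restricts the area).
#' @return data.frame with columns `class`, `label`, `percent` (summing to
#'   100).
#' @export
area_summary <- function(classes, grid = NULL) {
  if (inherits(classes, "accessibility_surface")) classes <- classes$class
  keep <- !is.na(classes)
  if (!is.null(grid) && !is.null(grid$mask)) keep <- keep & grid$mask
  n <- sum(keep)
  if (n == 0) stop("no unmasked cells to summarize", call. = FALSE)
  tab <- tabulate(classes[keep], nbins = 5)
  data.frame(class = 1:5, label = unname(level_labels()),
             percent = 100 * tab / n)
}

#' Run the full accessibility model
#'
#' Orchestrates the pipeline for one or more profiles: network distance
#' fields to benches and to the service variables the profiles demand,
#' rasterization onto the analysis grid, slope from the DTM resampled onto
#' the grid, reclassification of every layer onto the five-level scale, the
#' profile-weighted sum, quantization, and the per-class area summary.
#' Distance layers are computed once and shared across profiles. The run is
#' fully deterministic given its inputs.
#'
#' @param net a `pedestrian_network` (gradients assigned if
#'   `metric = "minutes"` is to be meaningful).
#' @param dtm the elevation raster.
#' @param inventory a [load_inventory()] result.
#' @param grid an [analysis_grid()].
#' @param profile a profile name, a [profile_weights()] object, or a list of
#'   either.
#' @param tables reclassification tables, default [builtin_reclass_tables()].
#' @param metric edge cost metric for the distance fields, `"meters"`
#'   (default; the distance bands are in meters) or `"minutes"`.
#' @param model [speed_model()] for `metric = "minutes"`.
#' @param off_network_radius see [distance_raster()].
#' @param snap_radius source snap radius (m).
#' @return for a single profile, a list with `$surface`
#'   (`accessibility_surface`) and `$summary`; for several profiles, a named
#'   list of such results.
#' @export
run_model <- function(net, dtm, inventory, grid, profile = "healthy",
                      tables = builtin_reclass_tables(),
                      metric = c("meters", "minutes"), model = speed_model(),
                      off_network_radius = 100, snap_radius = 25) {
  metric <- match.arg(metric)
  single <- !is.list(profile) || inherits(profile, "profile_weights")
  profiles <- if (single) list(profile) else profile
  profiles <- lapply(profiles, resolve_profile)
  names(profiles) <- vapply(profiles, `[[`, character(1), "name")

  if (metric == "minutes")
    net <- stage("terrain", assign_gradients(net, dtm))

  vars <- unique(unlist(lapply(profiles, function(p)
    setdiff(names(p$weights), "slope"))))

  # with time costs, the meter-denominated band edges and the off-network
  # walk are converted at the moderate speed (m per minute)
  m_per_min <- model$moderate_speed * 1000 / 60
  cost_per_m <- if (metric == "minutes") 1 / m_per_min else 1
  use_tables <- tables
  if (metric == "minutes") {
    for (v in vars) {
      tb <- use_tables[[v]]
      tb$bands$lower <- tb$bands$lower / m_per_min
      tb$bands$upper <- tb$bands$upper / m_per_min
      use_tables[[v]] <- tb
    }
  }

  layers <- list()
  for (v in vars) {
    src <- stage("inventory", select_sources(inventory, v))
    fld <- stage("network", distance_field(net, src, metric = metric,
                                           model = model,
                                           snap_radius = snap_radius))
    rast <- stage("model", distance_raster(fld, net, grid, off_network_radius,
                                           cost_per_meter = cost_per_m))
    layers[[v]] <- stage("model", reclassify(rast, use_tables[[v]]))
  }
  slope_grid <- stage("terrain", resample_to_grid(slope_percent(dtm), grid))
  layers$slope <- stage("model", reclassify(slope_grid, tables$slope))

  res <- lapply(profiles, function(p) {
    surf <- stage("model", weighted_sum(layers[names(p$weights)], p))
    list(surface = surf, summary = area_summary(surf, grid))
  })
  if (single) res[[1]] else res
}

# tag stage errors with the pipeline stage that raised them
stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}
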
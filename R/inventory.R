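#' The five facility groups
#'
#' Neighborhood services and facilities are categorized into five fixed
#' groups: health services (medical and emergency services, pharmacies),
#' municipal services and amenities, social and cultural facilities,
#' shopping, and schools and childcare facilities.
#'
#' @return character vector of the five group names.
#' @export
facility_groups <- function() {
  c("health_services", "municipal", "social_cultural", "shopping",
    "schools_childcare")
}

#' The surveyed bench kinds
#'
#' Formal public benches, bus-stop benches, and informal seating (such as low
#' walls). All three kinds count as resting amenities: a bench usable to wait
#' for a bus is equally usable as a relay bench during a walk.
#'
#' @return character vector of the three kinds.
#' @export
bench_kinds <- function() c("formal", "bus_stop", "informal")

#' Load and validate a site inventory
#'
#' Builds the inventory of point amenities the accessibility model draws
#' proximity sources from: categorized facilities and benches.
#'
#' @param facility_features data.frame with columns `x`, `y`, `group`
#'   (one of [facility_groups()]) and optionally `id`, `subtype`, `zone`;
#'   or a GeoJSON path readable by [read_geojson_points()].
#' @param bench_features data.frame with columns `x`, `y` and optionally
#'   `id`, `kind` (one of [bench_kinds()], default `"formal"`), `zone`;
#'   or a GeoJSON path.
#' @return an object of class `site_inventory` with `$facilities` and
#'   `$benches` data.frames.
#' @export
load_inventory <- function(facility_features = NULL, bench_features = NULL) {
  fac <- normalize_points(facility_features)
  ben <- normalize_points(bench_features)

  if (nrow(fac) > 0) {
    if (is.null(fac$group)) stop("facilities need a 'group' property", call. = FALSE)
    bad <- setdiff(unique(fac$group), facility_groups())
    if (length(bad) > 0)
      stop("unknown facility group: \"", bad[1], "\" (expected one of ",
           paste(facility_groups(), collapse = ", "), ")", call. = FALSE)
  } else fac$group <- character(0)
  if (is.null(fac$subtype)) fac$subtype <- rep(NA_character_, nrow(fac))
  if (is.null(fac$zone)) fac$zone <- rep(NA_character_, nrow(fac))
  if (is.null(fac$id)) fac$id <- seq_len(nrow(fac))

  if (nrow(ben) > 0) {
    if (is.null(ben$kind)) ben$kind <- rep("formal", nrow(ben))
    bad <- setdiff(unique(ben$kind), bench_kinds())
    if (length(bad) > 0)
      stop("unknown bench kind: \"", bad[1], "\" (expected one of ",
           paste(bench_kinds(), collapse = ", "), ")", call. = FALSE)
  } else ben$kind <- character(0)
  if (is.null(ben$zone)) ben$zone <- rep(NA_character_, nrow(ben))
  if (is.null(ben$id)) ben$id <- seq_len(nrow(ben))

  if (anyDuplicated(fac$id)) stop("duplicate facility ids", call. = FALSE)
  if (anyDuplicated(ben$id)) stop("duplicate bench ids", call. = FALSE)

  keep_f <- intersect(c("id", "x", "y", "group", "subtype", "zone"), names(fac))
  keep_b <- intersect(c("id", "x", "y", "kind", "zone"), names(ben))
  structure(list(facilities = fac[keep_f], benches = ben[keep_b]),
            class = "site_inventory")
}

normalize_points <- function(features) {
  if (is.null(features))
    return(data.frame(x = numeric(0), y = numeric(0)))
  if (is.character(features) && length(features) == 1)
    features <- read_geojson_points(features)
  df <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(df) > 0 && (is.null(df$x) || is.null(df$y)))
    stop("point features need x and y columns", call. = FALSE)
  df
}

#' @export
print.site_inventory <- function(x, ...) {
  cat(sprintf("<site_inventory> %d facilities, %d benches\n",
              nrow(x$facilities), nrow(x$benches)))
  if (nrow(x$facilities) > 0)
    print(table(factor(x$facilities$group, levels = facility_groups())))
  invisible(x)
}

#' Facility counts per group for a zone
#'
#' Tallies the facility inventory by group for one zone label, in the layout
#' of a services-and-facilities census table (five groups plus a total).
#'
#' @param inv a [load_inventory()] result.
#' @param zone zone label; `NULL` counts the whole inventory.
#' @return named list: one count per facility group plus `total`.
#' @export
count_by_group <- function(inv, zone = NULL) {
  stopifnot(inherits(inv, "site_inventory"))
  fac <- inv$facilities
  if (!is.null(zone)) {
    if (!zone %in% fac$zone && !zone %in% inv$benches$zone)
      stop("unknown zone label: \"", zone, "\"", call. = FALSE)
    fac <- fac[!is.na(fac$zone) & fac$zone == zone, , drop = FALSE]
  }
  tab <- table(factor(fac$group, levels = facility_groups()))
  out <- as.list(as.integer(tab))
  names(out) <- facility_groups()
  out$total <- nrow(fac)
  out
}

#' Write group counts as CSV
#'
#' @param inv a [load_inventory()] result.
#' @param path output CSV path.
#' @param zones zone labels to tabulate (columns); default: all zones present.
#' @return `path`, invisibly.
#' @export
write_group_counts_csv <- function(inv, path, zones = NULL) {
  if (is.null(zones))
    zones <- sort(unique(stats::na.omit(c(inv$facilities$zone, inv$benches$zone))))
  if (length(zones) == 0) zones <- NA
  cols <- lapply(zones, function(z) {
    cnt <- count_by_group(inv, if (is.na(z)) NULL else z)
    unlist(cnt)
  })
  df <- data.frame(group = c(facility_groups(), "total"), do.call(cbind, cols))
  names(df) <- c("group", ifelse(is.na(zones), "all", zones))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Select proximity sources for a model variable
#'
#' Maps a model variable name onto the point set whose proximity it
#' measures: all benches (every kind counts as a resting place), the health
#' services group alone, the other four groups, or all five groups.
#'
#' @param inv a [load_inventory()] result.
#' @param variable one of `"benches"`, `"health_services"`,
#'   `"other_services"`, `"all_services"`.
#' @return data.frame of source coordinates (`x`, `y`).
#' @export
select_sources <- function(inv, variable = c("benches", "health_services",
                                             "other_services", "all_services")) {
  stopifnot(inherits(inv, "site_inventory"))
  variable <- match.arg(variable)
  pts <- switch(variable,
    benches = inv$benches[c("x", "y")],
    health_services = inv$facilities[inv$facilities$group == "health_services",
                                     c("x", "y")],
    other_services = inv$facilities[inv$facilities$group != "health_services",
                                    c("x", "y")],
    all_services = inv$facilities[c("x", "y")]
  )
  if (nrow(pts) == 0)
    stop("no source sites for variable \"", variable, "\"", call. = FALSE)
  rownames(pts) <- NULL
  pts
}
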
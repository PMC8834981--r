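test_that("built-in profiles carry the published weight vectors", {
  p <- builtin_profiles()
  expect_equal(unname(p$healthy$weights[c("benches", "all_services", "slope")]),
               c(0.45, 0.45, 0.10))
  expect_equal(unname(p$chronic_disease$weights[
    c("benches", "health_services", "other_services", "slope")]),
    c(0.30, 0.40, 0.10, 0.20))
  expect_equal(unname(p$reduced_mobility$weights[
    c("benches", "all_services", "slope")]),
    c(0.30, 0.30, 0.40))
  expect_true(p$chronic_disease$split_services)
  expect_false(p$healthy$split_services)
  for (pw in p) expect_equal(sum(pw$weights), 1)
})

test_that("profile_weights validates its invariants", {
  expect_error(profile_weights("x", c(benches = 0.6, all_services = 0.6,
                                      slope = 0.1)), "sum to 1")
  expect_error(profile_weights("x", c(benches = 1.2, all_services = -0.3,
                                      slope = 0.1)), ">= 0")
  expect_error(profile_weights("x", c(benches = 0.5, slope = 0.5)),
               "all_services")
})

band_level <- function(v, table) {
  reclassify(matrix(v, 1, 1), table)$values[1, 1]
}

test_that("built-in reclass tables encode the printed bands", {
  tb <- builtin_reclass_tables()
  # benches: 50 m -> Very High; services: 400 m -> Moderate; slope 4% -> High
  expect_equal(band_level(50, tb$benches), 5)
  expect_equal(band_level(400, tb$all_services), 3)
  expect_equal(band_level(4, tb$slope), 4)
  # distance bands are [lo, hi): exactly 100 m falls in the next band
  expect_equal(band_level(100, tb$benches), 4)
  # slope bands are (lo, hi]: 5.00% is still High, 5.01% Moderate
  expect_equal(band_level(5, tb$slope), 4)
  expect_equal(band_level(5.01, tb$slope), 3)
  expect_equal(band_level(12.5, tb$slope), 1)
})

test_that("reclassify maps bands, the out-of-range rule, and unreached cells", {
  tb <- builtin_reclass_tables()
  vals <- matrix(c(400, 1500, Inf, 0), 2, 2)
  ly <- reclassify(elev_raster(vals, cellsize = 5), tb$benches)
  expect_equal(ly$values, matrix(c(3L, 1L, 1L, 5L), 2, 2))
  expect_error(reclassify(matrix(-5, 1, 1), tb$benches), "negative")
  # NA (masked) cells survive
  ly2 <- reclassify(matrix(c(NA, 10), 1, 2), tb$benches)
  expect_equal(ly2$values[1, ], c(NA_integer_, 5L))
})

test_that("weighted_sum computes the worked PA combinations", {
  mk_layer <- function(v, name) reclassify(matrix(v, 1, 1),
    builtin_reclass_tables()[[name]])
  lv <- function(level, name) {
    ly <- mk_layer(0, name); ly$values[] <- level; ly
  }
  p <- builtin_profiles()

  s1 <- weighted_sum(list(benches = lv(5, "benches"),
                          all_services = lv(3, "all_services"),
                          slope = lv(1, "slope")), p$healthy)
  expect_equal(s1$pa[1, 1], 0.45 * 5 + 0.45 * 3 + 0.10 * 1)
  expect_equal(s1$pa[1, 1], 3.70)
  expect_equal(s1$class[1, 1], 4L)

  s2 <- weighted_sum(list(benches = lv(2, "benches"),
                          health_services = lv(5, "health_services"),
                          other_services = lv(1, "other_services"),
                          slope = lv(4, "slope")), p$chronic_disease)
  expect_equal(s2$pa[1, 1], 3.50)

  # all layers at 5 under any valid weights stay at 5
  s3 <- weighted_sum(list(benches = lv(5, "benches"),
                          all_services = lv(5, "all_services"),
                          slope = lv(5, "slope")), p$reduced_mobility)
  expect_equal(s3$pa[1, 1], 5)

  expect_error(weighted_sum(list(benches = lv(5, "benches")), p$healthy),
               "missing layer")
})

test_that("quantize rounds to the nearest class with ties up", {
  expect_equal(quantize(3.70), 4L)
  expect_equal(quantize(2.5), 3L)
  expect_equal(quantize(5.0), 5L)
  expect_equal(quantize(1.49), 1L)
  expect_error(quantize(0.7), "\\[1, 5\\]")
  expect_error(quantize(5.2), "\\[1, 5\\]")
})

test_that("area_summary reports all five classes over the unmasked area", {
  cls <- matrix(c(5L, 3L, 5L, 1L), 2, 2)
  sm <- area_summary(cls)
  expect_equal(sm$percent[sm$class == 5], 50)
  expect_equal(sm$percent[sm$class == 3], 25)
  expect_equal(sm$percent[sm$class == 1], 25)
  expect_equal(sm$percent[sm$class %in% c(2, 4)], c(0, 0))
  expect_equal(sum(sm$percent), 100)

  expect_equal(area_summary(matrix(2L, 3, 3))$percent[2], 100)

  g <- analysis_grid(0, 0, 2, 2, cellsize = 5,
                     mask = matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2))
  sm2 <- area_summary(cls, g)
  expect_equal(sm2$percent[sm2$class == 5], 100)  # kept cells are both 5
  g0 <- analysis_grid(0, 0, 2, 2, cellsize = 5, mask = matrix(FALSE, 2, 2))
  expect_error(area_summary(cls, g0), "no unmasked cells")
})

test_that("area percentages always sum to 100 under random classes/masks", {
  set.seed(77)
  for (rep in 1:10) {
    nr <- sample(3:12, 1); nc <- sample(3:12, 1)
    cls <- matrix(sample(1:5, nr * nc, replace = TRUE), nr, nc)
    mask <- matrix(runif(nr * nc) > 0.3, nr, nc)
    if (!any(mask)) mask[1, 1] <- TRUE
    g <- analysis_grid(0, 0, nr, nc, cellsize = 5, mask = mask)
    expect_equal(sum(area_summary(cls, g)$percent), 100, tolerance = 1e-9)
  }
})

test_that("PA is convex-bounded by the layer levels under random weights", {
  set.seed(123)
  tb <- builtin_reclass_tables()
  for (rep in 1:10) {
    nr <- 6; nc <- 7
    mk <- function(name) {
      ly <- reclassify(matrix(0, nr, nc), tb[[name]])
      ly$values <- matrix(sample(1:5, nr * nc, replace = TRUE), nr, nc)
      ly
    }
    layers <- list(benches = mk("benches"), all_services = mk("all_services"),
                   slope = mk("slope"))
    w <- runif(3); w <- w / sum(w)
    pw <- profile_weights("rand", c(benches = w[1], all_services = w[2],
                                    slope = w[3]))
    surf <- weighted_sum(layers, pw)
    lo <- pmin(layers$benches$values, layers$all_services$values,
               layers$slope$values)
    hi <- pmax(layers$benches$values, layers$all_services$values,
               layers$slope$values)
    expect_true(all(surf$pa >= lo - 1e-9 & surf$pa <= hi + 1e-9))
  }
})

test_that("a half-weight health/other split equals the unsplit run", {
  tb <- builtin_reclass_tables()
  set.seed(4)
  nr <- 5; nc <- 5
  svc <- matrix(sample(1:5, nr * nc, replace = TRUE), nr, nc)
  mk <- function(name, v) {
    ly <- reclassify(matrix(0, nr, nc), tb[[name]]); ly$values <- v; ly
  }
  bench <- matrix(sample(1:5, nr * nc, replace = TRUE), nr, nc)
  slope <- matrix(sample(1:5, nr * nc, replace = TRUE), nr, nc)
  w <- 0.5
  split <- weighted_sum(
    list(benches = mk("benches", bench),
         health_services = mk("health_services", svc),
         other_services = mk("other_services", svc),
         slope = mk("slope", slope)),
    profile_weights("split", c(benches = 0.3, health_services = w / 2,
                               other_services = w / 2, slope = 0.2)))
  unsplit <- weighted_sum(
    list(benches = mk("benches", bench), all_services = mk("all_services", svc),
         slope = mk("slope", slope)),
    profile_weights("unsplit", c(benches = 0.3, all_services = w, slope = 0.2)))
  expect_equal(split$pa, unsplit$pa, tolerance = 1e-12)
})

test_that("distance_raster adds the off-network walk to the nearest node", {
  net <- build_network(square_town_lines(2, 100))  # 3x3 nodes at 2000+
  fld <- distance_field(net, cbind(2000, 2000))
  grid <- grid_from_extent(2000, 2000, 2200, 2200, cellsize = 5)
  dr <- distance_raster(fld, net, grid)
  xy <- agewalk:::expand_centers(grid)
  v <- as.vector(dr$values)
  # cell center nearest the source corner: field 0 + small diagonal offset
  i0 <- which.min((xy$x - 2000)^2 + (xy$y - 2000)^2)
  expect_equal(v[i0], sqrt(2 * 2.5^2), tolerance = 1e-9)
  # cell at (2102.5, 2002.5): nearest node (2100,2000), field 100
  i1 <- which.min((xy$x - 2102.5)^2 + (xy$y - 2002.5)^2)
  expect_equal(v[i1], 100 + sqrt(2.5^2 + 2.5^2), tolerance = 1e-9)
})

test_that("cells beyond the off-network radius are unreached", {
  net <- build_network(list(cbind(x = c(2000, 2100), y = c(2000, 2000))))
  fld <- distance_field(net, cbind(2000, 2000))
  grid <- grid_from_extent(2000, 1500, 2100, 2000, cellsize = 5)
  dr <- distance_raster(fld, net, grid, off_network_radius = 100)
  expect_true(any(is.infinite(dr$values)))
  tb <- builtin_reclass_tables()
  ly <- reclassify(dr, tb$benches)
  expect_true(all(ly$values[is.infinite(dr$values)] == 1L))
})

test_that("distance_raster rejects disjoint grid/network boxes", {
  net <- build_network(list(cbind(x = c(2000, 2100), y = c(2000, 2000))))
  fld <- distance_field(net, cbind(2000, 2000))
  far <- grid_from_extent(9000, 9000, 9100, 9100, cellsize = 5)
  expect_error(distance_raster(fld, net, far), "CRS")
})

test_that("run_model saturates when every corner has every amenity", {
  lines <- square_town_lines(2, 100)
  net <- build_network(lines)
  nodes <- net$nodes
  fac <- do.call(rbind, lapply(facility_groups(), function(g)
    data.frame(x = nodes$x, y = nodes$y, group = g)))
  fac$id <- seq_len(nrow(fac))
  inv <- load_inventory(fac, data.frame(x = nodes$x, y = nodes$y))
  dtm <- flat_dtm(200, origin = c(2000, 2000), size = 200)
  grid <- grid_from_extent(2000, 2000, 2200, 2200, cellsize = 5)
  res <- run_model(net, dtm, inv, grid, profile = "healthy")
  expect_true(all(res$surface$class == 5L))
  expect_equal(res$summary$percent[res$summary$class == 5], 100)
})

test_that("PA never increases with network distance from a lone amenity corner", {
  lines <- square_town_lines(4, 100)
  net <- build_network(lines)
  fac <- data.frame(x = 2000, y = 2000, group = "shopping")
  inv <- load_inventory(fac, data.frame(x = 2000, y = 2000))
  dtm <- flat_dtm(200, origin = c(2000, 2000), size = 400)
  grid <- grid_from_extent(2000, 2000, 2400, 2400, cellsize = 20)
  res <- run_model(net, dtm, inv, grid, profile = "healthy")
  fld <- distance_field(net, cbind(2000, 2000))
  dr <- distance_raster(fld, net, grid)
  o <- order(as.vector(dr$values))
  pa_sorted <- as.vector(res$surface$pa)[o]
  expect_true(all(diff(pa_sorted) <= 1e-9))
})

test_that("an isolated far-away health facility yields a uniform level-1 layer", {
  lines <- c(square_town_lines(2, 100),
             list(cbind(x = c(2000, 2000), y = c(2000, 500)))) # 1500 m spur
  net <- build_network(lines)
  fac <- data.frame(x = c(2000, 2100), y = c(500, 2100),
                    group = c("health_services", "shopping"))
  inv <- load_inventory(fac, data.frame(x = 2100, y = 2100))
  dtm <- flat_dtm(200, origin = c(2000, 500), size = 1800)
  grid <- grid_from_extent(2000, 2000, 2200, 2200, cellsize = 10)
  src <- select_sources(inv, "health_services")
  fld <- distance_field(net, src)
  dr <- distance_raster(fld, net, grid)
  ly <- reclassify(dr, builtin_reclass_tables()$health_services)
  expect_true(all(ly$values == 1L))
})

test_that("adding a bench never decreases any cell's bench level", {
  set.seed(55)
  net <- build_network(square_town_lines(4, 100))
  grid <- grid_from_extent(2000, 2000, 2400, 2400, cellsize = 25)
  tb <- builtin_reclass_tables()$benches
  benches <- data.frame(x = c(2100, 2350), y = c(2000, 2400))
  lv0 <- reclassify(distance_raster(
    distance_field(net, benches), net, grid), tb)
  for (rep in 1:3) {
    extra <- data.frame(x = 2000 + round(runif(1, 0, 400)),
                        y = 2000 + round(runif(1, 0, 4)) * 100)
    lv1 <- reclassify(distance_raster(
      distance_field(net, rbind(benches, extra)), net, grid), tb)
    expect_true(all(lv1$values >= lv0$values))
  }
})

test_that("run_model PA equals a brute-force per-cell recomputation", {
  # square town, amenities pinned to intersections so the oracle can work
  # from the node-level Bellman-Ford field directly
  lines <- square_town_lines(4, 100)  # 5x5 nodes, 400 m extent
  net <- build_network(lines)
  nodes <- net$nodes
  set.seed(99)
  bench_nodes <- sample.int(25, 4)
  health_nodes <- sample.int(25, 2)
  other_nodes <- sample.int(25, 3)
  fac <- rbind(
    data.frame(x = nodes$x[health_nodes], y = nodes$y[health_nodes],
               group = "health_services"),
    data.frame(x = nodes$x[other_nodes], y = nodes$y[other_nodes],
               group = "shopping"))
  fac$id <- seq_len(nrow(fac))
  inv <- load_inventory(fac, data.frame(x = nodes$x[bench_nodes],
                                        y = nodes$y[bench_nodes]))
  # gentle ramp terrain: z = 200 + 0.04 (x - 2000)
  cs <- 25; n <- 20
  xc <- 1950 + (seq_len(n) - 0.5) * cs
  dtm <- elev_raster(matrix(200 + 0.04 * (xc - 2000), n, n, byrow = TRUE),
                     xll = 1950, yll = 1950, cellsize = cs)
  grid <- grid_from_extent(2000, 2000, 2400, 2400, cellsize = 20)  # 20x20
  res <- run_model(net, dtm, inv, grid,
                   profile = list("healthy", "chronic_disease"))

  # ---- independent recomputation -------------------------------------
  bf_field <- function(src_nodes)
    bf_distances(25, net$edges$from, net$edges$to, net$edges$length, src_nodes)
  fields <- list(benches = bf_field(bench_nodes),
                 health_services = bf_field(health_nodes),
                 other_services = bf_field(other_nodes),
                 all_services = bf_field(c(health_nodes, other_nodes)))
  xy <- agewalk:::expand_centers(grid)
  cell_value <- function(fld, cx, cy) {
    d2 <- (nodes$x - cx)^2 + (nodes$y - cy)^2
    k <- which.min(d2)
    if (sqrt(d2[k]) > 100) return(Inf)
    fld[k] + sqrt(d2[k])
  }
  n_cells <- length(xy$x)
  pa_h <- pa_c <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    rb <- oracle_bench_level(cell_value(fields$benches, xy$x[i], xy$y[i]))
    ra <- oracle_service_level(cell_value(fields$all_services, xy$x[i], xy$y[i]))
    rh <- oracle_service_level(cell_value(fields$health_services, xy$x[i], xy$y[i]))
    ro <- oracle_service_level(cell_value(fields$other_services, xy$x[i], xy$y[i]))
    rs <- oracle_slope_level(4)  # uniform 4% ramp
    pa_h[i] <- 0.45 * rb + 0.45 * ra + 0.10 * rs
    pa_c[i] <- 0.30 * rb + 0.40 * rh + 0.10 * ro + 0.20 * rs
  }
  expect_equal(as.vector(res$healthy$surface$pa), pa_h, tolerance = 1e-9)
  expect_equal(as.vector(res$chronic_disease$surface$pa), pa_c,
               tolerance = 1e-9)
})

test_that("meters and minutes metrics agree on flat terrain", {
  net <- build_network(square_town_lines(3, 100))
  inv <- load_inventory(
    data.frame(x = 2000, y = 2000, group = "shopping"),
    data.frame(x = 2300, y = 2300))
  dtm <- flat_dtm(150, origin = c(2000, 2000), size = 300)
  grid <- grid_from_extent(2000, 2000, 2300, 2300, cellsize = 20)
  rm_m <- run_model(net, dtm, inv, grid, profile = "healthy", metric = "meters")
  rm_t <- run_model(net, dtm, inv, grid, profile = "healthy", metric = "minutes")
  expect_equal(rm_m$surface$pa, rm_t$surface$pa, tolerance = 1e-9)
})
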
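test_that("the raster loader returns the full 9 x 12 stack", {
  r <- generate_rasters(raster_spec(n_rows = 8, n_cols = 10), dir = tempfile())
  layers <- load_layers(r$dir)
  expect_length(layers, 108L)
  expect_setequal(unique(vapply(layers, function(l) l$variable, "")),
                  climate_variables())
  # a single elevation grid is replicated across months
  d2 <- tempfile(); dir.create(d2)
  file.copy(list.files(r$dir, full.names = TRUE), d2)
  file.rename(file.path(d2, "elevation_01.asc"), file.path(d2, "elevation.asc"))
  file.remove(file.path(d2, sprintf("elevation_%02d.asc", 2:12)))
  layers2 <- load_layers(d2)
  expect_length(layers2, 108L)
  elev <- Filter(function(l) l$variable == "elevation", layers2)
  expect_true(all(vapply(elev, function(l) identical(l$grid, elev[[1]]$grid),
                         TRUE)))
})

test_that("gaps and mixed shapes in the raster stack are named errors", {
  r <- generate_rasters(raster_spec(n_rows = 5, n_cols = 5), dir = tempfile())
  file.remove(file.path(r$dir, "wind_speed_07.asc"))
  expect_error(load_layers(r$dir), "wind_speed.*7")
  r2 <- generate_rasters(raster_spec(n_rows = 5, n_cols = 5), dir = tempfile())
  small <- bioexplore:::new_climate_layer("temp_avg", 3, matrix(1, 2, 2),
                                          -10, 55, 0.25, 0.25)
  write_ascii_grid(small, file.path(r2$dir, "temp_avg_03.asc"))
  expect_error(load_layers(r2$dir), "shape")
})

test_that("ascii grids round-trip through write and read", {
  lay <- constant_layer(0, n = 6)
  set.seed(3)
  lay$grid <- matrix(rnorm(36), 6, 6)
  p <- tempfile(fileext = ".asc")
  write_ascii_grid(lay, p)
  back <- read_ascii_grid(p, variable = "temp_avg", month = 1)
  expect_equal(back$grid, lay$grid)
  expect_equal(back$origin_lon, lay$origin_lon)
  expect_equal(back$origin_lat, lay$origin_lat)
})

test_that("hex binning conserves points and matches nearest-centre oracle", {
  expect_error(hexbin_occurrences(matrix(numeric(), 0, 2), 1), "no occurrence")
  one <- hexbin_occurrences(cbind(0.1, 0.1), 1)
  expect_length(one, 1L)
  expect_equal(one[[1]]$occurrence_count, 1L)

  pts <- as.matrix(generate_occurrences(1000, n_clusters = 4, seed = 21)[
    , c("decimalLongitude", "decimalLatitude")])
  zones <- hexbin_occurrences(pts, 1)
  expect_equal(sum(vapply(zones, function(z) z$occurrence_count, 1L)),
               1000L)
  impl_key <- vapply(zones, function(z) sub("^hex_", "", z$zone_id), "")
  impl_key <- sub("_", ":", impl_key)
  oracle <- oracle_hex_assign(pts, 1)
  otab <- table(oracle)
  expect_setequal(impl_key, names(otab))
  counts <- vapply(zones, function(z) z$occurrence_count, 1L)
  expect_equal(counts[match(names(otab), impl_key)],
               as.integer(otab), ignore_attr = TRUE)
})

test_that("zonal values are the cells inside the polygon", {
  lay <- constant_layer(7, n = 10)  # 10x10 grid, 1-degree cells, lon 0..10
  z <- square_zone(1.2, 3.2, 3.4, 5.4)  # covers centres (1.5,2.5)x(3.5,4.5)
  expect_equal(zonal_values(z, lay), rep(7, 4))
  # all-nodata region
  lay2 <- lay; lay2$grid[, ] <- lay2$nodata
  expect_length(zonal_values(z, lay2), 0L)
  # entirely outside extent
  expect_length(zonal_values(square_zone(50, 52, 3, 5), lay), 0L)
  # antimeridian-crossing polygons are refused
  expect_error(zonal_values(square_zone(-179, 179, 0, 1), lay),
               "antimeridian")
  # random polygons agree with an exhaustive centre scan
  set.seed(14)
  for (i in 1:5) {
    lay$grid <- matrix(rnorm(100), 10, 10)
    ring <- cbind(runif(5, 0, 10), runif(5, 0, 10))
    hull <- chull(ring)
    z <- list(zone_id = "r", polygon = rbind(ring[hull, ], ring[hull[1], ]),
              occurrence_count = 1L)
    got <- sort(zonal_values(z, lay))
    cc <- bioexplore:::cell_centres(lay)
    lon <- rep(cc$lon, each = 10); lat <- rep(cc$lat, times = 10)
    want <- sort(as.vector(lay$grid)[
      oracle_pip(lon, lat, ring[hull, , drop = FALSE])])
    expect_equal(got, want)
  }
})

test_that("planted monthly means recover the annual mean and range", {
  r <- generate_rasters(raster_spec(n_rows = 12, n_cols = 12,
                                    base_values = 1:12),
                        dir = tempfile())
  layers <- load_layers(r$dir)
  zones <- list(square_zone(-9.9, -8.1, 53.1, 54.9))
  cs <- climate_summary(zones, layers)
  expect_equal(unname(cs$annual_mean), rep(6.5, 9))
  expect_equal(unname(cs$range_min), rep(1, 9))
  expect_equal(unname(cs$range_max), rep(12, 9))
  expect_false(any(cs$missing))
})

test_that("summary is invariant to zone order and duplication", {
  r <- generate_rasters(raster_spec(gradient_amplitude = 30, seed = 2),
                        dir = tempfile())
  layers <- load_layers(r$dir)
  occ <- generate_occurrences(300, seed = 3)
  zones <- hexbin_occurrences(occ, 0.7)
  cs <- climate_summary(zones, layers)
  cs_rev <- climate_summary(rev(zones), layers)
  cs_dup <- climate_summary(c(zones, zones[1]), layers)
  expect_equal(cs_rev$monthly, cs$monthly)
  expect_equal(cs_dup$monthly, cs$monthly)
  expect_equal(cs_dup$n_cells, cs$n_cells)
})

test_that("affine rescaling of the grids rescales the summary", {
  r <- generate_rasters(raster_spec(n_rows = 15, n_cols = 15,
                                    gradient_amplitude = 10),
                        dir = tempfile())
  layers <- load_layers(r$dir)
  zones <- list(square_zone(-9.5, -7.5, 52, 54))
  cs <- climate_summary(zones, layers)
  a <- 2.5; b <- -3
  scaled <- lapply(layers, function(l) { l$grid <- a * l$grid + b; l })
  cs2 <- climate_summary(zones, scaled)
  expect_equal(cs2$annual_mean, a * cs$annual_mean + b, tolerance = 1e-12)
  expect_equal(cs2$range_min, a * cs$range_min + b, tolerance = 1e-12)
  expect_equal(cs2$range_max, a * cs$range_max + b, tolerance = 1e-12)
})

test_that("monthly means bound the range and match the brute-force oracle", {
  for (seed in 1:6) {
    r <- generate_rasters(raster_spec(n_rows = 20, n_cols = 25,
                                      gradient_amplitude = 25,
                                      nodata_fraction = 0.1, seed = seed),
                          dir = tempfile())
    layers <- load_layers(r$dir)
    occ <- generate_occurrences(150, n_clusters = 2, seed = seed + 100)
    zones <- hexbin_occurrences(occ, 0.8)
    cs <- climate_summary(zones, layers)
    want <- oracle_climate_monthly(zones, layers)
    expect_equal(cs$monthly, want, tolerance = 1e-9, ignore_attr = TRUE)
    for (v in climate_variables()) {
      mm <- cs$monthly[v, ]
      expect_true(all(mm >= cs$range_min[v] - 1e-12, na.rm = TRUE))
      expect_true(all(mm <= cs$range_max[v] + 1e-12, na.rm = TRUE))
    }
  }
})

test_that("zones with no valid cells flag variables missing, not zero", {
  layers <- constant_stack(rep(5, 12), n = 10)
  # poke nodata into one variable everywhere
  layers <- lapply(layers, function(l) {
    if (l$variable == "wind_speed") l$grid[, ] <- l$nodata
    l
  })
  cs <- climate_summary(list(square_zone(1, 4, 4, 8)), layers)
  expect_true(cs$missing[["wind_speed"]])
  expect_true(is.na(cs$annual_mean[["wind_speed"]]))
  expect_false(any(cs$missing[names(cs$missing) != "wind_speed"]))
  # everything nodata is an error
  dead <- lapply(constant_stack(rep(5, 12), n = 4), function(l) {
    l$grid[, ] <- l$nodata; l
  })
  expect_error(climate_summary(list(square_zone(1, 3, 7, 9)), dead),
               "no variable")
})

test_that("geojson zones round-trip", {
  zones <- hexbin_occurrences(generate_occurrences(50, seed = 8), 1)
  p <- tempfile(fileext = ".geojson")
  write_zones_geojson(zones, p)
  back <- read_zones_geojson(p)
  expect_length(back, length(zones))
  expect_equal(vapply(back, function(z) z$zone_id, ""),
               vapply(zones, function(z) z$zone_id, ""))
  expect_equal(back[[1]]$polygon, zones[[1]]$polygon,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sum(vapply(back, function(z) z$occurrence_count, 1L)), 50L)
})
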
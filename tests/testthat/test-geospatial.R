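test_that("ESRI ASCII grids round-trip exactly, including nodata", {
  vals <- matrix(c(1.5, 2.25, -3, NA, 0.001, 7e5, -0.125, 42, 9), 3, 3)
  lay <- raster_layer(vals, xllcorner = 10, yllcorner = -5, cellsize = 0.5)
  p <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(lay, p)
  back <- read_ascii_grid(p)
  expect_equal(unclass(back)[, ], unclass(lay)[, ])
  expect_equal(attr(back, "cellsize"), 0.5)
  expect_equal(attr(back, "xllcorner"), 10)
  expect_true(is.na(back[1, 2]))
  # header text is the 6-key ESRI block
  hdr <- readLines(p, n = 6)
  expect_match(hdr[1], "^ncols 3$")
  expect_match(hdr[6], "^NODATA_value")
})

test_that("malformed ASCII grids error with the offending line", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "1 2", "3"), p)
  expect_error(read_ascii_grid(p), "row at line 8")
  writeLines(c("ncols 2", "nrows 2", "xllcorner zero", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "1 2", "3 4"), p)
  expect_error(read_ascii_grid(p), "line 3")
  writeLines(c("ncols 2"), p)
  expect_error(read_ascii_grid(p), "too short")
})

test_that("temperature grids round-trip through 24 ASCII layers", {
  grid <- gen_temperature_grid(synthetic_grid_spec(n_rows = 4, n_cols = 3))
  dir <- withr::local_tempdir()
  write_temperature_grid(grid, dir)
  expect_length(list.files(dir, pattern = "\\.asc$"), 24)
  back <- read_temperature_grid(dir)
  expect_equal(back$tmin, grid$tmin)
  expect_equal(back$tmax, grid$tmax)
  expect_equal(back$cellsize, grid$cellsize)
})

test_that("area tabulation matches closed-form spherical band areas", {
  # 1-degree toy globe band from the equator to 60N, one class
  nr <- 60; nc <- 360
  lay <- raster_layer(matrix(0.5, nr, nc), xllcorner = -180, yllcorner = 0,
                      cellsize = 1, index_kind = "eri")
  tab <- tabulate_area(lay)
  expect_equal(nrow(dplyr::filter(tab, area_km2 > 0)), 1)
  total <- sum(tab$area_km2)
  R <- 111.32 * 180 / pi
  sphere <- 2 * pi * R^2 * (sin(60 * pi / 180) - sin(0))
  expect_equal(total, sphere, tolerance = 5e-3)
  expect_equal(sum(tab$pct_of_region_total), 100, tolerance = 1e-9)
})

test_that("symmetric bands about the equator have equal areas", {
  cls <- matrix(3, 20, 5)
  lay <- raster_layer(cls, xllcorner = 0, yllcorner = -10, cellsize = 1,
                      index_kind = "eri_class")
  mask <- raster_layer(matrix(rep(c(1, 2), each = 10), 20, 5),
                       xllcorner = 0, yllcorner = -10, cellsize = 1)
  tab <- tabulate_area(lay, mask)
  totals <- attr(tab, "region_totals")
  expect_equal(unname(totals["1"]), unname(totals["2"]))
  expect_equal(unname(dplyr::filter(
    tab, region == "1", eri_class == "suitable")$pct_of_region_total), 100)
})

test_that("change maps difference cellwise with nodata propagation and additivity", {
  base <- raster_layer(matrix(runif(12), 3, 4), 0, 0, 1, index_kind = "eri")
  same <- change_map(base, base)
  expect_true(all(unclass(same) == 0))
  shifted <- raster_layer(unclass(base) + 0.05, 0, 0, 1, index_kind = "eri")
  ch <- change_map(base, shifted)
  expect_equal(unique(round(as.vector(ch), 12)), 0.05)
  # nodata in either input is nodata out
  holed <- base; holed[2, 2] <- NA
  expect_true(is.na(change_map(base, holed)[2, 2]))
  # additivity of successive changes
  f1 <- raster_layer(unclass(base) + 0.1, 0, 0, 1, index_kind = "eri")
  f2 <- raster_layer(unclass(base) - 0.2, 0, 0, 1, index_kind = "eri")
  lhs <- unclass(change_map(base, f1)) + unclass(change_map(f1, f2))
  expect_equal(lhs[, ], unclass(change_map(base, f2))[, ], tolerance = 1e-12)
  other <- raster_layer(matrix(1, 3, 4), 0, 0, 1, index_kind = "gi")
  expect_error(change_map(base, other), "kind mismatch")
  moved <- raster_layer(unclass(base), 5, 0, 1, index_kind = "eri")
  expect_error(change_map(base, moved), "georeferencing")
})

test_that("scenario area bookkeeping conserves totals", {
  mk <- function(areas) {
    area_table(tibble::tibble(region = "toy",
                              eri_class = c("unsuitable", "suitable", "optimal"),
                              area_km2 = areas))
  }
  cur <- mk(c(100, 500, 400)); fut <- mk(c(200, 450, 350))
  expect_true(all(area_change_summary(cur, cur)$gain_km2 == 0))
  ch <- area_change_summary(cur, fut)
  expect_equal(sum(ch$gain_km2), 0)
  expect_equal(sum(ch$gain_pct), 0, tolerance = 1e-12)
  expect_error(area_change_summary(cur, area_table(tibble::tibble(
    region = "elsewhere", eri_class = "suitable", area_km2 = 1))), "region sets")
})

test_that("map_indices propagates nodata and is constant on uniform climates", {
  model <- gen_phenology_model(synthetic_phenology_spec())
  tmin <- array(16, c(2, 2, 12)); tmax <- array(26, c(2, 2, 12))
  tmin[2, 1, ] <- NA; tmax[2, 1, ] <- NA
  grid <- temperature_grid(tmin, tmax, 0, 0, 1)
  rmap <- map_indices(grid, model)
  cells <- rmap$cells
  valid <- dplyr::filter(cells, !(row == 2 & col == 1))
  expect_equal(length(unique(valid$eri)), 1)
  expect_equal(length(unique(valid$gi)), 1)
  masked <- dplyr::filter(cells, row == 2, col == 1)
  expect_true(is.na(masked$eri) && is.na(masked$gi) && is.na(masked$ai))
  expect_true(is.na(rmap$layers$eri[2, 1]))
})
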
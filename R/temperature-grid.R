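#' Monthly minimum/maximum temperature grids
#'
#' A `temperature_grid` holds 12 monthly-minimum and 12 monthly-maximum
#' layers on a shared georeference, stored as `nrow x ncol x 12` arrays
#' (rows top-down). This is the in-memory form of the WorldClim-style
#' monthly min/max rasters the risk pipeline consumes.
#'
#' @param tmin,tmax Numeric arrays `nrow x ncol x 12` (deg C), `NA` for
#'   nodata. `tmax` must be >= `tmin` wherever both are valid.
#' @inheritParams raster_layer
#' @return An object of class `temperature_grid`.
#' @export
temperature_grid <- function(tmin, tmax, xllcorner, yllcorner, cellsize,
                             nodata = -9999) {
  stopifnot(length(dim(tmin)) == 3, dim(tmin)[3] == 12,
            identical(dim(tmin), dim(tmax)))
  bad <- which(tmax < tmin)
  if (length(bad) > 0) {
    abort(sprintf("temperature_grid: tmax < tmin at %d cell-months", length(bad)))
  }
  structure(list(tmin = tmin, tmax = tmax,
                 xllcorner = as.numeric(xllcorner),
                 yllcorner = as.numeric(yllcorner),
                 cellsize = as.numeric(cellsize),
                 nodata = as.numeric(nodata)),
            class = "temperature_grid")
}

grid_dim <- function(grid) dim(grid$tmin)[1:2]

grid_layer <- function(grid, which = c("tmin", "tmax"), month) {
  which <- match.arg(which)
  raster_layer(grid[[which]][, , month, drop = TRUE],
               grid$xllcorner, grid$yllcorner, grid$cellsize, grid$nodata)
}

#' @export
print.temperature_grid <- function(x, ...) {
  d <- grid_dim(x)
  cat(sprintf("<temperature_grid %dx%d cells, 12 months, cellsize %g deg>\n",
              d[1], d[2], x$cellsize))
  cat(sprintf("  tmin range: [%.2f, %.2f] degC; tmax range: [%.2f, %.2f] degC\n",
              min(x$tmin, na.rm = TRUE), max(x$tmin, na.rm = TRUE),
              min(x$tmax, na.rm = TRUE), max(x$tmax, na.rm = TRUE)))
  invisible(x)
}

#' @rdname temperature_grid
#' @param x A `temperature_grid`.
#' @param ... Unused.
#' @return `as_tibble()` returns one row per cell-month with columns
#'   `row`, `col`, `lon`, `lat`, `month`, `tmin`, `tmax`.
#' @export
as_tibble.temperature_grid <- function(x, ...) {
  d <- grid_dim(x)
  lay <- grid_layer(x, "tmin", 1)
  lat <- layer_lat_centers(lay); lon <- layer_lon_centers(lay)
  tibble(
    row = rep(seq_len(d[1]), times = d[2] * 12),
    col = rep(rep(seq_len(d[2]), each = d[1]), times = 12),
    lon = rep(rep(lon, each = d[1]), times = 12),
    lat = rep(lat, times = d[2] * 12),
    month = rep(1:12, each = d[1] * d[2]),
    tmin = as.vector(x$tmin),
    tmax = as.vector(x$tmax)
  )
}

#' Read and write a temperature grid as 24 ESRI ASCII files
#'
#' Files are named `<prefix>tmin_01.asc` ... `<prefix>tmax_12.asc` in
#' `dir`. All 24 layers must share georeferencing.
#'
#' @param grid A [temperature_grid()].
#' @param dir Directory for the 24 `.asc` files (created if absent).
#' @param prefix Optional filename prefix (default "").
#' @return `write_temperature_grid()` returns the vector of file paths
#'   invisibly; `read_temperature_grid()` returns a [temperature_grid()].
#' @export
write_temperature_grid <- function(grid, dir, prefix = "") {
  stopifnot(inherits(grid, "temperature_grid"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (which in c("tmin", "tmax")) {
    for (m in 1:12) {
      p <- file.path(dir, sprintf("%s%s_%02d.asc", prefix, which, m))
      write_ascii_grid(grid_layer(grid, which, m), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' @rdname write_temperature_grid
#' @export
read_temperature_grid <- function(dir, prefix = "") {
  read_set <- function(which) {
    lapply(1:12, function(m) {
      p <- file.path(dir, sprintf("%s%s_%02d.asc", prefix, which, m))
      if (!file.exists(p)) abort(sprintf("missing layer file: %s", p))
      read_ascii_grid(p)
    })
  }
  mins <- read_set("tmin"); maxs <- read_set("tmax")
  ref <- mins[[1]]
  for (l in c(mins, maxs)) {
    if (!same_georef(ref, l)) abort("temperature layers disagree in georeferencing")
  }
  d <- dim(ref)
  tmin <- array(NA_real_, c(d, 12)); tmax <- array(NA_real_, c(d, 12))
  for (m in 1:12) {
    tmin[, , m] <- unclass(mins[[m]])
    tmax[, , m] <- unclass(maxs[[m]])
  }
  g <- layer_georef(ref)
  temperature_grid(tmin, tmax, g$xllcorner, g$yllcorner, g$cellsize, g$nodata)
}
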
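#' Georeferenced raster layers and ESRI ASCII grid I/O
#'
#' A `raster_layer` is a plain numeric matrix (rows top-down, the ESRI
#' ASCII convention) carrying lower-left-corner georeferencing attributes.
#' `NA` encodes nodata in memory; the writer substitutes the layer's
#' `nodata` sentinel on disk.
#'
#' @param values Numeric matrix, rows ordered north to south.
#' @param xllcorner,yllcorner Longitude/latitude of the lower-left corner
#'   of the grid (degrees).
#' @param cellsize Cell size in degrees.
#' @param nodata Sentinel written for missing cells (default -9999).
#' @param index_kind Optional tag (`"eri"`, `"gi"`, `"ai"`, `"eri_class"`,
#'   ...) identifying what the layer holds.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(values, xllcorner, yllcorner, cellsize,
                         nodata = -9999, index_kind = NULL) {
  stopifnot(is.matrix(values))
  structure(values,
            xllcorner = as.numeric(xllcorner),
            yllcorner = as.numeric(yllcorner),
            cellsize = as.numeric(cellsize),
            nodata = as.numeric(nodata),
            index_kind = index_kind,
            class = c("raster_layer", "matrix", "array"))
}

layer_georef <- function(layer) {
  list(xllcorner = attr(layer, "xllcorner"),
       yllcorner = attr(layer, "yllcorner"),
       cellsize = attr(layer, "cellsize"),
       nodata = attr(layer, "nodata"))
}

same_georef <- function(a, b, tol = 1e-9) {
  ga <- layer_georef(a); gb <- layer_georef(b)
  nrow(a) == nrow(b) && ncol(a) == ncol(b) &&
    abs(ga$xllcorner - gb$xllcorner) < tol &&
    abs(ga$yllcorner - gb$yllcorner) < tol &&
    abs(ga$cellsize - gb$cellsize) < tol
}

# latitude/longitude of cell centers; row 1 is the northernmost row.
layer_lat_centers <- function(layer) {
  g <- layer_georef(layer)
  g$yllcorner + (nrow(layer) - seq_len(nrow(layer)) + 0.5) * g$cellsize
}

layer_lon_centers <- function(layer) {
  g <- layer_georef(layer)
  g$xllcorner + (seq_len(ncol(layer)) - 0.5) * g$cellsize
}

#' @rdname raster_layer
#' @param x A `raster_layer`.
#' @param ... Unused.
#' @return `as_tibble()` returns one row per cell with columns `row`,
#'   `col`, `lon`, `lat`, `value`.
#' @export
as_tibble.raster_layer <- function(x, ...) {
  lat <- layer_lat_centers(x)
  lon <- layer_lon_centers(x)
  tibble(
    row = rep(seq_len(nrow(x)), times = ncol(x)),
    col = rep(seq_len(ncol(x)), each = nrow(x)),
    lon = rep(lon, each = nrow(x)),
    lat = rep(lat, times = ncol(x)),
    value = as.vector(unclass(x)[, , drop = TRUE])
  )
}

#' @export
print.raster_layer <- function(x, ...) {
  g <- layer_georef(x)
  cat(sprintf("<raster_layer %dx%d, cellsize %g deg, ll corner (%g, %g)%s>\n",
              nrow(x), ncol(x), g$cellsize, g$xllcorner, g$yllcorner,
              if (!is.null(attr(x, "index_kind")))
                paste0(", kind=", attr(x, "index_kind")) else ""))
  cat(sprintf("  values: min %.4g, max %.4g, nodata cells %d\n",
              suppressWarnings(min(x, na.rm = TRUE)),
              suppressWarnings(max(x, na.rm = TRUE)), sum(is.na(x))))
  invisible(x)
}

#' Read an ESRI ASCII grid
#'
#' Parses the 6-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by `nrows` whitespace-separated
#' data rows, top-down. Nodata cells become `NA`. Malformed headers and
#' ragged rows raise an error naming the offending line.
#'
#' @param path Path to a `.asc` file.
#' @return A [raster_layer()].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) abort(sprintf("%s: too short for an ASCII grid", path))
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) {
      abort(sprintf("%s: malformed header at line %d: '%s'", path, i, lines[i]))
    }
    val <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(val)) {
      abort(sprintf("%s: non-numeric header value at line %d", path, i))
    }
    hdr[[tolower(parts[1])]] <- val
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  missing <- setdiff(need, names(hdr))
  if (length(missing) > 0) {
    abort(sprintf("%s: header missing %s", path, paste(missing, collapse = ", ")))
  }
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nr) {
    abort(sprintf("%s: expected %d data rows, found %d", path, nr, length(body)))
  }
  vals <- matrix(NA_real_, nrow = nr, ncol = nc)
  for (r in seq_len(nr)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]]))
    if (length(row) != nc || anyNA(row)) {
      abort(sprintf("%s: ragged or non-numeric data row at line %d", path, r + 6))
    }
    vals[r, ] <- row
  }
  vals[vals == hdr$nodata_value] <- NA_real_
  raster_layer(vals, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
               nodata = hdr$nodata_value)
}

#' @rdname read_ascii_grid
#' @param layer A [raster_layer()].
#' @param digits Significant digits written (default 15, enough for an
#'   exact double round trip).
#' @return `write_ascii_grid()` returns `path` invisibly.
#' @export
write_ascii_grid <- function(layer, path, digits = 15) {
  stopifnot(inherits(layer, "raster_layer"))
  g <- layer_georef(layer)
  vals <- unclass(layer)
  vals[is.na(vals)] <- g$nodata
  hdr <- c(
    sprintf("ncols %d", ncol(layer)),
    sprintf("nrows %d", nrow(layer)),
    sprintf("xllcorner %.10g", g$xllcorner),
    sprintf("yllcorner %.10g", g$yllcorner),
    sprintf("cellsize %.10g", g$cellsize),
    sprintf("NODATA_value %.10g", g$nodata)
  )
  rows <- apply(vals, 1, function(r) {
    paste(formatC(r, format = "g", digits = digits), collapse = " ")
  })
  writeLines(c(hdr, rows), path)
  invisible(path)
}
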
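#' Map the three risk indices over a temperature grid
#'
#' Runs the full per-cell pipeline — [monthly_to_daily()] →
#' [daily_series()] → [compute_risk_indices()] — for every valid cell of
#' a [temperature_grid()]. Nodata propagates: a cell with any missing
#' month is nodata in all outputs. Cells whose 24 monthly values agree to
#' 0.01 deg C share one cached simulation, which makes gradient-dominated
#' grids cheap.
#'
#' @param grid A [temperature_grid()].
#' @param model A [phenology_model()].
#' @param survival_threshold,reproduction_rule,lambda_floor Index options,
#'   see [compute_eri()] and [compute_ai()].
#' @param steps,max_days,n_quantiles Engine resolution, see
#'   [daily_series()].
#' @return A `risk_map`: list with `cells` (tibble: `row`, `col`, `lon`,
#'   `lat`, `eri`, `gi`, `ai`, `eri_class`, `permanent_establishment`)
#'   and `layers` (named list of [raster_layer()]s `eri`, `gi`, `ai`,
#'   `eri_class` — the class layer holds bin codes 1-5).
#' @examples
#' \donttest{
#' grid <- gen_temperature_grid(synthetic_grid_spec(n_rows = 4, n_cols = 2))
#' model <- gen_phenology_model(synthetic_phenology_spec())
#' rmap <- map_indices(grid, model)
#' rmap$cells
#' }
#' @export
map_indices <- function(grid, model, survival_threshold = 0.01,
                        reproduction_rule = c("indicator", "capped"),
                        lambda_floor = 1e-6, steps = 48, max_days = 500,
                        n_quantiles = 25) {
  stopifnot(inherits(grid, "temperature_grid"),
            inherits(model, "phenology_model"))
  reproduction_rule <- match.arg(reproduction_rule)
  d <- grid_dim(grid)
  ref <- grid_layer(grid, "tmin", 1)
  lat <- layer_lat_centers(ref); lon <- layer_lon_centers(ref)

  cache <- new.env(parent = emptyenv())
  eri <- gi <- ai <- cls <- matrix(NA_real_, d[1], d[2])
  for (cc in seq_len(d[2])) {
    for (rr in seq_len(d[1])) {
      tmin <- grid$tmin[rr, cc, ]; tmax <- grid$tmax[rr, cc, ]
      if (anyNA(tmin) || anyNA(tmax)) next
      key <- paste(sprintf("%.2f", c(tmin, tmax)), collapse = "|")
      res <- cache[[key]]
      if (is.null(res)) {
        ser <- daily_series(model, tmin, tmax, steps = steps,
                            max_days = max_days, n_quantiles = n_quantiles)
        res <- compute_risk_indices(ser, survival_threshold,
                                    reproduction_rule, lambda_floor)
        cache[[key]] <- res
      }
      eri[rr, cc] <- res$eri
      gi[rr, cc] <- res$gi
      ai[rr, cc] <- res$ai
      cls[rr, cc] <- as.integer(res$eri_class)
    }
  }
  mk <- function(vals, kind) {
    raster_layer(vals, grid$xllcorner, grid$yllcorner, grid$cellsize,
                 nodata = grid$nodata, index_kind = kind)
  }
  cells <- tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    lon = rep(lon, each = d[1]),
    lat = rep(lat, times = d[2]),
    eri = as.vector(eri), gi = as.vector(gi), ai = as.vector(ai)
  )
  cells <- dplyr::bind_cols(
    dplyr::select(cells, -"eri"),
    classify_eri(cells$eri)
  )
  cells <- dplyr::select(cells, "row", "col", "lon", "lat", "eri", "gi",
                         "ai", "eri_class", "permanent_establishment")
  structure(
    list(cells = cells,
         layers = list(eri = mk(eri, "eri"), gi = mk(gi, "gi"),
                       ai = mk(ai, "ai"), eri_class = mk(cls, "eri_class")),
         options = list(survival_threshold = survival_threshold,
                        reproduction_rule = reproduction_rule,
                        lambda_floor = lambda_floor)),
    class = "risk_map")
}

#' @export
print.risk_map <- function(x, ...) {
  n_ok <- sum(!is.na(x$cells$eri))
  cat(sprintf("<risk_map: %d cells (%d valid)>\n", nrow(x$cells), n_ok))
  if (n_ok > 0) {
    cat(sprintf("  ERI range [%.3f, %.3f]; GI range [%.2f, %.2f]; AI range [%.1f, %.1f]\n",
                min(x$cells$eri, na.rm = TRUE), max(x$cells$eri, na.rm = TRUE),
                min(x$cells$gi, na.rm = TRUE), max(x$cells$gi, na.rm = TRUE),
                min(x$cells$ai, na.rm = TRUE), max(x$cells$ai, na.rm = TRUE)))
  }
  invisible(x)
}

#' Per-cell difference between two index rasters
#'
#' `future - current`, cellwise; nodata wherever either input is nodata.
#' Both layers must share georeferencing and `index_kind`.
#'
#' @param current,future [raster_layer()]s of the same index.
#' @return A [raster_layer()] tagged `<kind>_change`.
#' @export
change_map <- function(current, future) {
  stopifnot(inherits(current, "raster_layer"), inherits(future, "raster_layer"))
  if (!same_georef(current, future)) {
    abort("change_map(): georeferencing mismatch between layers")
  }
  ka <- attr(current, "index_kind"); kb <- attr(future, "index_kind")
  if (!is.null(ka) && !is.null(kb) && !identical(ka, kb)) {
    abort(sprintf("change_map(): index kind mismatch (%s vs %s)", ka, kb))
  }
  g <- layer_georef(current)
  diff <- unclass(future) - unclass(current)
  raster_layer(diff, g$xllcorner, g$yllcorner, g$cellsize, g$nodata,
               index_kind = paste0(ka %||% "index", "_change"))
}
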
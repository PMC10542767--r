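#' Specify and generate a synthetic monthly temperature grid
#'
#' The generator emulates the statistical structure the pipeline assumes of
#' WorldClim-style inputs — a latitudinal gradient, hemisphere-phased
#' seasonality and a fixed diurnal range — without attempting to mimic real
#' spatial covariance. Monthly mean at latitude `phi` and month `m` is
#'
#' `T_eq - lapse * |phi| + A * h(phi) * cos(2 pi (m - 7) / 12)`
#'
#' where `h = +1` in the northern hemisphere (seasonal peak at mid-July)
#' and `-1` in the southern (peak at mid-January). Gaussian noise of sd
#' `noise_sd` is added to the monthly mean per cell-month; `tmin`/`tmax`
#' sit `diurnal_range/2` below/above the (noisy) mean, so `tmax - tmin`
#' equals `diurnal_range` exactly and the max >= min invariant holds by
#' construction.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param lat_range,lon_range Length-2 degree intervals (south/north,
#'   west/east edges of the grid).
#' @param mean_annual_temp_at_equator Annual-mean temperature at 0 deg
#'   latitude (deg C).
#' @param lapse_per_degree_lat Cooling per degree of |latitude|
#'   (deg C / deg).
#' @param seasonal_amplitude Peak deviation of the monthly mean from the
#'   annual mean (deg C).
#' @param diurnal_range `tmax - tmin` (deg C, >= 0).
#' @param noise_sd Gaussian noise sd on the monthly mean (deg C, >= 0).
#' @param seed Integer seed; generation is deterministic for a fixed seed.
#' @return `synthetic_grid_spec()` returns a validated spec;
#'   `gen_temperature_grid()` returns a [temperature_grid()].
#' @examples
#' grid <- gen_temperature_grid(synthetic_grid_spec(n_rows = 4, n_cols = 3))
#' dplyr::filter(tibble::as_tibble(grid), month == 1)
#' @export
synthetic_grid_spec <- function(n_rows = 20, n_cols = 20,
                                lat_range = c(-40, 40),
                                lon_range = c(0, 40),
                                mean_annual_temp_at_equator = 26,
                                lapse_per_degree_lat = 0.55,
                                seasonal_amplitude = 6,
                                diurnal_range = 10,
                                noise_sd = 0.3,
                                seed = 1L) {
  if (n_rows < 1 || n_cols < 1) abort("grid dimensions must be positive")
  if (diurnal_range < 0) abort("diurnal_range must be >= 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (lat_range[1] >= lat_range[2] || lon_range[1] >= lon_range[2]) {
    abort("lat_range and lon_range must be increasing intervals")
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         lat_range = as.numeric(lat_range), lon_range = as.numeric(lon_range),
         mean_annual_temp_at_equator = mean_annual_temp_at_equator,
         lapse_per_degree_lat = lapse_per_degree_lat,
         seasonal_amplitude = seasonal_amplitude,
         diurnal_range = diurnal_range, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_grid_spec")
}

#' @rdname synthetic_grid_spec
#' @param spec A `synthetic_grid_spec`.
#' @export
gen_temperature_grid <- function(spec) {
  stopifnot(inherits(spec, "synthetic_grid_spec"))
  nr <- spec$n_rows; nc <- spec$n_cols
  cellsize <- (spec$lat_range[2] - spec$lat_range[1]) / nr
  xll <- spec$lon_range[1]; yll <- spec$lat_range[1]
  # row 1 = northernmost, per the ESRI ASCII top-down convention
  lat <- yll + (nr - seq_len(nr) + 0.5) * cellsize
  hemi <- ifelse(lat >= 0, 1, -1)
  tmin <- array(NA_real_, c(nr, nc, 12))
  tmax <- array(NA_real_, c(nr, nc, 12))
  noise <- withr::with_seed(spec$seed, {
    array(rnorm(nr * nc * 12, 0, spec$noise_sd), c(nr, nc, 12))
  })
  for (m in 1:12) {
    seasonal <- spec$seasonal_amplitude * hemi * cos(2 * pi * (m - 7) / 12)
    mean_lat <- spec$mean_annual_temp_at_equator -
      spec$lapse_per_degree_lat * abs(lat) + seasonal
    mean_mat <- matrix(mean_lat, nr, nc) + noise[, , m]
    tmin[, , m] <- mean_mat - spec$diurnal_range / 2
    tmax[, , m] <- mean_mat + spec$diurnal_range / 2
  }
  temperature_grid(tmin, tmax, xll, yll, cellsize)
}
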
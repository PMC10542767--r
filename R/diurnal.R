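#' Cosine reconstruction of within-day temperatures
#'
#' `halfday_temperature()` evaluates the half-day cosine interpolation
#'
#' `T_i = ((Max - Min)/2) * cos(pi * (i - 0.5) / 48) + ((Max + Min)/2)`
#'
#' which descends from `Max` at step 1 to `Min` at step 48 in 15-minute
#' steps. `build_diurnal_cycle()` chains two half-days into one 96-step
#' day: steps 1–48 interpolate between the day's own minimum and maximum,
#' steps 49–96 between the *next* day's minimum and the same maximum.
#'
#' @param t_min,t_max Daily minimum and maximum temperature (deg C),
#'   `t_max >= t_min`.
#' @param i Step index, integer(s) in `1..steps` (15-min steps when
#'   `steps = 48`).
#' @param steps Steps per half-day (default 48; use 360 for a 1-minute
#'   resolution sensitivity check).
#' @return `halfday_temperature()` returns temperatures (deg C) at the
#'   requested steps.
#' @examples
#' halfday_temperature(10, 30, c(1, 24, 48))
#' cyc <- build_diurnal_cycle(10, 30, next_day_min = 12)
#' mean(cyc$temperature)
#' @export
halfday_temperature <- function(t_min, t_max, i, steps = 48) {
  if (any(t_max < t_min)) abort("halfday_temperature(): t_max must be >= t_min")
  if (any(i < 1 | i > steps | i != floor(i))) {
    abort(sprintf("halfday_temperature(): step index must be an integer in 1..%d",
                  steps))
  }
  (t_max - t_min) / 2 * cos(pi * (i - 0.5) / steps) + (t_max + t_min) / 2
}

#' @rdname halfday_temperature
#' @param next_day_min Minimum temperature of the following day (deg C),
#'   used for the second half-day.
#' @return `build_diurnal_cycle()` returns a `diurnal_cycle`: a tibble
#'   with columns `step`, `time_h` and `temperature` (2 * `steps` rows)
#'   and attributes `t_min`, `t_max`, `next_day_min`, `steps_per_day`.
#' @export
build_diurnal_cycle <- function(t_min, t_max, next_day_min = t_min,
                                steps = 48) {
  if (t_max < t_min || t_max < next_day_min) {
    abort("build_diurnal_cycle(): t_max must be >= both minima")
  }
  idx <- seq_len(steps)
  temp <- c(halfday_temperature(t_min, t_max, idx, steps),
            halfday_temperature(next_day_min, t_max, idx, steps))
  n <- 2L * steps
  out <- tibble(step = seq_len(n),
                time_h = (seq_len(n) - 0.5) * 24 / n,
                temperature = temp)
  structure(out, t_min = t_min, t_max = t_max, next_day_min = next_day_min,
            steps_per_day = n,
            class = c("diurnal_cycle", class(out)))
}

cycle_temperatures <- function(cycle) {
  if (inherits(cycle, "diurnal_cycle")) cycle$temperature else as.numeric(cycle)
}

# non-leap calendar month lengths, hard-coded 365-day year
.month_days <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Expand monthly min/max values to a 365-day series of cycle triples
#'
#' Every day of a month carries that month's minimum and maximum; the
#' second half-day of the last day of each month uses the *following*
#' month's minimum (December wraps to January). A non-leap 365-day
#' calendar is used throughout, matching the year length hard-coded in
#' the risk indices.
#'
#' @param tmin,tmax Numeric vectors of 12 monthly values (deg C).
#' @return A tibble with 365 rows: `day`, `month`, `t_min`, `t_max`,
#'   `next_day_min`.
#' @export
monthly_to_daily <- function(tmin, tmax) {
  if (length(tmin) != 12 || length(tmax) != 12) {
    abort("monthly_to_daily(): need 12 monthly values of each of tmin and tmax")
  }
  if (anyNA(tmin) || anyNA(tmax)) {
    abort("monthly_to_daily(): nodata month; mark the cell nodata upstream")
  }
  month <- rep(1:12, times = .month_days)
  t_min <- tmin[month]
  t_max <- tmax[month]
  next_min <- t_min
  last_days <- cumsum(.month_days)
  next_min[last_days] <- tmin[c(2:12, 1)]
  tibble(day = 1:365, month = month, t_min = t_min, t_max = t_max,
         next_day_min = next_min)
}
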
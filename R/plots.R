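#' Plot methods
#'
#' ggplot2 views of the package's main result types: diurnal cycles,
#' daily life-table series, risk maps and fitted thermal curves.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @name phenorisk-plots
NULL

#' @rdname phenorisk-plots
#' @export
autoplot.diurnal_cycle <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_h, y = .data$temperature)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "hour of day", y = "temperature (°C)",
                  title = "Cosine-reconstructed diurnal cycle") +
    ggplot2::theme_minimal()
}

#' @rdname phenorisk-plots
#' @export
autoplot.daily_series <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "day", "r0", "lambda", "tc"),
    -"day", names_to = "parameter", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "day of year", y = NULL,
                  title = "Daily steady-state life-table parameters") +
    ggplot2::theme_minimal()
}

#' @rdname phenorisk-plots
#' @param index Which index layer of a risk map to draw.
#' @export
autoplot.risk_map <- function(object, index = c("eri", "gi", "ai"), ...) {
  index <- match.arg(index)
  cells <- object$cells
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$lon, y = .data$lat,
                                      fill = .data[[index]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude", fill = toupper(index)) +
    ggplot2::theme_minimal()
}

#' @rdname phenorisk-plots
#' @export
autoplot.thermal_fit <- function(object, ...) {
  xg <- seq(min(object$data$x), max(object$data$x), length.out = 200)
  curve <- tibble(x = xg, value = evaluate_fn(object$spec, xg))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = curve, color = "firebrick") +
    ggplot2::labs(x = if (fn_kind(object$spec) %in% c("devtime", "cumfec"))
                    "normalized age" else "temperature (°C)",
                  y = "value", title = sprintf("Fitted %s", object$family)) +
    ggplot2::theme_minimal()
}

#' Plot the temperature-response curves of a phenology model
#'
#' Development rate, daily mortality and lifetime fecundity across a
#' temperature range, one panel per curve type.
#'
#' @param model A [phenology_model()].
#' @param from,to Temperature range (deg C).
#' @return A ggplot object.
#' @export
plot_thermal_responses <- function(model, from = 0, to = 45) {
  tg <- seq(from, to, by = 0.1)
  imm <- immature_stages(model)
  rates <- purrr::imap(imm, function(s, nm) {
    tibble(temperature = tg, stage = nm, panel = "development rate (1/day)",
           value = evaluate_rate(s$dev_rate, tg))
  })
  morts <- purrr::imap(imm, function(s, nm) {
    tibble(temperature = tg, stage = nm, panel = "daily mortality",
           value = evaluate_mortality(s$mortality, tg))
  })
  fec <- tibble(temperature = tg, stage = "adult_female",
                panel = "lifetime fecundity (eggs)",
                value = evaluate_fecundity(model$fecundity_mean, tg))
  df <- dplyr::bind_rows(c(rates, morts, list(fec)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$temperature, y = .data$value,
                                   color = .data$stage)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "temperature (°C)", y = NULL) +
    ggplot2::theme_minimal()
}
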
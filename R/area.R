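#' Cell areas and suitability-class area tabulation
#'
#' Cell area uses a spherical Earth with 111.32 km per degree:
#' `area = (cellsize * 111.32)^2 * cos(latitude at the cell center)` km2.
#' `tabulate_area()` sums these per region and ERI class and expresses
#' each class as a percent of the region's total valid area.
#'
#' @param classified A `risk_map` (its `eri_class` layer is used), an
#'   `eri_class`-kind [raster_layer()] of bin codes 1-5, or an ERI-valued
#'   layer (classified on the fly).
#' @param region_mask Optional [raster_layer()] of integer region labels
#'   on the same georeference; `NULL` tabulates everything as one region
#'   `"all"`. Valid classified cells without a label are tabulated under
#'   `"unassigned"`.
#' @param region_names Optional named character vector mapping label
#'   codes to region names, e.g. `c("1" = "Africa")`.
#' @return An `area_table`: tibble with columns `region`, `eri_class`,
#'   `area_km2`, `pct_of_region_total`, carrying the per-region totals in
#'   the `region_totals` attribute.
#' @export
tabulate_area <- function(classified, region_mask = NULL,
                          region_names = NULL) {
  if (inherits(classified, "risk_map")) classified <- classified$layers$eri_class
  stopifnot(inherits(classified, "raster_layer"))
  kind <- attr(classified, "index_kind") %||% "eri_class"
  codes <- unclass(classified)
  if (!identical(kind, "eri_class")) {
    codes <- matrix(as.integer(classify_eri(as.vector(codes))$eri_class),
                    nrow(codes), ncol(codes))
  }
  lat <- layer_lat_centers(classified)
  cs <- attr(classified, "cellsize")
  cell_km2 <- matrix((cs * 111.32)^2 * cos(lat * pi / 180),
                     nrow(classified), ncol(classified))
  region <- if (is.null(region_mask)) {
    matrix("all", nrow(classified), ncol(classified))
  } else {
    if (!same_georef(classified, region_mask)) {
      abort("tabulate_area(): region mask georeferencing mismatch")
    }
    lab <- as.character(unclass(region_mask))
    if (!is.null(region_names)) {
      lab <- ifelse(lab %in% names(region_names), region_names[lab], lab)
    }
    matrix(ifelse(is.na(lab), "unassigned", lab),
           nrow(classified), ncol(classified))
  }
  keep <- !is.na(as.vector(codes))
  df <- tibble(
    region = as.vector(region)[keep],
    eri_class = factor(.eri_labels[as.vector(codes)[keep]],
                       levels = .eri_labels, ordered = TRUE),
    area_km2 = as.vector(cell_km2)[keep]
  )
  tab <- df |>
    dplyr::group_by(.data$region, .data$eri_class, .drop = FALSE) |>
    dplyr::summarise(area_km2 = sum(.data$area_km2), .groups = "drop")
  area_table(tab)
}

#' Construct an area table from class areas
#'
#' Wraps a tibble of `(region, eri_class, area_km2)` rows into an
#' `area_table`, computing the percent of each region's total. Region
#' totals default to the sum of the class areas but can be supplied
#' (e.g. a continent's published total) — percentages are then relative
#' to the supplied total.
#'
#' @param tab Data frame with columns `region`, `eri_class`, `area_km2`.
#' @param region_totals Optional named numeric vector of total areas per
#'   region (km2).
#' @return An `area_table` tibble.
#' @export
area_table <- function(tab, region_totals = NULL) {
  need <- c("region", "eri_class", "area_km2")
  if (!all(need %in% names(tab))) {
    abort("area_table(): need columns region, eri_class, area_km2")
  }
  tab <- as_tibble(tab)
  tab$eri_class <- factor(as.character(tab$eri_class), levels = .eri_labels,
                          ordered = TRUE)
  sums <- tapply(tab$area_km2, tab$region, sum)
  totals <- setNames(as.numeric(sums), names(sums))
  if (!is.null(region_totals)) {
    totals[names(region_totals)] <- region_totals
  }
  tab$pct_of_region_total <- 100 * tab$area_km2 / totals[tab$region]
  structure(tab, region_totals = totals,
            class = c("area_table", class(tibble())))
}

#' Gains and losses between two scenario area tables
#'
#' Signed per-class area differences (future minus current) with the
#' percent change expressed relative to the region's total area — the
#' bookkeeping used when comparing climate scenarios per continent.
#'
#' @param current,future `area_table`s over the same regions and class
#'   scheme.
#' @return A tibble: `region`, `eri_class`, `area_current`,
#'   `area_future`, `gain_km2`, `gain_pct` (percent of the region
#'   total). Within a region the gains and losses sum to ~0 when both
#'   tables cover the same total area.
#' @examples
#' cur <- area_table(tibble::tibble(
#'   region = "Africa",
#'   eri_class = c("suitable", "highly_suitable"),
#'   area_km2 = c(12461040, 7500600)), c(Africa = 30001150.78))
#' fut <- area_table(tibble::tibble(
#'   region = "Africa",
#'   eri_class = c("suitable", "highly_suitable"),
#'   area_km2 = c(11048400, 8622288)), c(Africa = 30001150.78))
#' area_change_summary(cur, fut)
#' @export
area_change_summary <- function(current, future) {
  stopifnot(inherits(current, "area_table"), inherits(future, "area_table"))
  if (!setequal(unique(current$region), unique(future$region))) {
    abort("area_change_summary(): region sets differ between tables")
  }
  totals <- attr(current, "region_totals")
  joined <- dplyr::full_join(
    dplyr::select(current, "region", "eri_class", area_current = "area_km2"),
    dplyr::select(future, "region", "eri_class", area_future = "area_km2"),
    by = c("region", "eri_class"))
  joined |>
    dplyr::mutate(
      area_current = dplyr::coalesce(.data$area_current, 0),
      area_future = dplyr::coalesce(.data$area_future, 0),
      gain_km2 = .data$area_future - .data$area_current,
      gain_pct = 100 * .data$gain_km2 / unname(totals[.data$region])
    ) |>
    dplyr::arrange(.data$region, .data$eri_class)
}
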
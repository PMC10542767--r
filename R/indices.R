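#' Establishment risk index (ERI)
#'
#' `ERI = (sum_i I_i / 365) * net-reproduction`, where `I_i` indicates a
#' *survivable* day — every immature stage's daily survival under day
#' `i`'s diurnal cycle exceeds `survival_threshold` — and the
#' net-reproduction factor reflects whether the population can replace
#' itself over the year: with `reproduction_rule = "indicator"` (default)
#' it is `1` when the annual mean R0 >= 1 and `0` otherwise; with
#' `"capped"` it is `min(1, mean R0)`. Either way ERI lies in `[0, 1]`.
#'
#' @param series A [daily_series()] (365 rows) or any data frame with the
#'   `surv_*` and `r0` columns.
#' @param survival_threshold Minimum daily immature survival that counts
#'   a day as survivable (default 0.01).
#' @param reproduction_rule `"indicator"` or `"capped"` (see above).
#' @return A single numeric ERI in `[0, 1]`.
#' @examples
#' model <- gen_phenology_model(synthetic_phenology_spec())
#' ser <- daily_series(model, rep(16, 12), rep(26, 12))
#' compute_eri(ser)
#' @export
compute_eri <- function(series, survival_threshold = 0.01,
                        reproduction_rule = c("indicator", "capped")) {
  reproduction_rule <- match.arg(reproduction_rule)
  .check_series(series, need_surv = TRUE)
  surv_cols <- grep("^surv_", names(series), value = TRUE)
  survivable <- rowSums(as.matrix(series[surv_cols]) > survival_threshold) ==
    length(surv_cols)
  mean_r0 <- mean(series$r0)
  net <- switch(reproduction_rule,
                indicator = as.numeric(mean_r0 >= 1),
                capped = min(1, mean_r0))
  sum(survivable) / 365 * net
}

#' Generation index (GI)
#'
#' `GI = sum_i (365 / Tc_i) / 365`, the mean number of generations
#' completable per year from the daily mean generation times. Days where
#' the population cannot replace itself (`R0 <= 1`) or where `Tc` is
#' undefined or non-positive contribute 0 generations.
#'
#' @inheritParams compute_eri
#' @return A single numeric GI >= 0.
#' @export
compute_gi <- function(series) {
  .check_series(series)
  contrib <- ifelse(series$r0 > 1 & is.finite(series$tc) & series$tc > 0,
                    365 / series$tc, 0)
  sum(contrib) / 365
}

#' Activity index (AI)
#'
#' `AI = log10 prod_i lambda_i = sum_i log10 lambda_i`, the log10 yearly
#' population multiplication factor: `AI = 4` means a 10,000-fold
#' potential increase within a year, `AI = 0` no net growth. Days with
#' `lambda = 0` (lethal regimes) would send the product to zero and AI to
#' `-Inf`; they are floored at `lambda_floor` before the log so cold
#' regions map to finite, strongly negative AI.
#'
#' @inheritParams compute_eri
#' @param lambda_floor Lower bound applied to each daily lambda before
#'   taking logs (default 1e-6).
#' @return A single numeric AI (may be negative).
#' @export
compute_ai <- function(series, lambda_floor = 1e-6) {
  .check_series(series)
  lam <- series$lambda
  if (any(lam < 0, na.rm = TRUE)) abort("compute_ai(): negative lambda in series")
  sum(log10(pmax(lam, lambda_floor)))
}

.check_series <- function(series, need_surv = FALSE) {
  if (!is.data.frame(series)) abort("series must be a data frame")
  if (nrow(series) != 365) {
    abort(sprintf("need a full 365-day series, got %d rows", nrow(series)))
  }
  need <- c("r0", "lambda", "tc")
  if (need_surv && !any(grepl("^surv_", names(series)))) {
    abort("series lacks per-stage surv_* columns")
  }
  missing <- setdiff(need, names(series))
  if (length(missing) > 0) {
    abort(paste("series lacks column(s):", paste(missing, collapse = ", ")))
  }
  if (anyNA(series$lambda)) abort("series contains missing days")
  invisible(series)
}

.eri_labels <- c("unsuitable", "marginal", "suitable", "highly_suitable",
                 "optimal")

#' Classify ERI into the five suitability classes
#'
#' Bins `[0, 0.2)`, `[0.2, 0.4)`, `[0.4, 0.6)`, `[0.6, 0.8)` and
#' `[0.8, 1]` map to unsuitable, marginally suitable, suitable, highly
#' suitable and optimal; bins are half-open with the top bin closed.
#' `ERI > 0.6` is additionally flagged as permanent establishment.
#'
#' @param eri Numeric vector of ERI values in `[0, 1]`.
#' @return A tibble with columns `eri`, `eri_class` (ordered factor) and
#'   `permanent_establishment` (logical).
#' @examples
#' classify_eri(c(0, 0.2, 0.65, 1))
#' @export
classify_eri <- function(eri) {
  ok <- is.na(eri) | (eri >= 0 & eri <= 1)
  if (!all(ok)) abort("classify_eri(): ERI values must be in [0, 1]")
  idx <- pmin(findInterval(eri, c(0, 0.2, 0.4, 0.6, 0.8)), 5L)
  tibble(
    eri = eri,
    eri_class = factor(.eri_labels[idx], levels = .eri_labels, ordered = TRUE),
    permanent_establishment = eri > 0.6
  )
}

#' All three risk indices for one daily series
#'
#' Convenience wrapper running [compute_eri()], [compute_gi()] and
#' [compute_ai()] and classifying the result.
#'
#' @inheritParams compute_eri
#' @inheritParams compute_ai
#' @return One-row tibble: `eri`, `gi`, `ai`, `eri_class`,
#'   `permanent_establishment`.
#' @export
compute_risk_indices <- function(series, survival_threshold = 0.01,
                                 reproduction_rule = c("indicator", "capped"),
                                 lambda_floor = 1e-6) {
  eri <- compute_eri(series, survival_threshold, reproduction_rule)
  cls <- classify_eri(eri)
  tibble(eri = eri, gi = compute_gi(series),
         ai = compute_ai(series, lambda_floor),
         eri_class = cls$eri_class,
         permanent_establishment = cls$permanent_establishment)
}
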
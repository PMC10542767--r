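#' Simulate a deterministic cohort under a repeating diurnal cycle
#'
#' A cohort of female eggs is stepped through egg, larva and pupa at the
#' cycle's time resolution (15 minutes for the default 96-step cycle),
#' with the day's cycle repeated until the cohort is extinct or `max_days`
#' is reached (a steady-state daily regime). Physiological age accrues as
#' the sum of `rate(T) * dt` per stage; a sub-cohort exits its stage when
#' normalized age reaches its development-time-distribution quantile;
#' survivorship multiplies the per-step factors `(1 - m(T))^dt`. Adult
#' females age along the senescence curve, die at their longevity
#' quantile, and lay `F(T) * dC(x)` eggs per step, where `C` is the
#' cumulative fecundity curve over normalized female age.
#'
#' @param model A [phenology_model()].
#' @param cycle A [build_diurnal_cycle()] result (or a plain numeric
#'   vector of within-day temperatures).
#' @param max_days Simulation horizon in days (default 500). If any
#'   sub-cohort is still alive at the horizon the schedule carries a
#'   `truncated` attribute.
#' @param n_quantiles Number of quantile sub-cohorts per stage
#'   (default 25).
#' @return A `cohort_schedule`: a tibble with columns `x` (age in days,
#'   day midpoints), `l_x` (proportion of the initial cohort alive at the
#'   start of the day) and `m_x` (female eggs per female per day), with
#'   attributes `immature_survival`, `truncated` and `stage_summary`.
#' @examples
#' model <- gen_phenology_model(synthetic_phenology_spec())
#' sched <- simulate_cohort(model, build_diurnal_cycle(18, 28))
#' lifetable_params(sched)
#' @export
simulate_cohort <- function(model, cycle, max_days = 500, n_quantiles = 25) {
  stopifnot(inherits(model, "phenology_model"))
  temps <- cycle_temperatures(cycle)
  steps <- length(temps)
  dt <- 1 / steps
  imm <- immature_stages(model)
  K <- as.integer(n_quantiles)
  q_probs <- (seq_len(K) - 0.5) / K

  da <- sapply(imm, function(s) evaluate_rate(s$dev_rate, temps) * dt)
  lsurv <- sapply(imm, function(s) {
    m <- evaluate_mortality(s$mortality, temps)
    log(pmax(1 - m, 1e-300)) * dt
  })
  exit_q <- sapply(imm, function(s) devtime_quantile(s$devtime_dist, q_probs))
  fem <- model$stages$adult_female
  sen_da <- evaluate_senescence(fem$senescence, temps) * dt
  long_q <- devtime_quantile(fem$devtime_dist, q_probs)
  fec_w <- evaluate_fecundity(model$fecundity_mean, temps)
  cf <- model$fecundity_cum$params

  res <- cohort_sim_cpp(matrix(da, steps), matrix(lsurv, steps),
                        matrix(exit_q, K), sen_da, long_q, fec_w,
                        cf$a, cf$b, cf$c, model$sex_ratio,
                        as.integer(max_days))

  lx <- res$lx
  mx <- ifelse(lx > 0, res$phi / lx, 0)
  stage_summary <- tibble(
    stage = names(imm),
    median_exit_day = apply(res$exit_day, 2, stats::median, na.rm = FALSE),
    completed_fraction = colMeans(!is.na(res$exit_day))
  )
  out <- tibble(x = seq_along(lx) - 0.5, l_x = lx, m_x = mx)
  structure(out,
            immature_survival = mean(res$adult_surv),
            truncated = res$truncated,
            stage_summary = stage_summary,
            class = c("cohort_schedule", class(out)))
}

#' Life-table parameters from an l_x/m_x schedule
#'
#' Computes the classical cohort life-table summary: net reproductive
#' rate `R0 = sum(l_x m_x)`, gross reproductive rate `GRR = sum(m_x)`,
#' the intrinsic rate of increase `r` solving the Lotka–Euler equation
#' `sum(exp(-r x) l_x m_x) = 1` (bracket expansion then bisection to
#' 1e-10), finite rate `lambda = exp(r)`, mean generation time
#' `Tc = log(R0)/r` and doubling time `Dt = log(2)/r`. A schedule with
#' `R0 = 0` yields the degenerate branch `r = -Inf`, `lambda = 0`.
#'
#' @param schedule Data frame with columns `x` (age, days), `l_x` and
#'   `m_x`; typically a [simulate_cohort()] result.
#' @return One-row tibble: `r0`, `grr`, `tc`, `r`, `lambda`,
#'   `doubling_time`, `immature_survival`, `truncated`, `degenerate`.
#' @export
lifetable_params <- function(schedule) {
  need <- c("x", "l_x", "m_x")
  if (!all(need %in% names(schedule))) {
    abort("lifetable_params(): schedule needs columns x, l_x, m_x")
  }
  x <- schedule$x
  phi <- schedule$l_x * schedule$m_x
  r0 <- sum(phi)
  grr <- sum(schedule$m_x)
  isurv <- attr(schedule, "immature_survival") %||% NA_real_
  trunc <- isTRUE(attr(schedule, "truncated"))
  if (r0 <= 0) {
    return(tibble(r0 = 0, grr = grr, tc = NA_real_, r = -Inf, lambda = 0,
                  doubling_time = NA_real_, immature_survival = isurv,
                  truncated = trunc, degenerate = TRUE))
  }
  r <- solve_lotka_euler(x, phi)
  tc <- if (abs(r) > 1e-12) log(r0) / r else sum(x * phi) / r0
  dt2 <- if (r == 0) Inf else log(2) / r
  tibble(r0 = r0, grr = grr, tc = tc, r = r, lambda = exp(r),
         doubling_time = dt2, immature_survival = isurv,
         truncated = trunc, degenerate = FALSE)
}

# bracketing + bisection for the Lotka-Euler root; f(r) is strictly
# decreasing in r, so expand the bracket until the sign changes.
solve_lotka_euler <- function(x, phi, tol = 1e-10) {
  keep <- phi > 0
  x <- x[keep]; phi <- phi[keep]
  f <- function(r) sum(exp(-r * x) * phi) - 1
  lo <- -2; hi <- 2
  while (f(lo) < 0 && lo > -50) lo <- lo * 2
  while (f(hi) > 0 && hi < 50) hi <- hi * 2
  flo <- f(lo); fhi <- f(hi)
  if (flo < 0 || fhi > 0) {
    warn("Lotka-Euler root outside [-50, 50]; returning boundary")
    return(if (flo < 0) lo else hi)
  }
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Daily life-table series for one grid cell
#'
#' Expands a cell's 12 monthly min/max values into 365 daily cycle
#' triples ([monthly_to_daily()]), treats each day's diurnal cycle as a
#' steady-state regime (the cycle repeats for the whole cohort life),
#' runs [simulate_cohort()] + [lifetable_params()] per *distinct* triple
#' (at most 24 per cell: each month's interior days share one triple,
#' its last day another) and expands back to 365 rows. The per-stage
#' daily survival columns `surv_egg`, `surv_larva`, `surv_pupa` are the
#' within-day products `prod((1 - m(T_i))^dt)` that feed the ERI
#' survivable-day indicator.
#'
#' @param model A [phenology_model()].
#' @param tmin,tmax Numeric vectors of 12 monthly values (deg C). Where
#'   a following month's minimum exceeds the current month's maximum,
#'   the second half-day minimum is clamped to the maximum.
#' @param steps Steps per half-day for the cosine cycle (default 48,
#'   i.e. 15-minute resolution).
#' @inheritParams simulate_cohort
#' @return A `daily_series` tibble with 365 rows: the triple columns
#'   plus `r0`, `grr`, `tc`, `r`, `lambda`, `doubling_time`,
#'   `immature_survival`, `truncated` and one `surv_*` column per
#'   immature stage.
#' @export
daily_series <- function(model, tmin, tmax, steps = 48, max_days = 500,
                         n_quantiles = 25) {
  days <- monthly_to_daily(tmin, tmax)
  days$next_day_min <- pmin(days$next_day_min, days$t_max)
  key <- sprintf("%.6f|%.6f|%.6f", days$t_min, days$t_max, days$next_day_min)
  uniq <- !duplicated(key)
  per_triple <- purrr::map(which(uniq), function(i) {
    cyc <- build_diurnal_cycle(days$t_min[i], days$t_max[i],
                               days$next_day_min[i], steps = steps)
    params <- lifetable_params(
      simulate_cohort(model, cyc, max_days = max_days,
                      n_quantiles = n_quantiles))
    surv <- purrr::map_dbl(immature_stages(model), function(s) {
      m <- evaluate_mortality(s$mortality, cyc$temperature)
      exp(sum(log(pmax(1 - m, 1e-300))) / length(m))
    })
    dplyr::bind_cols(params, tibble::as_tibble_row(setNames(
      as.list(surv), paste0("surv_", names(immature_stages(model))))))
  })
  lut <- setNames(per_triple, key[uniq])
  out <- dplyr::bind_cols(days, dplyr::bind_rows(lut[key]))
  class(out) <- c("daily_series", class(tibble()))
  out
}
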
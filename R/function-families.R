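#' Temperature-response function specifications
#'
#' A `fn_spec` bundles a function family, its named parameters and the
#' temperature domain over which the curve is biologically defined. Outside
#' `temp_domain` every evaluator returns the family's boundary behaviour
#' (rate/fecundity 0, mortality 1) rather than raising an error, so curves
#' compose safely inside the cohort simulator.
#'
#' Supported families and their canonical forms:
#'
#' * `briere_1` — development rate `a * T * (T - t_min) * sqrt(t_max - T)`
#'   on `[t_min, t_max]`, 0 outside (params `a`, `t_min`, `t_max`).
#' * `sharpe_demichele_1` — biophysical development rate
#'   `rho25 * (TK/298.15) * exp(ha/R (1/298.15 - 1/TK))` divided by
#'   `1 + exp(hl/R (1/tl - 1/TK)) + exp(hh/R (1/th - 1/TK))` with `TK` in
#'   kelvin and `R = 1.987` cal/mol/K (params `rho25`, `ha`, `tl`, `hl`,
#'   `th`, `hh`; `tl`/`th` in kelvin).
#' * `wang_mortality_1` — U-shaped daily mortality
#'   `1 - s_opt * exp(-k ((T - t_opt)/b)^2)`, clipped to `[0, 1]`
#'   (params `s_opt`, `t_opt`, `b`, optional `k`, default 1).
#' * `taylor_fecundity_1` — Gaussian lifetime fecundity
#'   `f_max * exp(-0.5 ((T - t_opt)/sigma)^2)` (params `f_max`, `t_opt`,
#'   `sigma`).
#' * `exp_modified_cumfec_3` — cumulative egg-laying fraction by normalized
#'   female age, `1 - exp(-(a x + b x^2 + c x^3))` with non-negative
#'   coefficients (params `a`, `b`, `c`).
#' * `exp_simple_senescence` — adult aging rate `a * exp(b * T)`
#'   (params `a`, `b`).
#' * `cll_devtime` — complementary log-log development-time distribution on
#'   normalized (physiological) age, `F(x) = 1 - exp(-exp(a + b log x))`
#'   (params `a`, `b > 0`).
#' * `logit_devtime` — logistic distribution `F(x) = 1/(1 + exp(-(a + b log x)))`
#'   (params `a`, `b > 0`).
#'
#' @param family One of the family names listed above.
#' @param params Named list or numeric vector of parameters; arity and
#'   constraints are checked at construction.
#' @param temp_domain Length-2 numeric, the temperature interval (deg C) on
#'   which the curve applies. Ignored by the two normalized-age
#'   distributions. Default `c(-50, 60)` (effectively unbounded).
#' @return An object of class `fn_spec`.
#' @examples
#' briere <- fn_spec("briere_1", list(a = 1e-4, t_min = 8, t_max = 35))
#' evaluate_rate(briere, c(8, 25, 36))
#' @export
fn_spec <- function(family, params, temp_domain = c(-50, 60)) {
  family <- match.arg(family, names(.fn_families))
  params <- as.list(params)
  req <- .fn_families[[family]]$required
  opt <- .fn_families[[family]]$optional
  missing <- setdiff(req, names(params))
  if (length(missing) > 0) {
    abort(sprintf("fn_spec('%s'): missing parameter(s) %s",
                  family, paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(params), c(req, names(opt)))
  if (length(extra) > 0) {
    abort(sprintf("fn_spec('%s'): unknown parameter(s) %s",
                  family, paste(extra, collapse = ", ")))
  }
  for (nm in names(opt)) {
    params[[nm]] <- params[[nm]] %||% opt[[nm]]
  }
  params <- lapply(params, as.numeric)
  if (!is.numeric(temp_domain) || length(temp_domain) != 2 ||
      temp_domain[1] >= temp_domain[2]) {
    abort("temp_domain must be an increasing length-2 numeric interval")
  }
  check <- .fn_families[[family]]$check
  if (!is.null(check)) check(params)
  structure(
    list(family = family, params = params, temp_domain = as.numeric(temp_domain)),
    class = "fn_spec"
  )
}

# registry: arity, optional defaults and constraint checks per family.
# kind drives which evaluate_* verbs accept the family.
.fn_families <- list(
  briere_1 = list(
    required = c("a", "t_min", "t_max"), optional = list(), kind = "rate",
    check = function(p) {
      if (p$t_min >= p$t_max) abort("briere_1: t_min must be < t_max")
      if (p$a < 0) abort("briere_1: a must be >= 0")
    }
  ),
  sharpe_demichele_1 = list(
    required = c("rho25", "ha", "tl", "hl", "th", "hh"),
    optional = list(), kind = "rate",
    check = function(p) {
      if (p$rho25 < 0) abort("sharpe_demichele_1: rho25 must be >= 0")
      if (p$tl <= 0 || p$th <= 0) {
        abort("sharpe_demichele_1: tl and th are kelvin temperatures (> 0)")
      }
    }
  ),
  wang_mortality_1 = list(
    required = c("s_opt", "t_opt", "b"), optional = list(k = 1),
    kind = "mortality",
    check = function(p) {
      if (p$s_opt <= 0 || p$s_opt > 1) abort("wang_mortality_1: s_opt must be in (0, 1]")
      if (p$b <= 0) abort("wang_mortality_1: b must be > 0")
      if (p$k <= 0) abort("wang_mortality_1: k must be > 0")
    }
  ),
  taylor_fecundity_1 = list(
    required = c("f_max", "t_opt", "sigma"), optional = list(),
    kind = "fecundity",
    check = function(p) {
      if (p$f_max < 0) abort("taylor_fecundity_1: f_max must be >= 0")
      if (p$sigma <= 0) abort("taylor_fecundity_1: sigma must be > 0")
    }
  ),
  exp_modified_cumfec_3 = list(
    required = c("a", "b", "c"), optional = list(), kind = "cumfec",
    check = function(p) {
      if (p$a < 0 || p$b < 0 || p$c < 0) {
        abort("exp_modified_cumfec_3: coefficients must be >= 0")
      }
      if (p$a + p$b + p$c <= 0) {
        abort("exp_modified_cumfec_3: at least one coefficient must be > 0")
      }
    }
  ),
  exp_simple_senescence = list(
    required = c("a", "b"), optional = list(), kind = "senescence",
    check = function(p) if (p$a <= 0) abort("exp_simple_senescence: a must be > 0")
  ),
  cll_devtime = list(
    required = c("a", "b"), optional = list(), kind = "devtime",
    check = function(p) if (p$b <= 0) abort("cll_devtime: b must be > 0")
  ),
  logit_devtime = list(
    required = c("a", "b"), optional = list(), kind = "devtime",
    check = function(p) if (p$b <= 0) abort("logit_devtime: b must be > 0")
  )
)

fn_kind <- function(spec) .fn_families[[spec$family]]$kind

#' @export
print.fn_spec <- function(x, ...) {
  cat(sprintf("<fn_spec: %s>\n", x$family))
  cat("  params:",
      paste(sprintf("%s = %.6g", names(x$params), unlist(x$params)),
            collapse = ", "), "\n")
  cat(sprintf("  temp_domain: [%g, %g] degC\n",
              x$temp_domain[1], x$temp_domain[2]))
  invisible(x)
}

.assert_kind <- function(spec, kinds, verb) {
  if (!inherits(spec, "fn_spec")) abort(sprintf("%s() needs a fn_spec", verb))
  if (!fn_kind(spec) %in% kinds) {
    abort(sprintf("%s() does not accept family '%s'", verb, spec$family))
  }
}

#' Evaluate a development-rate curve
#'
#' Returns the development rate (per day) at temperature `temp`. Rates are
#' never negative; Briere-1 is exactly 0 outside `[t_min, t_max]`, and every
#' rate family returns 0 outside the spec's `temp_domain`.
#'
#' @param spec A [fn_spec()] of a rate family (`briere_1`,
#'   `sharpe_demichele_1`).
#' @param temp Temperature(s) in deg C.
#' @return Numeric vector of rates (1/day), same length as `temp`.
#' @export
evaluate_rate <- function(spec, temp) {
  .assert_kind(spec, "rate", "evaluate_rate")
  p <- spec$params
  out <- switch(
    spec$family,
    briere_1 = {
      inside <- temp >= p$t_min & temp <= p$t_max
      r <- numeric(length(temp))
      ti <- temp[inside]
      r[inside] <- p$a * ti * (ti - p$t_min) * sqrt(p$t_max - ti)
      r
    },
    sharpe_demichele_1 = {
      R <- 1.987
      tk <- temp + 273.15
      num <- p$rho25 * (tk / 298.15) * exp(p$ha / R * (1 / 298.15 - 1 / tk))
      den <- 1 + exp(p$hl / R * (1 / p$tl - 1 / tk)) +
        exp(p$hh / R * (1 / p$th - 1 / tk))
      num / den
    }
  )
  out[temp < spec$temp_domain[1] | temp > spec$temp_domain[2]] <- 0
  pmax(out, 0)
}

#' Evaluate a U-shaped mortality curve
#'
#' Daily mortality probability of an immature stage at temperature `temp`,
#' minimal at the curve optimum and approaching 1 at temperature extremes.
#' Outside the spec's `temp_domain` mortality is exactly 1.
#'
#' @inheritParams evaluate_rate
#' @param spec A [fn_spec()] with family `wang_mortality_1`.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
evaluate_mortality <- function(spec, temp) {
  .assert_kind(spec, "mortality", "evaluate_mortality")
  p <- spec$params
  m <- 1 - p$s_opt * exp(-p$k * ((temp - p$t_opt) / p$b)^2)
  m <- pmin(pmax(m, 0), 1)
  m[temp < spec$temp_domain[1] | temp > spec$temp_domain[2]] <- 1
  m
}

#' Evaluate a normalized development-time distribution
#'
#' Cumulative probability that an individual has completed the stage by
#' normalized (physiological) age `x`, where `x = 1` is the median
#' development time. CLL: `F(x) = 1 - exp(-exp(a + b log x))`; logit:
#' `F(x) = 1/(1 + exp(-(a + b log x)))`.
#'
#' @param spec A [fn_spec()] with family `cll_devtime` or `logit_devtime`.
#' @param x Normalized age(s), strictly positive.
#' @return Numeric vector of probabilities, non-decreasing in `x`.
#' @export
evaluate_devtime_cdf <- function(spec, x) {
  .assert_kind(spec, "devtime", "evaluate_devtime_cdf")
  if (any(x <= 0)) abort("evaluate_devtime_cdf(): normalized age x must be > 0")
  p <- spec$params
  eta <- p$a + p$b * log(x)
  switch(spec$family,
    cll_devtime = 1 - exp(-exp(eta)),
    logit_devtime = 1 / (1 + exp(-eta))
  )
}

# quantile function of a devtime distribution (inverse CDF), used by the
# cohort simulator to place sub-cohort exit thresholds.
devtime_quantile <- function(spec, q) {
  .assert_kind(spec, "devtime", "devtime_quantile")
  stopifnot(all(q > 0 & q < 1))
  p <- spec$params
  eta <- switch(spec$family,
    cll_devtime = log(-log(1 - q)),
    logit_devtime = log(q / (1 - q))
  )
  exp((eta - p$a) / p$b)
}

#' Evaluate a mean-fecundity curve
#'
#' Lifetime fecundity (eggs per female) laid by a female living at
#' temperature `temp`: Gaussian `f_max * exp(-0.5 ((T - t_opt)/sigma)^2)`,
#' 0 outside the spec's `temp_domain`.
#'
#' @inheritParams evaluate_rate
#' @param spec A [fn_spec()] with family `taylor_fecundity_1`.
#' @return Numeric vector of egg counts (>= 0).
#' @export
evaluate_fecundity <- function(spec, temp) {
  .assert_kind(spec, "fecundity", "evaluate_fecundity")
  p <- spec$params
  f <- p$f_max * exp(-0.5 * ((temp - p$t_opt) / p$sigma)^2)
  f[temp < spec$temp_domain[1] | temp > spec$temp_domain[2]] <- 0
  f
}

#' Evaluate a cumulative-fecundity curve over normalized female age
#'
#' Fraction of lifetime eggs laid by normalized female age `x`:
#' `1 - exp(-(a x + b x^2 + c x^3))`, a monotone curve with `C(0) = 0`.
#'
#' @param spec A [fn_spec()] with family `exp_modified_cumfec_3`.
#' @param x Normalized female age(s) (>= 0).
#' @return Numeric vector of fractions in `[0, 1)`.
#' @export
evaluate_cumulative_fecundity <- function(spec, x) {
  .assert_kind(spec, "cumfec", "evaluate_cumulative_fecundity")
  if (any(x < 0)) abort("normalized female age must be >= 0")
  p <- spec$params
  1 - exp(-(p$a * x + p$b * x^2 + p$c * x^3))
}

#' Evaluate an adult senescence (aging-rate) curve
#'
#' Daily physiological aging rate of adults, `a * exp(b * T)`. The adult
#' dies when accumulated senescence age reaches its longevity quantile.
#'
#' @inheritParams evaluate_rate
#' @param spec A [fn_spec()] with family `exp_simple_senescence`.
#' @return Numeric vector of positive rates (1/day).
#' @export
evaluate_senescence <- function(spec, temp) {
  .assert_kind(spec, "senescence", "evaluate_senescence")
  p <- spec$params
  p$a * exp(p$b * temp)
}

# generic dispatcher used by fitting and plotting: evaluate any family at
# its natural abscissa (temperature or normalized age).
evaluate_fn <- function(spec, x) {
  switch(fn_kind(spec),
    rate = evaluate_rate(spec, x),
    mortality = evaluate_mortality(spec, x),
    fecundity = evaluate_fecundity(spec, x),
    senescence = evaluate_senescence(spec, x),
    devtime = evaluate_devtime_cdf(spec, x),
    cumfec = evaluate_cumulative_fecundity(spec, x)
  )
}
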
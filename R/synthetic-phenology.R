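#' Specify and generate a synthetic phenology model
#'
#' Builds a complete [phenology_model()] with a known thermal optimum, so
#' downstream stages (cohort simulation, risk mapping, parameter-recovery
#' tests) run against a ground truth. Development-rate curves peak within
#' a fraction of a degree of `optimum` (egg and larva via the
#' Sharpe–DeMichele biophysical form with the high-inhibition enthalpy
#' midpoint tuned numerically; pupa via Briere-1 with the upper threshold
#' placed analytically); mortality is minimal at `optimum` and exactly 1
#' outside `[lower_threshold, upper_threshold]`; fecundity peaks at
#' `optimum`. A small seeded jitter (within +/- 0.5 deg C on stage optima,
#' +/- 10% on distribution shapes) differentiates the stages while keeping
#' every contract intact.
#'
#' @param lower_threshold,optimum,upper_threshold Thermal limits and
#'   optimum (deg C), strictly ordered.
#' @param peak_daily_rate Egg development rate at the optimum (1/day);
#'   larval and pupal peaks are 0.40 and 0.55 of it, reflecting the usual
#'   ordering of stage durations.
#' @param peak_fecundity Lifetime eggs per female at the optimum.
#' @param survival_at_optimum Probability of surviving a whole immature
#'   stage at the optimum, in `(0, 1]`.
#' @param seed Integer seed for the stage jitter.
#' @return `synthetic_phenology_spec()` returns a validated spec;
#'   `gen_phenology_model()` returns a [phenology_model()].
#' @examples
#' model <- gen_phenology_model(synthetic_phenology_spec(optimum = 22.5))
#' @export
synthetic_phenology_spec <- function(lower_threshold = 10, optimum = 22.5,
                                     upper_threshold = 35,
                                     peak_daily_rate = 0.2,
                                     peak_fecundity = 260,
                                     survival_at_optimum = 0.97,
                                     seed = 1L) {
  if (!(lower_threshold < optimum && optimum < upper_threshold)) {
    abort("thresholds must satisfy lower_threshold < optimum < upper_threshold")
  }
  if (!(survival_at_optimum > 0 && survival_at_optimum <= 1)) {
    abort("survival_at_optimum must be in (0, 1]")
  }
  if (peak_daily_rate <= 0 || peak_fecundity < 0) {
    abort("peak_daily_rate must be > 0 and peak_fecundity >= 0")
  }
  structure(
    list(lower_threshold = lower_threshold, optimum = optimum,
         upper_threshold = upper_threshold,
         peak_daily_rate = peak_daily_rate,
         peak_fecundity = peak_fecundity,
         survival_at_optimum = survival_at_optimum,
         seed = as.integer(seed)),
    class = "synthetic_phenology_spec")
}

# Sharpe-DeMichele spec whose rate peaks at `opt` with value `peak`:
# low-inhibition terms fixed near the lower threshold, high-inhibition
# midpoint th solved so the smooth argmax lands on `opt`, then rho25
# rescaled to the requested peak.
.sd1_with_peak <- function(opt, peak, lower, upper) {
  base <- list(rho25 = 0.1, ha = 20000, tl = lower + 273.15, hl = -70000,
               th = opt + 273.15, hh = 200000)
  argmax_for <- function(th) {
    sp <- fn_spec("sharpe_demichele_1", modifyList(base, list(th = th)),
                  temp_domain = c(lower, upper))
    stats::optimize(function(t) -evaluate_rate(sp, t),
                    c(lower + 0.1, upper - 0.1))$minimum
  }
  th <- stats::uniroot(function(th) argmax_for(th) - opt,
                       c(opt + 273.15 - 8, opt + 273.15 + 20),
                       tol = 1e-6)$root
  sp <- fn_spec("sharpe_demichele_1", modifyList(base, list(th = th)),
                temp_domain = c(lower, upper))
  pk <- evaluate_rate(sp, opt)
  sp$params$rho25 <- sp$params$rho25 * peak / pk
  fn_spec("sharpe_demichele_1", sp$params, temp_domain = c(lower, upper))
}

# Briere-1 with lower threshold `lower` and peak exactly at `opt`:
# setting dr/dT = 0 gives t_max = opt + opt (opt - t_min) / (2 (2 opt - t_min)).
.briere_with_peak <- function(opt, peak, lower, upper) {
  t_max <- opt + opt * (opt - lower) / (2 * (2 * opt - lower))
  sp <- fn_spec("briere_1", list(a = 1, t_min = lower, t_max = t_max),
                temp_domain = c(lower, upper))
  sp$params$a <- peak / evaluate_rate(sp, opt)
  fn_spec("briere_1", sp$params, temp_domain = c(lower, upper))
}

.wang_for_stage <- function(opt, lower, upper, stage_survival, peak_rate) {
  # daily survival that compounds to the requested per-stage survival over
  # the mean stage duration 1/peak_rate; the curve widens so that daily
  # mortality is ~0.3 at the thermal thresholds and jumps to 1 beyond them
  # (domain clamp), giving the flat-bottomed U real stages show
  s_daily <- stage_survival^peak_rate
  delta <- min(opt - lower, upper - opt)
  b <- delta / sqrt(log(max(s_daily / 0.7, 1.05)))
  fn_spec("wang_mortality_1",
          list(s_opt = s_daily, t_opt = opt, b = b, k = 1),
          temp_domain = c(lower, upper))
}

#' @rdname synthetic_phenology_spec
#' @param spec A `synthetic_phenology_spec`.
#' @export
gen_phenology_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_phenology_spec"))
  lo <- spec$lower_threshold; opt <- spec$optimum; hi <- spec$upper_threshold
  jit <- withr::with_seed(spec$seed, list(
    opt = pmin(pmax(rnorm(3, 0, 0.2), -0.5), 0.5),
    shape = exp(rnorm(4, 0, 0.05))
  ))
  peaks <- spec$peak_daily_rate * c(egg = 1, larva = 0.40, pupa = 0.55)
  opts <- pmin(pmax(opt + jit$opt, lo + 2), hi - 2)

  cll <- function(b) fn_spec("cll_devtime", list(a = log(log(2)), b = b))
  lgt <- function(b) fn_spec("logit_devtime", list(a = 0, b = b))

  make_imm <- function(stage, rate_spec, stage_opt, dist) {
    stage_model(stage,
                devtime_dist = dist,
                dev_rate = rate_spec,
                mortality = .wang_for_stage(stage_opt, lo, hi,
                                            spec$survival_at_optimum,
                                            rate_spec |> evaluate_rate(stage_opt)))
  }
  egg <- make_imm("egg", .sd1_with_peak(opts[1], peaks["egg"], lo, hi),
                  opts[1], cll(12 * jit$shape[1]))
  larva <- make_imm("larva", .sd1_with_peak(opts[2], peaks["larva"], lo, hi),
                    opts[2], lgt(10 * jit$shape[2]))
  pupa <- make_imm("pupa", .briere_with_peak(opts[3], peaks["pupa"], lo, hi),
                   opts[3], cll(12 * jit$shape[3]))

  # adults: median longevity ~22 days at the optimum, mild thermal speed-up
  b_sen <- 0.07
  a_sen <- (1 / 22) * exp(-b_sen * opt)
  senescence <- fn_spec("exp_simple_senescence", list(a = a_sen, b = b_sen))
  longevity <- cll(8 * jit$shape[4])
  af <- stage_model("adult_female", devtime_dist = longevity,
                    senescence = senescence)
  am <- stage_model("adult_male", devtime_dist = longevity,
                    senescence = senescence)

  phenology_model(
    stages = list(egg, larva, pupa, af, am),
    fecundity_mean = fn_spec(
      "taylor_fecundity_1",
      list(f_max = spec$peak_fecundity, t_opt = opt, sigma = (hi - lo) / 6),
      temp_domain = c(lo, hi)),
    fecundity_cum = fn_spec("exp_modified_cumfec_3",
                            list(a = 0.2, b = 2.8, c = 0.5)),
    sex_ratio = 0.5
  )
}

#' Generate noisy life-table observations from a phenology model
#'
#' Emulates a constant-temperature laboratory life-table experiment:
#' per temperature and replicate, draws development time, development
#' rate, stage survival and fecundity around the model's true curves.
#' Noise is multiplicative lognormal (mean-preserving) on times, rates
#' and fecundity and binomial (cohorts of 30) on survival fractions;
#' `noise_sd = 0` returns the exact curve values, so refitting the
#' noiseless table recovers the generating parameters exactly.
#'
#' @param model A [phenology_model()].
#' @param temperatures Non-empty numeric vector of test temperatures
#'   (deg C); the classical design uses 15, 20, 25, 30 and 35.
#' @param n_per_temp Replicates per temperature (>= 1).
#' @param noise_sd Relative noise level (lognormal sd; default 0.05).
#' @param seed Integer seed.
#' @return A tibble with columns `stage`, `temperature_C`, `trait`
#'   (`development_time`, `development_rate`, `survival`, `fecundity`),
#'   `value` and `replicate`. Temperatures where a stage cannot develop
#'   yield `NA` development times.
#' @export
gen_lifetable_observations <- function(model, temperatures = c(15, 20, 25, 30, 35),
                                       n_per_temp = 30, noise_sd = 0.05,
                                       seed = 1L) {
  stopifnot(inherits(model, "phenology_model"))
  if (length(temperatures) == 0) abort("temperatures must be non-empty")
  if (n_per_temp < 1) abort("n_per_temp must be >= 1")

  lognoise <- function(true, n) {
    if (noise_sd == 0) rep(true, n)
    else true * exp(rnorm(n, -noise_sd^2 / 2, noise_sd))
  }
  rows <- withr::with_seed(seed, {
    acc <- list()
    for (tt in temperatures) {
      for (nm in names(immature_stages(model))) {
        st <- model$stages[[nm]]
        rate <- evaluate_rate(st$dev_rate, tt)
        m <- evaluate_mortality(st$mortality, tt)
        devt <- if (rate > 1e-9) 1 / rate else NA_real_
        s <- if (rate > 1e-9) (1 - m)^(1 / rate) else 0
        sobs <- if (noise_sd == 0) rep(s, n_per_temp)
                else rbinom(n_per_temp, 30, s) / 30
        acc[[length(acc) + 1]] <- tibble(
          stage = nm, temperature_C = tt,
          trait = rep(c("development_time", "development_rate", "survival"),
                      each = n_per_temp),
          value = c(if (is.na(devt)) rep(NA_real_, n_per_temp)
                    else lognoise(devt, n_per_temp),
                    lognoise(rate, n_per_temp),
                    sobs),
          replicate = rep(seq_len(n_per_temp), 3))
      }
      fec <- evaluate_fecundity(model$fecundity_mean, tt)
      acc[[length(acc) + 1]] <- tibble(
        stage = "adult_female", temperature_C = tt, trait = "fecundity",
        value = lognoise(fec, n_per_temp), replicate = seq_len(n_per_temp))
    }
    dplyr::bind_rows(acc)
  })
  rows
}
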
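# Shared fixtures, built in code at test time.

# A simple hand-built model with analytically convenient curves:
# egg rate 0.2/day at 25 C (Briere scaled), all stages share the same
# curve shapes, mortality optionally zero.
simple_model <- function(zero_mortality = FALSE, b_dist = 20) {
  briere_at <- function(peak, t_ref = 25, t_min = 8, t_max = 35) {
    a <- peak / (t_ref * (t_ref - t_min) * sqrt(t_max - t_ref))
    fn_spec("briere_1", list(a = a, t_min = t_min, t_max = t_max))
  }
  mort <- if (zero_mortality) {
    fn_spec("wang_mortality_1", list(s_opt = 1, t_opt = 25, b = 1000))
  } else {
    fn_spec("wang_mortality_1", list(s_opt = 0.995, t_opt = 25, b = 12))
  }
  cll <- fn_spec("cll_devtime", list(a = log(log(2)), b = b_dist))
  mk <- function(stage, peak) {
    stage_model(stage, devtime_dist = cll, dev_rate = briere_at(peak),
                mortality = mort)
  }
  sen <- fn_spec("exp_simple_senescence", list(a = 0.05 / exp(0.05 * 25), b = 0.05))
  ad <- function(stage) stage_model(stage, devtime_dist = cll, senescence = sen)
  phenology_model(
    list(mk("egg", 0.2), mk("larva", 0.1), mk("pupa", 0.15),
         ad("adult_female"), ad("adult_male")),
    fecundity_mean = fn_spec("taylor_fecundity_1",
                             list(f_max = 100, t_opt = 25, sigma = 5)),
    fecundity_cum = fn_spec("exp_modified_cumfec_3",
                            list(a = 0.2, b = 2.8, c = 0.5)),
    sex_ratio = 0.5
  )
}

# Hand-built 365-day series with the columns the index functions use.
const_series <- function(lambda = 1.1, r0 = 2, tc = 50, surv = 0.9, n = 365) {
  tibble::tibble(
    day = seq_len(n), r0 = r0, grr = r0, tc = tc,
    r = log(lambda), lambda = lambda,
    surv_egg = surv, surv_larva = surv, surv_pupa = surv
  )
}

# random l_x/m_x schedules for Lotka-Euler property tests
random_schedule <- function(n_days = 50) {
  x <- seq_len(n_days) - 0.5
  lx <- cumprod(runif(n_days, 0.9, 1))
  mx <- numeric(n_days)
  repro <- sample(10:n_days, 15)
  mx[repro] <- runif(15, 0, 3)
  tibble::tibble(x = x, l_x = lx, m_x = mx)
}
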
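test_that("Briere-1 evaluates its canonical form and thresholds", {
  sp <- fn_spec("briere_1", list(a = 1e-4, t_min = 8, t_max = 35))
  expect_equal(evaluate_rate(sp, 8), 0)
  expect_equal(evaluate_rate(sp, 25), 1e-4 * 25 * 17 * sqrt(10))
  expect_equal(evaluate_rate(sp, 36), 0)
  expect_equal(evaluate_rate(sp, 7), 0)
  # temp_domain clips even inside [t_min, t_max]
  sp2 <- fn_spec("briere_1", list(a = 1e-4, t_min = 8, t_max = 35),
                 temp_domain = c(10, 30))
  expect_equal(evaluate_rate(sp2, 32), 0)
  expect_gt(evaluate_rate(sp2, 25), 0)
})

test_that("development-time distributions match closed forms and are monotone", {
  lgt <- fn_spec("logit_devtime", list(a = 0, b = 5))
  cll <- fn_spec("cll_devtime", list(a = 0, b = 5))
  expect_equal(evaluate_devtime_cdf(lgt, 1), 0.5)
  expect_equal(evaluate_devtime_cdf(cll, 1), 1 - exp(-1))
  for (sp in list(lgt, cll)) {
    xs <- sort(runif(20, 0.05, 4))
    Fx <- evaluate_devtime_cdf(sp, xs)
    expect_true(all(diff(Fx) >= 0))
    expect_true(all(Fx >= 0 & Fx <= 1))
    expect_gte(evaluate_devtime_cdf(sp, 2), evaluate_devtime_cdf(sp, 1))
  }
  expect_error(evaluate_devtime_cdf(lgt, 0), "must be > 0")
  # quantile inverts the CDF
  q <- phenorisk:::devtime_quantile(cll, c(0.1, 0.5, 0.9))
  expect_equal(evaluate_devtime_cdf(cll, q), c(0.1, 0.5, 0.9))
})

test_that("Taylor fecundity is Gaussian around its optimum", {
  sp <- fn_spec("taylor_fecundity_1", list(f_max = 120, t_opt = 23, sigma = 4))
  expect_equal(evaluate_fecundity(sp, 23), 120)
  expect_equal(evaluate_fecundity(sp, 27), 120 * exp(-0.5))
  expect_equal(evaluate_fecundity(sp, 19), 120 * exp(-0.5))
  expect_lt(evaluate_fecundity(sp, 23 + 6 * 4), 1e-6 * 120)
})

test_that("exponential senescence matches its closed form", {
  flat <- fn_spec("exp_simple_senescence", list(a = 0.02, b = 0))
  expect_equal(evaluate_senescence(flat, c(-10, 0, 40)), rep(0.02, 3))
  sp <- fn_spec("exp_simple_senescence", list(a = 0.01, b = 0.1))
  expect_equal(evaluate_senescence(sp, 20), 0.01 * exp(2))
  expect_gt(evaluate_senescence(sp, 30), evaluate_senescence(sp, 20))
})

test_that("Wang-type mortality is a clipped symmetric U", {
  sp <- fn_spec("wang_mortality_1", list(s_opt = 0.95, t_opt = 25, b = 5))
  expect_equal(evaluate_mortality(sp, 25), 1 - 0.95)
  d <- runif(10, 0, 8)
  expect_equal(evaluate_mortality(sp, 25 + d), evaluate_mortality(sp, 25 - d),
               tolerance = 1e-9)
  expect_gte(min(evaluate_mortality(sp, c(-25, 75))), 0.999)
  # domain boundary behaviour: mortality 1 outside temp_domain
  sp2 <- fn_spec("wang_mortality_1", list(s_opt = 0.95, t_opt = 25, b = 5),
                 temp_domain = c(10, 35))
  expect_equal(evaluate_mortality(sp2, c(9.9, 35.1)), c(1, 1))
})

test_that("cumulative fecundity starts at zero and saturates monotonically", {
  sp <- fn_spec("exp_modified_cumfec_3", list(a = 0.2, b = 2.8, c = 0.5))
  expect_equal(evaluate_cumulative_fecundity(sp, 0), 0)
  xs <- seq(0, 1.2, by = 0.05)
  cx <- evaluate_cumulative_fecundity(sp, xs)
  expect_true(all(diff(cx) > 0))
  expect_true(all(cx >= 0 & cx < 1))
  # saturates toward (but never exceeds) 1 at old ages
  expect_lte(max(evaluate_cumulative_fecundity(sp, seq(0, 5, 0.1))), 1)
})

test_that("evaluations respect range contracts over random specs", {
  withr::with_seed(42, {
    for (i in 1:25) {
      tt <- runif(20, -30, 60)
      br <- fn_spec("briere_1",
                    list(a = runif(1, 1e-5, 1e-3), t_min = runif(1, 0, 12),
                         t_max = runif(1, 25, 40)))
      expect_true(all(evaluate_rate(br, tt) >= 0))
      wg <- fn_spec("wang_mortality_1",
                    list(s_opt = runif(1, 0.2, 1), t_opt = runif(1, 15, 30),
                         b = runif(1, 2, 20)))
      m <- evaluate_mortality(wg, tt)
      expect_true(all(m >= 0 & m <= 1))
      sd1 <- fn_spec("sharpe_demichele_1",
                     list(rho25 = runif(1, 0.01, 0.5), ha = runif(1, 5e3, 5e4),
                          tl = 280, hl = -runif(1, 3e4, 1e5),
                          th = runif(1, 295, 310), hh = runif(1, 1e5, 5e5)))
      expect_true(all(evaluate_rate(sd1, tt) >= 0))
    }
  })
})

test_that("construction validates arity and constraints; verbs check kinds", {
  expect_error(fn_spec("briere_1", list(a = 1e-4, t_min = 8)), "missing parameter")
  expect_error(fn_spec("briere_1", list(a = 1e-4, t_min = 8, t_max = 35, z = 1)),
               "unknown parameter")
  expect_error(fn_spec("briere_1", list(a = 1e-4, t_min = 35, t_max = 8)),
               "t_min must be <")
  expect_error(fn_spec("cll_devtime", list(a = 0, b = -1)), "b must be > 0")
  br <- fn_spec("briere_1", list(a = 1e-4, t_min = 8, t_max = 35))
  expect_error(evaluate_mortality(br, 20), "does not accept")
  expect_error(evaluate_fecundity(br, 20), "does not accept")
  expect_error(evaluate_rate(fn_spec("taylor_fecundity_1",
    list(f_max = 1, t_opt = 20, sigma = 2)), 20), "does not accept")
})
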
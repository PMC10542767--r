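test_that("ERI follows the survivable-day fraction and reproduction rule", {
  full <- const_series(r0 = 5, surv = 0.9)
  expect_equal(compute_eri(full), 1)
  none <- const_series(r0 = 5, surv = 0.001)
  expect_equal(compute_eri(none), 0)
  expect_equal(compute_eri(none, reproduction_rule = "capped"), 0)
  # 146 survivable days with replacement-level reproduction: 146/365 = 0.4
  part <- const_series(r0 = 5, surv = 0.9)
  part$surv_larva[147:365] <- 0.001
  expect_equal(compute_eri(part), 146 / 365)
  expect_equal(compute_eri(part), 0.4)
  # below-replacement reproduction zeroes (indicator) or scales (capped)
  poor <- const_series(r0 = 0.5, surv = 0.9)
  expect_equal(compute_eri(poor), 0)
  expect_equal(compute_eri(poor, reproduction_rule = "capped"), 0.5)
  expect_error(compute_eri(const_series(n = 100)), "365")
})

test_that("GI averages completable generations, skipping non-replacing days", {
  expect_equal(compute_gi(const_series(r0 = 3, tc = 36.5)), 10)
  expect_equal(compute_gi(const_series(r0 = 3, tc = 365)), 1)
  half <- const_series(r0 = 3, tc = 30)
  half$r0[183:365] <- 0.5  # cannot replace itself: contributes 0
  expect_equal(compute_gi(half), 182 * (365 / 30) / 365)
  expect_equal(compute_gi(half), 6.066, tolerance = 1e-3)
  all_dead <- const_series(r0 = 0, tc = NA_real_, lambda = 0)
  expect_equal(compute_gi(all_dead), 0)
})

test_that("AI is the log10 yearly growth factor", {
  expect_equal(compute_ai(const_series(lambda = 1)), 0)
  ser <- const_series(lambda = 10^(4 / 365))
  expect_equal(compute_ai(ser), 4)
  expect_equal(10^compute_ai(ser), 10000)
  two <- const_series(lambda = 1.02)
  two$lambda[183:365] <- 0.99
  expect_equal(compute_ai(two), 182 * log10(1.02) + 183 * log10(0.99))
  expect_equal(compute_ai(two), 0.766469, tolerance = 1e-5)
  # lethal days are floored, not -Inf
  lethal <- const_series(lambda = 1)
  lethal$lambda[1] <- 0
  expect_equal(compute_ai(lethal), log10(1e-6))
  expect_equal(compute_ai(lethal, lambda_floor = 1e-3), -3)
  neg <- const_series(); neg$lambda[5] <- -0.1
  expect_error(compute_ai(neg), "negative lambda")
})

test_that("ERI classification uses half-open bins with a closed top", {
  cls <- classify_eri(c(0, 0.19, 0.2, 0.39, 0.4, 0.6, 0.65, 0.8, 1.0))
  expect_equal(as.character(cls$eri_class),
               c("unsuitable", "unsuitable", "marginal", "marginal",
                 "suitable", "highly_suitable", "highly_suitable",
                 "optimal", "optimal"))
  expect_equal(cls$permanent_establishment,
               c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_error(classify_eri(1.2), "\\[0, 1\\]")
  expect_error(classify_eri(-0.1), "\\[0, 1\\]")
})

test_that("index invariants hold over random series", {
  withr::with_seed(99, {
    for (i in 1:20) {
      ser <- const_series(r0 = runif(1, 0, 6), surv = 1)
      ser$lambda <- runif(365, 0.5, 1.5)
      ser$r0 <- runif(365, 0, 6)
      ser$tc <- runif(365, 20, 80)
      surv_cols <- c("surv_egg", "surv_larva", "surv_pupa")
      for (sc in surv_cols) ser[[sc]] <- runif(365, 0, 0.6)
      eri <- compute_eri(ser)
      expect_gte(eri, 0); expect_lte(eri, 1)
      # GI is permutation invariant
      perm <- ser[sample(365), ]
      expect_equal(compute_gi(perm), compute_gi(ser))
      # AI inverts to the lambda product when no flooring triggers
      expect_equal(10^compute_ai(ser), prod(ser$lambda), tolerance = 1e-9)
      # ERI is monotone in the number of survivable days
      better <- ser
      flip <- sample(365, 40)
      for (sc in surv_cols) better[[sc]][flip] <- 0.9
      expect_gte(compute_eri(better, reproduction_rule = "capped"),
                 compute_eri(ser, reproduction_rule = "capped"))
    }
  })
})
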
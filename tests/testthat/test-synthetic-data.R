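test_that("temperature grids are deterministic and respect construction rules", {
  spec <- synthetic_grid_spec(n_rows = 8, n_cols = 6, seed = 1)
  g1 <- gen_temperature_grid(spec)
  g2 <- gen_temperature_grid(spec)
  expect_identical(g1$tmin, g2$tmin)
  expect_identical(g1$tmax, g2$tmax)
  g3 <- gen_temperature_grid(synthetic_grid_spec(n_rows = 8, n_cols = 6, seed = 2))
  expect_false(identical(g1$tmin, g3$tmin))
  # max >= min cellwise even with noise
  expect_true(all(g1$tmax >= g1$tmin))
  # diurnal range exact when noiseless
  g0 <- gen_temperature_grid(synthetic_grid_spec(
    n_rows = 5, n_cols = 4, noise_sd = 0, diurnal_range = 10))
  expect_equal(max(abs((g0$tmax - g0$tmin) - 10)), 0)
  expect_error(synthetic_grid_spec(n_rows = 0), "positive")
  expect_error(synthetic_grid_spec(noise_sd = -1), ">= 0")
})

test_that("latitudinal lapse and hemispheric seasonal phase are as constructed", {
  spec <- synthetic_grid_spec(n_rows = 18, n_cols = 2, lat_range = c(-45, 45),
                              mean_annual_temp_at_equator = 28,
                              lapse_per_degree_lat = 0.5,
                              seasonal_amplitude = 5, noise_sd = 0,
                              diurnal_range = 8)
  g <- gen_temperature_grid(spec)
  tb <- tibble::as_tibble(g)
  means <- dplyr::summarise(
    dplyr::group_by(tb, lat),
    annual = mean((tmin + tmax) / 2),
    july = mean(((tmin + tmax) / 2)[month == 7]),
    january = mean(((tmin + tmax) / 2)[month == 1]),
    .groups = "drop")
  # closed form of the generator: annual mean = 28 - 0.5 |lat|
  near20 <- means[which.min(abs(means$lat - 20)), ]
  expect_equal(near20$annual, 28 - 0.5 * abs(near20$lat), tolerance = 1e-9)
  # northern summer peaks in July, southern in January
  north <- means[means$lat > 10, ]
  south <- means[means$lat < -10, ]
  expect_true(all(north$july > north$january))
  expect_true(all(south$january > south$july))
})

test_that("generated phenology models honour optimum and survival contracts", {
  spec <- synthetic_phenology_spec(optimum = 22.5, seed = 3)
  m1 <- gen_phenology_model(spec)
  m2 <- gen_phenology_model(spec)
  expect_identical(m1$stages$larva$dev_rate$params,
                   m2$stages$larva$dev_rate$params)
  tg <- seq(10.1, 34.9, by = 0.01)
  for (nm in c("egg", "larva", "pupa")) {
    argmax <- tg[which.max(evaluate_rate(m1$stages[[nm]]$dev_rate, tg))]
    expect_lt(abs(argmax - 22.5), 1)
    # mortality minimal near the optimum, 1 outside the thresholds
    mort <- m1$stages[[nm]]$mortality
    expect_equal(evaluate_mortality(mort, c(9, 36)), c(1, 1))
    expect_lt(evaluate_mortality(mort, mort$params$t_opt), 0.05)
  }
  perfect <- gen_phenology_model(
    synthetic_phenology_spec(survival_at_optimum = 1, seed = 3))
  for (nm in c("egg", "larva", "pupa")) {
    mort <- perfect$stages[[nm]]$mortality
    expect_equal(evaluate_mortality(mort, mort$params$t_opt), 0)
  }
  expect_error(synthetic_phenology_spec(lower_threshold = 30, optimum = 20),
               "thresholds")
})

test_that("life-table observations reproduce the truth when noiseless", {
  model <- gen_phenology_model(synthetic_phenology_spec())
  obs <- gen_lifetable_observations(model, c(15, 20, 25, 30, 35),
                                    n_per_temp = 30, noise_sd = 0)
  devt <- dplyr::filter(obs, stage == "egg",
                        trait == "development_time")
  expect_equal(nrow(devt), 5 * 30)
  for (tt in c(15, 20, 25, 30)) {
    rate <- evaluate_rate(model$stages$egg$dev_rate, tt)
    vals <- devt$value[devt$temperature_C == tt]
    expect_equal(vals, rep(1 / rate, 30))
  }
  for (tr in unique(obs$trait)) {
    sub <- dplyr::filter(obs, trait == tr, stage ==
                           dplyr::first(obs$stage[obs$trait == tr]))
    expect_equal(nrow(sub), 5 * 30)
  }
  expect_error(gen_lifetable_observations(model, numeric(0)), "non-empty")
  expect_error(gen_lifetable_observations(model, 20, n_per_temp = 0), ">= 1")
})

test_that("fitting noiseless generated observations is an exact fixed point", {
  model <- gen_phenology_model(synthetic_phenology_spec())
  obs <- gen_lifetable_observations(model, c(12, 15, 18, 21, 24, 26),
                                    n_per_temp = 2, noise_sd = 0)
  rate_obs <- dplyr::filter(obs, stage == "pupa",
                            trait == "development_rate")
  tru <- model$stages$pupa$dev_rate
  fit <- fit_function("briere_1", dplyr::rename(rate_obs,
                                                temperature = "temperature_C"),
                      init = tru$params)
  expect_lt(fit$rss, 1e-10)
  fec_obs <- dplyr::filter(obs, trait == "fecundity")
  ffit <- fit_function("taylor_fecundity_1",
                       dplyr::rename(fec_obs, temperature = "temperature_C"))
  expect_lt(ffit$rss, 1e-10)
})
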
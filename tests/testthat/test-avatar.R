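test_that("feature building reproduces energy balance, macros, and weight deltas", {
  cat <- fx_catalog()
  d <- fx_diary(12, weights = 80 + 0.1 * (0:11))
  feats <- build_features(d, cat)
  expect_equal(nrow(feats), 12)
  eb <- daily_energy_balance(d, cat)
  expect_equal(feats$eb, eb$eb_kcal)
  expect_equal(feats$dw[1:11], rep(0.1, 11))
  expect_true(is.na(feats$dw[12]))
  expect_equal(feats$carb_frac + feats$protein_frac + feats$fat_frac,
               rep(1, 12))
})

test_that("short weight gaps are interpolated and long gaps stay unusable", {
  cat <- fx_catalog()
  w <- 80 + 0.1 * (0:19)
  w[c(5, 6)] <- NA          # 2-day gap: interpolable
  w[12:15] <- NA            # 4-day gap: too long
  d <- fx_diary(20, weights = w)
  feats <- build_features(d, cat)
  expect_equal(feats$weight[5], 80 + 0.1 * 4)
  expect_true(all(!feats$usable[12:15]))
  expect_true(feats$usable[5])
})

test_that("both backends learn the linear energy-balance physics without noise", {
  feats <- fx_series(120, noise = 0)
  for (bk in c("linear", "gru")) {
    cfg <- pma_config(backend = bk)
    m <- train_pma(feats[1:90, ], cfg)
    pred <- pma_predict(m, feats, 95:115)
    rmse <- sqrt(mean((pred - feats$dw[95:115])^2))
    expect_lt(rmse, 0.02)
  }
})

test_that("avatar training is deterministic given the configuration", {
  feats <- fx_series(100, noise = 0.2)
  cfg <- pma_config()
  m1 <- train_pma(feats, cfg)
  m2 <- train_pma(feats, cfg)
  expect_identical(m1$fit, m2$fit)
})

test_that("walk-forward validation never sees the weight it predicts", {
  # Decouple the weights from the diet: a pure random-walk weight series
  # carries no learnable signal, so any apparent skill (RMSE below the
  # step noise) would indicate the target leaking into training.
  set.seed(10)
  n <- 150
  feats <- fx_series(n, eb_sd = 500, noise = 0, seed = 10)
  dw_noise <- rnorm(n - 1, 0, 0.3)
  feats$weight <- 75 + c(0, cumsum(dw_noise))
  feats$dw <- c(dw_noise, NA)
  cfg <- pma_config(train_window_days = 90L)
  wfv <- walk_forward_validation(feats, cfg)
  expect_gt(wfv$rmse, 0.3 * 0.6)
})

test_that("walk-forward validation recovers the generator physics under noise", {
  feats <- fx_series(170, noise = 0.2, seed = 3)
  wfv <- walk_forward_validation(feats, pma_config())
  # predicting weight[t+1] = weight[t] + dw_hat against a 0.2 kg noise
  # floor: RMSE should sit near 0.2 kg
  expect_gt(wfv$rmse, 0.15)
  expect_lt(wfv$rmse, 0.35)
  expect_equal(nrow(wfv$predictions), wfv$n)
})

test_that("simulation with the factual diet equals plain forecasting", {
  feats <- fx_series(140, noise = 0)
  m <- train_pma(feats[1:90, ], pma_config())
  cf <- feats[100:113, c("date", feature_names())]
  s0 <- walk_forward_simulation(m, feats, feats$date[100], 14L)
  s1 <- walk_forward_simulation(m, feats, feats$date[100], 14L,
                                counterfactual = cf)
  expect_equal(s1$dw_simulated, s0$dw_simulated)
  expect_equal(s1$path, s0$path)
})

test_that("a sustained calorie cut simulates weight loss of the right size", {
  feats <- fx_series(140, noise = 0)
  m <- train_pma(feats[1:90, ], pma_config())
  cf <- feats[100:113, c("date", feature_names())]
  cf$eb <- cf$eb - 150
  s0 <- walk_forward_simulation(m, feats, feats$date[100], 14L)
  s1 <- walk_forward_simulation(m, feats, feats$date[100], 14L,
                                counterfactual = cf)
  response <- s0$dw_simulated - s1$dw_simulated
  theory <- 150 * 14 / 7700  # 0.273 kg
  expect_gt(response, theory * 0.6)
  expect_lt(response, theory * 1.4)
})

test_that("simulations refuse to start inside the training window", {
  feats <- fx_series(120, noise = 0)
  m <- train_pma(feats[1:90, ], pma_config())
  expect_error(walk_forward_simulation(m, feats, feats$date[80], 14L),
               class = "biohackr_error")
  expect_error(walk_forward_simulation(m, feats, feats$date[115], 14L),
               class = "biohackr_error")  # horizon past series end
})

test_that("period simulation pairs actual and simulated changes consistently", {
  cfg <- generator_config(n_days = 160L, rng_seed = 19L)
  cp <- generate_catalog(cfg)
  d <- generate_participant_diary(fx_profile(), cfg, catalog = cp$catalog,
                                  emissions = cp$emissions)
  res <- simulate_biohacked_periods(d, cp$catalog, cp$emissions,
                                    n_periods = 5L, seed = 2L)
  expect_equal(nrow(res), 5)
  expect_equal(as.integer(res$period_end - res$period_start), rep(14L, 5))
  expect_true(all(res$delta_eb >= 0))
  # actual change matches the recorded weights
  feats <- build_features(d, cp$catalog)
  i <- match(res$period_start[1], feats$date)
  expect_equal(res$dw_actual[1], feats$weight[i + 14] - feats$weight[i])
  # reproducible
  res2 <- simulate_biohacked_periods(d, cp$catalog, cp$emissions,
                                     n_periods = 5L, seed = 2L)
  expect_identical(res, res2)
})
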
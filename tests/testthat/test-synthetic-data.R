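test_that("generated catalogs satisfy all catalog invariants", {
  cp <- generate_catalog(generator_config(rng_seed = 5L))
  expect_silent(validate_catalog(cp$catalog))
  expect_silent(validate_emissions(cp$emissions))
  counts <- table(cp$catalog$macro_category)
  expect_equal(unname(counts[["condiment_spice"]]), 3)
  non_cond <- counts[names(counts) != "condiment_spice"]
  expect_true(all(non_cond == generator_config()$items_per_category))
  # every emission class used by the catalog is priced
  expect_true(all(cp$catalog$emission_class %in%
                    cp$emissions$emission_class))
})

test_that("emission class does not decrease with energy density within a category", {
  cp <- generate_catalog(generator_config(rng_seed = 9L))
  ranks <- match(cp$catalog$emission_class,
                 c("very_low", "low", "medium", "high", "very_high"))
  by_cat <- split(data.frame(k = cp$catalog$kcal_per_100g, r = ranks),
                  cp$catalog$macro_category)
  for (g in by_cat) {
    g <- g[order(g$k), ]
    expect_true(all(diff(g$r) >= 0))
  }
})

test_that("resting metabolic rate follows Mifflin-St Jeor", {
  expect_equal(mifflin_st_jeor(80, 178, 40, "male"),
               10 * 80 + 6.25 * 178 - 5 * 40 + 5)
  expect_equal(mifflin_st_jeor(65, 165, 30, "female"),
               10 * 65 + 6.25 * 165 - 5 * 30 - 161)
  expect_error(mifflin_st_jeor(65, 165, 30, "unknown"),
               class = "biohackr_error")
})

test_that("diary generation is a pure function of its configuration", {
  cfg <- generator_config(n_days = 30L, rng_seed = 21L)
  d1 <- generate_participant_diary(fx_profile(), cfg)
  d2 <- generate_participant_diary(fx_profile(), cfg)
  expect_identical(d1$entries, d2$entries)
  expect_identical(d1$physiology, d2$physiology)
  d3 <- generate_participant_diary(fx_profile(),
                                   generator_config(n_days = 30L,
                                                    rng_seed = 22L))
  expect_false(identical(d1$entries, d3$entries))
})

test_that("every generated day covers all six meal slots", {
  cfg <- generator_config(n_days = 25L, rng_seed = 2L)
  d <- generate_participant_diary(fx_profile(), cfg)
  slots_per_day <- tapply(d$entries$meal_slot, d$entries$date,
                          function(s) length(intersect(s, meal_slots())))
  expect_true(all(slots_per_day == 6))
})

test_that("realized surplus converges to the configured mean", {
  cfg <- generator_config(n_days = 400L, rng_seed = 31L)
  cp <- generate_catalog(cfg)
  d <- generate_participant_diary(fx_profile(), cfg, catalog = cp$catalog,
                                  emissions = cp$emissions)
  eb <- daily_energy_balance(d, cp$catalog)
  se <- cfg$surplus_kcal_sd / sqrt(cfg$n_days)
  expect_lt(abs(mean(eb$eb_kcal) - cfg$surplus_kcal_mean), 3 * se + 30)
})

test_that("weight trajectories follow the energy-balance physics", {
  cfg <- generator_config(n_days = 400L, rng_seed = 13L)
  cp <- generate_catalog(cfg)
  d <- generate_participant_diary(fx_profile(), cfg, catalog = cp$catalog,
                                  emissions = cp$emissions)
  eb <- daily_energy_balance(d, cp$catalog)
  n <- nrow(d$physiology)
  resid <- d$physiology$weight_kg[-1] - d$physiology$weight_kg[-n] -
    eb$eb_kcal[-n] / cfg$rho
  # residuals are the configured measurement noise
  expect_lt(abs(mean(resid)), 3 * cfg$weight_noise_sd / sqrt(n))
  expect_gt(sd(resid), cfg$weight_noise_sd * 0.8)
  expect_lt(sd(resid), cfg$weight_noise_sd * 1.2)
})

test_that("an overeating diary offers at least one substitution per day on average", {
  cfg <- generator_config(n_days = 100L, rng_seed = 17L)
  cp <- generate_catalog(cfg)
  d <- generate_participant_diary(fx_profile(), cfg, catalog = cp$catalog,
                                  emissions = cp$emissions)
  span <- range(d$physiology$date)
  r <- biohack_diary(d, span[1], span[2] + 1, cp$catalog, cp$emissions)
  expect_gte(nrow(r$substitutions), 100)
})

test_that("cohorts have distinct, reproducible participants", {
  cfg <- generator_config(n_days = 20L, rng_seed = 3L)
  cohort <- generate_cohort(3, cfg)
  expect_length(cohort, 3)
  expect_false(identical(cohort[[1]]$entries, cohort[[2]]$entries))
  cohort2 <- generate_cohort(3, cfg)
  expect_identical(cohort[[2]]$physiology, cohort2[[2]]$physiology)
})

test_that("idealized period outcomes recover the energy-density slope", {
  out <- simulate_period_outcomes(200, rho = 7700, sigma_w = 0.3, seed = 4L)
  reg <- regress_dw_on_deb(out)
  expect_gt(reg$slope, 0.5 / 7700)
  expect_lt(reg$slope, 2 / 7700)
})
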
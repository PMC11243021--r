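# biohackr

Digital biohacking of food diaries with a personalized metabolic avatar.

`biohackr` designs and evaluates *minimal* dietary interventions: for each
meal in a food diary it replaces the single highest-calorie item
(condiments, spices and oils excluded) with a same-food-group alternative
that cuts 100–200 kcal without raising the meal's carbon footprint. The
effect of the substituted diet on body weight is then estimated with a
**personalized metabolic avatar** — a small gated recurrent unit (GRU)
that forecasts next-day weight change from the trailing week of daily
energy balance and macronutrient composition — by simulating the weight
trajectory the participant *would* have had under the substituted diet
and comparing it with the recorded one.

The package provides:

- a diary/catalog data model with daily energy-balance, macronutrient and
  carbon-footprint accounting (`participant_diary()`,
  `daily_energy_balance()`, `daily_footprint()`);
- the substitution engine and its aggregated substitution dictionary
  (`biohack_diary()`, `build_dictionary()`, `intervention_summary()`);
- the avatar with GRU and closed-form linear backends, walk-forward
  validation and walk-forward (counterfactual) simulation
  (`train_pma()`, `walk_forward_validation()`,
  `walk_forward_simulation()`, `simulate_biohacked_periods()`);
- an evaluation layer: paired t-test and OLS regression of weight change
  on energy-balance difference, with textbook-exact statistics
  (`paired_t_test()`, `regress_dw_on_deb()`, `evaluate_cohort()`);
- a physics-grounded synthetic diary generator for end-to-end testing
  (`generate_participant_diary()`, `generate_cohort()`), plus CSV
  readers/writers and a reproducible one-call pipeline
  (`run_pipeline()`).

The GRU is implemented from scratch in base R (analytic backpropagation
through time, Adam, L2 weight decay), so the package has no
deep-learning dependency.

## The science in one paragraph

Daily energy balance `EB = intake − (RMR + activity)` drives weight via
`Δw ≈ EB/ρ` with `ρ = 7700` kcal/kg. A persistent ~300 kcal/day surplus
therefore gains ~0.04 kg/day in expectation, but day-to-day weight
*measurements* carry ~0.2 kg noise — an order of magnitude more — so a
two-week effect of a few hundred grams is only detectable across many
periods. The avatar learns the individual's `EB → Δw` mapping from
three months of history; feeding it the biohacked (calorie-reduced)
features for a two-week period yields the counterfactual weight change,
and a paired t-test over 50 such periods asks whether the substituted
diet would have produced systematic weight loss.

## Worked example

A synthetic overeating participant (450-day diary, mean surplus
+300 kcal/day):

```r
library(biohackr)

cfg <- generator_config(surplus_kcal_mean = 300, n_days = 450L,
                        rng_seed = 11L)
cat_pair <- generate_catalog(cfg)
profile <- list(age = 40, sex = "male", height_cm = 178, weight_kg = 80)
diary <- generate_participant_diary(profile, cfg,
                                    catalog = cat_pair$catalog,
                                    emissions = cat_pair$emissions)
diary
#> <participant_diary> synthetic_01: 450 days, 5660 entries (2023-01-01 to 2024-03-25)
```

Biohack the whole diary and summarize the intervention:

```r
span <- range(diary$physiology$date)
bh <- biohack_diary(diary, span[1], span[2] + 1,
                    cat_pair$catalog, cat_pair$emissions)
nrow(bh$substitutions)
#> [1] 709

bh$substitutions[1:3, c("date", "meal_slot", "old_food", "new_food",
                        "kcal_reduction")]
#> # A tibble: 3 × 5
#>   date       meal_slot    old_food  new_food  kcal_reduction
#>   <date>     <chr>        <chr>     <chr>              <dbl>
#> 1 2023-01-01 Breakfast    dairy_06  dairy_02            143.
#> 2 2023-01-01 MorningSnack grains_05 grains_16           104.
#> 3 2023-01-02 Breakfast    grains_09 grains_04           181.

intervention_summary(diary, bh$diary, cat_pair$catalog,
                     cat_pair$emissions, span[1], span[2] + 1)
#> $avg_daily_kcal_reduction
#> [1] 236.2902
#> $kcal_reduction_pct
#> [1] 9.464952
#> $avg_daily_co2_reduction
#> [1] 414.8804
#> $co2_reduction_pct
#> [1] 8.914688

build_dictionary(bh$substitutions)
#> <substitution_dictionary> 111 replaced foods, 709 substitutions
```

Simulate 50 two-week periods (per period: fresh avatar trained on the
preceding 3 months, period meals biohacked, counterfactual weight path
rolled out) and test the effect:

```r
res <- simulate_biohacked_periods(diary, cat_pair$catalog,
                                  cat_pair$emissions, n_periods = 50L)
paired_t_test(res$dw_actual, res$dw_simulated)
#> Paired t-test: t = -3.474 (df = 49), p = 0.00108, mean diff = -0.382 kg

mean(res$dw_actual)     #> 0.473  kg gained per two weeks, recorded
mean(res$dw_simulated)  #> 0.091  kg under the substituted diet
```

The negative t confirms simulated weight loss relative to the recorded
overeating trajectory. Finally, the regression protocol recovers the
energy density of weight change on idealized period outcomes:

```r
out <- simulate_period_outcomes(50, rho = 7700, sigma_w = 0.3, seed = 1L)
regress_dw_on_deb(out)
#> OLS dw ~ delta_eb (n = 50): slope = 0.000135 kg/kcal, R2 = 0.221,
#>   r = 0.470, p = 0.000575
```

The fitted slope 1.35e-4 kg/kcal matches the generating physics
1/7700 ≈ 1.3e-4.

## Reproduction

All randomness is seed-controlled; results above reproduce exactly with
the seeds shown.

```sh
# install (no docs needed)
R CMD INSTALL --no-docs --no-html --no-help .

# run the test suite against the installed package
Rscript -e 'testthat::test_dir("tests/testthat", package = "biohackr",
                               load_package = "installed")'

# headline metric: two-sided paired t-test p-value over 50 periods
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
# t4: p = 0.00460258 (t = -2.970, n = 50) -> acceptance.json
```

The acceptance script fixes the study condition (the participant above,
generator seed 11) and uses `--seed` for the method's own randomness
(avatar initialization, period sampling, substitution draws).

A methods vignette (`vignettes/methods.Rmd`) documents the algorithm,
the avatar's training scheme, and the evaluation design in detail.

## License

MIT.
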
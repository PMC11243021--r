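test_that("target selection picks the highest-calorie non-condiment item", {
  cat <- fx_catalog()
  d <- fx_diary(1)
  lunch <- d$entries[d$entries$meal_slot == "Lunch", ]
  target <- select_target_item(lunch, cat)
  expect_equal(target$food_name, "focaccia")  # 660 kcal beats 247.5
  # adding a condiment never changes the target
  with_oil <- dplyr::bind_rows(lunch,
    tibble::tibble(date = lunch$date[1], meal_slot = "Lunch",
                   food_name = "olive_oil", quantity_g = 100))
  expect_equal(select_target_item(with_oil, cat)$food_name, "focaccia")
})

test_that("meals below the calorie onset are left untouched", {
  cat <- fx_catalog()
  d <- fx_diary(1)
  snack <- tibble::tibble(date = d$entries$date[1], meal_slot = "MorningSnack",
                          food_name = "barley_plain", quantity_g = 80)
  expect_null(select_target_item(snack, cat))  # 96 kcal < 100
  snack$quantity_g <- 90   # 108 kcal, above onset
  expect_equal(select_target_item(snack, cat)$food_name, "barley_plain")
})

test_that("all-condiment meals yield no target", {
  cat <- fx_catalog()
  oil <- tibble::tibble(date = as.Date("2023-03-01"), meal_slot = "Dinner",
                        food_name = "olive_oil", quantity_g = 50)  # 442 kcal
  expect_null(select_target_item(oil, cat))
})

test_that("candidates share the macro-category and use historical portions", {
  cat <- fx_catalog()
  d <- fx_diary(4)
  lunch <- d$entries[d$entries$meal_slot == "Lunch" &
                       d$entries$date == d$entries$date[1], ]
  target <- select_target_item(lunch, cat)
  pool <- candidate_pool(target, d, cat)
  expect_setequal(pool$food_name, c("barley_plain", "bread_white"))
  # bread was eaten at 100 g throughout the diary; barley never, so it
  # inherits the target's 200 g
  expect_equal(pool$quantity_g[pool$food_name == "bread_white"], 100)
  expect_equal(pool$quantity_g[pool$food_name == "barley_plain"], 200)
})

test_that("replacements respect the calorie band and footprint constraint", {
  cat <- fx_catalog()
  em <- fx_emissions()
  d <- fx_diary(3)
  bf <- d$entries[d$entries$meal_slot == "Breakfast" &
                    d$entries$date == d$entries$date[1], ]
  target <- select_target_item(bf, cat)   # bread 100 g, 270 kcal
  pool <- candidate_pool(target, d, cat)
  set.seed(1)
  sub <- choose_replacement(target, pool, em)
  # barley (120 kcal at 100 g) cuts 150 kcal; focaccia would add energy
  expect_equal(sub$new_food, "barley_plain")
  expect_equal(sub$kcal_reduction, 150)
  expect_gte(sub$co2_reduction, 0)
})

test_that("an infeasible meal is left unchanged rather than force-swapped", {
  cat <- fx_catalog()
  em <- fx_emissions()
  d <- fx_diary(3)
  lunch <- d$entries[d$entries$meal_slot == "Lunch" &
                       d$entries$date == d$entries$date[1], ]
  target <- select_target_item(lunch, cat)  # focaccia 660 kcal
  pool <- candidate_pool(target, d, cat)
  # every same-category candidate cuts > 200 kcal: no feasible replacement
  set.seed(1)
  expect_null(choose_replacement(target, pool, em))
})

test_that("biohacking is reproducible, bounded to the period, and leaves the input intact", {
  cat <- fx_catalog()
  em <- fx_emissions()
  d <- fx_diary(6)
  before <- d$entries
  start <- as.Date("2023-03-02"); end <- as.Date("2023-03-05")
  r1 <- biohack_diary(d, start, end, cat, em)
  r2 <- biohack_diary(d, start, end, cat, em)
  expect_identical(r1$substitutions, r2$substitutions)
  expect_identical(d$entries, before)
  # only breakfasts are feasible here: one per day of the period
  expect_equal(nrow(r1$substitutions), 3)
  expect_true(all(r1$substitutions$date >= start &
                    r1$substitutions$date < end))
  # outside the period the biohacked diary matches the original
  outside <- r1$diary$entries$date < start | r1$diary$entries$date >= end
  expect_identical(r1$diary$entries[outside, ], d$entries[outside, ])
  # physiology is never touched
  expect_identical(r1$diary$physiology, d$physiology)
})

test_that("energy-balance difference equals the total intake cut", {
  cat <- fx_catalog()
  em <- fx_emissions()
  d <- fx_diary(6)
  start <- as.Date("2023-03-01"); end <- as.Date("2023-03-07")
  r <- biohack_diary(d, start, end, cat, em)
  deb <- delta_EB(d, r$diary, cat, start, end)
  expect_equal(deb, sum(r$substitutions$kcal_reduction))
  expect_gte(deb, 0)
})

test_that("the substitution dictionary aggregates swaps with counts", {
  cat <- fx_catalog()
  em <- fx_emissions()
  d <- fx_diary(6)
  r <- biohack_diary(d, as.Date("2023-03-01"), as.Date("2023-03-07"), cat, em)
  dict <- build_dictionary(r$substitutions)
  expect_s3_class(dict, "substitution_dictionary")
  expect_equal(sum(dict$n), nrow(r$substitutions))
  expect_equal(dict$old_food[1], "bread_white")
  empty <- build_dictionary(r$substitutions[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("intervention summary reports per-day means and percentages", {
  cat <- fx_catalog()
  em <- fx_emissions()
  d <- fx_diary(6)
  start <- as.Date("2023-03-01"); end <- as.Date("2023-03-07")
  r <- biohack_diary(d, start, end, cat, em)
  s <- intervention_summary(d, r$diary, cat, em, start, end)
  # one 150 kcal cut per day on a 1177.5 kcal/day diet
  expect_equal(s$avg_daily_kcal_reduction, 150)
  expect_equal(s$kcal_reduction_pct, 100 * 150 / 1177.5)
  expect_gt(s$avg_daily_co2_reduction, 0)
})
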
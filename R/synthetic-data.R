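#' Configuration for the synthetic-diary generator
#'
#' The generator produces food catalogs, emission tables, and year-scale
#' participant diaries whose weight dynamics follow the energy-balance model
#' `w[t+1] = w[t] + EB[t] / rho + N(0, weight_noise_sd)`, with six meals per
#' day and a catalog constructed so that calorie-cutting, footprint-neutral
#' substitutes exist for typical portions.
#'
#' @param rho Energy density of body-weight change, kcal per kg (default
#'   7700, the standard conversion for body tissue).
#' @param weight_noise_sd Standard deviation of the day-to-day weight
#'   increment noise, kg.
#' @param n_days Number of diary days.
#' @param surplus_kcal_mean,surplus_kcal_sd Daily caloric surplus (intake
#'   minus expenditure) distribution; a positive mean emulates chronic
#'   overeating.
#' @param items_per_category Catalog items per macro-category (>= 2 so that
#'   every category offers at least one alternative food).
#' @param portion_jitter_sdlog Lognormal (mean-one) meal-to-meal portion
#'   variation; 0 gives perfectly reproducible portions.
#' @param meal_energy_targets Named numeric vector, baseline kcal per slot;
#'   names must be [meal_slots()]. Scaled each day so that total intake
#'   matches expenditure plus the day's surplus draw.
#' @param rng_seed Integer seed; the generator is a pure function of its
#'   configuration.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(rho = 7700,
                             weight_noise_sd = 0.2,
                             n_days = 450L,
                             surplus_kcal_mean = 300,
                             surplus_kcal_sd = 300,
                             items_per_category = 16L,
                             portion_jitter_sdlog = 0.3,
                             meal_energy_targets = c(
                               Breakfast = 400, MorningSnack = 150,
                               Lunch = 700, AfternoonSnack = 150,
                               Dinner = 600, EveningSnack = 100),
                             rng_seed = 1L) {
  stopifnot(rho > 0, n_days >= 1, items_per_category >= 2,
            weight_noise_sd >= 0,
            setequal(names(meal_energy_targets), meal_slots()))
  structure(list(rho = rho, weight_noise_sd = weight_noise_sd,
                 n_days = as.integer(n_days),
                 surplus_kcal_mean = surplus_kcal_mean,
                 surplus_kcal_sd = surplus_kcal_sd,
                 items_per_category = as.integer(items_per_category),
                 portion_jitter_sdlog = portion_jitter_sdlog,
                 meal_energy_targets = meal_energy_targets[meal_slots()],
                 rng_seed = as.integer(rng_seed)),
            class = "generator_config")
}

# Per-category energy-density spans (kcal/100 g) and emission-class spans.
# Classes are assigned non-decreasing with energy density within a category,
# so a lower-energy same-category swap never raises the footprint class.
category_profiles <- function() {
  tibble::tribble(
    ~macro_category, ~kcal_lo, ~kcal_hi, ~class_lo, ~class_hi,
    "meat",        120, 400, 3L, 5L,
    "fish",         90, 300, 3L, 4L,
    "dairy",        50, 350, 2L, 4L,
    "grains",       80, 380, 1L, 3L,
    "legumes",      60, 300, 1L, 2L,
    "vegetables",   15, 150, 1L, 2L,
    "fruit",        30, 180, 1L, 2L,
    "sweets",      100, 450, 2L, 3L,
    "beverages",     1, 120, 1L, 2L
  )
}

emission_classes <- function() {
  tibble::tibble(
    emission_class = c("very_low", "low", "medium", "high", "very_high"),
    gco2eq_per_g = c(0.5, 1.5, 4.0, 9.0, 25.0))
}

#' Generate a synthetic food catalog and emission table
#'
#' For every non-condiment macro-category the items span an energy-density
#' ladder wide enough that, at typical portions, same-category swaps cutting
#' 100-200 kcal exist at an equal-or-lower emission class. Macronutrient
#' profiles are drawn from category-typical compositions and scaled to match
#' the energy density by the Atwater factors (4/4/9 kcal per g).
#'
#' @param config A [generator_config()].
#' @return List with elements `catalog` (tibble) and `emissions` (tibble).
#' @export
generate_catalog <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed_(derive_seed(config$rng_seed, 1L), {
    prof <- category_profiles()
    k <- config$items_per_category
    rows <- purrr::pmap(prof, function(macro_category, kcal_lo, kcal_hi,
                                       class_lo, class_hi) {
      dens <- seq(kcal_lo, kcal_hi, length.out = k)
      dens <- dens + runif(k, -0.02, 0.02) * (kcal_hi - kcal_lo) / k
      dens <- pmax(sort(dens), 1)
      cls <- emission_classes()$emission_class[
        round(seq(class_lo, class_hi, length.out = k))]
      # category-typical macro split (carb, protein, fat), then scale mass
      # to reproduce the energy density under 4/4/9 kcal per g
      split <- switch(macro_category,
        meat = c(0.02, 0.55, 0.43), fish = c(0.02, 0.65, 0.33),
        dairy = c(0.25, 0.30, 0.45), grains = c(0.75, 0.12, 0.13),
        legumes = c(0.60, 0.28, 0.12), vegetables = c(0.70, 0.20, 0.10),
        fruit = c(0.92, 0.04, 0.04), sweets = c(0.65, 0.05, 0.30),
        beverages = c(0.90, 0.05, 0.05))
      kcal_per_g_mix <- sum(split * c(4, 4, 9))
      mass <- dens / kcal_per_g_mix        # grams of macros per 100 g
      mass <- pmin(mass, 100)
      tibble::tibble(
        food_name = sprintf("%s_%02d", macro_category, seq_len(k)),
        macro_category = macro_category,
        kcal_per_100g = dens,
        carb_g_per_100g = mass * split[1],
        protein_g_per_100g = mass * split[2],
        fat_g_per_100g = mass * split[3],
        emission_class = cls)
    })
    condiments <- tibble::tibble(
      food_name = c("salt", "mixed_herbs", "olive_oil"),
      macro_category = "condiment_spice",
      kcal_per_100g = c(0, 250, 884),
      carb_g_per_100g = c(0, 40, 0),
      protein_g_per_100g = c(0, 10, 0),
      fat_g_per_100g = c(0, 5, 98),
      emission_class = c("very_low", "very_low", "low"))
    catalog <- dplyr::bind_rows(rows, condiments)
    validate_catalog(catalog)
    list(catalog = catalog, emissions = emission_classes())
  })
}

#' Mifflin-St Jeor resting metabolic rate
#'
#' @param weight_kg,height_cm,age_yr Anthropometrics.
#' @param sex `"male"` or `"female"`.
#' @return RMR in kcal/day.
#' @export
mifflin_st_jeor <- function(weight_kg, height_cm, age_yr, sex) {
  if (!all(sex %in% c("male", "female"))) {
    stop_input("sex must be \"male\" or \"female\"")
  }
  10 * weight_kg + 6.25 * height_cm - 5 * age_yr +
    ifelse(sex == "male", 5, -161)
}

#' Generate a synthetic participant diary
#'
#' Simulates daily six-slot meals whose quantities are solved so that total
#' intake equals expenditure (Mifflin-St Jeor RMR plus lognormal activity)
#' plus the day's surplus draw. Weight evolves by the energy-balance model
#' `w[t+1] = w[t] + EB[t]/rho + N(0, weight_noise_sd)`; the recorded weight
#' is the morning weight of each day.
#'
#' @param profile List with `age`, `sex` (`"male"`/`"female"`), `height_cm`,
#'   `weight_kg` (baseline); see [participant_diary()].
#' @param config A [generator_config()].
#' @param catalog,emissions Optionally a pre-generated catalog pair; by
#'   default [generate_catalog()] is called with the same config.
#' @param participant_id Identifier for the resulting diary.
#' @param start_date First diary day.
#' @return A [participant_diary()].
#' @export
generate_participant_diary <- function(profile,
                                       config = generator_config(),
                                       catalog = NULL, emissions = NULL,
                                       participant_id = "synthetic_01",
                                       start_date = as.Date("2023-01-01")) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(catalog)) {
    cat_pair <- generate_catalog(config)
    catalog <- cat_pair$catalog
    emissions <- cat_pair$emissions
  }
  slots <- meal_slots()
  targets <- config$meal_energy_targets
  non_cond <- catalog[catalog$macro_category != "condiment_spice", ]
  mains <- non_cond[non_cond$kcal_per_100g >= 100, ]
  sides <- non_cond[non_cond$kcal_per_100g >= 25, ]
  cond <- catalog[catalog$macro_category == "condiment_spice", ]
  portion_jitter_sdlog <- config$portion_jitter_sdlog
  with_seed_(derive_seed(config$rng_seed, 2L), {
    n <- config$n_days
    dates <- start_date + seq_len(n) - 1L
    weight <- numeric(n)
    weight[1] <- profile$weight_kg
    rmr <- numeric(n); act <- numeric(n); eb <- numeric(n)
    entry_list <- vector("list", n)
    sdlog <- 0.35
    for (t in seq_len(n)) {
      rmr[t] <- mifflin_st_jeor(weight[t], profile$height_cm,
                                profile$age, profile$sex)
      act[t] <- rlnorm(1, meanlog = log(400) - sdlog^2 / 2, sdlog = sdlog)
      surplus <- rnorm(1, config$surplus_kcal_mean, config$surplus_kcal_sd)
      intake <- max(rmr[t] + act[t] + surplus, 600)
      share <- targets / sum(targets) * intake
      day_rows <- purrr::map(seq_along(slots), function(s) {
        main <- mains[sample(nrow(mains), 1L), ]
        side <- sides[sample(nrow(sides), 1L), ]
        if (side$food_name == main$food_name) {
          side <- sides[(which(sides$food_name == main$food_name) %% nrow(sides)) + 1L, ]
        }
        # condiment (if any) is decided first so its calories come out of
        # the main item's share and the day's realized intake stays on target
        cond_row <- NULL
        cond_kcal <- 0
        if (slots[s] %in% c("Lunch", "Dinner") && runif(1) < 0.3) {
          ci <- cond[sample(nrow(cond), 1L), ]
          cond_q <- runif(1, 2, 8)
          cond_kcal <- ci$kcal_per_100g * cond_q / 100
          cond_row <- tibble::tibble(date = dates[t], meal_slot = slots[s],
                                     food_name = ci$food_name,
                                     quantity_g = cond_q)
        }
        main_kcal <- max(0.7 * share[s] - cond_kcal, 0.4 * share[s])
        # meal-to-meal portion variation (mean-one lognormal), as in real
        # diaries where the same food is served in quite different amounts
        jit <- rlnorm(2, meanlog = -portion_jitter_sdlog^2 / 2,
                      sdlog = portion_jitter_sdlog)
        rows <- tibble::tibble(
          date = dates[t], meal_slot = slots[s],
          food_name = c(main$food_name, side$food_name),
          quantity_g = c(jit[1] * main_kcal / main$kcal_per_100g * 100,
                         jit[2] * 0.3 * share[s] / side$kcal_per_100g * 100))
        dplyr::bind_rows(rows, cond_row)
      })
      day_entries <- dplyr::bind_rows(day_rows)
      joined_kcal <- sum(item_energy(
        catalog[match(day_entries$food_name, catalog$food_name), ],
        day_entries$quantity_g))
      eb[t] <- joined_kcal - rmr[t] - act[t]
      entry_list[[t]] <- day_entries
      if (t < n) {
        weight[t + 1] <- weight[t] + eb[t] / config$rho +
          rnorm(1, 0, config$weight_noise_sd)
      }
    }
    participant_diary(
      participant_id = participant_id,
      profile = profile,
      entries = dplyr::bind_rows(entry_list),
      physiology = tibble::tibble(date = dates, weight_kg = weight,
                                  rmr_kcal = rmr, activity_kcal = act))
  })
}

#' Generate a synthetic cohort
#'
#' Independent participant diaries with per-participant profile variation
#' (age 25-60 years, 3:1 male:female, heights and baseline BMI in normal
#' adult ranges), each generated under a sub-seed derived from the master
#' seed in `config`.
#'
#' @param n_participants Number of diaries (>= 1).
#' @param config A [generator_config()]; its `rng_seed` is the master seed.
#' @return A named list of [participant_diary()] objects.
#' @export
generate_cohort <- function(n_participants, config = generator_config()) {
  if (!is_scalar_number(n_participants) || n_participants < 1) {
    stop_input("n_participants must be >= 1")
  }
  n_participants <- as.integer(n_participants)
  cat_pair <- generate_catalog(config)
  profiles <- with_seed_(derive_seed(config$rng_seed, 3L), {
    purrr::map(seq_len(n_participants), function(i) {
      sex <- if (runif(1) < 0.75) "male" else "female"
      height <- if (sex == "male") rnorm(1, 176, 7) else rnorm(1, 163, 6)
      bmi <- runif(1, 21, 26)
      list(age = round(runif(1, 25, 60)), sex = sex,
           height_cm = round(height, 1),
           weight_kg = round(bmi * (height / 100)^2, 1))
    })
  })
  diaries <- purrr::imap(profiles, function(p, i) {
    cfg_i <- config
    cfg_i$rng_seed <- derive_seed(config$rng_seed, 100L + i)
    generate_participant_diary(
      p, cfg_i, catalog = cat_pair$catalog, emissions = cat_pair$emissions,
      participant_id = sprintf("synthetic_%02d", i))
  })
  names(diaries) <- purrr::map_chr(diaries, "participant_id")
  diaries
}

#' Simulate period-level outcomes under energy-balance physics
#'
#' Draws two-week-period outcomes directly from the generator's ground
#' truth: the cumulative energy-balance difference between a period's diet
#' and its biohacked counterpart, `delta_eb`, translates into weight change
#' as `dw = delta_eb / rho + N(0, sigma_w)`. Used to check that the
#' regression layer recovers the energy density of weight change.
#'
#' @param n Number of periods.
#' @param rho Energy density of weight change, kcal/kg.
#' @param sigma_w Period-level weight noise, kg.
#' @param deb_range Range of `delta_eb` (kcal over the period), drawn
#'   uniformly; wide by design, emulating periods from fully adherent to
#'   heavily divergent from the biohacked diet.
#' @param seed Integer seed.
#' @return Tibble `delta_eb`, `dw`.
#' @export
simulate_period_outcomes <- function(n, rho = 7700, sigma_w = 0.3,
                                     deb_range = c(0, 4000), seed = 1L) {
  stopifnot(n >= 1, rho > 0)
  with_seed_(seed, {
    deb <- runif(n, deb_range[1], deb_range[2])
    tibble::tibble(delta_eb = deb, dw = deb / rho + rnorm(n, 0, sigma_w))
  })
}
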
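# Shared fixtures: a tiny hand-built catalog/emissions pair and diary
# builders. Everything is constructed in code so the suite needs no data
# files.

fx_emissions <- function() {
  tibble::tibble(
    emission_class = c("very_low", "low", "medium", "high", "very_high"),
    gco2eq_per_g = c(0.5, 1.5, 4, 9, 25))
}

# Minimal catalog: three grain items on an energy ladder (same category,
# so they can substitute for one another), one protein item, one condiment.
fx_catalog <- function() {
  tibble::tibble(
    food_name = c("barley_plain", "bread_white", "focaccia",
                  "chicken_breast", "olive_oil"),
    macro_category = c("grains", "grains", "grains",
                       "meat", "condiment_spice"),
    kcal_per_100g = c(120, 270, 330, 165, 884),
    carb_g_per_100g = c(25, 50, 55, 0, 0),
    protein_g_per_100g = c(3, 9, 8, 31, 0),
    fat_g_per_100g = c(0.8, 3.5, 9, 3.6, 100),
    emission_class = c("very_low", "low", "medium", "high", "low"))
}

# A diary of n_days identical days: lunch of focaccia 200 g (660 kcal) and
# chicken 150 g, breakfast of white bread 100 g. Physiology flat at 80 kg
# unless weights supplied.
fx_diary <- function(n_days = 10, weights = NULL, id = "p1",
                     start = as.Date("2023-03-01")) {
  dates <- start + seq_len(n_days) - 1
  entries <- dplyr::bind_rows(
    tibble::tibble(date = dates, meal_slot = "Breakfast",
                   food_name = "bread_white", quantity_g = 100),
    tibble::tibble(date = dates, meal_slot = "Lunch",
                   food_name = "focaccia", quantity_g = 200),
    tibble::tibble(date = dates, meal_slot = "Lunch",
                   food_name = "chicken_breast", quantity_g = 150))
  entries <- dplyr::arrange(entries, date, meal_slot)
  physiology <- tibble::tibble(
    date = dates,
    weight_kg = if (is.null(weights)) rep(80, n_days) else weights,
    rmr_kcal = 1700, activity_kcal = 400)
  participant_diary(id, list(age = 40, sex = "male", height_cm = 178,
                             weight_kg = 80),
                    entries, physiology)
}

# Synthetic feature series following the generator's physics:
# dw = eb / rho + noise. Used for avatar tests.
fx_series <- function(n, eb_sd = 500, noise = 0, seed = 1, rho = 7700) {
  set.seed(seed)
  eb <- rnorm(n, 200, eb_sd)
  mac <- matrix(abs(rnorm(3 * n, c(0.5, 0.25, 0.25), 0.05)),
                ncol = 3, byrow = TRUE)
  mac <- mac / rowSums(mac)
  dw <- eb / rho + rnorm(n, 0, noise)
  w <- 75 + c(0, cumsum(dw))[1:n]
  tibble::tibble(date = as.Date("2023-01-01") + 0:(n - 1), eb = eb,
                 carb_frac = mac[, 1], protein_frac = mac[, 2],
                 fat_frac = mac[, 3], weight = w,
                 dw = c(diff(w), NA), usable = TRUE)
}

fx_profile <- function() {
  list(age = 40, sex = "male", height_cm = 178, weight_kg = 80)
}
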
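#' Canonical meal slots
#'
#' Food diaries are structured into six meals per day: the three main meals
#' plus the snacks between (and after) them. All diary operations require
#' `meal_slot` to be one of these canonical labels; free-text labels in input
#' files are mapped through an alias table by [read_diary()].
#'
#' @return Character vector of the six canonical slot names, in daily order.
#' @export
#' @examples
#' meal_slots()
meal_slots <- function() {
  c("Breakfast", "MorningSnack", "Lunch", "AfternoonSnack",
    "Dinner", "EveningSnack")
}

#' Macro-categories used by the food catalog
#'
#' Coarse food groups that constrain which foods may substitute for which.
#' `condiment_spice` is distinguished: condiments and spices are never
#' selected for replacement by the biohacking engine.
#'
#' @return Character vector of category names.
#' @export
macro_categories <- function() {
  c("meat", "fish", "dairy", "grains", "legumes", "vegetables",
    "fruit", "sweets", "beverages", "condiment_spice")
}

catalog_columns <- function() {
  c("food_name", "macro_category", "kcal_per_100g", "carb_g_per_100g",
    "protein_g_per_100g", "fat_g_per_100g", "emission_class")
}

#' Validate a food catalog
#'
#' A catalog is a data frame with one row per food and columns `food_name`,
#' `macro_category`, `kcal_per_100g`, `carb_g_per_100g`, `protein_g_per_100g`,
#' `fat_g_per_100g`, `emission_class`. Energy and macronutrient densities are
#' per 100 g of food; macronutrient mass per 100 g may not exceed 100 g.
#'
#' @param catalog A data frame of foods.
#' @return The catalog, invisibly, as a tibble; errors describe the first
#'   violated invariant.
#' @export
validate_catalog <- function(catalog) {
  catalog <- tibble::as_tibble(catalog)
  missing <- setdiff(catalog_columns(), names(catalog))
  if (length(missing) > 0) {
    stop_input("catalog is missing columns: %s", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(catalog$food_name)) {
    stop_input("catalog has duplicated food_name entries")
  }
  if (any(!catalog$macro_category %in% macro_categories())) {
    bad <- unique(setdiff(catalog$macro_category, macro_categories()))
    stop_input("unknown macro_category: %s", paste(bad, collapse = ", "))
  }
  dens <- catalog[c("kcal_per_100g", "carb_g_per_100g",
                    "protein_g_per_100g", "fat_g_per_100g")]
  bad_dens <- !stats::complete.cases(dens) | rowSums(as.matrix(dens) < 0) > 0
  if (any(bad_dens)) {
    stop_input("energy and macronutrient densities must be finite and >= 0 for: %s",
               paste(catalog$food_name[bad_dens], collapse = ", "))
  }
  macro_mass <- catalog$carb_g_per_100g + catalog$protein_g_per_100g +
    catalog$fat_g_per_100g
  if (any(macro_mass > 100 + 1e-9)) {
    stop_input("macronutrient mass per 100 g exceeds 100 g for: %s",
               paste(catalog$food_name[macro_mass > 100 + 1e-9], collapse = ", "))
  }
  invisible(catalog)
}

#' Validate an emission-factor table
#'
#' Maps each `emission_class` to a production-side greenhouse-gas factor in
#' gCO2eq per gram of purchased food.
#'
#' @param emissions A data frame with columns `emission_class`, `gco2eq_per_g`.
#' @return The table, invisibly, as a tibble.
#' @export
validate_emissions <- function(emissions) {
  emissions <- tibble::as_tibble(emissions)
  if (!all(c("emission_class", "gco2eq_per_g") %in% names(emissions))) {
    stop_input("emission table needs columns emission_class, gco2eq_per_g")
  }
  if (anyDuplicated(emissions$emission_class)) {
    stop_input("emission table has duplicated classes")
  }
  if (anyNA(emissions$gco2eq_per_g) || any(emissions$gco2eq_per_g < 0)) {
    stop_input("emission factors must be finite and >= 0")
  }
  invisible(emissions)
}

#' Construct a participant diary
#'
#' Bundles a participant's dated food-diary entries with their daily
#' physiology (morning weight, resting metabolic rate, physical-activity
#' energy expenditure) and a basic anthropometric profile.
#'
#' @param participant_id Identifier string.
#' @param profile List with `age` (years), `sex` (`"male"` or `"female"`),
#'   `height_cm`, and `weight_kg` (baseline).
#' @param entries Tibble with columns `date` (`Date`), `meal_slot` (one of
#'   [meal_slots()]), `food_name`, `quantity_g` (> 0).
#' @param physiology Tibble with columns `date` (strictly increasing),
#'   `weight_kg` (may be `NA`; morning weight), `rmr_kcal` (> 0),
#'   `activity_kcal` (>= 0).
#' @return An object of class `participant_diary`.
#' @export
participant_diary <- function(participant_id, profile, entries, physiology) {
  entries <- tibble::as_tibble(entries)
  physiology <- tibble::as_tibble(physiology)
  stopifnot(all(c("date", "meal_slot", "food_name", "quantity_g") %in%
                  names(entries)),
            all(c("date", "weight_kg", "rmr_kcal", "activity_kcal") %in%
                  names(physiology)))
  if (!inherits(entries$date, "Date") || !inherits(physiology$date, "Date")) {
    stop_input("diary dates must be of class Date")
  }
  bad_slot <- setdiff(unique(entries$meal_slot), meal_slots())
  if (length(bad_slot) > 0) {
    stop_input("unknown meal_slot: %s", paste(bad_slot, collapse = ", "))
  }
  if (any(!is.finite(entries$quantity_g)) || any(entries$quantity_g <= 0)) {
    stop_input("quantity_g must be finite and > 0")
  }
  if (is.unsorted(physiology$date, strictly = TRUE)) {
    stop_input("physiology dates must be strictly increasing")
  }
  w <- physiology$weight_kg
  if (any(!is.na(w) & w <= 0)) stop_input("weight_kg must be > 0 when present")
  rmr <- physiology$rmr_kcal
  if (any(!is.na(rmr) & rmr <= 0)) stop_input("rmr_kcal must be > 0 when present")
  act <- physiology$activity_kcal
  if (any(!is.na(act) & act < 0)) stop_input("activity_kcal must be >= 0")
  gaps <- diff(as.integer(physiology$date))
  structure(
    list(participant_id = as.character(participant_id),
         profile = profile,
         entries = dplyr::arrange(entries, .data$date, .data$meal_slot),
         physiology = physiology,
         has_date_gaps = any(gaps > 1)),
    class = "participant_diary"
  )
}

#' @export
print.participant_diary <- function(x, ...) {
  cat(sprintf("<participant_diary> %s: %d days, %d entries (%s to %s)%s\n",
              x$participant_id, nrow(x$physiology), nrow(x$entries),
              min(x$physiology$date), max(x$physiology$date),
              if (isTRUE(x$has_date_gaps)) ", has date gaps" else ""))
  invisible(x)
}

#' Restrict a diary to a date window
#'
#' Windows are half-open, `[start, end)`, in whole days.
#'
#' @param diary A [participant_diary()].
#' @param start,end `Date` bounds.
#' @return A `participant_diary` covering only the window.
#' @export
diary_slice <- function(diary, start, end) {
  stopifnot(inherits(diary, "participant_diary"))
  start <- as.Date(start); end <- as.Date(end)
  if (end <= start) stop_input("empty period: end must be after start")
  keep_e <- diary$entries$date >= start & diary$entries$date < end
  keep_p <- diary$physiology$date >= start & diary$physiology$date < end
  out <- diary
  out$entries <- diary$entries[keep_e, ]
  out$physiology <- diary$physiology[keep_p, ]
  out
}

#' Energy of a food portion
#'
#' @param item One or more catalog rows (a data frame with `kcal_per_100g`).
#' @param quantity_g Grams consumed; recycled against rows of `item`.
#' @return Energy in kcal, `kcal_per_100g * quantity_g / 100`.
#' @export
#' @examples
#' item <- data.frame(kcal_per_100g = 250)
#' item_energy(item, 150) # 375 kcal
item_energy <- function(item, quantity_g) {
  if (any(!is.finite(quantity_g)) || any(quantity_g < 0)) {
    stop_input("quantity_g must be finite and >= 0")
  }
  item$kcal_per_100g * quantity_g / 100
}

#' Carbon footprint of a food portion
#'
#' Looks up the item's `emission_class` in the emission table and scales the
#' per-gram factor by the quantity.
#'
#' @inheritParams item_energy
#' @param emissions Emission table, see [validate_emissions()].
#' @return Footprint in gCO2eq.
#' @export
item_footprint <- function(item, quantity_g, emissions) {
  if (any(!is.finite(quantity_g)) || any(quantity_g < 0)) {
    stop_input("quantity_g must be finite and >= 0")
  }
  factor <- emissions$gco2eq_per_g[match(item$emission_class,
                                         emissions$emission_class)]
  if (anyNA(factor)) {
    bad <- unique(item$emission_class[is.na(factor)])
    stop_input("emission_class not in emission table: %s",
               paste(bad, collapse = ", "))
  }
  factor * quantity_g
}

# Join diary entries with the catalog, erroring on foods the catalog lacks.
entries_with_catalog <- function(entries, catalog) {
  idx <- match(entries$food_name, catalog$food_name)
  if (anyNA(idx)) {
    bad <- unique(entries$food_name[is.na(idx)])
    stop_input("foods absent from catalog: %s", paste(bad, collapse = ", "))
  }
  dplyr::bind_cols(entries, catalog[idx, setdiff(catalog_columns(), "food_name")])
}

#' Total energy of one meal
#'
#' @param entries Diary entries that all share one `(date, meal_slot)` pair.
#' @param catalog Food catalog.
#' @return Total kcal of the meal; 0 for an empty entry set.
#' @export
meal_total_energy <- function(entries, catalog) {
  if (nrow(entries) == 0) return(0)
  if (length(unique(entries$date)) > 1L ||
      length(unique(entries$meal_slot)) > 1L) {
    stop_input("entries must belong to a single (date, meal_slot)")
  }
  joined <- entries_with_catalog(entries, catalog)
  sum(item_energy(joined, joined$quantity_g))
}

#' Daily energy intake
#'
#' @param diary A [participant_diary()].
#' @param catalog Food catalog.
#' @return Tibble `date`, `intake_kcal`, one row per physiology day (days
#'   without entries count 0 kcal).
#' @export
daily_intake <- function(diary, catalog) {
  joined <- entries_with_catalog(diary$entries, catalog)
  joined$kcal <- item_energy(joined, joined$quantity_g)
  per_day <- dplyr::summarise(dplyr::group_by(joined, .data$date),
                              intake_kcal = sum(.data$kcal), .groups = "drop")
  out <- tibble::tibble(date = diary$physiology$date)
  out$intake_kcal <- per_day$intake_kcal[match(out$date, per_day$date)]
  out$intake_kcal[is.na(out$intake_kcal)] <- 0
  out
}

#' Daily energy balance
#'
#' Energy balance for a day is total intake minus total expenditure, the
#' latter taken as resting metabolic rate plus physical-activity expenditure.
#' Positive values are a caloric surplus.
#'
#' @inheritParams daily_intake
#' @return Tibble `date`, `intake_kcal`, `eb_kcal`.
#' @export
daily_energy_balance <- function(diary, catalog) {
  phys <- diary$physiology
  if (anyNA(phys$rmr_kcal) || anyNA(phys$activity_kcal)) {
    bad <- phys$date[is.na(phys$rmr_kcal) | is.na(phys$activity_kcal)]
    stop_input("missing RMR or activity expenditure on: %s",
               paste(head(bad, 5), collapse = ", "))
  }
  out <- daily_intake(diary, catalog)
  out$eb_kcal <- out$intake_kcal - (phys$rmr_kcal + phys$activity_kcal)
  out
}

#' Daily macronutrient composition
#'
#' Mass fractions of carbohydrate, protein, and fat consumed each day. The
#' three fractions sum to 1 (within 1e-9) on every day with nonzero recorded
#' macronutrient mass.
#'
#' @inheritParams daily_intake
#' @return Tibble `date`, `carb_frac`, `protein_frac`, `fat_frac`.
#' @export
daily_macros <- function(diary, catalog) {
  joined <- entries_with_catalog(diary$entries, catalog)
  q <- joined$quantity_g / 100
  joined$carb_g <- joined$carb_g_per_100g * q
  joined$protein_g <- joined$protein_g_per_100g * q
  joined$fat_g <- joined$fat_g_per_100g * q
  per_day <- dplyr::summarise(
    dplyr::group_by(joined, .data$date),
    carb_g = sum(.data$carb_g), protein_g = sum(.data$protein_g),
    fat_g = sum(.data$fat_g), .groups = "drop")
  total <- per_day$carb_g + per_day$protein_g + per_day$fat_g
  if (nrow(per_day) == 0 || any(total <= 0)) {
    stop_input("day with zero recorded macronutrient mass; cannot form fractions")
  }
  tibble::tibble(date = per_day$date,
                 carb_frac = per_day$carb_g / total,
                 protein_frac = per_day$protein_g / total,
                 fat_frac = per_day$fat_g / total)
}

#' Daily carbon footprint
#'
#' @inheritParams daily_intake
#' @param emissions Emission table.
#' @return Tibble `date`, `gco2eq` (days without entries count 0).
#' @export
daily_footprint <- function(diary, catalog, emissions) {
  joined <- entries_with_catalog(diary$entries, catalog)
  joined$gco2eq <- item_footprint(joined, joined$quantity_g, emissions)
  per_day <- dplyr::summarise(dplyr::group_by(joined, .data$date),
                              gco2eq = sum(.data$gco2eq), .groups = "drop")
  out <- tibble::tibble(date = diary$physiology$date)
  out$gco2eq <- per_day$gco2eq[match(out$date, per_day$date)]
  out$gco2eq[is.na(out$gco2eq)] <- 0
  out
}
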
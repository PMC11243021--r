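#' Configuration of the digital-biohacking substitution algorithm
#'
#' @param meal_kcal_threshold Meals whose total energy is strictly below this
#'   threshold are left untouched (kcal; default 100).
#' @param reduction_min,reduction_max Admissible band for the calorie cut of
#'   a single substitution (kcal; defaults 100 and 200).
#' @param require_lower_footprint If `TRUE` (default), a replacement may not
#'   increase the carbon footprint of the swapped portion; the comparison is
#'   non-strict so equal-class swaps remain admissible.
#' @param rng_seed Integer seed; the random draw among feasible replacements
#'   is uniform and fully reproducible given the seed.
#' @return A list of class `biohack_config`.
#' @export
biohack_config <- function(meal_kcal_threshold = 100,
                           reduction_min = 100,
                           reduction_max = 200,
                           require_lower_footprint = TRUE,
                           rng_seed = 1L) {
  stopifnot(meal_kcal_threshold >= 0, reduction_min > 0,
            reduction_min <= reduction_max)
  structure(list(meal_kcal_threshold = meal_kcal_threshold,
                 reduction_min = reduction_min,
                 reduction_max = reduction_max,
                 require_lower_footprint = isTRUE(require_lower_footprint),
                 rng_seed = as.integer(rng_seed)),
            class = "biohack_config")
}

#' Select the meal item targeted for replacement
#'
#' The target is the entry with the highest caloric intake in the meal,
#' excluding condiments and spices. No target is returned when the meal's
#' total energy falls below the configured threshold or when every entry is
#' a condiment. Ties are broken by diary order (first occurrence).
#'
#' @param meal_entries Entries of one `(date, meal_slot)`.
#' @param catalog Food catalog.
#' @param config A [biohack_config()].
#' @return A one-row tibble (the chosen entry joined with its catalog
#'   columns and its `kcal`), or `NULL` when no replacement applies.
#' @export
select_target_item <- function(meal_entries, catalog,
                               config = biohack_config()) {
  if (nrow(meal_entries) == 0) return(NULL)
  joined <- entries_with_catalog(meal_entries, catalog)
  joined$kcal <- item_energy(joined, joined$quantity_g)
  if (sum(joined$kcal) < config$meal_kcal_threshold) return(NULL)
  eligible <- joined[joined$macro_category != "condiment_spice", ]
  if (nrow(eligible) == 0) return(NULL)
  eligible[which.max(eligible$kcal), ]
}

#' Candidate replacement foods for a target entry
#'
#' Candidates share the target's macro-category and are drawn from the union
#' of foods the participant historically consumed in the target's meal slot
#' and the full catalog; the target food itself is excluded. Each candidate
#' carries a proposed quantity: the participant's median historical quantity
#' for that food, falling back to the target's quantity for foods never
#' eaten before.
#'
#' @param target A one-row tibble from [select_target_item()].
#' @param diary The participant's (unmodified) diary, used as history.
#' @param catalog Food catalog.
#' @param .history Optional precomputed per-food median quantities (internal,
#'   lets [biohack_diary()] compute them once per run).
#' @return Tibble of candidate foods with columns of the catalog plus
#'   `quantity_g`; may have zero rows.
#' @export
candidate_pool <- function(target, diary, catalog, .history = NULL) {
  cands <- catalog[catalog$macro_category == target$macro_category &
                     catalog$food_name != target$food_name, ]
  if (nrow(cands) == 0) return(cands)
  if (is.null(.history)) .history <- history_quantities(diary)
  m <- match(cands$food_name, .history$food_name)
  cands$quantity_g <- ifelse(is.na(m), target$quantity_g, .history$quantity_g[m])
  cands
}

# Median historical quantity per food over the whole diary.
history_quantities <- function(diary) {
  stats::aggregate(quantity_g ~ food_name, data = diary$entries,
                   FUN = stats::median)
}

#' Choose one feasible replacement at random
#'
#' Filters the candidate pool to replacements whose calorie cut lies in the
#' configured 100-200 kcal band and (when required) whose footprint at the
#' proposed quantity does not exceed the target portion's footprint, then
#' draws one uniformly at random.
#'
#' @param target One-row tibble from [select_target_item()] (must carry
#'   `kcal`).
#' @param pool Tibble from [candidate_pool()].
#' @param emissions Emission table.
#' @param config A [biohack_config()].
#' @return A one-row substitution tibble (`date`, `meal_slot`, `old_food`,
#'   `old_quantity_g`, `new_food`, `new_quantity_g`, `kcal_reduction`,
#'   `co2_reduction`), or `NULL` when no candidate is feasible.
#' @export
choose_replacement <- function(target, pool, emissions,
                               config = biohack_config()) {
  if (is.null(pool) || nrow(pool) == 0) return(NULL)
  cand_kcal <- item_energy(pool, pool$quantity_g)
  reduction <- target$kcal - cand_kcal
  keep <- reduction >= config$reduction_min & reduction <= config$reduction_max
  old_fp <- item_footprint(target, target$quantity_g, emissions)
  cand_fp <- item_footprint(pool, pool$quantity_g, emissions)
  if (config$require_lower_footprint) keep <- keep & cand_fp <= old_fp
  if (!any(keep)) return(NULL)
  idx <- which(keep)
  pick <- idx[sample.int(length(idx), 1L)]
  tibble::tibble(
    date = target$date, meal_slot = target$meal_slot,
    old_food = target$food_name, old_quantity_g = target$quantity_g,
    new_food = pool$food_name[pick], new_quantity_g = pool$quantity_g[pick],
    kcal_reduction = reduction[pick],
    co2_reduction = old_fp - cand_fp[pick])
}

#' Biohack a diary over a period
#'
#' Applies the substitution algorithm to every `(date, meal_slot)` in the
#' half-open period `[start, end)`: the highest-calorie non-condiment item of
#' each sufficiently caloric meal is replaced by a randomly chosen
#' same-category alternative cutting 100-200 kcal without raising the meal's
#' footprint. At most one entry per meal is replaced; infeasible meals are
#' left unchanged. The input diary is never modified, and the result is a
#' deterministic function of `(diary, catalog, emissions, config)`.
#'
#' @param diary A [participant_diary()].
#' @param start,end Period bounds (`Date`), half-open.
#' @param catalog Food catalog.
#' @param emissions Emission table.
#' @param config A [biohack_config()].
#' @return List with `diary` (the biohacked copy) and `substitutions`
#'   (tibble, one row per replacement made).
#' @export
biohack_diary <- function(diary, start, end, catalog, emissions,
                          config = biohack_config()) {
  stopifnot(inherits(diary, "participant_diary"))
  start <- as.Date(start); end <- as.Date(end)
  if (end <= start) stop_input("empty period: end must be after start")
  span <- range(diary$physiology$date)
  if (start < span[1] || (end - 1) > span[2]) {
    stop_input("period [%s, %s) extends outside the diary span [%s, %s]",
               start, end, span[1], span[2])
  }
  entries <- diary$entries
  in_period <- which(entries$date >= start & entries$date < end)
  meal_key <- paste(entries$date[in_period], entries$meal_slot[in_period])
  groups <- split(in_period, meal_key)
  subs <- vector("list", length(groups))
  history <- history_quantities(diary)
  with_seed_(config$rng_seed, {
    for (g in seq_along(groups)) {
      rows <- groups[[g]]
      target <- select_target_item(entries[rows, ], catalog, config)
      if (is.null(target)) next
      pool <- candidate_pool(target, diary, catalog, .history = history)
      sub <- choose_replacement(target, pool, emissions, config)
      if (is.null(sub)) next
      hit <- rows[entries$food_name[rows] == sub$old_food &
                    entries$quantity_g[rows] == sub$old_quantity_g][1]
      entries$food_name[hit] <- sub$new_food
      entries$quantity_g[hit] <- sub$new_quantity_g
      subs[[g]] <- sub
    }
  })
  substitutions <- dplyr::bind_rows(subs)
  if (nrow(substitutions) > 0) {
    substitutions <- dplyr::arrange(substitutions, .data$date, .data$meal_slot)
  }
  out <- diary
  out$entries <- entries
  list(diary = out, substitutions = substitutions)
}

#' Cumulative energy-balance difference between two diaries
#'
#' `delta_EB` is the period total of the actual diet's daily energy balance
#' minus the biohacked diet's, `EB_act - EB_bh`. Both diaries must share the
#' same physiology (the expenditure terms cancel), so the result equals the
#' total intake reduction and is nonnegative for calorie-cutting
#' substitutions.
#'
#' @param actual,biohacked Two [participant_diary()] objects covering the
#'   period with identical physiology.
#' @param catalog Food catalog.
#' @param start,end Period bounds, half-open.
#' @return Scalar kcal.
#' @export
delta_EB <- function(actual, biohacked, catalog, start, end) {
  a <- diary_slice(actual, start, end)
  b <- diary_slice(biohacked, start, end)
  if (!identical(a$physiology$date, b$physiology$date)) {
    stop_input("diaries do not cover the period identically")
  }
  if (!isTRUE(all.equal(a$physiology[c("rmr_kcal", "activity_kcal")],
                        b$physiology[c("rmr_kcal", "activity_kcal")]))) {
    stop_input("physiology differs between the two diaries")
  }
  sum(daily_energy_balance(a, catalog)$eb_kcal) -
    sum(daily_energy_balance(b, catalog)$eb_kcal)
}

#' Aggregate substitutions into a replacement dictionary
#'
#' Compiles the mapping from each replaced food to the alternatives it was
#' swapped for, with occurrence counts, over a whole diary or period.
#'
#' @param substitutions Tibble from [biohack_diary()].
#' @return Tibble `old_food`, `new_food`, `n`, sorted by decreasing count
#'   within each replaced food; class `substitution_dictionary`.
#' @export
build_dictionary <- function(substitutions) {
  if (is.null(substitutions) || nrow(substitutions) == 0) {
    out <- tibble::tibble(old_food = character(), new_food = character(),
                          n = integer())
  } else {
    out <- dplyr::count(substitutions, .data$old_food, .data$new_food,
                        sort = FALSE)
    out <- dplyr::arrange(out, .data$old_food, dplyr::desc(.data$n))
  }
  class(out) <- c("substitution_dictionary", class(out))
  out
}

#' @export
print.substitution_dictionary <- function(x, ...) {
  cat(sprintf("<substitution_dictionary> %d replaced foods, %d substitutions\n",
              length(unique(x$old_food)), sum(x$n)))
  NextMethod()
}

#' Summarise the dietary intervention
#'
#' Per-day mean calorie and carbon-footprint reductions of the biohacked
#' diet relative to the actual diet, with percentages relative to the actual
#' diet's per-day means.
#'
#' @inheritParams delta_EB
#' @param emissions Emission table.
#' @return List with `avg_daily_kcal_reduction`, `kcal_reduction_pct`,
#'   `avg_daily_co2_reduction`, `co2_reduction_pct`.
#' @export
intervention_summary <- function(actual, biohacked, catalog, emissions,
                                 start, end) {
  a <- diary_slice(actual, start, end)
  b <- diary_slice(biohacked, start, end)
  kcal_a <- daily_intake(a, catalog)$intake_kcal
  kcal_b <- daily_intake(b, catalog)$intake_kcal
  co2_a <- daily_footprint(a, catalog, emissions)$gco2eq
  co2_b <- daily_footprint(b, catalog, emissions)$gco2eq
  if (mean(kcal_a) <= 0) stop_input("actual diary has zero intake in period")
  if (mean(co2_a) <= 0) stop_input("actual diary has zero footprint in period")
  list(avg_daily_kcal_reduction = mean(kcal_a - kcal_b),
       kcal_reduction_pct = 100 * mean(kcal_a - kcal_b) / mean(kcal_a),
       avg_daily_co2_reduction = mean(co2_a - co2_b),
       co2_reduction_pct = 100 * mean(co2_a - co2_b) / mean(co2_a))
}
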
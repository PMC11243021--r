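# CSV dialects
#
# diary:      date (ISO-8601), meal_slot, food_name, quantity_g
# physiology: date, weight_kg, rmr_kcal, activity_kcal
# catalog:    food_name, macro_category, kcal_per_100g, carb_g_per_100g,
#             protein_g_per_100g, fat_g_per_100g, emission_class
# emissions:  emission_class, gco2eq_per_g
# All files UTF-8, comma-separated, mandatory header row.

#' Default meal-slot alias table
#'
#' Maps free-text slot labels (case, spaces, hyphens, underscores ignored)
#' to the canonical six slots of [meal_slots()].
#'
#' @return Named character vector: normalized label -> canonical slot.
#' @export
default_slot_aliases <- function() {
  c(breakfast = "Breakfast",
    morningsnack = "MorningSnack", midmorningsnack = "MorningSnack",
    snack1 = "MorningSnack",
    lunch = "Lunch",
    afternoonsnack = "AfternoonSnack", midafternoonsnack = "AfternoonSnack",
    snack2 = "AfternoonSnack",
    dinner = "Dinner", supper = "Dinner",
    eveningsnack = "EveningSnack", aftersupper = "EveningSnack",
    snack3 = "EveningSnack")
}

normalize_slot <- function(x) gsub("[ _-]", "", tolower(x))

#' Read a food catalog CSV
#' @param path File path.
#' @return A validated catalog tibble.
#' @export
read_catalog <- function(path) {
  catalog <- readr::read_csv(path, show_col_types = FALSE)
  validate_catalog(catalog)
  tibble::as_tibble(catalog)
}

#' Read an emission-factor CSV
#' @param path File path.
#' @return A validated emission table tibble.
#' @export
read_emissions <- function(path) {
  emissions <- readr::read_csv(path, show_col_types = FALSE)
  validate_emissions(emissions)
  tibble::as_tibble(emissions)
}

#' Read a participant diary from its two CSV files
#'
#' Malformed rows are rejected with their file and line number (line 1 is
#' the header); foods absent from the catalog and meal slots not covered by
#' the alias table are reported by name.
#'
#' @param diary_csv Path to the diary CSV.
#' @param physiology_csv Path to the daily-physiology CSV.
#' @param catalog Food catalog the entries must reference.
#' @param participant_id Identifier for the diary.
#' @param profile Participant profile list (see [participant_diary()]).
#' @param slot_aliases Alias table, see [default_slot_aliases()].
#' @return A [participant_diary()].
#' @export
read_diary <- function(diary_csv, physiology_csv, catalog,
                       participant_id = "participant",
                       profile = list(age = NA_real_, sex = NA_character_,
                                      height_cm = NA_real_, weight_kg = NA_real_),
                       slot_aliases = default_slot_aliases()) {
  entries <- readr::read_csv(diary_csv, show_col_types = FALSE,
                             col_types = readr::cols(
                               date = readr::col_date(),
                               meal_slot = readr::col_character(),
                               food_name = readr::col_character(),
                               quantity_g = readr::col_double()))
  line <- function(i) i + 1L  # header occupies line 1
  bad_date <- which(is.na(entries$date))
  if (length(bad_date) > 0) {
    stop_input("%s:%d: unparseable date", diary_csv, line(bad_date[1]))
  }
  bad_q <- which(!is.finite(entries$quantity_g) | entries$quantity_g <= 0)
  if (length(bad_q) > 0) {
    stop_input("%s:%d: quantity_g must be > 0 (got %s)",
               diary_csv, line(bad_q[1]), entries$quantity_g[bad_q[1]])
  }
  slot <- slot_aliases[normalize_slot(entries$meal_slot)]
  bad_slot <- which(is.na(slot))
  if (length(bad_slot) > 0) {
    stop_input("%s:%d: unknown meal slot '%s'", diary_csv,
               line(bad_slot[1]), entries$meal_slot[bad_slot[1]])
  }
  entries$meal_slot <- unname(slot)
  unknown <- setdiff(unique(entries$food_name), catalog$food_name)
  if (length(unknown) > 0) {
    stop_input("%s: foods absent from catalog: %s", diary_csv,
               paste(unknown, collapse = ", "))
  }
  physiology <- readr::read_csv(physiology_csv, show_col_types = FALSE,
                                col_types = readr::cols(
                                  date = readr::col_date(),
                                  weight_kg = readr::col_double(),
                                  rmr_kcal = readr::col_double(),
                                  activity_kcal = readr::col_double()))
  participant_diary(participant_id, profile, entries, physiology)
}

#' Write a participant diary to its two CSV files
#' @param diary A [participant_diary()].
#' @param diary_csv,physiology_csv Output paths.
#' @return The diary, invisibly.
#' @export
write_diary <- function(diary, diary_csv, physiology_csv) {
  readr::write_csv(diary$entries, diary_csv)
  readr::write_csv(diary$physiology, physiology_csv)
  invisible(diary)
}

#' Write the catalog / emission table
#' @param x Catalog or emission tibble.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(x)
}

#' Configuration of a full pipeline run
#'
#' All per-stage seeds are derived deterministically from `seed`, so a run
#' is a pure function of its configuration.
#'
#' @param outdir Output directory (created if missing).
#' @param seed Master seed.
#' @param n_participants,n_days Cohort shape.
#' @param n_periods Two-week periods simulated per participant.
#' @param generator A [generator_config()] (its `rng_seed` is overridden).
#' @param biohack A [biohack_config()] (idem).
#' @param avatar A [pma_config()] (idem).
#' @return List of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, n_participants = 4L,
                       n_days = 450L, n_periods = 50L,
                       generator = generator_config(),
                       biohack = biohack_config(),
                       avatar = pma_config()) {
  generator$n_days <- as.integer(n_days)
  generator$rng_seed <- derive_seed(seed, 11L)
  biohack$rng_seed <- derive_seed(seed, 12L)
  avatar$rng_seed <- derive_seed(seed, 13L)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 n_periods = as.integer(n_periods),
                 generator = generator, biohack = biohack, avatar = avatar),
            class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Generates a cohort, biohacks every diary over its full span, simulates
#' the configured number of two-week periods per participant, and evaluates
#' the cohort. Writes the input CSVs, per-participant substitution CSVs, a
#' `report.json`, and a `manifest.json` recording seeds, a configuration
#' hash, and per-stage row counts.
#'
#' @param config A [run_config()].
#' @return List with `report` (see [evaluate_cohort()]) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  cat_pair <- generate_catalog(config$generator)
  catalog <- cat_pair$catalog; emissions <- cat_pair$emissions
  write_table_csv(catalog, file.path(config$outdir, "catalog.csv"))
  write_table_csv(emissions, file.path(config$outdir, "emissions.csv"))
  cohort <- generate_cohort(config$n_participants, config$generator)
  results <- list(); summaries <- list(); counts <- list()
  for (id in names(cohort)) {
    d <- cohort[[id]]
    write_diary(d, file.path(config$outdir, paste0(id, "_diary.csv")),
                file.path(config$outdir, paste0(id, "_physiology.csv")))
    span <- range(d$physiology$date)
    bh <- biohack_diary(d, span[1], span[2] + 1, catalog, emissions,
                        config$biohack)
    readr::write_csv(bh$substitutions,
                     file.path(config$outdir, paste0(id, "_substitutions.csv")))
    summaries[[id]] <- intervention_summary(d, bh$diary, catalog, emissions,
                                            span[1], span[2] + 1)
    results[[id]] <- simulate_biohacked_periods(
      d, catalog, emissions, config$biohack, config$avatar,
      n_periods = config$n_periods)
    readr::write_csv(results[[id]],
                     file.path(config$outdir, paste0(id, "_periods.csv")))
    counts[[id]] <- list(diary_rows = nrow(d$entries),
                         substitution_rows = nrow(bh$substitutions),
                         period_rows = nrow(results[[id]]))
  }
  report <- evaluate_cohort(results, summaries)
  jsonlite::write_json(
    list(weight_comparison = report$weight_comparison,
         regression = report$regression,
         intervention = report$intervention),
    file.path(config$outdir, "report.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  manifest <- list(
    package_version = as.character(utils::packageVersion("biohackr")),
    master_seed = config$seed,
    stage_seeds = list(generator = config$generator$rng_seed,
                       biohack = config$biohack$rng_seed,
                       avatar = config$avatar$rng_seed),
    config_hash = rlang::hash(config[setdiff(names(config), "outdir")]),
    row_counts = counts)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(report = report, manifest = manifest)
}
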
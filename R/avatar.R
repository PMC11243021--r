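#' Configuration of the personalized metabolic avatar
#'
#' The avatar is a per-participant forecaster of next-day weight change from
#' the trailing `lookback` days of daily energy balance and macronutrient
#' composition. Two backends share one interface: a gated recurrent unit
#' (`"gru"`, the default) and a closed-form linear energy-balance model
#' (`"linear"`), the latter serving as a fast, exactly solvable reference.
#'
#' @param backend `"gru"` or `"linear"`.
#' @param lookback Days of input history per prediction (default 7).
#' @param hidden_units GRU hidden-state size (default 16).
#' @param learning_rate Adam step size (default 0.01).
#' @param max_epochs Training epochs cap (default 200).
#' @param patience Early-stopping patience (default 200, i.e. run all
#'   epochs; the default regularizer is weight decay, not early stopping).
#' @param l2 L2 weight-decay strength on the GRU weight matrices (default
#'   0.1). Three-month training windows yield only ~80 samples whose
#'   day-to-day weight changes are dominated by ~0.2 kg measurement noise;
#'   without decay the GRU overfits that noise, and tail-holdout early
#'   stopping on so few samples is erratic enough to sometimes wash out the
#'   learned energy-balance sensitivity entirely. Weight decay keeps the
#'   fit stable across training windows while preserving the response to
#'   energy-balance changes.
#' @param val_fraction Tail fraction of training samples held out for early
#'   stopping (default 0: no holdout; see `l2`). Ignored when the window
#'   yields < 10 samples.
#' @param train_window_days Training-window length for walk-forward schemes,
#'   in days (default 90, i.e. three months).
#' @param horizon_days Simulation horizon, days (default 14).
#' @param wfv_finetune_epochs Warm-start epochs per walk-forward-validation
#'   step after the initial full fit (default 30).
#' @param rng_seed Integer seed for parameter initialization; training is
#'   full-batch and therefore deterministic given the seed.
#' @return A list of class `pma_config`.
#' @export
pma_config <- function(backend = c("gru", "linear"),
                       lookback = 7L,
                       hidden_units = 16L,
                       learning_rate = 0.01,
                       max_epochs = 200L,
                       patience = 200L,
                       l2 = 0.1,
                       val_fraction = 0,
                       train_window_days = 90L,
                       horizon_days = 14L,
                       wfv_finetune_epochs = 30L,
                       rng_seed = 1L) {
  backend <- match.arg(backend)
  stopifnot(lookback >= 1, hidden_units >= 1, horizon_days >= 1,
            train_window_days > lookback + 1)
  structure(list(backend = backend, lookback = as.integer(lookback),
                 hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 l2 = l2,
                 val_fraction = val_fraction,
                 train_window_days = as.integer(train_window_days),
                 horizon_days = as.integer(horizon_days),
                 wfv_finetune_epochs = as.integer(wfv_finetune_epochs),
                 rng_seed = as.integer(rng_seed)),
            class = "pma_config")
}

feature_names <- function() c("eb", "carb_frac", "protein_frac", "fat_frac")

# Like daily_macros() but returns NA fractions for zero-mass days instead of
# erroring; the avatar flags such days unusable rather than refusing the diary.
daily_macros_safe <- function(diary, catalog) {
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
  total[total <= 0] <- NA_real_
  tibble::tibble(date = per_day$date,
                 carb_frac = per_day$carb_g / total,
                 protein_frac = per_day$protein_g / total,
                 fat_frac = per_day$fat_g / total)
}

#' Build the avatar's daily feature series from a diary
#'
#' Aligns daily energy balance, macronutrient fractions, and morning weight
#' on a complete daily grid. Weight gaps of up to three days are linearly
#' interpolated; longer gaps stay missing and are flagged unusable. The
#' daily target is `dw[t] = weight[t+1] - weight[t]`.
#'
#' @param diary A [participant_diary()].
#' @param catalog Food catalog.
#' @return Tibble `date`, `eb`, `carb_frac`, `protein_frac`, `fat_frac`,
#'   `weight`, `dw`, `usable`.
#' @export
build_features <- function(diary, catalog) {
  phys <- diary$physiology
  if (all(is.na(phys$weight_kg))) stop_input("diary has no weight data")
  dates <- seq(min(phys$date), max(phys$date), by = "day")
  out <- tibble::tibble(date = dates)
  pm <- match(dates, phys$date)
  out$weight <- phys$weight_kg[pm]
  out$rmr <- phys$rmr_kcal[pm]
  out$activity <- phys$activity_kcal[pm]
  eb <- daily_energy_balance_safe(diary, catalog)
  em <- match(dates, eb$date)
  out$eb <- eb$eb_kcal[em]
  mac <- daily_macros_safe(diary, catalog)
  mm <- match(dates, mac$date)
  out$carb_frac <- mac$carb_frac[mm]
  out$protein_frac <- mac$protein_frac[mm]
  out$fat_frac <- mac$fat_frac[mm]
  out$weight <- interpolate_short_gaps(out$weight, max_gap = 3L)
  out$dw <- c(diff(out$weight), NA_real_)
  out$usable <- is.finite(out$eb) & is.finite(out$carb_frac) &
    is.finite(out$weight)
  out[c("date", feature_names(), "weight", "dw", "usable")]
}

# daily_energy_balance that tolerates days missing from the physiology and
# NA expenditure terms (returns NA for those days).
daily_energy_balance_safe <- function(diary, catalog) {
  out <- daily_intake(diary, catalog)
  phys <- diary$physiology
  pm <- match(out$date, phys$date)
  out$eb_kcal <- out$intake_kcal - (phys$rmr_kcal[pm] + phys$activity_kcal[pm])
  out
}

# Linear interpolation across interior NA runs of length <= max_gap.
interpolate_short_gaps <- function(x, max_gap = 3L) {
  if (!anyNA(x) || all(is.na(x))) return(x)
  filled <- approx(seq_along(x), x, xout = seq_along(x), method = "linear",
                   rule = 1)$y
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values & r$lengths > max_gap)) {
    filled[starts[i]:ends[i]] <- NA_real_
  }
  filled
}

# Indices t of the series that can serve as a training/prediction sample:
# the whole lookback window of inputs is usable and (if targets are needed)
# dw[t] is finite.
sample_indices <- function(features, lookback, need_target = TRUE) {
  ok_in <- features$usable
  win_ok <- rep(TRUE, nrow(features))
  for (k in 0:(lookback - 1)) {
    shifted <- c(rep(FALSE, k), head(ok_in, nrow(features) - k))
    win_ok <- win_ok & shifted
  }
  idx <- which(win_ok & seq_len(nrow(features)) >= lookback)
  if (need_target) idx <- idx[is.finite(features$dw[idx])]
  idx
}

# Assemble the GRU input: list over lookback steps of (n x 4) matrices of
# standardized features, for sample end-indices `idx`.
make_windows <- function(features, idx, lookback, x_mean, x_sd) {
  fm <- as.matrix(features[feature_names()])
  fm <- sweep(sweep(fm, 2, x_mean), 2, x_sd, "/")
  lapply(seq_len(lookback), function(step) {
    rows <- idx - lookback + step
    fm[rows, , drop = FALSE]
  })
}

#' Train a personalized metabolic avatar
#'
#' Fits the configured backend to predict next-day weight change from the
#' trailing `lookback` days of (energy balance, macronutrient fractions).
#' Features and target are z-scored with statistics from the training series
#' only; zero-variance features trigger a degenerate-fit warning and are
#' left unscaled, which yields a constant prediction in the fully degenerate
#' case.
#'
#' @param features A feature series from [build_features()] restricted to
#'   the intended training window.
#' @param config A [pma_config()].
#' @return An object of class `pma_model`.
#' @export
train_pma <- function(features, config = pma_config()) {
  L <- config$lookback
  idx <- sample_indices(features, L, need_target = TRUE)
  if (length(idx) < 2) {
    stop_input(paste0("insufficient training data: need at least %d usable ",
                      "consecutive days (lookback %d + 1), found %d samples"),
               L + 1, L, length(idx))
  }
  fm <- as.matrix(features[feature_names()])
  used_rows <- sort(unique(as.vector(outer(idx, 0:(L - 1), "-"))))
  x_mean <- colMeans(fm[used_rows, , drop = FALSE])
  x_sd <- apply(fm[used_rows, , drop = FALSE], 2, sd)
  if (any(x_sd == 0)) {
    warn("degenerate fit: zero-variance input feature(s); predictions may be constant")
    x_sd[x_sd == 0] <- 1
  }
  y_raw <- features$dw[idx]
  y_mean <- mean(y_raw); y_sd <- sd(y_raw)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  y <- (y_raw - y_mean) / y_sd
  norm <- list(x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd)
  if (config$backend == "linear") {
    xt <- sweep(sweep(fm[idx, , drop = FALSE], 2, x_mean), 2, x_sd, "/")
    fit <- stats::lm.fit(cbind(1, xt), y)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    fitted <- list(coef = cf)
  } else {
    X <- make_windows(features, idx, L, x_mean, x_sd)
    n_val <- if (config$val_fraction > 0 && length(idx) >= 10) {
      max(1L, floor(config$val_fraction * length(idx)))
    } else 0L
    val_idx <- if (n_val > 0) seq(length(idx) - n_val + 1L, length(idx)) else integer(0)
    fitted <- gru_train(X, y, n_hidden = config$hidden_units,
                        seed = config$rng_seed, lr = config$learning_rate,
                        max_epochs = config$max_epochs,
                        patience = config$patience, val_idx = val_idx,
                        l2 = config$l2)
  }
  structure(list(backend = config$backend, fit = fitted, norm = norm,
                 config = config, n_samples = length(idx),
                 train_start = min(features$date),
                 train_end = max(features$date)),
            class = "pma_model")
}

#' @export
print.pma_model <- function(x, ...) {
  cat(sprintf("<pma_model> backend=%s, lookback=%d, %d training samples (%s to %s)\n",
              x$backend, x$config$lookback, x$n_samples,
              x$train_start, x$train_end))
  invisible(x)
}

# Predict dw (kg) for sample end-indices idx of `features`.
pma_predict <- function(model, features, idx) {
  L <- model$config$lookback
  if (any(idx < L)) stop_input("prediction window extends before the series")
  if (model$backend == "linear") {
    fm <- as.matrix(features[feature_names()])[idx, , drop = FALSE]
    xt <- sweep(sweep(fm, 2, model$norm$x_mean), 2, model$norm$x_sd, "/")
    yhat <- drop(cbind(1, xt) %*% model$fit$coef)
  } else {
    X <- make_windows(features, idx, L, model$norm$x_mean, model$norm$x_sd)
    yhat <- gru_predict(model$fit$params, X)
  }
  yhat * model$norm$y_sd + model$norm$y_mean
}

#' Walk-forward validation of the avatar
#'
#' Slides a train-window/predict-next-day scheme across the series: at each
#' step the avatar is (re)fit on the trailing `train_window_days` and
#' predicts the next day's weight as `weight[t] + dw_hat[t]`. The GRU
#' backend fits fully at the first step and warm-starts with
#' `wfv_finetune_epochs` at subsequent steps. Returns the RMSE of one-step
#' weight predictions against recorded weights.
#'
#' @param features A feature series from [build_features()].
#' @param config A [pma_config()].
#' @return List with `rmse` (kg), `n` predictions, and a `predictions`
#'   tibble (`date`, `actual`, `predicted`).
#' @export
walk_forward_validation <- function(features, config = pma_config()) {
  W <- config$train_window_days
  N <- nrow(features)
  if (N < W + 2) {
    stop_input("series too short for walk-forward validation: %d days, need > %d",
               N, W + 1)
  }
  preds <- list()
  warm <- NULL
  L <- config$lookback
  for (t in W:(N - 1)) {
    win <- features[(t - W + 1):t, ]
    win$dw[W] <- NA_real_  # the target at day t is tomorrow's weight: held out
    if (!is.finite(features$weight[t]) || !is.finite(features$weight[t + 1]) ||
        !all(features$usable[(t - L + 1):t])) next
    if (config$backend == "gru" && !is.null(warm)) {
      model <- finetune_pma(warm, win, config)
    } else {
      model <- train_pma(win, config)
    }
    warm <- model
    # window row index of day t is W; predict dw[t]
    dw_hat <- pma_predict(model, win, W)
    preds[[length(preds) + 1]] <- tibble::tibble(
      date = features$date[t + 1],
      actual = features$weight[t + 1],
      predicted = features$weight[t] + dw_hat)
  }
  if (length(preds) == 0) stop_input("no usable prediction days in series")
  ptab <- dplyr::bind_rows(preds)
  list(rmse = sqrt(mean((ptab$actual - ptab$predicted)^2)),
       n = nrow(ptab), predictions = ptab)
}

# Continue training an existing GRU model on a new window (warm start).
finetune_pma <- function(model, features, config) {
  L <- config$lookback
  idx <- sample_indices(features, L, need_target = TRUE)
  if (length(idx) < 2) return(model)
  fm_idx <- idx
  X <- make_windows(features, fm_idx, L, model$norm$x_mean, model$norm$x_sd)
  y <- (features$dw[fm_idx] - model$norm$y_mean) / model$norm$y_sd
  fitted <- gru_train(X, y, n_hidden = config$hidden_units,
                      seed = config$rng_seed, lr = config$learning_rate,
                      max_epochs = config$wfv_finetune_epochs,
                      patience = config$wfv_finetune_epochs,
                      init_params = model$fit$params, l2 = config$l2)
  model$fit <- fitted
  model$train_start <- min(features$date)
  model$train_end <- max(features$date)
  model
}

#' Walk-forward simulation of a (counterfactual) diet
#'
#' Iteratively predicts each day's weight change over the horizon, feeding
#' the predicted weights forward into the output path. Input features come
#' from the `counterfactual` series where it covers a date (e.g. the
#' biohacked diet), and from the actual series elsewhere; with no
#' counterfactual the simulation forecasts the recorded diet.
#'
#' @param model A trained [train_pma()] model whose training window ends
#'   before `start_day`.
#' @param features The actual feature series covering the simulation window.
#' @param start_day First day of the simulated period (`Date`); day 0 of the
#'   forecast.
#' @param horizon Days to simulate (default from the model's config).
#' @param counterfactual Optional tibble with columns `date` and the feature
#'   columns of [build_features()]; its rows replace the matching dates'
#'   inputs.
#' @return List of class `pma_simulation`: `start`, `end`, `dw_actual`,
#'   `dw_simulated`, `path` (predicted weights for days 1..horizon),
#'   `dates`.
#' @export
walk_forward_simulation <- function(model, features, start_day,
                                    horizon = model$config$horizon_days,
                                    counterfactual = NULL) {
  start_day <- as.Date(start_day)
  s <- match(start_day, features$date)
  if (is.na(s)) stop_input("start_day %s not in feature series", start_day)
  if (model$train_end >= start_day) {
    stop_input("model training window (ending %s) must precede start_day %s",
               model$train_end, start_day)
  }
  N <- nrow(features)
  if (s + horizon > N) {
    stop_input("horizon extends past available features (%d days after %s)",
               N - s, start_day)
  }
  feats <- features
  if (!is.null(counterfactual)) {
    cm <- match(counterfactual$date, feats$date)
    if (anyNA(cm)) stop_input("counterfactual contains dates outside the series")
    for (col in feature_names()) {
      feats[[col]][cm] <- counterfactual[[col]]
    }
  }
  idx <- s:(s + horizon - 1)
  if (any(!is.finite(as.matrix(feats[idx, feature_names()])))) {
    stop_input("missing input features within the simulation horizon")
  }
  dw_hat <- pma_predict(model, feats, idx)
  w0 <- features$weight[s]
  path <- w0 + cumsum(dw_hat)
  dw_actual <- features$weight[s + horizon] - w0
  structure(list(start = start_day, end = start_day + horizon,
                 dw_actual = dw_actual,
                 dw_simulated = path[horizon] - w0,
                 path = path,
                 dates = features$date[idx + 1L]),
            class = "pma_simulation")
}

#' @export
print.pma_simulation <- function(x, ...) {
  cat(sprintf("<pma_simulation> [%s, %s): dw_actual=%.3f kg, dw_simulated=%.3f kg\n",
              x$start, x$end, x$dw_actual, x$dw_simulated))
  invisible(x)
}

#' Simulate biohacked two-week periods across a diary
#'
#' Samples `n_periods` period start days (without replacement; overlapping
#' periods are allowed), and for each period: trains a fresh avatar on the
#' preceding `train_window_days`, biohacks the period's diet, and runs a
#' walk-forward simulation with the biohacked features as counterfactual
#' input. The pairing of actual and simulated weight change per period feeds
#' the paired t-test; the cumulative energy-balance difference feeds the
#' regression analysis.
#'
#' @param diary A [participant_diary()].
#' @param catalog,emissions Food catalog and emission table.
#' @param bh_config A [biohack_config()]; a per-period sub-seed is derived
#'   from its `rng_seed`.
#' @param avatar_config A [pma_config()].
#' @param n_periods Number of periods (0 gives an empty result).
#' @param seed Seed for period sampling; defaults to the avatar seed.
#' @return Tibble with one row per period: `period_start`, `period_end`,
#'   `dw_actual`, `dw_simulated`, `delta_eb`, `n_substitutions`.
#' @export
simulate_biohacked_periods <- function(diary, catalog, emissions,
                                       bh_config = biohack_config(),
                                       avatar_config = pma_config(),
                                       n_periods = 50L,
                                       seed = NULL) {
  features <- build_features(diary, catalog)
  W <- avatar_config$train_window_days
  H <- avatar_config$horizon_days
  N <- nrow(features)
  eligible <- if (N - H >= W + 1) (W + 1):(N - H) else integer(0)
  eligible <- eligible[is.finite(features$weight[eligible]) &
                         is.finite(features$weight[eligible + H])]
  if (n_periods == 0) {
    return(tibble::tibble(period_start = as.Date(character()),
                          period_end = as.Date(character()),
                          dw_actual = numeric(), dw_simulated = numeric(),
                          delta_eb = numeric(), n_substitutions = integer()))
  }
  if (length(eligible) < n_periods) {
    stop_input("diary too short: only %d eligible periods (requested %d)",
               length(eligible), n_periods)
  }
  seed <- if (is.null(seed)) avatar_config$rng_seed else seed
  starts <- with_seed_(
    derive_seed(seed, 7L),
    sort(eligible[sample.int(length(eligible), n_periods)]))
  rows <- purrr::map(seq_along(starts), function(i) {
    s <- starts[i]
    start_date <- features$date[s]
    end_date <- start_date + H
    model <- train_pma(features[(s - W):(s - 1), ], avatar_config)
    cfg_i <- bh_config
    cfg_i$rng_seed <- derive_seed(bh_config$rng_seed, s)
    bh <- biohack_diary(diary, start_date, end_date, catalog, emissions, cfg_i)
    cf <- counterfactual_features(bh$diary, catalog, start_date, end_date)
    sim <- walk_forward_simulation(model, features, start_date, H,
                                   counterfactual = cf)
    deb <- sum(features$eb[s:(s + H - 1)] - cf$eb)
    tibble::tibble(period_start = start_date, period_end = end_date,
                   dw_actual = sim$dw_actual, dw_simulated = sim$dw_simulated,
                   delta_eb = deb, n_substitutions = nrow(bh$substitutions))
  })
  dplyr::bind_rows(rows)
}

# Feature rows (eb + macro fractions) of a biohacked diary over a period.
counterfactual_features <- function(diary, catalog, start, end) {
  sl <- diary_slice(diary, start, end)
  eb <- daily_energy_balance_safe(sl, catalog)
  mac <- daily_macros_safe(sl, catalog)
  out <- tibble::tibble(date = eb$date, eb = eb$eb_kcal)
  mm <- match(out$date, mac$date)
  out$carb_frac <- mac$carb_frac[mm]
  out$protein_frac <- mac$protein_frac[mm]
  out$fat_frac <- mac$fat_frac[mm]
  out
}
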
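#' Default DLM parameters per data source
#'
#' The observational-variance percentages and discount factors used for the
#' four streams: variance 7.50% / 16.00% / 0.40% / 0.65% of the series mean
#' and discounts 0.98 / 0.97 / 0.88 / 0.88 for water flow, activation
#' frequency, solid-floor and slatted-floor temperature respectively (the
#' calibrated operating points of the validation study; both can be
#' re-derived with [calibrate_obs_variance()] and [calibrate_discount()]).
#'
#' @return data.frame `source`, `obs_variance_pct`, `discount`.
#' @export
default_dlm_parameters <- function() {
  data.frame(
    source = c("water_flow", "activation_freq", "temp_solid", "temp_slatted"),
    obs_variance_pct = c(7.50, 16.00, 0.40, 0.65),
    discount = c(0.98, 0.97, 0.88, 0.88)
  )
}

sensor_hour_index <- function(sensors) {
  (sensors$day_index - 1) * 24 + sensors$hour_of_day + 1
}

modelling_values <- function(sensors, source) {
  d <- sensors[sensors$source == source, , drop = FALSE]
  if (source %in% WATER_SOURCES) {
    bad <- is.finite(d$value) & d$value < 0
    if (any(bad)) stop("negative water-usage values cannot be sqrt-transformed")
    d$value <- sqrt(d$value)
  }
  d
}

series_matrix <- function(d) {
  # one column per pen, rows = hour index; NA where unobserved
  t_idx <- sensor_hour_index(d)
  n <- max(t_idx)
  pens <- unique(d$pen_id)
  out <- matrix(NA_real_, n, length(pens), dimnames = list(NULL, pens))
  out[cbind(t_idx, match(d$pen_id, pens))] <- d$value
  out
}

#' Fit the DLM for one data source
#'
#' Square-root transforms the water sources, estimates the state prior by
#' harmonic regression on the no-event training pens ([estimate_theta0()])
#' and fixes the observational-variance percentage and discount (defaults
#' from [default_dlm_parameters()]).
#'
#' @param sensors long sensor data.frame (training batch).
#' @param source data source name.
#' @param non_event_pens pen ids with no tail-biting event.
#' @param obs_variance_pct,discount DLM parameters; `NULL` picks the default
#'   for the source.
#' @return List of class `source_dlm_fit` with `source`, `theta0`, `C0`,
#'   `obs_variance_pct`, `discount`.
#' @export
fit_source_dlm <- function(sensors, source, non_event_pens,
                           obs_variance_pct = NULL, discount = NULL) {
  pars <- default_dlm_parameters()
  pars <- pars[pars$source == source, ]
  if (nrow(pars) != 1) stop("unknown source: ", source)
  if (is.null(obs_variance_pct)) obs_variance_pct <- pars$obs_variance_pct
  if (is.null(discount)) discount <- pars$discount
  d <- modelling_values(sensors, source)
  d <- d[d$pen_id %in% non_event_pens, , drop = FALSE]
  if (nrow(d) == 0) stop("no training data from no-event pens for ", source)
  est <- estimate_theta0(data.frame(pen_id = d$pen_id,
                                    t = sensor_hour_index(d),
                                    value = d$value))
  structure(list(source = source, theta0 = est$theta0, C0 = est$C0,
                 obs_variance_pct = obs_variance_pct, discount = discount),
            class = "source_dlm_fit")
}

#' Filter every pen's stream for one source
#'
#' Applies the fitted DLM to each pen (V fixed from the pen's own series
#' mean on the modelling scale) and returns the hourly standardized forecast
#' errors next to the natural-scale raw values.
#'
#' @param sensors long sensor data.frame.
#' @param fit a [fit_source_dlm()] result.
#' @return data.frame `pen_id`, `source`, `day_index`, `hour_of_day`,
#'   `value` (natural scale), `u`.
#' @export
filter_source <- function(sensors, fit) {
  raw <- sensors[sensors$source == fit$source, , drop = FALSE]
  mod <- modelling_values(sensors, fit$source)
  mat <- series_matrix(mod)
  out <- lapply(colnames(mat), function(pen) {
    y <- mat[, pen]
    spec <- dlm_spec(n_waves = 3, theta0 = fit$theta0, C0 = fit$C0,
                     obs_variance_pct = fit$obs_variance_pct,
                     discount = fit$discount,
                     series_mean = mean(y, na.rm = TRUE))
    fl <- dlm_filter(y, spec)$filtered
    data.frame(pen_id = pen, source = fit$source,
               day_index = ceiling(fl$t / 24),
               hour_of_day = (fl$t - 1) %% 24, u = fl$u)
  })
  flt <- do.call(rbind, out)
  merged <- merge(flt,
                  raw[c("pen_id", "day_index", "hour_of_day", "value")],
                  by = c("pen_id", "day_index", "hour_of_day"),
                  all.x = TRUE)
  merged <- merged[order(merged$pen_id, merged$day_index,
                         merged$hour_of_day),
                   c("pen_id", "source", "day_index", "hour_of_day",
                     "value", "u")]
  rownames(merged) <- NULL
  merged
}

#' Run the full pipeline on a synthetic barn pair
#'
#' End-to-end experiment: simulates a training batch and a separate test
#' batch, fits the per-source DLMs on the training batch's no-event pens,
#' filters every pen, builds daily features, pairs event pens with controls,
#' optimises (optionally) and trains the two networks per source for the
#' UNTIMED alarm type, fuses the sources with the Bayesian ensemble (first
#' source supplies the prior) and evaluates day-level on the test batch with
#' 3-day alarm clustering.
#'
#' @param seed integer seed driving both batches and all training.
#' @param n_train_pens,n_test_pens pens per batch.
#' @param weeks study length.
#' @param deviation_profile pre-event deviation profile (default the
#'   standard profile; use [zero_deviation_profile()] as negative control).
#' @param sources data sources to include, in ensemble order (the first
#'   supplies the prior probability).
#' @param grid architecture grid for [cv_optimize()]; a single-config list
#'   skips the search.
#' @param epochs training epochs per network.
#' @return List with `roc` (day-level [realtime_roc()] on the test batch),
#'   `models`, `pairs`, `posteriors`, `barn_train`, `barn_test`.
#' @export
run_synthetic_experiment <- function(seed,
                                     n_train_pens = 32,
                                     n_test_pens = 28,
                                     weeks = 10,
                                     deviation_profile =
                                       default_deviation_profile(),
                                     sources = c("water_flow", "temp_solid"),
                                     grid = list(net_config("rectifier", 1)),
                                     epochs = 250) {
  barn_train <- simulate_barn(sim_config(
    n_pens = n_train_pens, weeks = weeks, batch = 1, seed = seed,
    deviation_profile = deviation_profile))
  barn_test <- simulate_barn(sim_config(
    n_pens = n_test_pens, weeks = weeks, batch = 2, seed = seed + 131L,
    deviation_profile = deviation_profile))

  tb_train <- first_event_day(barn_train$pens, barn_train$events)
  non_event <- barn_train$pens$pen_id[is.na(tb_train)]
  pairs <- make_training_pairs(barn_train$pens, barn_train$events,
                               seed = seed + 7L)

  models <- list()
  test_daily <- NULL
  for (src in sources) {
    fit <- fit_source_dlm(barn_train$sensors, src, non_event)
    feats_train <- build_feature_table(
      filter_source(barn_train$sensors, fit))
    feats_test <- build_feature_table(
      filter_source(barn_test$sensors, fit))

    wf1 <- window_features(feats_train, pairs$set1, "UNTIMED")
    wf2 <- window_features(feats_train, pairs$set2, "UNTIMED")
    if (length(grid) > 1) {
      cfg1 <- cv_optimize(wf1, grid, seed = seed + 11L,
                          epochs = epochs)$best_config
      cfg2 <- cv_optimize(wf2, grid, seed = seed + 13L,
                          epochs = epochs)$best_config
    } else {
      cfg1 <- cfg2 <- grid[[1]]
    }
    model <- train_final_and_threshold(wf1, wf2, cfg1, cfg2,
                                       seed = seed + 17L, epochs = epochs)
    models[[src]] <- model

    daily <- predict_daily_probabilities(model, feats_test)
    names(daily)[names(daily) == "prob"] <- src
    test_daily <- if (is.null(test_daily)) daily else
      merge(test_daily, daily, by = c("pen_id", "day_index"))
  }

  members <- lapply(sources[-1], function(src) {
    m <- models[[src]]
    alarm_source(src, m$threshold, m$sensitivity, m$specificity)
  })
  posteriors <- realtime_daily_probabilities(test_daily, sources[1], members)
  roc <- realtime_roc(posteriors, barn_test$events)
  list(roc = roc, models = models, pairs = pairs, posteriors = posteriors,
       barn_train = barn_train, barn_test = barn_test)
}
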
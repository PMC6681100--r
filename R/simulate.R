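#' Reference weekly tail-biting probabilities by treatment and week
#'
#' The weekly probability (in percent, converted here to [0, 1]) of a
#' tail-biting event for each combination of tail docking, straw provision
#' and space allowance in each of the 10 study weeks, as estimated by the
#' main-effects logistic risk model of the validation study. Used as the
#' simulator's default weekly hazard and as the fixture for the
#' logit-additivity checks.
#'
#' @return data.frame with columns `tail`, `straw`, `space`, `week`,
#'   `probability`.
#' @export
default_weekly_event_probabilities <- function() {
  path <- system.file("extdata", "weekly_event_probabilities.csv",
                      package = "pigwatch", mustWork = TRUE)
  wide <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(1:10, function(w) {
    data.frame(tail = wide$tail, straw = wide$straw, space = wide$space,
               week = w, probability = wide[[paste0("w", w)]] / 100)
  }))
  rownames(out) <- NULL
  out
}

#' Default diurnal parameters per data source
#'
#' Level, hourly slope and three-wave amplitudes/phases on each source's
#' modelling scale (square-root scale for the water sources, degrees Celsius
#' for the temperatures). The shapes are qualitative: a two-peak-dominant
#' water pattern (morning and late-afternoon drinking), a weaker
#' activation-frequency pattern of the same form, and single-peak
#' temperature patterns with a slow downward trend mirroring the ventilation
#' curve (21 to 17 degrees over the period).
#'
#' @return data.frame with one row per source: `source`, `scale`, `level`,
#'   `slope`, `a1`, `a2`, `a3`, `c1`, `c2`, `c3`.
#' @export
default_diurnal_parameters <- function() {
  data.frame(
    source = c("water_flow", "activation_freq", "temp_solid", "temp_slatted"),
    scale = c("sqrt", "sqrt", "natural", "natural"),
    level = c(3.0, 4.0, 19.5, 19.0),
    slope = c(5e-4, 3e-4, -2.5e-3, -2.5e-3),
    a1 = c(0.35, 0.50, 0.45, 0.35),
    a2 = c(0.55, 0.80, 0.12, 0.10),
    a3 = c(0.15, 0.20, 0.04, 0.03),
    c1 = c(-2.0, -2.0, 0.5, 0.5),
    c2 = c(1.0, 1.2, 0.3, 0.3),
    c3 = c(0.5, 0.6, 0.1, 0.1)
  )
}

#' Default pre-event deviation profile
#'
#' Additive/multiplicative shifts applied to a pen's streams on the three
#' days before its first tail-biting event: +15% water flow, +10% drinker
#' activations, -0.5 degrees C above the solid floor, no change above the
#' slatted floor. The magnitudes are free simulator parameters (the
#' direction of each follows field observations of pre-event behaviour); the
#' zero profile serves as the negative control.
#'
#' @return data.frame with columns `source`, `kind`
#'   (`"multiplicative"`/`"additive"`), `amount`.
#' @export
default_deviation_profile <- function() {
  data.frame(
    source = c("water_flow", "activation_freq", "temp_solid", "temp_slatted"),
    kind = c("multiplicative", "multiplicative", "additive", "additive"),
    amount = c(1.15, 1.10, -0.5, 0)
  )
}

#' Zero deviation profile (negative control)
#'
#' @return A [default_deviation_profile()] with all effects switched off.
#' @export
zero_deviation_profile <- function() {
  prof <- default_deviation_profile()
  prof$amount <- ifelse(prof$kind == "multiplicative", 1, 0)
  prof
}

#' Simulation configuration
#'
#' @param n_pens number of pens (a balanced 2x2x2 factorial needs a multiple
#'   of 8).
#' @param weeks study length in weeks (default 10).
#' @param batch batch label stamped on the pens.
#' @param noise_pct named observational-variance percentages per source
#'   (variance = pct/100 x series level on the modelling scale); defaults
#'   7.50 (water flow), 16.00 (activation frequency), 0.40 (solid-floor
#'   temperature), 0.65 (slatted-floor temperature).
#' @param diurnal diurnal parameters, see [default_diurnal_parameters()].
#' @param weekly_event_probabilities weekly tail-biting hazard per treatment
#'   cell and week, see [default_weekly_event_probabilities()].
#' @param deviation_profile pre-event deviations, see
#'   [default_deviation_profile()].
#' @param fouling_weekly_rate,diarrhoea_weekly_rate weekly per-pen rates of
#'   the two other undesired event types.
#' @param seed integer seed; the whole barn is a deterministic function of
#'   the configuration.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_pens = 32, weeks = 10, batch = 1,
                       noise_pct = c(water_flow = 7.50,
                                     activation_freq = 16.00,
                                     temp_solid = 0.40,
                                     temp_slatted = 0.65),
                       diurnal = default_diurnal_parameters(),
                       weekly_event_probabilities =
                         default_weekly_event_probabilities(),
                       deviation_profile = default_deviation_profile(),
                       fouling_weekly_rate = 0.05,
                       diarrhoea_weekly_rate = 0.03,
                       seed = 1) {
  stopifnot(n_pens >= 2, weeks >= 1)
  p <- weekly_event_probabilities$probability
  if (any(p <= 0 | p >= 1)) stop("weekly probabilities must lie in (0, 1)")
  if (any(noise_pct <= 0)) stop("noise percentages must be positive")
  structure(list(n_pens = n_pens, weeks = weeks, batch = batch,
                 noise_pct = noise_pct, diurnal = diurnal,
                 weekly_event_probabilities = weekly_event_probabilities,
                 deviation_profile = deviation_profile,
                 fouling_weekly_rate = fouling_weekly_rate,
                 diarrhoea_weekly_rate = diarrhoea_weekly_rate,
                 seed = seed),
            class = "sim_config")
}

#' Simulate pen metadata
#'
#' Balanced factorial assignment of the three treatments (tail docking,
#' straw, space allowance) over the pens; group size follows the space
#' allowance (18 pigs at low, 11 at high).
#'
#' @param config a [sim_config()].
#' @param seed integer seed (defaults to the config's).
#' @return data.frame `pen_id`, `batch`, `tail`, `straw`, `space`,
#'   `group_size`.
#' @export
simulate_pens <- function(config, seed = config$seed) {
  cells <- expand.grid(tail = c("docked", "undocked"),
                       straw = c("yes", "no"),
                       space = c("low", "high"),
                       stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(cells)), length.out = config$n_pens)
  withr::with_seed(seed, {
    idx <- sample(idx)
  })
  out <- cells[idx, ]
  out$pen_id <- sprintf("b%d_p%02d", config$batch, seq_len(config$n_pens))
  out$batch <- config$batch
  out$group_size <- ifelse(out$space == "low", 18L, 11L)
  out <- out[c("pen_id", "batch", "tail", "straw", "space", "group_size")]
  rownames(out) <- NULL
  out
}

#' Schedule tail-biting, fouling and diarrhoea events
#'
#' Per pen and week, a Bernoulli draw with the treatment cell's weekly
#' probability decides whether a tail-biting event occurs; the event day is
#' uniform within the week, resampled to day >= 4 so the first event always
#' has a complete 3-day pre-event window. Fouling and diarrhoea are
#' independent weekly Bernoulli schedules with their own rates.
#'
#' @param pens pen metadata from [simulate_pens()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return Event log data.frame `pen_id`, `day_index`, `type`.
#' @export
schedule_events <- function(pens, config, seed = config$seed + 1) {
  wep <- config$weekly_event_probabilities
  pw <- merge(pens[c("pen_id", "tail", "straw", "space")],
              data.frame(week = seq_len(config$weeks)))
  pw <- pw[order(pw$pen_id, pw$week), ]
  key <- function(d) paste(d$tail, d$straw, d$space, d$week)
  p <- wep$probability[match(key(pw), key(wep))]
  if (any(is.na(p))) stop("no weekly probability for a treatment cell")
  withr::with_seed(seed, {
    draw_days <- function(hit, min_day1) {
      w <- pw$week[hit]
      # uniform day within the week; week-1 tail-biting days are resampled
      # to >= 4 so the first event always has a complete 3-day window
      lo <- ifelse(min_day1 & w == 1, 4L, (w - 1L) * 7L + 1L)
      hi <- w * 7L
      lo + floor(stats::runif(length(w)) * (hi - lo + 1))
    }
    tb_hit <- which(stats::runif(nrow(pw)) < p)
    fl_hit <- which(stats::runif(nrow(pw)) < config$fouling_weekly_rate)
    di_hit <- which(stats::runif(nrow(pw)) < config$diarrhoea_weekly_rate)
    out <- rbind(
      data.frame(pen_id = pw$pen_id[tb_hit],
                 day_index = draw_days(tb_hit, TRUE),
                 type = rep("tail_biting", length(tb_hit))),
      data.frame(pen_id = pw$pen_id[fl_hit],
                 day_index = draw_days(fl_hit, FALSE),
                 type = rep("fouling", length(fl_hit))),
      data.frame(pen_id = pw$pen_id[di_hit],
                 day_index = draw_days(di_hit, FALSE),
                 type = rep("diarrhoea", length(di_hit)))
    )
    out <- out[order(out$pen_id, out$day_index), ]
    rownames(out) <- NULL
    out
  })
}

diurnal_mean <- function(pars, t) {
  omega <- 2 * pi / 24
  pars$level + pars$slope * t +
    pars$a1 * sin(omega * t + pars$c1) +
    pars$a2 * sin(2 * omega * t + pars$c2) +
    pars$a3 * sin(3 * omega * t + pars$c3)
}

#' Simulate the four hourly sensor streams of one pen
#'
#' Each stream is a linear trend plus three harmonic waves plus Gaussian
#' observation noise with variance `pct/100 x level` on the modelling scale.
#' Water flow and activation frequency are generated on the square-root
#' scale and squared back, so the stored values are natural-scale (negative
#' square-root draws are clipped at 0 and counted in attribute
#' `"n_clipped"`). The first hour of each day is missing for the temperature
#' streams, mimicking the recording gap of the reference setup.
#'
#' @param pen_id pen identifier.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return data.frame `pen_id`, `day_index`, `hour_of_day`, `source`,
#'   `value`.
#' @export
simulate_sensor_stream <- function(pen_id, config, seed) {
  n <- config$weeks * 7 * 24
  t <- seq_len(n)
  withr::with_seed(seed, {
    out <- lapply(seq_len(nrow(config$diurnal)), function(i) {
      pars <- config$diurnal[i, ]
      mu <- diurnal_mean(pars, t)
      # V is a percentage of the series mean (on the modelling scale), not
      # of the initial level: with a sloped trend the two differ
      v <- config$noise_pct[[pars$source]] / 100 * mean(mu)
      y <- mu + stats::rnorm(n, sd = sqrt(v))
      n_clipped <- 0L
      if (pars$scale == "sqrt") {
        n_clipped <- sum(y < 0)
        y <- pmax(y, 0)^2
      } else {
        y[(t - 1) %% 24 == 0] <- NA_real_  # hour-0 temperature gap
      }
      d <- data.frame(pen_id = pen_id, day_index = ceiling(t / 24),
                      hour_of_day = (t - 1) %% 24,
                      source = pars$source, value = y)
      attr(d, "n_clipped") <- n_clipped
      d
    })
    res <- do.call(rbind, out)
    attr(res, "n_clipped") <- sum(vapply(out, attr, integer(1), "n_clipped"))
    rownames(res) <- NULL
    res
  })
}

#' Inject pre-event deviations into a pen's streams
#'
#' Applies the configured per-source shifts on the three days before each
#' pen's first tail-biting event (never on day 0 or later — the pipeline is
#' meant to alarm before serious tail damage). Water-source shifts are
#' multiplicative on the stored natural-scale values; temperature shifts are
#' additive.
#'
#' @param sensors long sensor data.frame from [simulate_sensor_stream()].
#' @param events event log.
#' @param profile deviation profile, see [default_deviation_profile()].
#' @return List with `sensors` (modified) and `ground_truth` (one row per
#'   pen-source with the injected amount and the affected days).
#' @export
inject_pre_event_deviation <- function(sensors, events, profile) {
  tb <- events[events$type == "tail_biting", , drop = FALSE]
  if (nrow(tb) == 0) {
    return(list(sensors = sensors,
                ground_truth = data.frame(pen_id = character(0),
                                          source = character(0),
                                          kind = character(0),
                                          amount = numeric(0),
                                          first_day = numeric(0),
                                          last_day = numeric(0))))
  }
  first <- tapply(tb$day_index, tb$pen_id, min)
  gt <- list()
  for (pen in names(first)) {
    d0 <- first[[pen]]
    stopifnot(d0 >= 4)  # the scheduler guarantees a complete window
    days <- (d0 - 3):(d0 - 1)
    for (i in seq_len(nrow(profile))) {
      pr <- profile[i, ]
      sel <- sensors$pen_id == pen & sensors$source == pr$source &
        sensors$day_index %in% days
      if (pr$kind == "multiplicative") {
        sensors$value[sel] <- sensors$value[sel] * pr$amount
      } else {
        sensors$value[sel] <- sensors$value[sel] + pr$amount
      }
      gt[[length(gt) + 1]] <- data.frame(pen_id = pen, source = pr$source,
                                         kind = pr$kind, amount = pr$amount,
                                         first_day = min(days),
                                         last_day = max(days))
    }
  }
  list(sensors = sensors, ground_truth = do.call(rbind, gt))
}

#' Simulate a complete synthetic barn
#'
#' Pens with treatments, the four hourly sensor streams per pen, the event
#' schedule, and the pre-event deviations, all deterministic functions of
#' the configuration seed.
#'
#' @param config a [sim_config()].
#' @return List with `pens`, `events`, `sensors`, `ground_truth`, `config`.
#' @export
simulate_barn <- function(config) {
  pens <- simulate_pens(config)
  events <- schedule_events(pens, config)
  sensors <- do.call(rbind, lapply(seq_len(nrow(pens)), function(i) {
    simulate_sensor_stream(pens$pen_id[i], config,
                           seed = config$seed + 1000L + i)
  }))
  rownames(sensors) <- NULL
  inj <- inject_pre_event_deviation(sensors, events,
                                    config$deviation_profile)
  list(pens = pens, events = events, sensors = inj$sensors,
       ground_truth = inj$ground_truth, config = config)
}
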
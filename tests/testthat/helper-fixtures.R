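# Shared fixture builders. Everything is generated in code under fixed seeds.

# a default 8-dim spec around a temperature-like stream
tiny_spec <- function(discount = 0.88, pct = 0.40, series_mean = 19,
                      theta0 = c(19, 0, 0.4, 0.2, 0.1, 0.05, 0.02, 0.01)) {
  dlm_spec(3, theta0, diag(10, 8), obs_variance_pct = pct,
           discount = discount, series_mean = series_mean)
}

# hourly values from a deterministic diurnal curve plus seeded noise
synth_stream <- function(n_hours, level = 19.5, slope = 0,
                         amps = c(0.45, 0.12, 0.04),
                         phases = c(0.5, 0.3, 0.1),
                         noise_sd = 0.28, seed = 1) {
  t <- seq_len(n_hours)
  omega <- 2 * pi / 24
  mu <- level + slope * t +
    amps[1] * sin(omega * t + phases[1]) +
    amps[2] * sin(2 * omega * t + phases[2]) +
    amps[3] * sin(3 * omega * t + phases[3])
  withr::with_seed(seed, mu + rnorm(n_hours, sd = noise_sd))
}

# pen roster with fully controlled treatments and event days
toy_pens <- function(n, batch = 1, tail = "docked", straw = "yes",
                     space = "low", prefix = "t") {
  data.frame(pen_id = sprintf("b%d_%s%02d", batch, prefix, seq_len(n)),
             batch = batch,
             tail = tail, straw = straw, space = space,
             group_size = ifelse(space == "low", 18L, 11L))
}

toy_events <- function(pen_ids, days, type = "tail_biting") {
  data.frame(pen_id = pen_ids, day_index = days,
             type = rep_len(type, length(pen_ids)))
}

# window-feature table with a controllable class separation
toy_window_features <- function(n_pairs, shift = 3, seed = 1,
                                days = c(-3L, -2L, -1L)) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_pairs), function(i) {
      out <- lapply(c(1, 0), function(lab) {
        d <- data.frame(pair_id = i,
                        pen_id = sprintf("p%02d_%d", i, lab),
                        label = lab, day_rel = days)
        for (col in predictor_columns()) {
          d[[col]] <- rnorm(length(days)) + lab * shift
        }
        d
      })
      do.call(rbind, out)
    })
    do.call(rbind, rows)
  })
}

# one small simulated barn, built once and reused across tests
small_barn <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressMessages(suppressWarnings(
        simulate_barn(sim_config(n_pens = 16, weeks = 4, seed = 99))))
    }
    cache
  }
})
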
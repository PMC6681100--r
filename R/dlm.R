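#' Harmonic component of a diurnal pattern
#'
#' A single sinusoid of the diurnal cycle with `peaks_per_day` peaks per 24 h,
#' stored both in sine-cosine form (`beta_sin`, `beta_cos`) and in the more
#' interpretable amplitude/phase form. The wave is
#' `beta_cos * cos(N*omega*t) + beta_sin * sin(N*omega*t)` with
#' `omega = 2*pi/24`, equivalently `A * sin(N*omega*t + c)`.
#'
#' @param peaks_per_day integer, 1, 2 or 3 (24-, 12- or 8-hour cycle).
#' @param beta_sin,beta_cos coefficients of the sine-cosine form.
#' @return An object of class `harmonic_component`: a list with fields
#'   `peaks_per_day`, `beta_sin`, `beta_cos`, `amplitude`, `phase`,
#'   `period_hours`.
#' @examples
#' w <- harmonic_component(1, beta_sin = 3, beta_cos = 4)
#' w$amplitude  # 5
#' @export
harmonic_component <- function(peaks_per_day, beta_sin, beta_cos) {
  if (!peaks_per_day %in% 1:3) {
    stop("peaks_per_day must be 1, 2 or 3")
  }
  ap <- amplitude_phase(beta_sin, beta_cos)
  structure(
    list(
      peaks_per_day = as.integer(peaks_per_day),
      beta_sin = beta_sin,
      beta_cos = beta_cos,
      amplitude = ap[["amplitude"]],
      phase = ap[["phase"]],
      period_hours = 24 / peaks_per_day
    ),
    class = "harmonic_component"
  )
}

#' Amplitude and phase of a sine-cosine wave
#'
#' Converts the sine-cosine parameterisation
#' `f(t) = beta_cos * cos(N*omega*t) + beta_sin * sin(N*omega*t)`
#' to amplitude `A = sqrt(beta_sin^2 + beta_cos^2)` and phase
#' `c = atan2(beta_cos, beta_sin)`, so that `f(t) = A * sin(N*omega*t + c)`.
#'
#' @param beta_sin,beta_cos coefficients of the sine and cosine terms.
#' @return Named numeric vector with elements `amplitude` and `phase`
#'   (phase in `(-pi, pi]`; 0 by convention when both betas are 0).
#' @export
amplitude_phase <- function(beta_sin, beta_cos) {
  a <- sqrt(beta_sin^2 + beta_cos^2)
  ph <- ifelse(a == 0, 0, atan2(beta_cos, beta_sin))
  c(amplitude = a, phase = ph)
}

#' Specify a trend-plus-harmonics dynamic linear model
#'
#' Builds the univariate DLM used for every sensor stream: a local linear
#' trend (level + hourly slope) plus `n_waves` harmonic waves with 1, 2, ...
#' peaks per 24 h. The state vector is
#' `(level, slope, beta_cos_1, beta_sin_1, ..., beta_cos_k, beta_sin_k)`;
#' the system matrix is block-diagonal with one 2x2 trend block
#' `[[1,1],[0,1]]` and one 2x2 rotation block of angle `N*omega` per wave
#' (`omega = 2*pi/24`). The design vector selects the level and the cosine
#' entry of each wave. State evolution noise is implied by the discount
#' factor (see [discount_covariance()]); the observational variance is held
#' constant at `V = obs_variance_pct/100 * series_mean`.
#'
#' @param n_waves number of harmonic waves (0 to 3; the pipeline uses 3).
#' @param theta0 prior state mean, length `2 + 2*n_waves`.
#' @param C0 prior state covariance, symmetric PSD of matching dimension.
#' @param obs_variance_pct observational variance as a percentage of the
#'   series mean (in (0, 100]).
#' @param discount discount factor in (0, 1]; lower values give a more
#'   flexible (faster-adapting) model.
#' @param series_mean mean of the (transformed) training series, used to fix
#'   `V` before filtering.
#' @return Object of class `dlm_spec`.
#' @examples
#' sp <- dlm_spec(3, c(10, 0, 1, 0, 0.5, 0, 0.2, 0), diag(8),
#'                obs_variance_pct = 0.40, discount = 0.88, series_mean = 19)
#' sp$V  # 0.076
#' @export
dlm_spec <- function(n_waves = 3, theta0, C0, obs_variance_pct, discount,
                     series_mean) {
  if (!n_waves %in% 0:3) stop("n_waves must be between 0 and 3")
  p <- 2L + 2L * n_waves
  if (length(theta0) != p) {
    stop(sprintf("theta0 must have length %d (2 trend + 2 per wave), got %d",
                 p, length(theta0)))
  }
  C0 <- as.matrix(C0)
  if (!all(dim(C0) == p)) stop("C0 dimensions do not match the state vector")
  if (max(abs(C0 - t(C0))) > 1e-8) stop("C0 must be symmetric")
  if (!is.finite(obs_variance_pct) || obs_variance_pct <= 0 ||
      obs_variance_pct > 100) {
    stop("obs_variance_pct must lie in (0, 100]")
  }
  if (!is.finite(discount) || discount <= 0 || discount > 1) {
    stop("discount must lie in (0, 1]")
  }
  if (!is.finite(series_mean)) stop("series_mean must be finite")

  omega <- 2 * pi / 24
  G <- matrix(0, p, p)
  G[1:2, 1:2] <- matrix(c(1, 0, 1, 1), 2, 2)  # level <- level + slope
  Fv <- numeric(p)
  Fv[1] <- 1
  if (n_waves > 0) {
    for (k in seq_len(n_waves)) {
      i <- 2L + 2L * (k - 1L) + 1L
      phi <- k * omega
      G[i:(i + 1), i:(i + 1)] <- matrix(c(cos(phi), -sin(phi),
                                          sin(phi), cos(phi)), 2, 2)
      Fv[i] <- 1  # cosine entry of the wave
    }
  }
  V <- obs_variance_pct / 100 * series_mean
  if (V <= 0) stop("implied observational variance V must be positive")

  structure(
    list(n_waves = n_waves, theta0 = as.numeric(theta0), C0 = C0,
         design_vector = Fv, system_matrix = G,
         obs_variance_pct = obs_variance_pct, discount = discount, V = V),
    class = "dlm_spec"
  )
}

#' @export
print.dlm_spec <- function(x, ...) {
  cat(sprintf(
    "DLM: trend + %d harmonic wave(s); state dim %d\n  V = %.6g (%.2f%% of series mean), discount = %.2f\n",
    x$n_waves, length(x$theta0), x$V, x$obs_variance_pct, x$discount))
  invisible(x)
}

#' Discounted prior covariance
#'
#' One-step prior covariance under the single-discount construction
#' `R = G %*% C_prev %*% t(G) / discount`, which replaces an explicit
#' state-evolution covariance `W`: the discount inflates the propagated
#' posterior covariance, so lower discounts give a more flexible model.
#'
#' @param C_prev posterior covariance from the previous step.
#' @param G system matrix.
#' @param discount discount factor in (0, 1].
#' @return Prior covariance matrix `R`.
#' @export
discount_covariance <- function(C_prev, G, discount) {
  if (!is.finite(discount) || discount <= 0 || discount > 1) {
    stop("discount must lie in (0, 1]")
  }
  (G %*% C_prev %*% t(G)) / discount
}

#' Create a filter state
#'
#' @param m posterior state mean.
#' @param C posterior state covariance.
#' @param t hour index of the last processed observation (0 before any).
#' @return Object of class `filter_state` with fields `m`, `C`, `a`, `R`,
#'   `f`, `Q`, `e`, `u`, `t` (forecast fields are `NA` until a step is run).
#' @export
filter_state <- function(m, C, t = 0L) {
  structure(list(m = as.numeric(m), C = as.matrix(C),
                 a = NULL, R = NULL, f = NA_real_, Q = NA_real_,
                 e = NA_real_, u = NA_real_, t = as.integer(t)),
            class = "filter_state")
}

#' Standardize a one-step forecast error
#'
#' `u = e / sqrt(Q)`. Under a correctly specified model the standardized
#' errors are approximately standard Gaussian, which is what makes them
#' comparable across sensor streams and usable as anomaly features.
#'
#' @param e forecast error `y - f`.
#' @param Q forecast variance (must be positive).
#' @return Standardized forecast error.
#' @export
standardize_error <- function(e, Q) {
  if (any(!is.finite(Q)) || any(Q <= 0)) stop("Q must be positive and finite")
  e / sqrt(Q)
}

#' One Kalman filtering step
#'
#' Propagates the state (`a = G m`, `R` by [discount_covariance()]),
#' forecasts (`f = F'a`, `Q = F'RF + V`, `e = y - f`, `u = e/sqrt(Q)`) and
#' updates the posterior by the Kalman gain. A missing (or non-finite)
#' observation propagates the state without an update and flags `e`, `u`
#' as `NA`.
#'
#' @param state a [filter_state()].
#' @param y the observation at the next hour, or `NA`.
#' @param spec a [dlm_spec()].
#' @return Updated `filter_state`.
#' @export
kalman_step <- function(state, y, spec) {
  G <- spec$system_matrix
  Fv <- spec$design_vector
  a <- as.numeric(G %*% state$m)
  R <- discount_covariance(state$C, G, spec$discount)
  RF <- as.numeric(R %*% Fv)
  f <- sum(Fv * a)
  Q <- sum(Fv * RF) + spec$V
  st <- state
  st$a <- a
  st$R <- R
  st$f <- f
  st$Q <- Q
  st$t <- state$t + 1L
  if (is.null(y) || length(y) == 0 || !is.finite(y)) {
    st$m <- a
    st$C <- R
    st$e <- NA_real_
    st$u <- NA_real_
  } else {
    e <- y - f
    A <- RF / Q
    C <- R - tcrossprod(A) * Q
    st$m <- a + A * e
    st$C <- (C + t(C)) / 2
    st$e <- e
    st$u <- standardize_error(e, Q)
  }
  st
}

#' Filter a whole hourly series
#'
#' Runs the Kalman filter over an hourly series, returning the one-step
#' forecast `f`, forecast variance `Q`, forecast error `e` and standardized
#' error `u` per hour. Missing hours propagate the state without an update
#' (no imputation); their `e` and `u` are `NA`.
#'
#' @param y numeric vector of hourly observations (`NA` = missing).
#' @param spec a [dlm_spec()].
#' @return A list with `filtered`, a data.frame with columns `t`, `y`, `f`,
#'   `Q`, `e`, `u`, and `state`, the final [filter_state()].
#' @export
dlm_filter <- function(y, spec) {
  n <- length(y)
  if (n == 0) stop("empty series")
  G <- spec$system_matrix
  Fv <- spec$design_vector
  V <- spec$V
  delta <- spec$discount
  m <- spec$theta0
  C <- spec$C0
  f <- Q <- e <- u <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    a <- as.numeric(G %*% m)
    R <- (G %*% C %*% t(G)) / delta
    RF <- as.numeric(R %*% Fv)
    ft <- sum(Fv * a)
    Qt <- sum(Fv * RF) + V
    f[t] <- ft
    Q[t] <- Qt
    yt <- y[t]
    if (is.finite(yt)) {
      et <- yt - ft
      A <- RF / Qt
      Cn <- R - tcrossprod(A) * Qt
      m <- a + A * et
      C <- (Cn + t(Cn)) / 2
      e[t] <- et
      u[t] <- et / sqrt(Qt)
    } else {
      m <- a
      C <- R
    }
  }
  st <- filter_state(m, C, t = n)
  st$f <- f[n]; st$Q <- Q[n]; st$e <- e[n]; st$u <- u[n]
  list(filtered = data.frame(t = seq_len(n), y = y, f = f, Q = Q, e = e, u = u),
       state = st)
}

#' Estimate the prior state vector by harmonic regression
#'
#' Fits `value ~ t + cos/sin terms for 24-, 12- and 8-hour cycles` on
#' training data from pens with no tail-biting event, pooling pens with a
#' pen-level random intercept (a plain fixed-effects fit is used when only
#' one pen is present or the mixed fit fails). The fitted coefficients seed
#' the DLM state prior `theta0 = (level, slope, beta_cos_1, beta_sin_1, ...)`;
#' `C0` is a diffuse diagonal prior scaled to 10 times the series variance.
#'
#' @param data data.frame with columns `pen_id`, `t` (hour index, 1-based)
#'   and `value` (`NA` allowed).
#' @param n_waves number of harmonic waves (default 3).
#' @return List with `theta0` (length `2 + 2*n_waves`) and `C0`.
#' @export
estimate_theta0 <- function(data, n_waves = 3) {
  stopifnot(all(c("pen_id", "t", "value") %in% names(data)))
  d <- data[is.finite(data$value), , drop = FALSE]
  if (nrow(d) < 24) stop("need at least 24 hourly observations to identify the diurnal waves")
  omega <- 2 * pi / 24
  # time is rescaled for conditioning; the slope is rescaled back below
  X <- data.frame(value = d$value, t = d$t / 1000, pen_id = factor(d$pen_id))
  terms <- "t"
  for (k in seq_len(n_waves)) {
    X[[paste0("cos", k)]] <- cos(k * omega * d$t)
    X[[paste0("sin", k)]] <- sin(k * omega * d$t)
    terms <- c(terms, paste0("cos", k), paste0("sin", k))
  }
  rhs <- paste(terms, collapse = " + ")
  coefs <- NULL
  if (nlevels(X$pen_id) > 1) {
    fit <- tryCatch(
      lme4::lmer(stats::as.formula(paste("value ~", rhs, "+ (1 | pen_id)")),
                 data = X,
                 control = lme4::lmerControl(check.conv.singular = "ignore")),
      error = function(e) NULL)
    if (!is.null(fit)) coefs <- lme4::fixef(fit)
  }
  if (is.null(coefs)) {
    coefs <- stats::coef(stats::lm(stats::as.formula(paste("value ~", rhs)),
                                   data = X))
  }
  theta0 <- numeric(2 + 2 * n_waves)
  theta0[1] <- coefs[["(Intercept)"]]
  theta0[2] <- coefs[["t"]] / 1000
  for (k in seq_len(n_waves)) {
    theta0[2 * k + 1] <- coefs[[paste0("cos", k)]]
    theta0[2 * k + 2] <- coefs[[paste0("sin", k)]]
  }
  C0 <- diag(10 * stats::var(d$value), 2 + 2 * n_waves)
  list(theta0 = theta0, C0 = C0)
}

#' Extract the fitted harmonic components from a state vector
#'
#' @param theta state vector `(level, slope, beta_cos_1, beta_sin_1, ...)`.
#' @return List of [harmonic_component()] objects, one per wave.
#' @export
harmonic_components <- function(theta) {
  n_waves <- (length(theta) - 2) / 2
  lapply(seq_len(n_waves), function(k) {
    harmonic_component(k, beta_sin = theta[2 * k + 2], beta_cos = theta[2 * k + 1])
  })
}

pooled_filter <- function(series_list, theta0, C0, obs_variance_pct, discount,
                          burn_in) {
  out <- lapply(series_list, function(y) {
    spec <- dlm_spec(n_waves = (length(theta0) - 2) / 2, theta0 = theta0,
                     C0 = C0, obs_variance_pct = obs_variance_pct,
                     discount = discount, series_mean = mean(y, na.rm = TRUE))
    fl <- dlm_filter(y, spec)$filtered
    if (nrow(fl) > burn_in) fl[-seq_len(burn_in), ] else fl[0, ]
  })
  do.call(rbind, out)
}

#' Calibrate the observational variance percentage
#'
#' Filters every training series at each candidate percentage and returns
#' the percentage whose pooled standardized forecast errors have sample
#' standard deviation closest to 1 (the Gaussianity target for `u`).
#'
#' @param series_list list of numeric hourly series (non-event pens).
#' @param theta0,C0 state prior, e.g. from [estimate_theta0()].
#' @param discount discount factor used while calibrating.
#' @param pct_grid candidate percentages of the series mean.
#' @param burn_in hours discarded at the start of each series (default 48).
#' @return The selected percentage, with the sweep (`pct`, `sd_u`) attached
#'   as attribute `"sweep"`.
#' @export
calibrate_obs_variance <- function(series_list, theta0, C0, discount,
                                   pct_grid, burn_in = 48) {
  if (length(series_list) == 0) stop("empty series set")
  if (length(pct_grid) == 0) stop("empty percentage grid")
  sd_u <- vapply(pct_grid, function(p) {
    fl <- pooled_filter(series_list, theta0, C0, p, discount, burn_in)
    stats::sd(fl$u, na.rm = TRUE)
  }, numeric(1))
  best <- pct_grid[which.min(abs(sd_u - 1))]
  attr(best, "sweep") <- data.frame(pct = pct_grid, sd_u = sd_u)
  best
}

#' Calibrate the discount factor
#'
#' Filters every training series at each candidate discount and returns the
#' value minimizing the pooled one-step-ahead forecast RMSE. The MAE
#' minimizer is also computed; a message is emitted when the two disagree
#' (RMSE wins).
#'
#' @param series_list list of numeric hourly series.
#' @param theta0,C0 state prior.
#' @param obs_variance_pct observational variance percentage.
#' @param grid candidate discounts (default 0.80 to 1.00 by 0.01, the
#'   21-value grid).
#' @param burn_in hours discarded at the start of each series.
#' @return The selected discount, with the sweep (`discount`, `rmse`, `mae`)
#'   attached as attribute `"sweep"`.
#' @export
calibrate_discount <- function(series_list, theta0, C0, obs_variance_pct,
                               grid = seq(0.80, 1.00, by = 0.01),
                               burn_in = 48) {
  if (length(series_list) == 0) stop("empty series set")
  if (any(grid <= 0 | grid > 1)) stop("discount grid must lie in (0, 1]")
  sweep <- do.call(rbind, lapply(grid, function(d) {
    fl <- pooled_filter(series_list, theta0, C0, obs_variance_pct, d, burn_in)
    data.frame(discount = d,
               rmse = sqrt(mean(fl$e^2, na.rm = TRUE)),
               mae = mean(abs(fl$e), na.rm = TRUE))
  }))
  best <- sweep$discount[which.min(sweep$rmse)]
  best_mae <- sweep$discount[which.min(sweep$mae)]
  if (!isTRUE(all.equal(best, best_mae))) {
    message(sprintf(
      "RMSE- and MAE-optimal discounts disagree (%.2f vs %.2f); using RMSE",
      best, best_mae))
  }
  attr(best, "sweep") <- sweep
  best
}
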
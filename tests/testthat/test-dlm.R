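test_that("system matrix has the trend + rotation block structure", {
  sp <- tiny_spec()
  G <- sp$system_matrix
  expect_equal(dim(G), c(8, 8))
  expect_equal(G[1:2, 1:2], matrix(c(1, 0, 1, 1), 2, 2))
  # off-block entries are zero
  expect_true(all(G[1:2, 3:8] == 0) && all(G[3:8, 1:2] == 0))
  # the 24-hour wave block raised to the 24th power is a full cycle
  B <- G[3:4, 3:4]
  P <- diag(2)
  for (i in 1:24) P <- P %*% B
  expect_equal(P, diag(2), tolerance = 1e-12)
  # the 12-hour wave completes a cycle in 12 steps
  B2 <- G[5:6, 5:6]
  P2 <- diag(2)
  for (i in 1:12) P2 <- P2 %*% B2
  expect_equal(P2, diag(2), tolerance = 1e-12)
  # design vector selects level and the cosine entry of each wave
  expect_equal(sp$design_vector, c(1, 0, 1, 0, 1, 0, 1, 0))
})

test_that("spec construction rejects malformed inputs", {
  expect_error(dlm_spec(3, rep(0, 6), diag(8), 1, 0.9, 10), "length 8")
  expect_error(dlm_spec(3, rep(0, 8), diag(8), -1, 0.9, 10),
               "obs_variance_pct")
  expect_error(dlm_spec(3, rep(0, 8), diag(8), 1, 0, 10), "discount")
  expect_error(dlm_spec(3, rep(0, 8), diag(6), 1, 0.9, 10), "dimensions")
  # V is the stated percentage of the series mean
  expect_equal(tiny_spec(pct = 0.40, series_mean = 19)$V, 0.0019 * 40)
})

test_that("discounted prior covariance: limits and monotonicity", {
  expect_equal(discount_covariance(diag(3), diag(3), 1), diag(3))
  expect_equal(discount_covariance(diag(3), diag(3), 0.5), 2 * diag(3))
  expect_error(discount_covariance(diag(3), diag(3), 0), "discount")
  # diagonal entries are non-increasing in the discount for fixed C, G
  G <- tiny_spec()$system_matrix
  C <- crossprod(matrix(rnorm(64), 8, 8)) / 8
  grid <- seq(0.5, 1, by = 0.05)
  diags <- sapply(grid, function(d) diag(discount_covariance(C, G, d)))
  expect_true(all(apply(diags, 1, diff) <= 1e-12))
})

test_that("filter equals conjugate-normal sequential updating when static", {
  # wave-free model, discount 1, known-slope 0: the Kalman level estimate
  # must match the closed-form posterior mean of a normal mean with known
  # variance after every observation
  set.seed(42)
  y <- rnorm(1000, mean = 5, sd = 1)
  m0 <- 0; C0v <- 100
  spec <- dlm_spec(0, c(m0, 0), diag(c(C0v, 0)), obs_variance_pct = 20,
                   discount = 1, series_mean = 5)
  V <- spec$V
  st <- filter_state(spec$theta0, spec$C0)
  prec <- 1 / C0v + seq_along(y) / V
  oracle <- (m0 / C0v + cumsum(y) / V) / prec
  for (t in seq_along(y)) {
    st <- kalman_step(st, y[t], spec)
    expect_lt(abs(st$m[1] - oracle[t]), 1e-8)
  }
  # posterior variance matches too
  expect_lt(abs(st$C[1, 1] - 1 / prec[1000]), 1e-8)
})

test_that("noise-free limit, missing values and error flags", {
  # nearly noise-free observation with diffuse prior: one update lands on y
  spec <- dlm_spec(0, c(0, 0), diag(c(1e6, 0)), obs_variance_pct = 1e-8,
                   discount = 1, series_mean = 1)
  st <- kalman_step(filter_state(spec$theta0, spec$C0), 7.3, spec)
  expect_equal(st$m[1], 7.3, tolerance = 1e-6)
  # missing observation: posterior equals prior, e and u absent
  sp <- tiny_spec()
  st0 <- filter_state(sp$theta0, sp$C0)
  st1 <- kalman_step(st0, NA, sp)
  expect_equal(st1$m, st1$a)
  expect_equal(st1$C, st1$R)
  expect_true(is.na(st1$e) && is.na(st1$u))
  # hour-0 temperature gaps just propagate through a whole series
  y <- synth_stream(240, seed = 5)
  y[seq(1, 240, by = 24)] <- NA
  fl <- dlm_filter(y, tiny_spec(discount = 1))$filtered
  expect_true(all(is.na(fl$u[seq(1, 240, by = 24)])))
  expect_true(all(!is.na(fl$f)))
  expect_true(all(fl$Q > 0))
})

test_that("standardized forecast errors use the root of Q", {
  expect_equal(standardize_error(0, 4), 0)
  expect_equal(standardize_error(2, 4), 1)
  expect_error(standardize_error(1, 0), "positive")
  # filtering a correctly specified stream gives u ~ N(0, 1)
  y <- synth_stream(5000, noise_sd = sqrt(0.004 * 19.5), seed = 11)
  spec <- dlm_spec(3, c(19.5, 0, rep(0.1, 6)), diag(10, 8),
                   obs_variance_pct = 0.40, discount = 1,
                   series_mean = mean(y))
  u <- dlm_filter(y, spec)$filtered$u[-(1:48)]
  expect_lt(abs(mean(u)), 0.05)
  expect_lt(abs(sd(u) - 1), 0.1)
})

test_that("forecast variance decreases with the discount", {
  y <- synth_stream(200, seed = 21)
  qs <- sapply(c(0.85, 0.95, 1), function(d) {
    fl <- dlm_filter(y, tiny_spec(discount = d, series_mean = mean(y)))
    fl$filtered$Q[100:200]
  })
  expect_true(all(qs > 0))
  expect_true(all(qs[, 1] >= qs[, 2] - 1e-10))
  expect_true(all(qs[, 2] >= qs[, 3] - 1e-10))
})

test_that("variance-percentage calibration recovers the generating value", {
  gen_pct <- 5
  series <- lapply(1:3, function(i) {
    synth_stream(720, level = 20, noise_sd = sqrt(gen_pct / 100 * 20),
                 seed = 100 + i)
  })
  est <- estimate_theta0(data.frame(
    pen_id = rep(seq_along(series), each = 720),
    t = rep(1:720, length(series)), value = unlist(series)))
  grid <- c(2, 3.5, 5, 7, 10)
  got <- calibrate_obs_variance(series, est$theta0, est$C0, discount = 1,
                                pct_grid = grid)
  expect_equal(as.numeric(got), 5)
  # single-candidate grid returns that candidate
  one <- calibrate_obs_variance(series, est$theta0, est$C0, 1, pct_grid = 7)
  expect_equal(as.numeric(one), 7)
  expect_error(calibrate_obs_variance(list(), est$theta0, est$C0, 1, grid),
               "empty")
})

test_that("discount calibration separates drifting from static series", {
  withr::with_seed(33, {
    rw <- cumsum(rnorm(1000, sd = 0.5)) + 20 + rnorm(1000, sd = 0.3)
    flat <- rep(20, 1000) + rnorm(1000, sd = 0.3)
  })
  th <- c(20, 0); C0 <- diag(c(10, 0))
  d_rw <- calibrate_discount(list(rw), th, C0, obs_variance_pct = 0.45)
  d_flat <- calibrate_discount(list(flat), th, C0, obs_variance_pct = 0.45)
  expect_lt(as.numeric(d_rw), 1)
  expect_gte(as.numeric(d_flat), 0.97)
  # the default grid is the 21 values 0.80 ... 1.00
  sweep <- attr(d_rw, "sweep")
  expect_equal(sweep$discount, seq(0.80, 1.00, by = 0.01))
  expect_equal(nrow(sweep), 21)
})

test_that("theta0 estimation recovers harmonic structure", {
  omega <- 2 * pi / 24
  t <- 1:240
  # noise-free single wave: exact recovery
  y <- 5 + 2 * cos(omega * t)
  est <- estimate_theta0(data.frame(pen_id = "a", t = t, value = y))
  expect_equal(est$theta0[1], 5, tolerance = 1e-8)
  expect_equal(est$theta0[2], 0, tolerance = 1e-10)
  amps <- vapply(harmonic_components(est$theta0), `[[`, 0, "amplitude")
  expect_equal(amps, c(2, 0, 0), tolerance = 1e-8)
  # the state vector has length eight
  expect_length(est$theta0, 8)
  expect_equal(dim(est$C0), c(8, 8))
  # too little data to identify the waves
  expect_error(estimate_theta0(data.frame(pen_id = "a", t = 1:10,
                                          value = rnorm(10))), "24")
  # noisy multi-pen recovery stays close to the truth
  d <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(pen_id = i, t = 1:720,
               value = synth_stream(720, level = 19.5, slope = -0.002,
                                    seed = 200 + i))
  }))
  est2 <- estimate_theta0(d)
  expect_equal(est2$theta0[1], 19.5, tolerance = 0.1)
  expect_lt(abs(est2$theta0[2] - (-0.002)), 5e-4)
  amps2 <- vapply(harmonic_components(est2$theta0), `[[`, 0, "amplitude")
  expect_equal(amps2, c(0.45, 0.12, 0.04), tolerance = 0.05)
})

test_that("amplitude/phase conversion reconstructs the wave", {
  expect_equal(amplitude_phase(3, 4)[["amplitude"]], 5)
  expect_equal(amplitude_phase(2, 0)[["phase"]], 0)
  expect_equal(amplitude_phase(0, 0), c(amplitude = 0, phase = 0))
  omega <- 2 * pi / 24
  withr::with_seed(8, {
    for (i in 1:10) {
      b1 <- rnorm(1); b2 <- rnorm(1); N <- sample(1:3, 1)
      ap <- amplitude_phase(b1, b2)
      t <- seq(0, 24, by = 0.5)
      expect_equal(ap[["amplitude"]] * sin(N * omega * t + ap[["phase"]]),
                   b2 * cos(N * omega * t) + b1 * sin(N * omega * t),
                   tolerance = 1e-10)
    }
  })
  # harmonic_component validates and stores both forms
  w <- harmonic_component(2, beta_sin = 3, beta_cos = 4)
  expect_equal(w$amplitude^2, w$beta_sin^2 + w$beta_cos^2)
  expect_equal(w$period_hours, 12)
  expect_error(harmonic_component(4, 1, 1), "peaks_per_day")
})

test_that("fitted waves reproduce the generating diurnal curve", {
  y <- synth_stream(2400, seed = 77)
  est <- estimate_theta0(data.frame(pen_id = "a", t = 1:2400, value = y))
  omega <- 2 * pi / 24
  tt <- 1:24
  truth <- 0.45 * sin(omega * tt + 0.5) + 0.12 * sin(2 * omega * tt + 0.3) +
    0.04 * sin(3 * omega * tt + 0.1)
  fit <- rowSums(sapply(1:3, function(k) {
    est$theta0[2 * k + 1] * cos(k * omega * tt) +
      est$theta0[2 * k + 2] * sin(k * omega * tt)
  }))
  expect_lt(sqrt(sum((fit - truth)^2)) / sqrt(sum(truth^2)), 0.05)
})
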
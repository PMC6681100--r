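ACTIVATIONS <- c("rectifier", "rectifier_dropout", "maxout", "maxout_dropout")

#' Alarm-type day windows
#'
#' The three alarm types differ in which days relative to the event day
#' (day 0) contribute daily predictions: `UNTIMED` uses days -3, -2 and -1,
#' `BEFORE` days -3 and -2, `ON` day -1 only.
#'
#' @param name `"UNTIMED"`, `"BEFORE"` or `"ON"`.
#' @return Integer vector of included days relative to day 0.
#' @export
alarm_days <- function(name = c("UNTIMED", "BEFORE", "ON")) {
  switch(match.arg(name),
         UNTIMED = c(-3L, -2L, -1L),
         BEFORE = c(-3L, -2L),
         ON = -1L)
}

#' Network configuration
#'
#' @param activation one of `"rectifier"`, `"rectifier_dropout"`, `"maxout"`,
#'   `"maxout_dropout"` (maxout uses two linear pieces; dropout rate 0.5 on
#'   hidden activations).
#' @param layer1_factor first hidden layer size as a multiple of the number
#'   of predictors (2/3, 1 or 4/3).
#' @param layer2_factor optional second hidden layer size as a multiple of
#'   the first layer's node count.
#' @param n_predictors number of input predictors (12 in the pipeline).
#' @return Object of class `net_config` with the resolved integer layer
#'   sizes in `hidden_sizes`.
#' @export
net_config <- function(activation, layer1_factor, layer2_factor = NULL,
                       n_predictors = 12) {
  activation <- match.arg(activation, ACTIVATIONS)
  s1 <- max(1L, as.integer(round(n_predictors * layer1_factor)))
  hidden <- s1
  if (!is.null(layer2_factor) && !is.na(layer2_factor)) {
    hidden <- c(s1, max(1L, as.integer(round(s1 * layer2_factor))))
  }
  structure(list(activation = activation,
                 n_hidden_layers = length(hidden),
                 layer1_factor = layer1_factor,
                 layer2_factor = if (length(hidden) == 2) layer2_factor else NA,
                 hidden_sizes = hidden,
                 n_predictors = n_predictors),
            class = "net_config")
}

#' @export
print.net_config <- function(x, ...) {
  cat(sprintf("net_config: %s, hidden [%s] (%d parameters)\n", x$activation,
              paste(x$hidden_sizes, collapse = ", "), n_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a configuration
#'
#' @param config a [net_config()].
#' @return Integer parameter count (maxout layers carry two linear pieces).
#' @export
n_params <- function(config) {
  sizes <- c(config$n_predictors, config$hidden_sizes)
  pieces <- if (grepl("^maxout", config$activation)) 2L else 1L
  hidden <- sum((sizes[-length(sizes)] + 1L) * sizes[-1L]) * pieces
  hidden + utils::tail(sizes, 1) + 1L
}

#' Enumerate the architecture grid
#'
#' The tuning grid crosses the four activation functions with six size
#' choices: three one-layer sizes (2/3, 1 or 4/3 times the number of
#' predictors) and three two-layer arms where the second layer applies the
#' same factor to the first layer's node count, giving exactly 24
#' configurations.
#'
#' @param n_predictors number of input predictors (12).
#' @return List of 24 [net_config()] objects.
#' @export
enumerate_grid <- function(n_predictors = 12) {
  factors <- c(2 / 3, 1, 4 / 3)
  grid <- list()
  for (act in ACTIVATIONS) {
    for (f1 in factors) {
      grid[[length(grid) + 1]] <- net_config(act, f1,
                                             n_predictors = n_predictors)
    }
    for (f in factors) {
      grid[[length(grid) + 1]] <- net_config(act, f, f,
                                             n_predictors = n_predictors)
    }
  }
  grid
}

## ---- minimal feed-forward network (full-batch Adam, backprop) ----

init_net <- function(config, n_in) {
  sizes <- c(n_in, config$hidden_sizes)
  maxout <- grepl("^maxout", config$activation)
  layers <- lapply(seq_along(config$hidden_sizes), function(l) {
    fan_in <- sizes[l]
    out <- sizes[l + 1]
    lay <- list(W = matrix(stats::rnorm(fan_in * out, sd = sqrt(2 / fan_in)),
                           fan_in, out),
                b = rep(0, out))
    if (maxout) {
      lay$W2 <- matrix(stats::rnorm(fan_in * out, sd = sqrt(2 / fan_in)),
                       fan_in, out)
      lay$b2 <- rep(0, out)
    }
    lay
  })
  last <- utils::tail(sizes, 1)
  list(layers = layers,
       w_out = matrix(stats::rnorm(last, sd = sqrt(1 / last)), last, 1),
       b_out = 0,
       maxout = maxout,
       dropout = grepl("dropout$", config$activation),
       config = config)
}

net_forward <- function(net, X, train = FALSE, dropout_rate = 0.5) {
  cache <- list()
  H <- X
  for (l in seq_along(net$layers)) {
    lay <- net$layers[[l]]
    Z1 <- sweep(H %*% lay$W, 2, lay$b, "+")
    if (net$maxout) {
      Z2 <- sweep(H %*% lay$W2, 2, lay$b2, "+")
      take1 <- Z1 >= Z2
      A <- ifelse(take1, Z1, Z2)
      cache[[l]] <- list(input = H, take1 = take1)
    } else {
      A <- pmax(Z1, 0)
      cache[[l]] <- list(input = H, active = Z1 > 0)
    }
    if (net$dropout && train) {
      mask <- matrix(stats::runif(length(A)) > dropout_rate, nrow(A), ncol(A))
      A <- A * mask / (1 - dropout_rate)
      cache[[l]]$mask <- mask
    }
    H <- A
  }
  z <- as.numeric(H %*% net$w_out) + net$b_out
  p <- 1 / (1 + exp(-z))
  list(p = p, H = H, cache = cache)
}

net_gradients <- function(net, fw, y, dropout_rate = 0.5) {
  n <- length(y)
  grads <- list()
  dz <- matrix((fw$p - y) / n, n, 1)
  grads$w_out <- crossprod(fw$H, dz)
  grads$b_out <- sum(dz)
  dH <- dz %*% t(net$w_out)
  for (l in rev(seq_along(net$layers))) {
    lay <- net$layers[[l]]
    cc <- fw$cache[[l]]
    if (net$dropout && !is.null(cc$mask)) {
      dH <- dH * cc$mask / (1 - dropout_rate)
    }
    g <- list()
    if (net$maxout) {
      d1 <- dH * cc$take1
      d2 <- dH * !cc$take1
      g$W <- crossprod(cc$input, d1)
      g$b <- colSums(d1)
      g$W2 <- crossprod(cc$input, d2)
      g$b2 <- colSums(d2)
      dH <- d1 %*% t(lay$W) + d2 %*% t(lay$W2)
    } else {
      d1 <- dH * cc$active
      g$W <- crossprod(cc$input, d1)
      g$b <- colSums(d1)
      dH <- d1 %*% t(lay$W)
    }
    grads$layers[[l]] <- g
  }
  grads
}

#' Train a feed-forward classifier
#'
#' Small fully connected network with sigmoid output, binary cross-entropy
#' loss and full-batch Adam, seeded for reproducibility. Activations follow
#' the configuration: rectified linear or two-piece maxout, each optionally
#' with inverted dropout (rate 0.5) on hidden activations during training.
#' Training stops early when the loss plateaus. A non-finite loss triggers a
#' reinitialisation with a shifted seed (at most 3 tries).
#'
#' @param X numeric predictor matrix (rows = pen-days), already standardized.
#' @param y 0/1 labels.
#' @param config a [net_config()].
#' @param seed integer seed.
#' @param epochs maximum training epochs.
#' @param lr Adam learning rate.
#' @param l2 weight-decay strength. The training sets are tiny (a few dozen
#'   pen-days), so without a ridge penalty the networks memorize them and
#'   their training-set evaluation degenerates to sensitivity = specificity
#'   = 1, which makes the downstream Bayes fusion all-or-nothing; the
#'   default keeps the training evaluation honest.
#' @return Object of class `mlp` (the trained network).
#' @export
mlp_train <- function(X, y, config, seed, epochs = 300, lr = 0.05,
                      l2 = 0.05) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  for (try in 0:2) {
    net <- withr::with_seed(seed + try * 7919L,
                            train_once(X, y, config, epochs, lr, l2))
    if (is.finite(net$final_loss)) {
      class(net) <- "mlp"
      return(net)
    }
  }
  stop("network training failed to converge after 3 reinitialisations")
}

train_once <- function(X, y, config, epochs, lr, l2) {
  net <- init_net(config, ncol(X))
  ms <- vs <- NULL
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  flat_names <- NULL
  get_params <- function(net) {
    p <- list(w_out = net$w_out, b_out = net$b_out)
    for (l in seq_along(net$layers)) {
      for (nm in names(net$layers[[l]])) {
        p[[paste0("L", l, "_", nm)]] <- net$layers[[l]][[nm]]
      }
    }
    p
  }
  set_params <- function(net, p) {
    net$w_out <- p$w_out; net$b_out <- p$b_out
    for (l in seq_along(net$layers)) {
      for (nm in names(net$layers[[l]])) {
        net$layers[[l]][[nm]] <- p[[paste0("L", l, "_", nm)]]
      }
    }
    net
  }
  grads_flat <- function(g) {
    p <- list(w_out = g$w_out, b_out = g$b_out)
    for (l in seq_along(g$layers)) {
      for (nm in names(g$layers[[l]])) {
        p[[paste0("L", l, "_", nm)]] <- g$layers[[l]][[nm]]
      }
    }
    p
  }
  params <- get_params(net)
  ms <- lapply(params, function(x) x * 0)
  vs <- ms
  best_loss <- Inf
  stall <- 0L
  loss <- NA_real_
  for (ep in seq_len(epochs)) {
    fw <- net_forward(net, X, train = TRUE)
    p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
    loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
    if (!is.finite(loss)) break
    g <- grads_flat(net_gradients(net, fw, y))
    for (nm in names(params)) {
      if (l2 > 0 && !nm %in% c("b_out") && !grepl("_b2?$", nm)) {
        g[[nm]] <- g[[nm]] + l2 * params[[nm]]
      }
      ms[[nm]] <- beta1 * ms[[nm]] + (1 - beta1) * g[[nm]]
      vs[[nm]] <- beta2 * vs[[nm]] + (1 - beta2) * g[[nm]]^2
      mhat <- ms[[nm]] / (1 - beta1^ep)
      vhat <- vs[[nm]] / (1 - beta2^ep)
      params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    net <- set_params(net, params)
    if (loss < best_loss - 1e-6) {
      best_loss <- loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= 30L) break
    }
  }
  net$final_loss <- loss
  net
}

#' Predict event probabilities from a trained network
#'
#' @param net an [mlp_train()] result.
#' @param X standardized predictor matrix.
#' @return Numeric vector of probabilities.
#' @export
mlp_predict <- function(net, X) {
  net_forward(net, as.matrix(X), train = FALSE)$p
}

#' Pen-level probability from daily probabilities
#'
#' A pen's single prediction is the maximum predicted probability across the
#' days included by the alarm type.
#'
#' @param daily_probs numeric vector of daily probabilities (>= 1 value).
#' @return The maximum.
#' @export
pen_probability <- function(daily_probs) {
  daily_probs <- daily_probs[is.finite(daily_probs)]
  if (length(daily_probs) == 0) stop("no daily predictions available")
  max(daily_probs)
}

#' First tail-biting event day per pen
#'
#' @param pens pen metadata data.frame (column `pen_id`).
#' @param events event log data.frame (`pen_id`, `day_index`, `type`).
#' @return Named numeric vector: first `tail_biting` day per pen, `NA` for
#'   pens with no event.
#' @export
first_event_day <- function(pens, events) {
  tb <- events[events$type == "tail_biting", , drop = FALSE]
  first <- tapply(tb$day_index, tb$pen_id, min)
  out <- stats::setNames(rep(NA_real_, nrow(pens)), pens$pen_id)
  out[names(first)] <- first
  out
}

#' Construct the two balanced training pairings
#'
#' Each event pen is matched to one control pen from the same batch with the
#' same straw and space levels and no tail-biting event in the whole period,
#' so each training set is exactly 50/50 event/control. When an event pen
#' has two eligible controls they are split across the two sets; a pen with
#' a single eligible control contributes the same control to both sets
#' (logged); a pen with none is dropped with a warning. The assignment is
#' seed-deterministic.
#'
#' @param pens pen metadata data.frame (`pen_id`, `batch`, `straw`, `space`).
#' @param events event log data.frame.
#' @param seed integer seed.
#' @return List with data.frames `set1` and `set2`, each with columns
#'   `pair_id`, `event_pen`, `control_pen`, `event_day`.
#' @export
make_training_pairs <- function(pens, events, seed) {
  tb_day <- first_event_day(pens, events)
  event_ids <- pens$pen_id[!is.na(tb_day[as.character(pens$pen_id)])]
  if (length(event_ids) == 0) stop("no event pens to pair")
  withr::with_seed(seed, {
    event_ids <- sample(event_ids)
    used <- character(0)
    rows1 <- rows2 <- list()
    for (ep in event_ids) {
      meta <- pens[pens$pen_id == ep, ]
      elig <- pens$pen_id[pens$batch == meta$batch &
                            pens$straw == meta$straw &
                            pens$space == meta$space &
                            is.na(tb_day[as.character(pens$pen_id)]) &
                            !pens$pen_id %in% used]
      if (length(elig) == 0) {
        warning(sprintf("event pen %s has no eligible control; dropped", ep))
        next
      }
      picked <- if (length(elig) >= 2) sample(elig, 2) else {
        message(sprintf(
          "event pen %s has a single eligible control (%s); reused in both sets",
          ep, elig))
        c(elig, elig)
      }
      used <- union(used, picked)
      i <- length(rows1) + 1L
      rows1[[i]] <- data.frame(pair_id = i, event_pen = ep,
                               control_pen = picked[1],
                               event_day = tb_day[[as.character(ep)]])
      rows2[[i]] <- data.frame(pair_id = i, event_pen = ep,
                               control_pen = picked[2],
                               event_day = tb_day[[as.character(ep)]])
    }
    list(set1 = do.call(rbind, rows1), set2 = do.call(rbind, rows2))
  })
}

#' Extract pre-event window features for a pairing set
#'
#' For each pair, takes the event pen's and its control pen's feature
#' vectors on the alarm-type days relative to the event pen's day 0 (the
#' control pen is anchored to the same calendar days as its event pen).
#'
#' @param features feature table (one data source) from
#'   [build_feature_table()].
#' @param pairs one pairing set from [make_training_pairs()].
#' @param alarm_type `"UNTIMED"`, `"BEFORE"` or `"ON"`.
#' @return data.frame with `pair_id`, `pen_id`, `label` (1 = event pen),
#'   `day_rel` and the 12 predictor columns.
#' @export
window_features <- function(features, pairs, alarm_type = "UNTIMED") {
  days <- alarm_days(alarm_type)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- pairs[i, ]
    out <- lapply(c(event = pr$event_pen, control = pr$control_pen),
                  function(pen) {
      d <- features[features$pen_id == pen &
                      features$day_index %in% (pr$event_day + days), ,
                    drop = FALSE]
      if (nrow(d) == 0) return(NULL)
      data.frame(pair_id = pr$pair_id, pen_id = pen,
                 label = as.integer(pen == pr$event_pen),
                 day_rel = d$day_index - pr$event_day,
                 d[predictor_columns()])
    })
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

pen_level_predictions <- function(prob, pen_id) {
  agg <- tapply(prob, pen_id, max)
  data.frame(pen_id = names(agg), prob = as.numeric(agg), row.names = NULL)
}

#' Leave-one-pair-out architecture search
#'
#' For every configuration in the grid, iterates n folds (n = number of
#' pairs), training on all other pairs and predicting the held-out pair's
#' pen-days; each pen's prediction is its maximum daily probability, and
#' cross-validated sensitivity, specificity and accuracy are computed at a
#' 0.5 threshold. The accuracy-maximizing configuration wins; ties go to the
#' configuration with fewer parameters, then grid order. Standardization
#' statistics are recomputed inside each training fold (no leakage).
#'
#' @param wf window feature table from [window_features()] (unstandardized).
#' @param grid list of configurations, e.g. [enumerate_grid()].
#' @param seed integer seed.
#' @param epochs training epochs per fold.
#' @return List with `best_config`, `best_index`, and `metrics` (one row per
#'   configuration: accuracy, sensitivity, specificity, n_params).
#' @export
cv_optimize <- function(wf, grid, seed, epochs = 300) {
  pair_ids <- sort(unique(wf$pair_id))
  if (length(pair_ids) < 3) stop("need at least 3 pairs for cross-validation")
  cols <- predictor_columns()
  metrics <- do.call(rbind, lapply(seq_along(grid), function(g) {
    cfg <- grid[[g]]
    pen_lab <- c(); pen_prob <- c()
    for (i in seq_along(pair_ids)) {
      train <- wf[wf$pair_id != pair_ids[i], ]
      test <- wf[wf$pair_id == pair_ids[i], ]
      stopifnot(length(unique(train$label)) == 2)  # guaranteed by pairing
      st <- feature_stats(train)
      tr <- standardize_features(train, st)
      te <- standardize_features(test, st)
      net <- mlp_train(as.matrix(tr[cols]), tr$label, cfg,
                       seed = seed + g * 1009L + i * 31L, epochs = epochs)
      p <- mlp_predict(net, as.matrix(te[cols]))
      pens <- pen_level_predictions(p, te$pen_id)
      labs <- te$label[match(pens$pen_id, te$pen_id)]
      pen_lab <- c(pen_lab, labs)
      pen_prob <- c(pen_prob, pens$prob)
    }
    alarm <- pen_prob >= 0.5
    cc <- confusion_counts(tp = sum(alarm & pen_lab == 1),
                           tn = sum(!alarm & pen_lab == 0),
                           fp = sum(alarm & pen_lab == 0),
                           fn = sum(!alarm & pen_lab == 1))
    met <- confusion_metrics(cc)
    data.frame(config = g, activation = cfg$activation,
               hidden = paste(cfg$hidden_sizes, collapse = "x"),
               n_params = n_params(cfg), accuracy = met$accuracy,
               sensitivity = met$sensitivity, specificity = met$specificity)
  }))
  ord <- order(-metrics$accuracy, metrics$n_params, metrics$config)
  best <- metrics$config[ord[1]]
  list(best_config = grid[[best]], best_index = best, metrics = metrics)
}

#' Train the two final networks and select training thresholds
#'
#' Trains one network per training pairing set with its cross-validated
#' configuration, then sweeps classification thresholds 0.01..1.00 (step
#' 0.01) on the training pen-level predictions, keeping the
#' accuracy-maximizing threshold with its sensitivity and specificity per
#' set. The ensemble consumes the averages of the two sets' threshold,
#' sensitivity and specificity.
#'
#' @param wf1,wf2 window feature tables for the two pairing sets.
#' @param config1,config2 configurations from [cv_optimize()].
#' @param seed integer seed.
#' @param epochs training epochs.
#' @return Object of class `pen_ann` with the two trained models (each
#'   carrying its own standardization statistics), per-set training
#'   threshold/sensitivity/specificity and their averages.
#' @export
train_final_and_threshold <- function(wf1, wf2, config1, config2, seed,
                                      epochs = 300) {
  cols <- predictor_columns()
  fit_one <- function(wf, cfg, sd_offset) {
    st <- feature_stats(wf)
    tr <- standardize_features(wf, st)
    net <- mlp_train(as.matrix(tr[cols]), tr$label, cfg,
                     seed = seed + sd_offset, epochs = epochs)
    pens <- pen_level_predictions(mlp_predict(net, as.matrix(tr[cols])),
                                  tr$pen_id)
    labs <- tr$label[match(pens$pen_id, tr$pen_id)]
    sweep <- threshold_sweep(pens$prob, labs)
    thr <- best_threshold(sweep, "max_accuracy")
    at <- sweep[sweep$threshold == thr, ]
    list(net = net, config = cfg, stats = st, threshold = thr,
         sensitivity = at$sensitivity, specificity = at$specificity)
  }
  m1 <- fit_one(wf1, config1, 1L)
  m2 <- fit_one(wf2, config2, 2L)
  structure(list(
    models = list(m1, m2),
    threshold = mean(c(m1$threshold, m2$threshold)),
    sensitivity = mean(c(m1$sensitivity, m2$sensitivity)),
    specificity = mean(c(m1$specificity, m2$specificity))
  ), class = "pen_ann")
}

#' @export
print.pen_ann <- function(x, ...) {
  cat(sprintf(
    "pen_ann: two-network average; training threshold %.2f, sens %.3f, spec %.3f\n",
    x$threshold, x$sensitivity, x$specificity))
  invisible(x)
}

#' Daily probabilities from the two-network average
#'
#' At prediction time the two training sets' networks are combined by
#' averaging their predicted probabilities; each network standardizes the
#' incoming features with its own training statistics.
#'
#' @param model a [train_final_and_threshold()] result.
#' @param features feature table rows to score.
#' @return data.frame `pen_id`, `day_index`, `prob`.
#' @export
predict_daily_probabilities <- function(model, features) {
  cols <- predictor_columns()
  probs <- vapply(model$models, function(m) {
    std <- standardize_features(features, m$stats)
    mlp_predict(m$net, as.matrix(std[cols]))
  }, numeric(nrow(features)))
  if (nrow(features) == 1) probs <- matrix(probs, nrow = 1)
  data.frame(pen_id = features$pen_id, day_index = features$day_index,
             prob = rowMeans(probs))
}
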
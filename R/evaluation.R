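#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP %d  TN %d  FP %d  FN %d\n",
              x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, alarm error rate
#' `FP/(TP+FP)` (the fraction of raised alarms that are false) and accuracy
#' `(TP+TN)/total`. A metric whose denominator is zero is reported as `NA`.
#'
#' @param counts a [confusion_counts()].
#' @return List with `sensitivity`, `specificity`, `alarm_error_rate`,
#'   `accuracy`.
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, list(
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    alarm_error_rate = ratio(fp, tp + fp),
    accuracy = ratio(tp + tn, tp + tn + fp + fn)
  ))
}

#' Sweep classification thresholds
#'
#' Classifies `prob >= threshold` as an alarm at each candidate threshold
#' and tabulates the confusion counts and metrics.
#'
#' @param probs predicted probabilities.
#' @param labels 0/1 labels.
#' @param thresholds candidate thresholds (default the 100-value grid
#'   0.01..1.00 by 0.01).
#' @return data.frame with one row per threshold: counts, `sensitivity`,
#'   `specificity`, `accuracy`, `alarm_error_rate` and `sum_sens_spec`.
#' @export
threshold_sweep <- function(probs, labels,
                            thresholds = seq(0.01, 1, by = 0.01)) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  out <- do.call(rbind, lapply(thresholds, function(th) {
    alarm <- probs >= th
    cc <- confusion_counts(tp = sum(alarm & labels == 1),
                           tn = sum(!alarm & labels == 0),
                           fp = sum(alarm & labels == 0),
                           fn = sum(!alarm & labels == 1))
    met <- confusion_metrics(cc)
    data.frame(threshold = th, tp = cc$tp, tn = cc$tn, fp = cc$fp,
               fn = cc$fn, sensitivity = met$sensitivity,
               specificity = met$specificity, accuracy = met$accuracy,
               alarm_error_rate = met$alarm_error_rate)
  }))
  out$sum_sens_spec <- out$sensitivity + out$specificity
  out
}

#' Pick the best threshold from a sweep
#'
#' `max_accuracy` is used during training-set optimisation,
#' `max_sens_plus_spec` during test-set evaluation. Ties go to the smallest
#' (most sensitive) threshold.
#'
#' @param sweep a [threshold_sweep()] result (or any data.frame with a
#'   `threshold` column and the criterion column).
#' @param criterion `"max_accuracy"` or `"max_sens_plus_spec"`.
#' @return The selected threshold.
#' @export
best_threshold <- function(sweep,
                           criterion = c("max_accuracy",
                                         "max_sens_plus_spec")) {
  criterion <- match.arg(criterion)
  if (nrow(sweep) == 0) stop("empty threshold sweep")
  score <- switch(criterion,
                  max_accuracy = sweep$accuracy,
                  max_sens_plus_spec = sweep$sensitivity + sweep$specificity)
  score[!is.finite(score)] <- -Inf
  cand <- sweep$threshold[score == max(score)]
  min(cand)
}

#' Hanley-McNeil confidence interval for an AUC
#'
#' Standard error of the AUC from the point estimate and the class sizes:
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`,
#' `SE = sqrt((A(1-A) + (N1-1)(Q1-A^2) + (N2-1)(Q2-A^2)) / (N1*N2))`,
#' interval `A +/- z*SE` clipped to [0, 1] (z = 1.96 for the default 95%
#' level). The model beats random guessing when the interval excludes 0.5.
#'
#' @param auc AUC point estimate in [0, 1].
#' @param n_pos number of positives (events).
#' @param n_neg number of negatives (controls or no-event days).
#' @param z normal quantile (default exactly 1.96).
#' @return Named numeric vector `lower`, `upper`, with the standard error as
#'   attribute `"se"`.
#' @export
auc_confidence_interval <- function(auc, n_pos, n_neg, z = 1.96) {
  stopifnot(auc >= 0, auc <= 1, n_pos >= 1, n_neg >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  out <- c(lower = max(0, auc - z * se), upper = min(1, auc + z * se))
  attr(out, "se") <- se
  out
}

#' ROC curve and AUC from a threshold sweep
#'
#' Builds the ROC curve by varying the classification threshold over the
#' 100-value grid, appends the (0,0) and (1,1) endpoints and integrates by
#' trapezoids; the 95% CI comes from [auc_confidence_interval()].
#'
#' @param probs predicted probabilities.
#' @param labels 0/1 labels (both classes must be present).
#' @param thresholds threshold grid.
#' @return Object of class `roc_result`: `sweep`, `points` (fpr/tpr), `auc`,
#'   `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(probs, labels, thresholds = seq(0.01, 1, by = 0.01)) {
  if (length(unique(labels)) < 2) {
    stop("both classes must be present to compute a ROC curve")
  }
  sweep <- threshold_sweep(probs, labels, thresholds)
  pts <- data.frame(fpr = c(0, 1 - sweep$specificity, 1),
                    tpr = c(0, sweep$sensitivity, 1))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  ci <- auc_confidence_interval(auc, n_pos, n_neg)
  structure(list(sweep = sweep, points = pts, auc = auc,
                 ci_low = ci[["lower"]], ci_high = ci[["upper"]],
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f), %d positives / %d negatives\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' Pair event pens with 4-5 controls each for test-set evaluation
#'
#' Test-set pairing is deliberately imbalanced (bias is not a concern at
#' evaluation time): each event pen gets four or five eligible controls,
#' depending on availability, honouring the same-batch / same-straw /
#' same-space / no-event constraints; accuracy is therefore not a usable
#' metric on these rosters. Controls are not reused unless forced; an event
#' pen with fewer than four eligible controls keeps all available (logged).
#'
#' @param pens pen metadata data.frame.
#' @param events event log data.frame.
#' @param seed integer seed.
#' @param n_controls target controls per event pen (default 4:5).
#' @return data.frame with `event_pen`, `control_pen`, `event_day`.
#' @export
pair_for_testing <- function(pens, events, seed, n_controls = 4:5) {
  tb_day <- first_event_day(pens, events)
  event_ids <- pens$pen_id[!is.na(tb_day[as.character(pens$pen_id)])]
  if (length(event_ids) == 0) stop("no event pens to pair")
  withr::with_seed(seed, {
    event_ids <- sample(event_ids)
    used <- character(0)
    rows <- list()
    for (ep in event_ids) {
      meta <- pens[pens$pen_id == ep, ]
      elig <- pens$pen_id[pens$batch == meta$batch &
                            pens$straw == meta$straw &
                            pens$space == meta$space &
                            is.na(tb_day[as.character(pens$pen_id)])]
      fresh <- setdiff(elig, used)
      want <- max(n_controls)
      take <- if (length(fresh) >= want) sample(fresh, want) else fresh
      if (length(take) < min(n_controls) &&
          length(elig) > length(take)) {
        extra <- sample(setdiff(elig, take),
                        min(min(n_controls) - length(take),
                            length(elig) - length(take)))
        take <- c(take, extra)  # reuse only when forced
      }
      if (length(take) < min(n_controls)) {
        message(sprintf("event pen %s has only %d eligible control(s)",
                        ep, length(take)))
      }
      if (length(take) == 0) next
      used <- union(used, take)
      rows[[length(rows) + 1]] <-
        data.frame(event_pen = ep, control_pen = take,
                   event_day = tb_day[[as.character(ep)]])
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Day-level real-life evaluation with 3-day alarm clustering
#'
#' Implements the day-level protocol: alarms are clustered over the 3 days
#' before each first tail-biting event (days -3..-1). An alarm on any window
#' day counts as one true positive per event; no alarm on any window day is
#' one false negative. Every non-window pen-day with an alarm is one false
#' positive, without an alarm one true negative (so the event day itself and
#' the day after count as false positives when alarmed; they are also
#' tallied separately, as are alarms in fouling and diarrhoea pre-event
#' windows, for reporting).
#'
#' @param posteriors data.frame `pen_id`, `day_index`, `posterior`, one row
#'   per scored pen-day.
#' @param events event log data.frame (`pen_id`, `day_index`, `type`).
#' @param threshold classification threshold (alarm when
#'   `posterior >= threshold`).
#' @return List with `counts` ([confusion_counts()]), `metrics`, and
#'   `tallies`, a data.frame of alarmed/total by day type (`no_event_day`,
#'   `tb_window`, `tb_day0`, `tb_day_plus1`, `fouling_window`,
#'   `diarrhoea_window`).
#' @export
realtime_evaluate <- function(posteriors, events, threshold) {
  stopifnot(all(c("pen_id", "day_index", "posterior") %in% names(posteriors)))
  alarm <- posteriors$posterior >= threshold
  key <- paste(posteriors$pen_id, posteriors$day_index)

  tb <- events[events$type == "tail_biting", , drop = FALSE]
  tb_first <- tapply(tb$day_index, tb$pen_id, min)

  window_keys <- character(0)
  day0_keys <- character(0)
  day1_keys <- character(0)
  tp <- fn <- 0L
  for (pen in names(tb_first)) {
    d0 <- tb_first[[pen]]
    wk <- paste(pen, (d0 - 3):(d0 - 1))
    window_keys <- c(window_keys, wk)
    day0_keys <- c(day0_keys, paste(pen, d0))
    day1_keys <- c(day1_keys, paste(pen, d0 + 1))
    present <- key %in% wk
    if (!any(present)) next  # event without any scored window day: skipped
    if (any(alarm[present])) tp <- tp + 1L else fn <- fn + 1L
  }

  in_window <- key %in% window_keys
  non_window <- !in_window
  fp <- sum(alarm & non_window)
  tn <- sum(!alarm & non_window)
  counts <- confusion_counts(tp = tp, tn = tn, fp = fp, fn = fn)

  is_day0 <- key %in% day0_keys
  is_day1 <- key %in% day1_keys
  plain <- non_window & !is_day0 & !is_day1

  event_window_tally <- function(type) {
    ev <- events[events$type == type, , drop = FALSE]
    if (nrow(ev) == 0) return(c(0L, 0L))
    hit <- 0L; total <- 0L
    for (i in seq_len(nrow(ev))) {
      wk <- paste(ev$pen_id[i], (ev$day_index[i] - 3):(ev$day_index[i] - 1))
      present <- key %in% wk
      if (!any(present)) next
      total <- total + 1L
      if (any(alarm[present])) hit <- hit + 1L
    }
    c(hit, total)
  }
  fl <- event_window_tally("fouling")
  di <- event_window_tally("diarrhoea")

  tallies <- data.frame(
    day_type = c("no_event_day", "tb_window", "tb_day0", "tb_day_plus1",
                 "fouling_window", "diarrhoea_window"),
    alarmed = c(sum(alarm & plain), tp, sum(alarm & is_day0),
                sum(alarm & is_day1), fl[1], di[1]),
    total = c(sum(plain), tp + fn, sum(is_day0), sum(is_day1), fl[2], di[2])
  )
  list(counts = counts, metrics = confusion_metrics(counts),
       tallies = tallies)
}

#' Real-life ROC over the threshold grid
#'
#' Applies [realtime_evaluate()] at each threshold of the 0.01..1.00 grid,
#' builds the ROC curve (with endpoints) and the Hanley-McNeil CI, using the
#' number of events as N1 and the number of non-window pen-days as N2.
#'
#' @inheritParams realtime_evaluate
#' @param thresholds threshold grid.
#' @return Object of class `roc_result` (with the day-level sweep in
#'   `sweep`), plus `best_threshold` chosen by highest sensitivity +
#'   specificity.
#' @export
realtime_roc <- function(posteriors, events, thresholds = seq(0.01, 1, 0.01)) {
  sweep <- do.call(rbind, lapply(thresholds, function(th) {
    r <- realtime_evaluate(posteriors, events, th)
    data.frame(threshold = th, tp = r$counts$tp, tn = r$counts$tn,
               fp = r$counts$fp, fn = r$counts$fn,
               sensitivity = r$metrics$sensitivity,
               specificity = r$metrics$specificity,
               alarm_error_rate = r$metrics$alarm_error_rate,
               accuracy = r$metrics$accuracy)
  }))
  sweep$sum_sens_spec <- sweep$sensitivity + sweep$specificity
  pts <- data.frame(fpr = c(0, 1 - sweep$specificity, 1),
                    tpr = c(0, sweep$sensitivity, 1))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  n_pos <- sweep$tp[1] + sweep$fn[1]
  n_neg <- sweep$tn[1] + sweep$fp[1]
  ci <- auc_confidence_interval(auc, n_pos, n_neg)
  structure(list(sweep = sweep, points = pts, auc = auc,
                 ci_low = ci[["lower"]], ci_high = ci[["upper"]],
                 n_pos = n_pos, n_neg = n_neg,
                 best_threshold = best_threshold(sweep,
                                                 "max_sens_plus_spec")),
            class = "roc_result")
}
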
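test_that("confusion metrics are the stated ratios", {
  # all events caught: sensitivity 1
  m <- confusion_metrics(confusion_counts(tp = 14, tn = 1086, fp = 937,
                                          fn = 0))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1086 / 2023)
  m2 <- confusion_metrics(confusion_counts(1, 1, 1, 1))
  expect_true(all(unlist(m2) == 0.5))
  # zero denominators are reported as NA, not errors
  m3 <- confusion_metrics(confusion_counts(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_true(is.na(m3$sensitivity) && is.na(m3$alarm_error_rate))
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
  # brute-force oracle over random prediction sets
  withr::with_seed(23, {
    for (i in 1:10) {
      lab <- rbinom(30, 1, 0.4)
      pred <- rbinom(30, 1, 0.5)
      cc <- confusion_counts(tp = sum(pred & lab), tn = sum(!pred & !lab),
                             fp = sum(pred & !lab), fn = sum(!pred & lab))
      met <- confusion_metrics(cc)
      if (sum(lab) > 0) {
        expect_equal(met$sensitivity, mean(pred[lab == 1]))
      }
      if (sum(!lab) > 0) {
        expect_equal(met$specificity, mean(1 - pred[lab == 0]))
      }
      expect_equal(met$accuracy, mean(pred == lab))
    }
  })
})

test_that("ROC/AUC agrees with the Mann-Whitney oracle", {
  # perfectly separated scores
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  # identical scores for everything: the diagonal
  r0 <- roc_auc(rep(0.4, 20), rep(c(0, 1), 10))
  expect_equal(r0$auc, 0.5, tolerance = 1e-12)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
  # random scores: trapezoid AUC within grid error of the U statistic
  withr::with_seed(31, {
    for (i in 1:5) {
      probs <- runif(80)
      labs <- rbinom(80, 1, 0.4)
      if (length(unique(labs)) < 2) next
      r <- roc_auc(probs, labs)
      pos <- probs[labs == 1]; neg <- probs[labs == 0]
      u_auc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
      expect_equal(r$auc, u_auc, tolerance = 0.02)
    }
  })
  # label-shuffled scores hover around 0.5
  withr::with_seed(32, {
    probs <- runif(400)
    labs <- sample(rep(c(0, 1), 200))
  })
  expect_lt(abs(roc_auc(probs, labs)$auc - 0.5), 0.08)
})

test_that("AUC confidence interval is clipped, ordered and symmetric", {
  ci <- auc_confidence_interval(0.5, 1, 1)
  expect_equal(ci[["upper"]] - 0.5, 0.5 - ci[["lower"]], tolerance = 1e-12)
  ci2 <- auc_confidence_interval(0.99, 5, 5)
  expect_lte(ci2[["upper"]], 1)
  expect_true(ci2[["lower"]] <= 0.99 && 0.99 <= ci2[["upper"]])
  expect_error(auc_confidence_interval(1.2, 5, 5))
})

test_that("best threshold follows the criterion with smallest-tie rule", {
  sw <- data.frame(threshold = c(0.2, 0.4, 0.6),
                   accuracy = c(0.7, 0.9, 0.9),
                   sensitivity = c(1, 0.8, 0.2),
                   specificity = c(0.2, 0.8, 1))
  expect_equal(best_threshold(sw, "max_accuracy"), 0.4)  # tie -> smaller
  expect_equal(best_threshold(sw, "max_sens_plus_spec"), 0.4)
  expect_equal(best_threshold(sw[2, ], "max_accuracy"), 0.4)
  expect_error(best_threshold(sw[0, ], "max_accuracy"), "empty")
  # exhaustive scan oracle on random sweeps
  withr::with_seed(44, {
    for (i in 1:10) {
      probs <- runif(40)
      labs <- rbinom(40, 1, 0.5)
      sw <- threshold_sweep(probs, labs)
      got <- best_threshold(sw, "max_sens_plus_spec")
      s <- sw$sensitivity + sw$specificity
      expect_equal(got, min(sw$threshold[s == max(s)]))
    }
  })
})

test_that("test-set pairing assigns 4-5 controls under the constraints", {
  pens <- rbind(toy_pens(15, batch = 4),
                toy_pens(8, batch = 4, straw = "no", prefix = "s"))
  events <- toy_events(c(pens$pen_id[1], pens$pen_id[16]), c(20, 30))
  roster <- pair_for_testing(pens, events, seed = 2)
  by_event <- split(roster$control_pen, roster$event_pen)
  # the straw=yes event pen has 14 candidates -> gets 5
  expect_equal(length(by_event[[pens$pen_id[1]]]), 5)
  # the straw=no event pen has 7 candidates -> still gets 5
  expect_equal(length(by_event[[pens$pen_id[16]]]), 5)
  # eligibility honours the treatment match
  expect_true(all(pens$straw[match(by_event[[pens$pen_id[16]]],
                                   pens$pen_id)] == "no"))
  # no event pen is used as a control
  expect_false(any(roster$control_pen %in% roster$event_pen))
  # scarce controls: keep all available, logged
  pens2 <- toy_pens(3)
  ev2 <- toy_events(pens2$pen_id[1], 10)
  expect_message(roster2 <- pair_for_testing(pens2, ev2, seed = 1),
                 "eligible control")
  expect_equal(nrow(roster2), 2)
})

test_that("day-level protocol clusters alarms over the 3-day window", {
  # one pen, event on day 10; posteriors on days 1..12
  mk_post <- function(alarm_days_on) {
    data.frame(pen_id = "a", day_index = 1:12,
               posterior = ifelse(1:12 %in% alarm_days_on, 0.9, 0.1))
  }
  events <- toy_events("a", 10)
  # alarms on days -3 and -1: exactly one TP, no window FP
  r <- realtime_evaluate(mk_post(c(7, 9)), events, threshold = 0.5)
  expect_equal(r$counts$tp, 1)
  expect_equal(r$counts$fn, 0)
  expect_equal(r$counts$fp, 0)
  expect_equal(r$counts$tn, 9)  # 12 days - 3 window days
  # alarm only on day 0: one FN plus one FP (day 0 is not in the window)
  r2 <- realtime_evaluate(mk_post(10), events, threshold = 0.5)
  expect_equal(r2$counts$tp, 0)
  expect_equal(r2$counts$fn, 1)
  expect_equal(r2$counts$fp, 1)
  d0 <- r2$tallies[r2$tallies$day_type == "tb_day0", ]
  expect_equal(d0$alarmed, 1)
  # invariants: TP+FN = events, TN+FP = non-window days
  for (r_ in list(r, r2)) {
    expect_equal(r_$counts$tp + r_$counts$fn, 1)
    expect_equal(r_$counts$tn + r_$counts$fp, 9)
  }
  # day +1 and plain no-event tallies are separated
  r3 <- realtime_evaluate(mk_post(c(8, 11)), events, threshold = 0.5)
  t3 <- r3$tallies
  expect_equal(t3$alarmed[t3$day_type == "tb_day_plus1"], 1)
  expect_equal(t3$total[t3$day_type == "no_event_day"], 7)
  # fouling pre-event windows are tallied for reporting
  ev2 <- rbind(events, toy_events("a", 5, type = "fouling"))
  r4 <- realtime_evaluate(mk_post(c(2, 7)), ev2, threshold = 0.5)
  fl <- r4$tallies[r4$tallies$day_type == "fouling_window", ]
  expect_equal(fl$alarmed, 1)
  expect_equal(fl$total, 1)
})

test_that("real-life ROC integrates the day-level sweep", {
  withr::with_seed(61, {
    post <- data.frame(pen_id = rep(c("a", "b", "c"), each = 20),
                       day_index = rep(1:20, 3), posterior = runif(60))
  })
  post$posterior[post$pen_id == "a" & post$day_index %in% 7:9] <- 0.95
  events <- toy_events("a", 10)
  roc <- realtime_roc(post, events)
  expect_true(roc$auc >= 0 && roc$auc <= 1)
  expect_equal(roc$n_pos, 1)
  expect_equal(roc$n_neg, 57)
  expect_true(roc$ci_low <= roc$auc && roc$auc <= roc$ci_high)
  expect_true(roc$best_threshold %in% seq(0.01, 1, 0.01))
})
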
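#' One row per pen-week with a tail-biting indicator
#'
#' Maps event days to study weeks (days 1-7 are week 1, so week =
#' `ceiling(day/7)`) and emits one observation per pen per week indicating
#' whether the pen had a tail-biting event within that week. Pens keep
#' contributing rows after their first event (daily recording continues for
#' the whole period).
#'
#' @param pens pen metadata data.frame (`pen_id`, `tail`, `straw`, `space`).
#' @param events event log data.frame (`pen_id`, `day_index`, `type`).
#' @param weeks number of study weeks (default 10).
#' @return data.frame with columns `pen_id`, `week`, `tail`, `straw`,
#'   `space`, `event` (0/1).
#' @export
build_pen_week_table <- function(pens, events, weeks = 10) {
  tb <- events[events$type == "tail_biting", , drop = FALSE]
  tb_weeks <- unique(data.frame(pen_id = tb$pen_id,
                                week = ceiling(tb$day_index / 7)))
  out <- merge(
    pens[c("pen_id", "tail", "straw", "space")],
    data.frame(week = seq_len(weeks))
  )
  hit <- paste(out$pen_id, out$week) %in% paste(tb_weeks$pen_id,
                                                tb_weeks$week)
  out$event <- as.integer(hit)
  out <- out[order(out$pen_id, out$week), ]
  rownames(out) <- NULL
  out
}

#' Fit the fixed-probability logistic model
#'
#' Main-effects logistic regression of the weekly tail-biting indicator on
#' the three pen treatments (tail docking, straw provision, space allowance)
#' and the study week as a categorical factor. With no interactions, the
#' predicted probabilities are additive on the log-odds scale across the
#' treatments within any week.
#'
#' @param table pen-week table from [build_pen_week_table()].
#' @return Object of class `fixed_probability`: the `glm` fit plus the
#'   predicted probability for every treatment-combination x week cell.
#' @export
fit_fixed_model <- function(table) {
  if (sum(table$event) < 1) stop("no events in the pen-week table")
  fit <- stats::glm(event ~ tail + straw + space + factor(week),
                    data = table, family = stats::binomial())
  mu <- stats::fitted(fit)
  if (any(mu > 1 - 1e-8) || any(mu < 1e-8)) {
    stop(paste("complete separation in the fixed-probability fit;",
               "enlarge the synthetic sample"))
  }
  grid <- expand.grid(tail = unique(table$tail),
                      straw = unique(table$straw),
                      space = unique(table$space),
                      week = sort(unique(table$week)),
                      stringsAsFactors = FALSE)
  grid$probability <- stats::predict(fit, grid, type = "response")
  structure(list(fit = fit, probabilities = grid),
            class = "fixed_probability")
}

#' @export
print.fixed_probability <- function(x, ...) {
  cat("fixed_probability: weekly tail-biting risk ~ tail + straw + space + week\n")
  print(utils::head(x$probabilities))
  invisible(x)
}

#' Weekly probability for given pens and weeks
#'
#' @param model a [fit_fixed_model()] result.
#' @param pens pen metadata data.frame.
#' @param weeks weeks to predict (default all fitted weeks).
#' @return data.frame `pen_id`, `week`, `probability`.
#' @export
predict_weekly_probabilities <- function(model, pens,
                                         weeks = sort(unique(
                                           model$probabilities$week))) {
  newdata <- merge(pens[c("pen_id", "tail", "straw", "space")],
                   data.frame(week = weeks))
  newdata$probability <- stats::predict(model$fit, newdata,
                                        type = "response")
  out <- newdata[order(newdata$pen_id, newdata$week),
                 c("pen_id", "week", "probability")]
  rownames(out) <- NULL
  out
}

#' Reconstruct a probability cell by logit additivity
#'
#' Under a main-effects logistic model, a cell that differs from a base cell
#' in two factors is recoverable from three same-week cells:
#' `logit(p) = logit(p_change1) + logit(p_change2) - logit(p_base)`, where
#' `p_change1`/`p_change2` each flip one of the two factors relative to the
#' base.
#'
#' @param p_base probability of the base cell.
#' @param p_change1,p_change2 probabilities of the two single-flip cells.
#' @return The reconstructed probability.
#' @export
logit_additive_reconstruction <- function(p_base, p_change1, p_change2) {
  stats::plogis(stats::qlogis(p_change1) + stats::qlogis(p_change2) -
                  stats::qlogis(p_base))
}

#' Week-banded classification threshold search
#'
#' Training-data threshold optimisation for the fixed-probability model,
#' with separate accuracy-maximizing thresholds for weeks 1-6 (grid
#' 0.01..1.00 by 0.01, 100 values) and weeks 7-10 (grid 0.001..0.010 by
#' 0.0001, 91 values), reflecting the drop in weekly risk late in the study.
#' Sensitivity and specificity are then pooled over all 10 weeks at the
#' band-specific thresholds, for use in the Bayesian ensemble.
#'
#' @param probabilities predicted weekly probabilities.
#' @param labels 0/1 weekly event indicators.
#' @param weeks week of each observation.
#' @return List with `threshold_w1_6`, `threshold_w7_10`, pooled
#'   `sensitivity` and `specificity`, and the two band sweeps.
#' @export
weekbanded_threshold_search <- function(probabilities, labels, weeks) {
  stopifnot(length(probabilities) == length(labels),
            length(labels) == length(weeks))
  bands <- list(
    w1_6 = list(idx = weeks <= 6, grid = seq(0.01, 1, by = 0.01)),
    w7_10 = list(idx = weeks >= 7, grid = seq(0.001, 0.01, by = 0.0001))
  )
  pick <- lapply(bands, function(b) {
    if (!any(b$idx)) return(list(threshold = max(b$grid), sweep = NULL))
    if (sum(labels[b$idx]) == 0) {
      message("week band with no events; threshold set to the band maximum")
      return(list(threshold = max(b$grid), sweep = NULL))
    }
    sw <- threshold_sweep(probabilities[b$idx], labels[b$idx], b$grid)
    list(threshold = best_threshold(sw, "max_accuracy"), sweep = sw)
  })
  alarm <- ifelse(weeks <= 6,
                  probabilities >= pick$w1_6$threshold,
                  probabilities >= pick$w7_10$threshold)
  cc <- confusion_counts(tp = sum(alarm & labels == 1),
                         tn = sum(!alarm & labels == 0),
                         fp = sum(alarm & labels == 0),
                         fn = sum(!alarm & labels == 1))
  met <- confusion_metrics(cc)
  list(threshold_w1_6 = pick$w1_6$threshold,
       threshold_w7_10 = pick$w7_10$threshold,
       sensitivity = met$sensitivity, specificity = met$specificity,
       sweep_w1_6 = pick$w1_6$sweep, sweep_w7_10 = pick$w7_10$sweep)
}
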
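#' Alarm source for the Bayesian ensemble
#'
#' A non-first ensemble member contributes a binary alarm (its probability
#' thresholded at its training-derived threshold) weighted by its training
#' sensitivity and specificity: `P(+|TB) = sens`, `P(-|TB) = 1 - sens`,
#' `P(+|NoTB) = 1 - spec`, `P(-|NoTB) = spec`. The threshold, sensitivity
#' and specificity are the averages over the two training sets.
#'
#' @param name member name.
#' @param threshold classification threshold.
#' @param sensitivity,specificity training performance in [0, 1].
#' @return Object of class `alarm_source`.
#' @export
alarm_source <- function(name, threshold, sensitivity, specificity) {
  vals <- c(sensitivity = sensitivity, specificity = specificity)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("sensitivity and specificity must lie in [0, 1]")
  }
  structure(list(name = name, threshold = threshold,
                 sensitivity = sensitivity, specificity = specificity),
            class = "alarm_source")
}

#' One Bayes update of the tail-biting probability
#'
#' Posterior after observing member's alarm state:
#' alarm raised: `P(TB|+) = sens*p / (sens*p + (1-spec)*(1-p))`;
#' no alarm: `P(TB|-) = (1-sens)*p / ((1-sens)*p + spec*(1-p))`.
#' A degenerate 0/0 denominator (perfect member contradicted by the
#' evidence) returns the prior, with a message. Vectorized over `prior` and
#' `alarm`.
#'
#' @param prior prior probability of a tail-biting event, in [0, 1].
#' @param alarm logical (TRUE = alarm raised) or `"+"`/`"-"`.
#' @param sensitivity,specificity the member's training sensitivity and
#'   specificity.
#' @return Posterior probability.
#' @export
bayes_update <- function(prior, alarm, sensitivity, specificity) {
  if (is.character(alarm)) alarm <- alarm == "+"
  vals <- c(prior, sensitivity, specificity)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("prior, sensitivity and specificity must lie in [0, 1]")
  }
  p_pos <- sensitivity * prior /
    (sensitivity * prior + (1 - specificity) * (1 - prior))
  p_neg <- (1 - sensitivity) * prior /
    ((1 - sensitivity) * prior + specificity * (1 - prior))
  out <- ifelse(alarm, p_pos, p_neg)
  bad <- !is.finite(out)
  if (any(bad)) {
    message("degenerate 0/0 Bayes update; returning the prior")
    out[bad] <- prior[bad]
  }
  out
}

#' Run a Bayesian ensemble for one pen (or vector of pens)
#'
#' The first member's predicted probability is the prior; each subsequent
#' member contributes its binary alarm through [bayes_update()] in listed
#' order. For a fixed prior the final posterior is invariant to the order of
#' the remaining members; the choice of which member supplies the prior,
#' however, matters.
#'
#' @param prior prior probability (first member's output).
#' @param members list of [alarm_source()] objects (the non-first members).
#' @param probs named list or data.frame of the members' predicted
#'   probabilities (matched to members by name), each the same length as
#'   `prior`.
#' @return Posterior probability vector.
#' @export
run_ensemble <- function(prior, members, probs) {
  posterior <- prior
  for (m in members) {
    p <- probs[[m$name]]
    if (is.null(p)) stop("missing member output: ", m$name)
    posterior <- bayes_update(posterior, p >= m$threshold,
                              m$sensitivity, m$specificity)
  }
  posterior
}

#' Daily ensemble posteriors over all pens and days
#'
#' Real-time scoring for the UNTIMED alarm type: for every scored pen-day,
#' the first member's daily probability is the prior and every other member
#' updates it with its thresholded alarm. The fixed-probability member, when
#' present, contributes the pen's current-week probability. Pen-days missing
#' any member's output are skipped (logged).
#'
#' @param daily data.frame with `pen_id`, `day_index` and one probability
#'   column per member name.
#' @param prior_member name of the member supplying the prior.
#' @param members list of [alarm_source()] for the remaining members, in
#'   update order.
#' @return data.frame `pen_id`, `day_index`, `posterior`.
#' @export
realtime_daily_probabilities <- function(daily, prior_member, members) {
  needed <- c(prior_member, vapply(members, `[[`, "", "name"))
  missing_cols <- setdiff(needed, names(daily))
  if (length(missing_cols) > 0) {
    stop("missing member column(s): ", paste(missing_cols, collapse = ", "))
  }
  ok <- stats::complete.cases(daily[needed])
  if (any(!ok)) {
    message(sprintf("%d pen-day(s) missing a member output; skipped",
                    sum(!ok)))
    daily <- daily[ok, , drop = FALSE]
  }
  posterior <- run_ensemble(daily[[prior_member]], members,
                            daily[needed[-1]])
  data.frame(pen_id = daily$pen_id, day_index = daily$day_index,
             posterior = posterior)
}
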
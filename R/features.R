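SOURCES <- c("water_flow", "activation_freq", "temp_solid", "temp_slatted")
WATER_SOURCES <- c("water_flow", "activation_freq")

#' Hourly series for one pen and one data source
#'
#' @param pen_id pen identifier.
#' @param source one of `"water_flow"`, `"activation_freq"`, `"temp_solid"`,
#'   `"temp_slatted"`.
#' @param values numeric hourly values; length must be a multiple of 24.
#' @return Object of class `hourly_series` with fields `pen_id`, `source`,
#'   `values`, `observed_mask` (FALSE wherever the value is missing).
#' @export
hourly_series <- function(pen_id, source, values) {
  source <- match.arg(source, SOURCES)
  values <- as.numeric(values)
  if (length(values) %% 24 != 0) {
    stop("hourly series length must be a whole number of 24-hour days")
  }
  structure(list(pen_id = pen_id, source = source, values = values,
                 observed_mask = is.finite(values)),
            class = "hourly_series")
}

#' @export
print.hourly_series <- function(x, ...) {
  cat(sprintf("hourly_series: pen %s, %s, %d days (%d missing hours)\n",
              x$pen_id, x$source, length(x$values) / 24,
              sum(!x$observed_mask)))
  invisible(x)
}

#' Square-root transform water-usage streams
#'
#' Water flow and activation frequency are square-root transformed before
#' modelling so that their noise is closer to Gaussian; temperature streams
#' pass through unchanged.
#'
#' @param series an [hourly_series()].
#' @return The transformed `hourly_series`.
#' @export
sqrt_transform <- function(series) {
  stopifnot(inherits(series, "hourly_series"))
  if (!series$source %in% WATER_SOURCES) return(series)
  bad <- which(is.finite(series$values) & series$values < 0)
  if (length(bad) > 0) {
    stop(sprintf("negative %s values for pen %s at hours: %s",
                 series$source, series$pen_id,
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  series$values <- sqrt(series$values)
  series
}

#' Aggregate raw sensor records to pen-hour streams
#'
#' Water flow and activation frequency are summed over the pen's two drinker
#' sensors; the two temperature positions (above the solid and the slatted
#' floor) are kept separate, each averaged over its within-hour recordings.
#' Every pen therefore yields four hourly streams.
#'
#' @param records data.frame with columns `pen_id`, `source`, `sensor_id`,
#'   `hour` (1-based hour index) and `value`.
#' @return data.frame with columns `pen_id`, `source`, `hour`, `value`, one
#'   row per pen-hour-source.
#' @export
aggregate_pen_hour <- function(records) {
  stopifnot(all(c("pen_id", "source", "sensor_id", "hour", "value") %in%
                  names(records)))
  bad <- setdiff(unique(records$source), SOURCES)
  if (length(bad) > 0) {
    stop("unknown sensor source tag(s): ", paste(bad, collapse = ", "))
  }
  agg_one <- function(d, fun) {
    out <- stats::aggregate(value ~ pen_id + source + hour, data = d,
                            FUN = fun, na.action = stats::na.omit)
    out[order(out$pen_id, out$source, out$hour), ]
  }
  water <- records[records$source %in% WATER_SOURCES, , drop = FALSE]
  temp <- records[!records$source %in% WATER_SOURCES, , drop = FALSE]
  out <- rbind(
    if (nrow(water) > 0) agg_one(water, sum) else NULL,
    if (nrow(temp) > 0) agg_one(temp, mean) else NULL
  )
  rownames(out) <- NULL
  out
}

six_summaries <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(rep(NA_real_, 6))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(min(x), q[1], mean(x), q[2], q[3], max(x))
}

SUMMARY_NAMES <- c("min", "q1", "mean", "median", "q3", "max")
RAW_COLS <- paste0("raw_", SUMMARY_NAMES)
ERR_COLS <- paste0("err_", SUMMARY_NAMES)

#' Predictor column names of the daily feature vector
#'
#' @return Character vector of the 12 predictor columns: six order/location
#'   statistics (min, Q1, mean, median, Q3, max) of the raw values and the
#'   same six of the standardized forecast errors.
#' @export
predictor_columns <- function() c(RAW_COLS, ERR_COLS)

#' Daily feature vector for one pen-day-source
#'
#' Computes the six order/location statistics (min, Q1, mean, median, Q3,
#' max) of one day's raw values and of the day's standardized forecast
#' errors, skipping missing hours. A day with no observed hour yields `NA`
#' for all twelve entries (excluded downstream). Since the whole day is
#' needed, a vector (and hence a potential alarm) only becomes available at
#' the midnight ending the day.
#'
#' @param raw_values numeric vector of the day's raw values.
#' @param errors numeric vector of the day's standardized forecast errors.
#' @return Named numeric vector of length 12 (`raw_min` ... `err_max`).
#' @export
daily_summaries <- function(raw_values, errors) {
  out <- c(six_summaries(raw_values), six_summaries(errors))
  names(out) <- predictor_columns()
  out
}

#' Build the per pen-day-source feature table
#'
#' @param hourly data.frame with columns `pen_id`, `source`, `day_index`,
#'   `value` (raw) and `u` (standardized forecast error), one row per
#'   pen-hour-source.
#' @return data.frame with key columns `pen_id`, `source`, `day_index` and
#'   the 12 predictor columns; all-missing pen-days are dropped.
#' @export
build_feature_table <- function(hourly) {
  stopifnot(all(c("pen_id", "source", "day_index", "value", "u") %in%
                  names(hourly)))
  keys <- unique(hourly[c("pen_id", "source", "day_index")])
  split_idx <- split(seq_len(nrow(hourly)),
                     interaction(hourly$pen_id, hourly$source,
                                 hourly$day_index, drop = TRUE))
  rows <- lapply(split_idx, function(idx) {
    d <- hourly[idx, ]
    feats <- daily_summaries(d$value, d$u)
    cbind(d[1, c("pen_id", "source", "day_index")], as.data.frame(t(feats)))
  })
  out <- do.call(rbind, rows)
  out <- out[stats::complete.cases(out[predictor_columns()]), , drop = FALSE]
  out <- out[order(out$pen_id, out$source, out$day_index), ]
  rownames(out) <- NULL
  out
}

#' Training-set standardization statistics for feature columns
#'
#' @param features feature table from [build_feature_table()] (training pens
#'   only, one data source).
#' @return data.frame with columns `predictor`, `mean`, `sd`. A predictor
#'   with zero spread gets `sd = 1` (centred but not amplified).
#' @export
feature_stats <- function(features) {
  cols <- predictor_columns()
  m <- vapply(features[cols], mean, numeric(1))
  s <- vapply(features[cols], stats::sd, numeric(1))
  zero <- !is.finite(s) | s == 0
  if (any(zero)) {
    message("constant predictor column(s) passed through centred: ",
            paste(cols[zero], collapse = ", "))
    s[zero] <- 1
  }
  data.frame(predictor = cols, mean = m, sd = s, row.names = NULL)
}

#' Standardize feature vectors with training statistics
#'
#' Z-scores the 12 predictors using means and standard deviations computed on
#' the training pens; test-set vectors reuse the training statistics so no
#' information leaks from test to training.
#'
#' @param features feature table.
#' @param stats statistics from [feature_stats()]; if `NULL`, computed from
#'   `features` itself.
#' @return The standardized feature table, with the statistics used attached
#'   as attribute `"stats"`.
#' @export
standardize_features <- function(features, stats = NULL) {
  if (is.null(stats)) stats <- feature_stats(features)
  for (i in seq_len(nrow(stats))) {
    col <- stats$predictor[i]
    features[[col]] <- (features[[col]] - stats$mean[i]) / stats$sd[i]
  }
  attr(features, "stats") <- stats
  features
}
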
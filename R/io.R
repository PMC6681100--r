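fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

#' Write an hourly sensor table to CSV
#'
#' One row per pen-hour-source with columns `pen_id`, `batch`, `day_index`,
#' `hour_of_day`, `source`, `value`; missing values are written as empty
#' fields and numbers with 17 significant digits so the file round-trips
#' losslessly.
#'
#' @param sensors sensor data.frame (a `batch` column is added as 1 if
#'   absent).
#' @param path output file path.
#' @export
write_sensor_csv <- function(sensors, path) {
  if (!"batch" %in% names(sensors)) sensors$batch <- 1L
  out <- data.frame(pen_id = sensors$pen_id, batch = sensors$batch,
                    day_index = sensors$day_index,
                    hour_of_day = sensors$hour_of_day,
                    source = sensors$source, value = fmt_num(sensors$value))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an hourly sensor table from CSV
#'
#' Validates the header, the source enum, the 0-23 hour range and numeric
#' values (empty fields become missing), and rejects duplicated
#' pen-day-hour-source keys naming the offending lines.
#'
#' @param path input file path.
#' @return Sensor data.frame with columns `pen_id`, `batch`, `day_index`,
#'   `hour_of_day`, `source`, `value`.
#' @export
read_sensor_csv <- function(path) {
  if (!file.exists(path)) stop("sensor file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(pen_id = "character",
                                      source = "character"))
  needed <- c("pen_id", "batch", "day_index", "hour_of_day", "source",
              "value")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols) > 0) {
    stop("sensor file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_src <- which(!d$source %in% SOURCES)
  if (length(bad_src) > 0) {
    stop(sprintf("invalid source at line(s) %s",
                 paste(utils::head(bad_src + 1L, 5), collapse = ", ")))
  }
  bad_hour <- which(!is.finite(d$hour_of_day) | d$hour_of_day < 0 |
                      d$hour_of_day > 23 | d$hour_of_day != round(d$hour_of_day))
  if (length(bad_hour) > 0) {
    stop(sprintf("hour_of_day outside 0-23 at line(s) %s",
                 paste(utils::head(bad_hour + 1L, 5), collapse = ", ")))
  }
  d$value <- suppressWarnings(as.numeric(d$value))
  key <- paste(d$pen_id, d$day_index, d$hour_of_day, d$source)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    stop(sprintf("duplicate pen-hour-source rows at line(s) %s",
                 paste(utils::head(which(dup) + 1L, 10), collapse = ", ")))
  }
  d[needed]
}

#' Write / read pen metadata
#'
#' @param pens pen metadata data.frame.
#' @param path file path.
#' @export
write_pen_metadata <- function(pens, path) {
  utils::write.csv(pens, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pen_metadata
#' @export
read_pen_metadata <- function(path) {
  if (!file.exists(path)) stop("pen metadata file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(pen_id = "character"))
  needed <- c("pen_id", "batch", "tail", "straw", "space")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols) > 0) {
    stop("pen metadata lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  d
}

#' Write / read the event log
#'
#' @param events event log data.frame (`pen_id`, `day_index`, `type`).
#' @param path file path.
#' @export
write_event_log <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("event log file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(pen_id = "character"))
  needed <- c("pen_id", "day_index", "type")
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols) > 0) {
    stop("event log lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!d$type %in% c("tail_biting", "fouling", "diarrhoea"))
  if (length(bad) > 0) {
    stop(sprintf("unknown event type at line(s) %s",
                 paste(utils::head(bad + 1L, 5), collapse = ", ")))
  }
  d
}

#' Write filtered DLM output per pen-source
#'
#' @param filtered data.frame with per-hour `f`, `Q`, `e`, `u` columns.
#' @param path file path.
#' @export
write_filtered_csv <- function(filtered, path) {
  num <- vapply(filtered, is.numeric, logical(1))
  filtered[num] <- lapply(filtered[num], fmt_num)
  utils::write.csv(filtered, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a daily feature table
#'
#' @param features feature table from [build_feature_table()].
#' @param path file path.
#' @export
write_feature_csv <- function(features, path) {
  out <- features
  for (col in predictor_columns()) out[[col]] <- fmt_num(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(pen_id = "character"))
  missing_cols <- setdiff(c("pen_id", "source", "day_index",
                            predictor_columns()), names(d))
  if (length(missing_cols) > 0) {
    stop("feature file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  d
}

#' Write a fitted DLM description
#'
#' Plain-text key=value file holding the state prior, the observational
#' variance percentage, the discount factor and the fitted wave
#' amplitudes/phases, so a fit can be archived and re-applied.
#'
#' @param fit list with `theta0`, `obs_variance_pct`, `discount` (e.g. from
#'   [fit_source_dlm()]).
#' @param path file path.
#' @export
write_dlm_fit <- function(fit, path) {
  waves <- harmonic_components(fit$theta0)
  lines <- c(
    paste0("source=", fit$source),
    paste0("theta0=", paste(sprintf("%.17g", fit$theta0), collapse = ",")),
    paste0("obs_variance_pct=", sprintf("%.17g", fit$obs_variance_pct)),
    paste0("discount=", sprintf("%.17g", fit$discount)),
    vapply(waves, function(w) {
      sprintf("wave%d=amplitude:%.17g,phase:%.17g", w$peaks_per_day,
              w$amplitude, w$phase)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
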
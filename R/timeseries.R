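#' Construct a symptom time series
#'
#' The raw input of the planning pipeline: one patient's repeated Likert-type
#' symptom ratings, `T` timestamped assessments by `I` items. Missing
#' responses are stored as `NA`.
#'
#' @param values numeric matrix, `T x I`; `NA` marks a missing response.
#' @param timestamps `POSIXct` vector of length `T`, strictly increasing.
#' @param item_ids character vector of `I` unique item identifiers.
#' @param item_texts optional character vector of `I` item wordings.
#' @param scale_min,scale_max numeric response-scale bounds
#'   (`scale_max > scale_min`); every non-missing value must lie inside.
#'
#' @return An object of class `symptom_ts`: a list with fields `values`,
#'   `timestamps`, `item_ids`, `item_texts`, `scale_min`, `scale_max`.
#' @export
symptom_ts <- function(values, timestamps, item_ids,
                       item_texts = item_ids, scale_min, scale_max) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("symptom_ts: need at least one row and one item", call. = FALSE)
  if (length(timestamps) != nrow(values))
    stop("symptom_ts: timestamps must match the number of rows", call. = FALSE)
  if (!inherits(timestamps, "POSIXct")) timestamps <- as.POSIXct(timestamps, tz = "UTC")
  if (anyNA(timestamps))
    stop("symptom_ts: non-parsable timestamp", call. = FALSE)
  if (nrow(values) > 1L && any(diff(as.numeric(timestamps)) <= 0))
    stop("symptom_ts: timestamps must be strictly increasing", call. = FALSE)
  if (length(item_ids) != ncol(values) || anyDuplicated(item_ids))
    stop("symptom_ts: item_ids must be unique and match the number of columns",
         call. = FALSE)
  if (length(item_texts) != length(item_ids))
    stop("symptom_ts: item_texts must match item_ids", call. = FALSE)
  if (!is.numeric(scale_min) || !is.numeric(scale_max) || scale_max <= scale_min)
    stop("symptom_ts: scale_max must exceed scale_min", call. = FALSE)
  bad <- which(!is.na(values) & (values < scale_min | values > scale_max),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf(
      "symptom_ts: value %g outside scale bounds [%g, %g] at row %d, item '%s'",
      values[bad[1, 1], bad[1, 2]], scale_min, scale_max,
      bad[1, 1], item_ids[bad[1, 2]]), call. = FALSE)
  dimnames(values) <- list(NULL, item_ids)
  structure(
    list(values = values, timestamps = timestamps,
         item_ids = as.character(item_ids),
         item_texts = as.character(item_texts),
         scale_min = scale_min, scale_max = scale_max),
    class = "symptom_ts")
}

#' @export
print.symptom_ts <- function(x, ...) {
  cat(sprintf("<symptom_ts> %d assessments x %d items on [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$scale_min, x$scale_max))
  cat(sprintf("  %s to %s; missing rate %.1f%%\n",
              format(min(x$timestamps)), format(max(x$timestamps)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Missingness mask of a symptom time series
#' @param ts a `symptom_ts`.
#' @return logical `T x I` matrix, `TRUE` where the response is missing.
#' @export
missing_mask <- function(ts) is.na(ts$values)

#' Patient configuration
#'
#' Describes one patient's assessment setup: the items administered, the
#' response scale, and the daily assessment schedule.
#'
#' @param patient_code non-empty identification string (opaque; chosen by the
#'   therapist, no person-related data).
#' @param items data frame with columns `id` and `text`, one row per item.
#' @param scale_min,scale_max numeric response-scale bounds.
#' @param schedule character vector of daily assessment times (`"HH:MM"` or
#'   `"HH:MM:SS"`), strictly increasing within the day.
#'
#' @return An object of class `patient_config`.
#' @export
patient_config <- function(patient_code, items, scale_min, scale_max,
                           schedule = c("08:00", "14:00", "20:00")) {
  if (!is.character(patient_code) || length(patient_code) != 1L ||
      !nzchar(patient_code))
    stop("patient_config: patient_code must be a non-empty string", call. = FALSE)
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  if (nrow(items) < 1L || !all(c("id", "text") %in% names(items)))
    stop("patient_config: items must be a non-empty data frame with 'id' and 'text'",
         call. = FALSE)
  if (scale_max <= scale_min)
    stop("patient_config: scale_max must exceed scale_min", call. = FALSE)
  secs <- .parse_tod(schedule)
  if (any(diff(secs) <= 0))
    stop("patient_config: schedule times must be strictly increasing", call. = FALSE)
  structure(
    list(patient_code = patient_code,
         items = items[, c("id", "text")],
         scale_min = scale_min, scale_max = scale_max,
         schedule = schedule,
         assessments_per_day = length(schedule)),
    class = "patient_config")
}

# time-of-day "HH:MM[:SS]" -> seconds since midnight
.parse_tod <- function(x) {
  vapply(strsplit(as.character(x), ":", fixed = TRUE), function(p) {
    p <- suppressWarnings(as.numeric(p))
    if (length(p) < 2L || length(p) > 3L || anyNA(p))
      stop("invalid time of day", call. = FALSE)
    if (length(p) == 2L) p <- c(p, 0)
    if (p[1] > 23 || p[2] > 59 || p[3] >= 60 || any(p < 0))
      stop("invalid time of day", call. = FALSE)
    p[1] * 3600 + p[2] * 60 + p[3]
  }, numeric(1))
}

.format_tod <- function(secs) {
  secs <- round(secs)
  sprintf("%02d:%02d:%02d", secs %/% 3600, (secs %% 3600) %/% 60, secs %% 60)
}

#' Read and write patient configurations
#'
#' Configurations are stored as YAML key-value files with fields
#' `patient_code`, `scale_min`, `scale_max`, `schedule`, and `items`
#' (a list of `id`/`text` pairs).
#'
#' @param path file path.
#' @return `read_patient_config` returns a [patient_config()];
#'   `write_patient_config` returns `path` invisibly.
#' @export
read_patient_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("patient_code", "items", "scale_min", "scale_max")
  if (!all(need %in% names(cfg)))
    stop("patient config: missing fields ",
         paste(setdiff(need, names(cfg)), collapse = ", "), call. = FALSE)
  items <- do.call(rbind, lapply(cfg$items, function(it)
    data.frame(id = as.character(it$id), text = as.character(it$text),
               stringsAsFactors = FALSE)))
  patient_config(cfg$patient_code, items, cfg$scale_min, cfg$scale_max,
                 schedule = if (is.null(cfg$schedule)) c("08:00", "14:00", "20:00")
                            else as.character(cfg$schedule))
}

#' @rdname read_patient_config
#' @param config a `patient_config`.
#' @export
write_patient_config <- function(config, path) {
  stopifnot(inherits(config, "patient_config"))
  yaml::write_yaml(
    list(patient_code = config$patient_code,
         scale_min = config$scale_min, scale_max = config$scale_max,
         schedule = config$schedule,
         items = lapply(seq_len(nrow(config$items)), function(i)
           list(id = config$items$id[i], text = config$items$text[i]))),
    path)
  invisible(path)
}

#' Read a symptom time series from CSV
#'
#' The CSV dialect is comma-separated with a header row, a `timestamp`
#' column holding ISO-8601 datetimes, and one column per configured item id.
#' Empty cells or the literal `NA` mark missing responses.
#'
#' @param source path to a CSV file, or a character vector of CSV lines.
#' @param config a [patient_config()]; fixes item order, item texts and the
#'   scale bounds.
#' @return A [symptom_ts()] with missing cells masked.
#' @export
read_timeseries <- function(source, config) {
  stopifnot(inherits(config, "patient_config"))
  df <- if (length(source) == 1L && file.exists(source)) {
    utils::read.csv(source, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), check.names = FALSE)
  } else {
    utils::read.csv(text = paste(source, collapse = "\n"),
                    stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), check.names = FALSE)
  }
  if (!"timestamp" %in% names(df))
    stop("read_timeseries: no 'timestamp' column", call. = FALSE)
  ids <- config$items$id
  missing_cols <- setdiff(ids, names(df))
  if (length(missing_cols) > 0L)
    stop("read_timeseries: missing item columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(df), c("timestamp", ids))
  if (length(unknown) > 0L)
    stop("read_timeseries: unknown columns: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  tstamps <- tryCatch(
    as.POSIXct(df$timestamp, tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                              "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                              "%Y-%m-%d")),
    error = function(e) rep(as.POSIXct(NA), nrow(df)))
  if (anyNA(tstamps))
    stop("read_timeseries: non-parsable timestamp at row ",
         which(is.na(tstamps))[1], call. = FALSE)
  vals <- sapply(ids, function(id) suppressWarnings(as.numeric(df[[id]])))
  vals <- matrix(vals, nrow = nrow(df), ncol = length(ids),
                 dimnames = list(NULL, ids))
  nonnum <- which(is.na(vals) & !is.na(as.matrix(df[ids])), arr.ind = TRUE)
  if (nrow(nonnum) > 0L)
    stop("read_timeseries: non-numeric value at row ", nonnum[1, 1],
         ", item '", ids[nonnum[1, 2]], "'", call. = FALSE)
  ts <- symptom_ts(vals, tstamps, ids, config$items$text,
                   config$scale_min, config$scale_max)
  .warn_irregular(ts)
  ts
}

# equal index spacing is assumed downstream; warn on badly irregular gaps
.warn_irregular <- function(ts) {
  if (length(ts$timestamps) < 3L) return(invisible())
  gaps <- diff(as.numeric(ts$timestamps))
  modal <- as.numeric(names(sort(table(gaps), decreasing = TRUE))[1])
  if (any(abs(gaps - modal) > 0.5 * modal))
    warning("timestamp gaps deviate more than 50% from the modal gap; ",
            "observations are treated as equally spaced in index order",
            call. = FALSE)
  invisible()
}

#' Write a symptom time series to CSV
#'
#' Inverse of [read_timeseries()]: writes the same comma-separated dialect
#' (ISO-8601 timestamps, `NA` for missing responses), so a read-write-read
#' round trip reproduces the series exactly.
#'
#' @param ts a `symptom_ts`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "symptom_ts"))
  df <- data.frame(timestamp = format(ts$timestamps, "%Y-%m-%dT%H:%M:%S",
                                      tz = "UTC"),
                   stringsAsFactors = FALSE)
  for (j in seq_along(ts$item_ids)) df[[ts$item_ids[j]]] <- ts$values[, j]
  utils::write.csv(df, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' Clean a symptom time series for model fitting
#'
#' Internal missing runs of length at most `max_gap` are filled per item by
#' linear interpolation over the observation index; rows still containing
#' missing values afterwards (including leading/trailing gaps, which cannot
#' be interpolated) are dropped. The output contains no missing values.
#'
#' @param ts a `symptom_ts`.
#' @param max_gap longest internal missing run (per item) to interpolate;
#'   default 1.
#' @return A list with `ts` (the cleaned series) and `report`, a
#'   `cleaning_report` with fields `n_rows_in`, `n_rows_out`, `missing_rate`
#'   (input missing fraction), `interpolated_cells`, `dropped_rows`.
#' @export
clean_timeseries <- function(ts, max_gap = 1L) {
  stopifnot(inherits(ts, "symptom_ts"), max_gap >= 0L)
  vals <- ts$values
  n_in <- nrow(vals)
  miss_rate <- mean(is.na(vals))
  interp <- 0L
  for (j in seq_len(ncol(vals))) {
    y <- vals[, j]
    obs <- which(!is.na(y))
    if (length(obs) < 2L)
      stop("clean_timeseries: item '", ts$item_ids[j],
           "' has fewer than 2 observed values", call. = FALSE)
    if (max_gap > 0L && anyNA(y)) {
      runs <- rle(is.na(y))
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (r in which(runs$values)) {
        internal <- starts[r] > 1L && ends[r] < length(y)
        if (internal && runs$lengths[r] <= max_gap) {
          idx <- starts[r]:ends[r]
          y[idx] <- stats::approx(obs, ts$values[obs, j], xout = idx)$y
          interp <- interp + length(idx)
        }
      }
      vals[, j] <- y
    }
  }
  keep <- !apply(is.na(vals), 1L, any)
  out <- symptom_ts(vals[keep, , drop = FALSE], ts$timestamps[keep],
                    ts$item_ids, ts$item_texts, ts$scale_min, ts$scale_max)
  report <- structure(
    list(n_rows_in = n_in, n_rows_out = sum(keep),
         missing_rate = miss_rate, interpolated_cells = interp,
         dropped_rows = n_in - sum(keep)),
    class = "cleaning_report")
  list(ts = out, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf(
    "<cleaning_report> %d -> %d rows; missing %.1f%%; %d cells interpolated, %d rows dropped\n",
    x$n_rows_in, x$n_rows_out, 100 * x$missing_rate,
    x$interpolated_cells, x$dropped_rows))
  invisible(x)
}

#' Build an equally spaced daily assessment schedule
#'
#' Splits the waking window into equal parts: for `n >= 2` assessments the
#' wake and sleep times are the first and last assessments and the rest are
#' equally spaced between them; a single daily assessment is placed at the
#' window midpoint.
#'
#' @param wake,sleep times of day (`"HH:MM"` or `"HH:MM:SS"`); `sleep` must
#'   be later than `wake` within the same day.
#' @param n number of daily assessments, a positive integer.
#' @return Character vector of `n` times (`"HH:MM:SS"`), strictly increasing.
#' @examples
#' make_schedule("08:00", "20:00", 3) # 08:00, 14:00, 20:00
#' @export
make_schedule <- function(wake, sleep, n) {
  w <- .parse_tod(wake); s <- .parse_tod(sleep)
  if (length(w) != 1L || length(s) != 1L || n < 1L || n != round(n))
    stop("make_schedule: scalar wake/sleep and integer n >= 1 required",
         call. = FALSE)
  if (s <= w)
    stop("make_schedule: sleep must be later than wake", call. = FALSE)
  secs <- if (n == 1L) (w + s) / 2 else w + (0:(n - 1L)) * (s - w) / (n - 1L)
  .format_tod(secs)
}
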
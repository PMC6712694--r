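#' One participant's 1-s epoch count stream
#'
#' Light container for vertical-axis accelerometer counts recorded at 1-s
#' epochs. Timestamps must advance in exact 1-s steps within each calendar
#' day (gaps between days are allowed, e.g. after [restrict_hours()]), and
#' counts must be non-negative whole numbers.
#'
#' @param participant_id Identifier (recycled).
#' @param timestamp `POSIXct` vector.
#' @param counts Non-negative integer counts per 1-s epoch.
#' @return A tibble of class `epoch_series` with columns `participant_id`,
#'   `timestamp`, `counts`.
#' @export
epoch_series <- function(participant_id, timestamp, counts) {
  if (!inherits(timestamp, "POSIXct")) {
    stop("timestamp must be POSIXct", call. = FALSE)
  }
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (length(timestamp) != length(counts)) {
    stop("timestamp and counts lengths differ", call. = FALSE)
  }
  if (length(timestamp) > 1L) {
    dt <- diff(as.numeric(timestamp))
    same_day <- diff(as.numeric(.series_date_raw(timestamp))) == 0
    if (any(dt <= 0)) {
      stop("timestamps must be strictly increasing", call. = FALSE)
    }
    if (any(same_day & dt != 1)) {
      stop("timestamps must advance in 1-s steps within a day",
           call. = FALSE)
    }
  }
  out <- tibble::tibble(
    participant_id = rep_len(participant_id, length(counts)),
    timestamp = timestamp, counts = counts
  )
  class(out) <- c("epoch_series", class(out))
  out
}

.series_tz <- function(series) {
  tz <- attr(series$timestamp, "tzone")
  if (is.null(tz) || !nzchar(tz[1L])) "UTC" else tz[1L]
}

.series_date_raw <- function(timestamp) {
  tz <- attr(timestamp, "tzone")
  if (is.null(tz) || !nzchar(tz[1L])) tz <- "UTC"
  as.Date(format(timestamp, "%Y-%m-%d", tz = tz))
}

.series_date <- function(series) .series_date_raw(series$timestamp)

#' Restrict an epoch series to waking hours
#'
#' Keeps epochs whose local time of day lies in \[06:00:00, 23:59:59\] (by
#' default), dropping the night-time block the protocol does not analyse.
#'
#' @param series An [epoch_series()].
#' @param start_hour,end_hour Retained window: `start_hour <= hour < end_hour`.
#' @return The filtered `epoch_series`.
#' @export
restrict_hours <- function(series, start_hour = 6, end_hour = 24) {
  stopifnot(inherits(series, "epoch_series"))
  hr <- as.integer(format(series$timestamp, "%H", tz = .series_tz(series)))
  keep <- hr >= start_hour & hr < end_hour
  out <- series[keep, , drop = FALSE]
  class(out) <- unique(c("epoch_series", class(out)))
  out
}

#' Flag non-wear epochs
#'
#' An epoch is non-wear when it belongs to a run of at least `min_minutes`
#' (default 60) consecutive zero-count 1-s epochs. Runs are computed within
#' contiguous recording segments: a jump in the timestamp (e.g. the
#' overnight gap left by [restrict_hours()]) breaks a run. No interruption
#' tolerance is applied -- a single non-zero count ends a run.
#'
#' @param series An [epoch_series()].
#' @param min_minutes Minimum zero-run duration classed as non-wear.
#' @return Logical wear mask, `TRUE` for wear epochs, aligned to the series.
#' @export
detect_nonwear <- function(series, min_minutes = 60) {
  stopifnot(inherits(series, "epoch_series"))
  n <- nrow(series)
  if (n == 0L) return(logical(0))
  z <- series$counts == 0
  gap <- c(TRUE, diff(as.numeric(series$timestamp)) != 1)
  change <- gap | z != c(z[1L], z[-n])
  change[1L] <- TRUE
  run_id <- cumsum(change)
  run_len <- tabulate(run_id)
  nonwear <- z & run_len[run_id] >= min_minutes * 60
  !nonwear
}

#' Wear-time validity of calendar days and of the measurement
#'
#' A day is valid when it accumulates at least `min_wear_minutes` (default
#' 480 = 8 h) of wear; the whole measurement is valid when at least
#' `min_days` (default 4) days are valid.
#'
#' @param series An [epoch_series()].
#' @param wear Logical wear mask from [detect_nonwear()].
#' @param min_wear_minutes Daily wear requirement in minutes.
#' @param min_days Minimum number of valid days.
#' @return A list with `days` (tibble: `date`, `wear_minutes`, `valid`),
#'   `n_valid_days` and `valid`.
#' @export
valid_days <- function(series, wear = detect_nonwear(series),
                       min_wear_minutes = 480, min_days = 4) {
  stopifnot(inherits(series, "epoch_series"), length(wear) == nrow(series))
  date <- .series_date(series)
  wm <- tapply(wear, date, sum) / 60
  days <- tibble::tibble(
    date = as.Date(names(wm)),
    wear_minutes = as.numeric(wm),
    valid = as.numeric(wm) >= min_wear_minutes
  )
  list(days = days, n_valid_days = sum(days$valid),
       valid = sum(days$valid) >= min_days)
}

#' Per-participant intensity profile from an epoch stream
#'
#' Classifies each wear 1-s epoch into a cpm intensity bin by scaling the
#' epoch count by 60 (the standard epoch-to-cpm mapping) and comparing it to
#' the scheme's left-closed/right-open edges, accumulates seconds per bin per
#' calendar day, converts to minutes, and averages over valid days only.
#' Bin minutes sum exactly to wear minutes for every day by construction.
#'
#' @param series An [epoch_series()] (typically after [restrict_hours()]).
#' @param scheme A [bin_scheme()].
#' @param wear Logical wear mask; defaults to [detect_nonwear()].
#' @param min_wear_minutes,min_days Validity thresholds, see [valid_days()].
#' @return An `intensity_profile`: list with `participant_id`,
#'   `bin_minutes` (named, min/day), `wear_minutes`, `n_valid_days`,
#'   `scheme`, `valid`.
#' @export
bin_profile <- function(series, scheme, wear = detect_nonwear(series),
                        min_wear_minutes = 480, min_days = 4) {
  stopifnot(inherits(series, "epoch_series"), inherits(scheme, "bin_scheme"))
  vd <- valid_days(series, wear, min_wear_minutes, min_days)
  if (!vd$valid) {
    stop(structure(class = c("invalid_wear_error", "error", "condition"),
                   list(message = sprintf(
                     "insufficient wear time: %d valid day(s), %d required",
                     vd$n_valid_days, min_days), call = NULL)))
  }
  good_days <- vd$days$date[vd$days$valid]
  date <- .series_date(series)
  keep <- wear & date %in% good_days
  sub_date <- factor(date[keep], levels = as.character(sort(good_days)))
  cpm <- series$counts[keep] * 60
  bin <- factor(findInterval(cpm, scheme$edges), levels = seq_along(scheme$edges))
  sec <- table(sub_date, bin)
  day_minutes <- unclass(sec) / 60
  bin_minutes <- colMeans(day_minutes)
  names(bin_minutes) <- scheme$labels
  wear_minutes <- mean(rowSums(day_minutes))
  structure(list(
    participant_id = series$participant_id[1L],
    bin_minutes = bin_minutes,
    wear_minutes = wear_minutes,
    n_valid_days = length(good_days),
    scheme = scheme,
    valid = TRUE
  ), class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat("<intensity_profile> ", x$participant_id, ": ",
      length(x$bin_minutes), " bins (", x$scheme$name, "), ",
      round(x$wear_minutes, 1), " min/day wear over ", x$n_valid_days,
      " valid day(s)\n", sep = "")
  print(round(x$bin_minutes, 2))
  invisible(x)
}

#' @export
as.data.frame.intensity_profile <- function(x, ...) {
  out <- as.data.frame(as.list(x$bin_minutes))
  cbind(data.frame(participant_id = x$participant_id), out,
        data.frame(wear_minutes = x$wear_minutes,
                   n_valid_days = x$n_valid_days, valid = x$valid))
}

#' Traditional-category summary measures
#'
#' From a traditional-scheme profile: MVPA (MPA + VPA, min/day), the
#' guideline flag (mean MVPA >= 60 min/day), and -- when the underlying
#' series and wear mask are supplied -- overall intensity as total counts
#' over wear epochs divided by wear minutes (cpm), computed over valid days.
#'
#' @param profile An `intensity_profile` on the traditional scheme.
#' @param series,wear Optional epoch series and wear mask for the cpm
#'   summary.
#' @param guideline_minutes MVPA guideline threshold (min/day).
#' @return List with `mvpa_minutes`, `meets_guideline`, `overall_cpm`
#'   (`NA` unless `series` is given).
#' @export
derive_summary <- function(profile, series = NULL, wear = NULL,
                           guideline_minutes = 60) {
  stopifnot(inherits(profile, "intensity_profile"))
  bm <- profile$bin_minutes
  if (!all(c("MPA", "VPA") %in% names(bm))) {
    stop("derive_summary needs a traditional-scheme profile (MPA/VPA bins)",
         call. = FALSE)
  }
  mvpa <- unname(bm[["MPA"]] + bm[["VPA"]])
  cpm <- NA_real_
  if (!is.null(series)) {
    if (is.null(wear)) wear <- detect_nonwear(series)
    vd <- valid_days(series, wear)
    good <- vd$days$date[vd$days$valid]
    keep <- wear & .series_date(series) %in% good
    wear_min <- sum(keep) / 60
    if (wear_min == 0) {
      stop("overall cpm undefined: zero wear minutes", call. = FALSE)
    }
    cpm <- sum(series$counts[keep]) / wear_min
  }
  list(mvpa_minutes = mvpa,
       meets_guideline = mvpa >= guideline_minutes,
       overall_cpm = cpm)
}
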
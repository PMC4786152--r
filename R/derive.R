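# Derived per-subject and aggregate variables consumed by the renderers.
# Day arithmetic is exact calendar-day difference; day 0 is the start date.

#' Pick one start date per subject
#'
#' @param dates `Date` vector of candidate start dates for one subject.
#' @param starttype `"first"` (earliest) or `"last"` (latest).
#' @return A single `Date`, or `NA` (with a warning) when every candidate is
#'   missing — callers exclude such subjects.
#' @export
select_start_date <- function(dates, starttype = c("first", "last")) {
  starttype <- match.arg(starttype)
  dates <- dates[!is.na(dates)]
  if (length(dates) == 0) {
    warning("subject has no non-missing start date; excluded", call. = FALSE)
    return(as.Date(NA))
  }
  if (starttype == "first") min(dates) else max(dates)
}

#' Truncated follow-up time and event status
#'
#' Raw follow-up is the calendar-day count from `start` to `end`. Subjects
#' followed beyond `maxtime` are administratively censored there: follow-up is
#' capped at `maxtime` and the event flag forced to `FALSE` (an event after
#' the plotting horizon is unobserved within it).
#'
#' @param start,end `Date` scalars, `end >= start`.
#' @param event Logical event flag at `end`.
#' @param maxtime Horizon in days (> 0).
#' @param id Subject identifier used in error messages.
#' @return List with `followup_day` (integer in `[0, maxtime]`) and `event`.
#' @export
compute_follow_up <- function(start, end, event, maxtime, id = "?") {
  raw <- as.integer(end - start)
  if (is.na(raw)) stop("subject '", id, "': missing start or end date", call. = FALSE)
  if (raw < 0) {
    stop("subject '", id, "': end date ", format(end),
      " precedes start date ", format(start),
      call. = FALSE
    )
  }
  if (raw > maxtime) {
    list(followup_day = as.integer(maxtime), event = FALSE)
  } else {
    list(followup_day = raw, event = isTRUE(event))
  }
}

#' Attribute the last longitudinal value to an event
#'
#' Returns the value of the latest observation at or before `event_day` whose
#' age at the event (`event_day - obs_day`) is at most `window` days; the
#' boundary is inclusive. Used to place the death marker at (event day, last
#' measurement) only when the measurement is recent enough to be meaningful.
#'
#' @param days,values Parallel vectors of observation day and value.
#' @param event_day Day of the event.
#' @param window Maximum allowed age of the attributed observation, in days.
#' @return The attributed value, or `NULL` when no observation qualifies.
#' @export
attribute_last_value <- function(days, values, event_day, window) {
  stopifnot(window >= 0, length(days) == length(values))
  ok <- !is.na(days) & !is.na(values) & days <= event_day &
    (event_day - days) <= window
  if (!any(ok)) {
    return(NULL)
  }
  values[ok][which.max(days[ok])]
}

#' Transform longitudinal values for the plotting scale
#'
#' @param values Numeric vector.
#' @param trans One of `"identity"`, `"sqrt"`, `"log"`, `"log10"`. Tick labels
#'   stay on the original scale; only positions are transformed.
#' @return Transformed values.
#' @export
transform_values <- function(values, trans = c("identity", "sqrt", "log", "log10")) {
  trans <- match.arg(trans)
  v <- values[!is.na(values)]
  if (trans == "sqrt" && any(v < 0)) {
    stop("sqrt transform: negative values present; pre-filter with longsubset", call. = FALSE)
  }
  if (trans %in% c("log", "log10") && any(v <= 0)) {
    stop(trans, " transform: non-positive values present; pre-filter with longsubset",
      call. = FALSE
    )
  }
  switch(trans,
    identity = values,
    sqrt = sqrt(values),
    log = log(values),
    log10 = log10(values)
  )
}

#' Discretize dates into animation periods
#'
#' Period labels sort chronologically as plain text: `"2011"`, `"2011-Q1"`,
#' `"2011-03"`.
#'
#' @param dates `Date` vector.
#' @param period `"year"`, `"quarter"` or `"month"`.
#' @return Character vector of period labels (`NA` for missing dates).
#' @export
discretize_period <- function(dates, period = c("year", "quarter", "month")) {
  period <- match.arg(period)
  y <- format(dates, "%Y")
  m <- as.integer(format(dates, "%m"))
  switch(period,
    year = y,
    quarter = ifelse(is.na(y), NA, sprintf("%s-Q%d", y, (m - 1) %/% 3 + 1)),
    month = format(dates, "%Y-%m")
  )
}

#' Baseline measurement closest to an anchor date
#'
#' Among observations dated within `[anchor - window_before, anchor +
#' window_after]`, returns the value whose date is closest to the anchor;
#' on an exact distance tie the earlier observation wins (a pre-anchor value
#' cannot have been influenced by what the anchor marks, e.g. therapy start).
#'
#' @param dates,values Parallel observation vectors.
#' @param anchor Anchor `Date` (enrollment or ART start).
#' @param window_before,window_after Eligibility window in days (default
#'   180 before / 30 after).
#' @return The baseline value, or `NULL` when no observation qualifies.
#' @export
baseline_value <- function(dates, values, anchor, window_before = 180, window_after = 30) {
  stopifnot(window_before >= 0, window_after >= 0)
  off <- as.numeric(dates - anchor)
  ok <- !is.na(off) & !is.na(values) & off >= -window_before & off <= window_after
  if (!any(ok)) {
    return(NULL)
  }
  off <- off[ok]
  vals <- values[ok]
  d <- abs(off)
  best <- which(d == min(d))
  if (length(best) > 1) best <- best[which.min(off[best])]
  vals[best]
}

#' Append a baseline-measure column to a patient-level table
#'
#' Convenience wrapper producing the kind of derived table the bubble and map
#' plots consume (e.g. `basic` plus a baseline CD4 column): for every subject
#' in `table`, looks up the longitudinal table and takes the
#' [baseline_value()] around that subject's anchor date.
#'
#' @param cohort A `cohort_data`.
#' @param table Name of the patient-level table to extend.
#' @param longtable,longvar,longvardate Longitudinal source table and columns.
#' @param anchor_col Date column of `table` used as the anchor.
#' @param out_col Name of the new column (default `paste0(longvar, "_base")`).
#' @inheritParams baseline_value
#' @return The extended data frame.
#' @export
add_baseline <- function(cohort, table, longtable, longvar, longvardate,
                         anchor_col, out_col = paste0(longvar, "_base"),
                         window_before = 180, window_after = 30) {
  stopifnot(inherits(cohort, "cohort_data"))
  df <- cohort$tables[[table]]
  lg <- cohort$tables[[longtable]]
  id <- cohort$id_field
  split_idx <- split(seq_len(nrow(lg)), as.character(lg[[id]]))
  out <- rep(NA_real_, nrow(df))
  for (i in seq_len(nrow(df))) {
    rows <- split_idx[[as.character(df[[id]][i])]]
    if (is.null(rows)) next
    b <- baseline_value(
      lg[[longvardate]][rows], lg[[longvar]][rows],
      df[[anchor_col]][i], window_before, window_after
    )
    if (!is.null(b)) out[i] <- b
  }
  df[[out_col]] <- out
  df
}

#' Aggregate an indicator to country-year proportions
#'
#' For every (country, year) cell: denominator = rows with a non-missing
#' indicator, numerator = rows where it is `TRUE`. Cells with denominator 0
#' are omitted, so every emitted proportion is well defined.
#'
#' @param country Character vector of ISO-3 codes.
#' @param year Vector of time-point labels (coerced to character).
#' @param indicator Logical vector (may contain `NA`).
#' @return Data frame of class `country_year_table` with columns `iso3`,
#'   `year`, `numerator`, `denominator`, `proportion`, sorted by country then
#'   year.
#' @export
aggregate_country_year <- function(country, year, indicator) {
  stopifnot(length(country) == length(year), length(year) == length(indicator))
  keep <- !is.na(indicator) & !is.na(country) & !is.na(year)
  country <- as.character(country[keep])
  year <- as.character(year[keep])
  indicator <- indicator[keep]
  if (length(indicator) == 0) {
    out <- data.frame(
      iso3 = character(), year = character(),
      numerator = integer(), denominator = integer(),
      proportion = numeric(), stringsAsFactors = FALSE
    )
    return(structure(out, class = c("country_year_table", "data.frame")))
  }
  key <- interaction(country, year, drop = TRUE, lex.order = TRUE)
  den <- tapply(indicator, key, length)
  num <- tapply(indicator, key, sum)
  parts <- do.call(rbind, strsplit(names(den), ".", fixed = TRUE))
  out <- data.frame(
    iso3 = parts[, 1], year = parts[, 2],
    numerator = as.integer(num), denominator = as.integer(den),
    proportion = as.numeric(num) / as.numeric(den),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$iso3, out$year), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("country_year_table", "data.frame"))
}
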
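#' Sample-count data coverage of an interval
#'
#' Coverage of regularly sampled channels (heart rate, respiratory rate,
#' skin temperature; also any windowed modality) is the number of clean
#' samples observed in the interval divided by the number expected from the
#' nominal sampling rate, capped at 1 to absorb timestamp jitter.
#'
#' @param series a cleaned [sample_series()].
#' @param start,end interval bounds in seconds, half-open `(start, end]`.
#' @return Coverage fraction in `[0, 1]`.
#' @export
coverage_sampled <- function(series, start, end) {
  if (end <= start) stop("zero-length interval")
  n <- length(series_window(series, start, end)$time)
  min(1, n / (series$nominal_rate * (end - start)))
}

#' Duration-based coverage of the R-to-R channel
#'
#' The R-to-R channel is a sequence of interbeat intervals, so coverage is
#' the summed interval duration divided by the length of the actual
#' measurement period: the intersection of the query interval with the
#' wear sessions (runs of samples separated by gaps shorter than
#' `session_gap_min` minutes). Capped at 1.
#'
#' @param series the cleaned R-to-R [sample_series()] (values in ms).
#' @param start,end interval bounds in seconds.
#' @param session_gap_min gaps longer than this (minutes) split wear
#'   sessions.
#' @return Coverage fraction in `[0, 1]`; 0 when no samples fall inside.
#' @export
coverage_rr <- function(series, start, end, session_gap_min = 30) {
  if (end <= start) stop("zero-length interval")
  w <- series_window(series, start, end)
  if (!length(w$time)) return(0)
  gap <- session_gap_min * 60
  brk <- which(diff(w$time) > gap)
  s_idx <- c(1L, brk + 1L); e_idx <- c(brk, length(w$time))
  # measurement period: intersection of the interval with each session's
  # [first beat - its interval, last beat] span
  period <- sum(pmin(w$time[e_idx], end) -
                  pmax(w$time[s_idx] - w$value[s_idx] / 1000, start))
  if (period <= 0) return(0)
  min(1, sum(w$value) / 1000 / period)
}

#' Per-day and per-participant coverage of one modality
#'
#' Daily coverage is computed midnight-to-midnight (local time fixed per
#' participant); the participant-level value is the mean of the daily
#' values.
#'
#' @param series a cleaned [sample_series()].
#' @param days integer vector of day indices to evaluate (0-based from the
#'   recording epoch); default all days spanned by the data.
#' @param method `"sampled"` ([coverage_sampled()]) or `"rr"`
#'   ([coverage_rr()]).
#' @return `list(daily, participant)`: data.frame of per-day coverage and
#'   the participant mean.
#' @export
coverage_daily <- function(series, days = NULL,
                           method = c("sampled", "rr")) {
  method <- match.arg(method)
  if (is.null(days)) {
    if (!length(series$time)) return(list(daily = data.frame(), participant = NA_real_))
    # days are half-open (midnight, midnight]; a sample at exactly midnight
    # belongs to the day it closes
    days <- seq(floor((min(series$time) - 1e-9) / 86400),
                floor((max(series$time) - 1e-9) / 86400))
  }
  fn <- if (method == "rr") coverage_rr else coverage_sampled
  cov <- vapply(days, function(d) fn(series, d * 86400, (d + 1) * 86400), numeric(1))
  list(daily = data.frame(participant_id = series$participant_id,
                          modality = series$modality, day = days, coverage = cov),
       participant = mean(cov))
}

#' Expected daily PRO schedule
#'
#' Items and the daily questionnaire slots (local clock hours) at which a
#' response is expected: Likert fatigue/mood items at all four slots
#' (9:00, 13:00, 17:00, 21:00), sleep items in the morning only, sleepiness
#' at the three non-morning slots, daily-activity items in the evening.
#'
#' @return Named list: item -> numeric vector of slot hours.
#' @export
pro_schedule <- function() {
  list(physical_fatigue = c(9, 13, 17, 21),
       mental_fatigue   = c(9, 13, 17, 21),
       anxiousness      = c(9, 13, 17, 21),
       depression       = c(9, 13, 17, 21),
       pain             = c(9, 13, 17, 21),
       bed_time         = 9,
       wake_time        = 9,
       sleep_quality    = 9,
       sleepiness       = c(13, 17, 21),
       activity_physical = 21,
       activity_mental   = 21)
}

#' PRO coverage over wearable wear days
#'
#' Responses received divided by responses expected on wear days, per item.
#'
#' @param pro PRO data.frame with columns `item` and `day`.
#' @param wear_days integer vector of days the sensor was worn.
#' @param schedule item slot schedule, see [pro_schedule()].
#' @return data.frame with columns `item`, `n_received`, `n_expected`,
#'   `coverage` (NA when no wear days).
#' @export
coverage_pro <- function(pro, wear_days, schedule = pro_schedule()) {
  items <- intersect(names(schedule), unique(pro$item))
  if (!length(items)) items <- names(schedule)
  res <- lapply(items, function(it) {
    expected <- length(schedule[[it]]) * length(wear_days)
    received <- sum(pro$item == it & pro$day %in% wear_days)
    data.frame(item = it, n_received = received, n_expected = expected,
               coverage = if (expected > 0) min(1, received / expected) else NA_real_)
  })
  do.call(rbind, res)
}
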
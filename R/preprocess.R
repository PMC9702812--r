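#' Cleaning configuration: accepted ranges and contextual-outlier windows
#'
#' Physiological channels are cleaned in three fixed stages: (1) invalid
#' values (the manufacturer sentinel), (2) range outliers outside the
#' accepted physiological range, (3) contextual outliers that deviate from
#' their local sliding-window mean by more than a fractional threshold.
#' Steps and posture receive only sorting/deduplication and invalid-value
#' removal.
#'
#' Defaults: accepted ranges (inclusive on both ends) heart rate 30--200
#' beats/min, R-to-R 300--2000 ms, respiratory rate 4--60 breaths/min, skin
#' temperature 28--40 deg C; contextual thresholds 30% for all channels
#' except respiratory rate (50%, since respiration is under voluntary
#' control and legitimately more variable); time-centred sliding windows of
#' 1 min (HR, R-to-R), 3 min (respiratory rate) and 5 min (skin
#' temperature).
#'
#' @param accepted_range named list of `c(min, max)` per modality.
#' @param contextual_window named numeric, window length in minutes.
#' @param contextual_threshold named numeric, fractional deviation limit.
#' @param max_sleep_h plausibility bound (hours) for self-reported sleep
#'   duration, used by [repair_sleep_times()].
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(
    accepted_range = list(hr = c(30, 200), rr_interval = c(300, 2000),
                          resp_rate = c(4, 60), skin_t = c(28, 40)),
    contextual_window = c(hr = 1, rr_interval = 1, resp_rate = 3, skin_t = 5),
    contextual_threshold = c(hr = 0.30, rr_interval = 0.30,
                             resp_rate = 0.50, skin_t = 0.30),
    max_sleep_h = 16) {
  for (m in names(accepted_range)) {
    r <- accepted_range[[m]]
    if (r[1] >= r[2]) stop("accepted range min must be < max for ", m)
  }
  if (any(contextual_threshold <= 0)) stop("contextual thresholds must be > 0")
  structure(list(accepted_range = accepted_range,
                 contextual_window = contextual_window,
                 contextual_threshold = contextual_threshold,
                 max_sleep_h = max_sleep_h),
            class = "cleaning_config")
}

#' Sort samples by timestamp and drop duplicate timestamps
#'
#' For duplicated timestamps the first-seen record is kept. Idempotent.
#'
#' @param series a [sample_series()].
#' @return The sorted, deduplicated series.
#' @export
sort_dedup <- function(series) {
  ord <- order(series$time)           # stable: preserves first-seen on ties
  t <- series$time[ord]; v <- series$value[ord]
  keep <- c(TRUE, diff(t) > 0)
  sample_series(series$participant_id, series$modality, t[keep], v[keep],
                series$nominal_rate)
}

#' Remove invalid (sentinel-coded) samples
#'
#' @param series a [sample_series()].
#' @param sentinel the invalid-value code, see [invalid_sentinel()].
#' @return `list(series, removed)` with removed sample indices (relative to
#'   the input).
#' @export
filter_invalid <- function(series, sentinel = invalid_sentinel()) {
  bad <- which(series$value == sentinel | is.na(series$value))
  list(series = drop_idx(series, bad), removed = bad)
}

#' Remove physiologically unrealistic values (range outliers)
#'
#' A value survives iff `min <= v <= max` with the modality's accepted
#' range; bounds are inclusive on both ends.
#'
#' @param series a [sample_series()].
#' @param config a [cleaning_config()].
#' @return `list(series, removed)` with removed sample indices.
#' @export
filter_range <- function(series, config = cleaning_config()) {
  r <- config$accepted_range[[series$modality]]
  if (is.null(r)) stop("no accepted range configured for modality ", series$modality)
  bad <- which(series$value < r[1] | series$value > r[2])
  list(series = drop_idx(series, bad), removed = bad)
}

#' Remove contextual outliers against a centred sliding-window mean
#'
#' Each sample is compared to the mean `m` of all *other* samples within a
#' time-centred window (window boundaries inclusive): it is removed iff
#' `|x - m| / m > threshold`. A single pass is made over the range-filtered
#' series: window means are computed over values surviving the earlier
#' stages, not updated as contextual outliers are removed. Samples with no
#' in-window neighbour are kept, and samples whose window mean is
#' non-positive are kept but flagged rather than divided by.
#'
#' @param series a sorted, range-filtered [sample_series()].
#' @param config a [cleaning_config()].
#' @return `list(series, removed, flagged)`; indices relative to the input.
#' @export
filter_contextual <- function(series, config = cleaning_config()) {
  w <- config$contextual_window[[series$modality]] * 60
  thr <- config$contextual_threshold[[series$modality]]
  t <- series$time; v <- series$value; n <- length(v)
  if (n == 0) return(list(series = series, removed = integer(0), flagged = integer(0)))
  # neighbours j with |t_j - t_i| <= w/2, found by binary search on the
  # sorted time axis; cumulative sums give each window's mean in O(1)
  lo <- findInterval(t - w / 2, t, left.open = TRUE) + 1L
  hi <- findInterval(t + w / 2, t)
  cs <- c(0, cumsum(v))
  cnt <- hi - lo + 1L
  m <- (cs[hi + 1L] - cs[lo] - v) / (cnt - 1L)
  has_nb <- cnt > 1L
  flagged <- which(has_nb & m <= 0)
  bad <- which(has_nb & m > 0 & abs(v - m) / m > thr)
  list(series = drop_idx(series, bad), removed = bad, flagged = flagged)
}

#' Interpolate repaired R-to-R values at range/contextual outlier positions
#'
#' Range and contextual outliers (classes 2--3) of the R-to-R channel are
#' replaced by values linearly interpolated in time between the nearest
#' surviving neighbours, so that heart-rate-variability analysis sees a
#' continuous tachogram. Invalid (class 1) positions remain gaps. Outliers
#' at a series boundary, with a surviving neighbour on one side only, are
#' dropped rather than extrapolated. Interpolation writes only at removed
#' positions; surviving samples and their timestamps are untouched.
#'
#' @param series the cleaned (post-filter) R-to-R [sample_series()].
#' @param removed_times timestamps of the removed class-2/3 samples.
#' @return `list(series, interpolated)` where `interpolated` counts values
#'   written back.
#' @export
repair_rr <- function(series, removed_times) {
  stopifnot(series$modality == "rr_interval")
  if (length(removed_times) == 0 || length(series$time) < 2)
    return(list(series = series, interpolated = 0L))
  inside <- removed_times > min(series$time) & removed_times < max(series$time)
  rt <- removed_times[inside]
  if (!length(rt)) return(list(series = series, interpolated = 0L))
  vals <- stats::approx(series$time, series$value, xout = rt, method = "linear")$y
  t <- c(series$time, rt); v <- c(series$value, vals)
  ord <- order(t)
  list(series = sample_series(series$participant_id, series$modality,
                              t[ord], v[ord], series$nominal_rate),
       interpolated = length(rt))
}

#' Clean one series through the full fixed-order pipeline
#'
#' Order: sort/deduplicate, drop invalid values, drop range outliers, drop
#' contextual outliers (single pass, window means over values surviving the
#' earlier stages). For the R-to-R channel, range and contextual outlier
#' positions are then re-filled by linear interpolation ([repair_rr()]).
#' Steps and posture are only sorted/deduplicated and stripped of invalid
#' values.
#'
#' @param series a raw [sample_series()].
#' @param config a [cleaning_config()].
#' @return `list(series, report, removed)` where `report` is a one-row
#'   data.frame of per-class counts/fractions and `removed` holds the
#'   removed timestamps per class.
#' @export
clean_series <- function(series, config = cleaning_config()) {
  s <- sort_dedup(series)
  n0 <- length(s$time)
  inv <- filter_invalid(s)
  t_invalid <- s$time[inv$removed]
  s <- inv$series
  if (series$modality %in% c("steps", "posture")) {
    rng_t <- numeric(0); ctx_t <- numeric(0); n_interp <- 0L
  } else {
    rng <- filter_range(s, config)
    rng_t <- s$time[rng$removed]
    s <- rng$series
    ctx <- filter_contextual(s, config)
    ctx_t <- s$time[ctx$removed]
    s <- ctx$series
    n_interp <- 0L
    if (series$modality == "rr_interval") {
      rep_ <- repair_rr(s, c(rng_t, ctx_t))
      s <- rep_$series
      n_interp <- rep_$interpolated
    }
  }
  report <- data.frame(
    modality = series$modality, n_raw = n0,
    n_invalid = length(t_invalid), n_range = length(rng_t),
    n_contextual = length(ctx_t),
    frac_invalid = if (n0) length(t_invalid) / n0 else 0,
    frac_range = if (n0) length(rng_t) / n0 else 0,
    frac_contextual = if (n0) length(ctx_t) / n0 else 0,
    n_interpolated = n_interp, stringsAsFactors = FALSE)
  list(series = s, report = report,
       removed = list(invalid = t_invalid, range = rng_t, contextual = ctx_t))
}

#' Clean all modalities of one participant bundle
#'
#' @param bundle named list of [sample_series()] (as produced by
#'   [generate_participant()]).
#' @param config a [cleaning_config()].
#' @return `list(series, report)`: cleaned series list and the combined
#'   cleaning report (one row per modality).
#' @export
clean_bundle <- function(bundle, config = cleaning_config()) {
  out <- lapply(bundle, clean_series, config = config)
  list(series = lapply(out, `[[`, "series"),
       report = do.call(rbind, lapply(out, `[[`, "report")))
}

#' Repair 12-hour shifts in self-reported sleep times
#'
#' Bed and wake times are entered on a 24-h clock interface that users
#' sometimes misread by 12 hours, especially for late-evening bedtimes. For
#' each morning report the naive interpretation puts the bedtime on the
#' previous evening when it exceeds the wake time, else on the wake-up day;
#' if the implied sleep duration is non-positive or exceeds `max_sleep_h`,
#' the bedtime is shifted by 12 h provided that yields a duration in
#' `(0, max_sleep_h]`; otherwise the pair is marked unusable.
#'
#' @param pro a PRO data.frame (see [generate_participant()]) containing
#'   `bed_time` / `wake_time` rows with values as decimal hours in `[0, 24)`.
#' @param max_sleep_h plausibility bound in hours.
#' @return `list(pro, shifted, unusable)`: the repaired table, the count of
#'   shifted bedtimes, and row indices of unusable pairs (both rows of each
#'   pair are flagged via the added logical column `sleep_unusable`).
#' @export
repair_sleep_times <- function(pro, max_sleep_h = 16) {
  pro$sleep_unusable <- FALSE
  beds <- which(pro$item == "bed_time")
  shifted <- 0L
  for (i in beds) {
    j <- which(pro$item == "wake_time" &
                 pro$participant_id == pro$participant_id[i] &
                 pro$day == pro$day[i])
    if (!length(j)) next
    j <- j[1]
    b <- pro$value[i]; w <- pro$value[j]
    dur <- naive_sleep_duration(b, w)
    if (dur > 0 && dur <= max_sleep_h) next
    b2 <- (b + 12) %% 24
    dur2 <- naive_sleep_duration(b2, w)
    if (dur2 > 0 && dur2 <= max_sleep_h) {
      pro$value[i] <- b2
      shifted <- shifted + 1L
    } else {
      pro$sleep_unusable[c(i, j)] <- TRUE
    }
  }
  list(pro = pro, shifted = shifted,
       unusable = which(pro$sleep_unusable & pro$item == "bed_time"))
}

# Naive same/next-day reading: bedtime after the wake hour belongs to the
# previous evening.
naive_sleep_duration <- function(bed, wake) {
  if (bed > wake) (24 - bed) + wake else wake - bed
}

# Drop samples by index, keeping series metadata.
drop_idx <- function(series, idx) {
  if (!length(idx)) return(series)
  sample_series(series$participant_id, series$modality,
                series$time[-idx], series$value[-idx], series$nominal_rate)
}
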
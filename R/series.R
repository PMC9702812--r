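#' Timestamped sample series for one participant and one modality
#'
#' The raw and cleaned signal carrier used throughout the pipeline. A
#' `sample_series` holds one modality's samples for one participant as two
#' parallel numeric vectors: `time` (seconds since the recording epoch, UTC)
#' and `value` (modality units). Sampling is nominally regular (0.25 Hz for
#' the ECG-derived channels and skin temperature, 1 Hz for steps and
#' posture) but wear gaps and cleaning leave the series irregular, so all
#' downstream computations are time-based rather than index-based.
#'
#' @param participant_id character scalar, participant identifier.
#' @param modality one of `"hr"` (beats/min), `"rr_interval"` (ms),
#'   `"resp_rate"` (breaths/min), `"skin_t"` (deg C), `"steps"`
#'   (count/sample), `"posture"` (class code, see [posture_codes()]).
#' @param time numeric vector of sample times in seconds (UTC epoch offset).
#' @param value numeric vector of sample values, same length as `time`.
#' @param nominal_rate nominal sampling rate in Hz; defaults to the device
#'   rate for the modality (0.25 Hz physiological channels, 1 Hz activity).
#' @return An object of class `sample_series`.
#' @export
sample_series <- function(participant_id, modality, time, value,
                          nominal_rate = default_rate(modality)) {
  modality <- match.arg(modality, names(MODALITIES))
  stopifnot(length(time) == length(value), is.numeric(time))
  structure(
    list(participant_id = as.character(participant_id),
         modality = modality,
         time = as.numeric(time),
         value = as.numeric(value),
         nominal_rate = nominal_rate),
    class = "sample_series")
}

# Modality registry: device sampling rates and units.
MODALITIES <- list(
  hr          = list(rate = 0.25, unit = "beats/min"),
  rr_interval = list(rate = 0.25, unit = "ms"),
  resp_rate   = list(rate = 0.25, unit = "breaths/min"),
  skin_t      = list(rate = 0.25, unit = "degC"),
  steps       = list(rate = 1,    unit = "count"),
  posture     = list(rate = 1,    unit = "class")
)

#' Nominal device sampling rate for a modality
#' @param modality modality name, see [sample_series()].
#' @return Rate in Hz.
#' @export
default_rate <- function(modality) MODALITIES[[match.arg(modality, names(MODALITIES))]]$rate

#' Posture class codes
#'
#' Posture is emitted by the device as a categorical class at 1 Hz. Codes:
#' 1 = lying, 2 = sitting, 3 = standing, 4 = walking.
#' @return Named integer vector of class codes.
#' @export
posture_codes <- function() c(lying = 1L, sitting = 2L, standing = 3L, walking = 4L)

#' Manufacturer-style invalid-value sentinel
#'
#' Unsuccessfully measured samples are marked with a single documented
#' out-of-band code. All physiological channels take strictly positive
#' values, so a negative sentinel is unambiguous.
#' @return The sentinel value (-1).
#' @export
invalid_sentinel <- function() -1

#' @export
print.sample_series <- function(x, ...) {
  cat(sprintf("<sample_series> %s / %s: %d samples", x$participant_id,
              x$modality, length(x$time)))
  if (length(x$time)) {
    cat(sprintf(", t = [%.0f, %.0f] s, nominal %.2g Hz",
                min(x$time), max(x$time), x$nominal_rate))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.sample_series <- function(x, ...) {
  data.frame(participant_id = rep(x$participant_id, length(x$time)),
             modality = rep(x$modality, length(x$time)),
             time = x$time, value = x$value)
}

#' @export
length.sample_series <- function(x) length(x$time)

#' Restrict a series to a half-open time interval (start, end]
#'
#' @param series a [sample_series()].
#' @param start,end interval bounds in seconds; samples with
#'   `start < time <= end` are kept.
#' @return A `sample_series` with the subset of samples.
#' @export
series_window <- function(series, start, end) {
  # series times are sorted after cleaning; findInterval keeps this O(log n)
  lo <- findInterval(start, series$time) + 1L
  hi <- findInterval(end, series$time)
  idx <- if (hi >= lo) lo:hi else integer(0)
  sample_series(series$participant_id, series$modality,
                series$time[idx], series$value[idx], series$nominal_rate)
}

#' Write a sample series as tidy two-column CSV
#'
#' One file per participant-modality, columns `timestamp` (ISO-8601 UTC)
#' and `value`.
#' @param series a [sample_series()].
#' @param path output file path.
#' @param epoch POSIXct origin the numeric times are measured from.
#' @export
write_series_csv <- function(series, path, epoch = as.POSIXct("2021-01-01", tz = "UTC")) {
  ts <- format(epoch + series$time, "%Y-%m-%dT%H:%M:%OS2Z", tz = "UTC")
  utils::write.csv(data.frame(timestamp = ts, value = series$value),
                   path, row.names = FALSE, quote = FALSE)
}

#' Read a tidy two-column CSV back into a sample series
#'
#' @param path file written by [write_series_csv()].
#' @param participant_id,modality series identity.
#' @param epoch POSIXct origin for the numeric time axis.
#' @return A [sample_series()].
#' @export
read_series_csv <- function(path, participant_id, modality,
                            epoch = as.POSIXct("2021-01-01", tz = "UTC")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  t <- as.numeric(as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")) -
    as.numeric(epoch)
  sample_series(participant_id, modality, t, df$value)
}
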
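#' Aggregate one 2-h pre-PRO window
#'
#' Computes the statistical aggregates (mean, SD, min, max) of each
#' physiological channel over the half-open window `(anchor - 2h, anchor]`
#' ending at the PRO submission time, the per-channel coverage inside the
#' window, and the full HRV feature battery on the window's NN series.
#' Empty channels yield NA aggregates with coverage 0.
#'
#' @param series named list of cleaned [sample_series()] (needs `hr`,
#'   `rr_interval`, `resp_rate`, `skin_t`).
#' @param anchor_time PRO submission time (seconds).
#' @param window_s window length in seconds (default 7200).
#' @return One-row data.frame: `participant_id`, `anchor_time`, per-channel
#'   `<mod>_mean/_sd/_min/_max/_coverage`, and the HRV feature columns.
#' @export
aggregate_window <- function(series, anchor_time, window_s = 7200) {
  start <- anchor_time - window_s
  out <- list(participant_id = series$hr$participant_id, anchor_time = anchor_time)
  for (m in c("hr", "resp_rate", "skin_t")) {
    w <- series_window(series[[m]], start, anchor_time)
    out <- c(out, channel_aggs(m, w$value),
             stats::setNames(list(coverage_sampled(series[[m]], start, anchor_time)),
                             paste0(m, "_coverage")))
  }
  wrr <- series_window(series$rr_interval, start, anchor_time)
  out <- c(out, channel_aggs("rr_interval", wrr$value),
           list(rr_interval_coverage = coverage_rr(series$rr_interval, start, anchor_time)))
  out <- c(out, hrv_features(wrr))
  as.data.frame(out, stringsAsFactors = FALSE)
}

channel_aggs <- function(m, v) {
  if (length(v) == 0)
    return(stats::setNames(as.list(rep(NA_real_, 4)),
                           paste0(m, c("_mean", "_sd", "_min", "_max"))))
  stats::setNames(list(mean(v), stats::sd(v), min(v), max(v)),
                  paste0(m, c("_mean", "_sd", "_min", "_max")))
}

#' Build the aggregate table for all of a participant's PRO anchors
#'
#' One row per distinct PRO submission time (all items submitted together
#' share a window).
#'
#' @param series cleaned series list.
#' @param pro the participant's PRO table.
#' @param window_s window length in seconds.
#' @return data.frame of [aggregate_window()] rows.
#' @export
build_aggregates <- function(series, pro, window_s = 7200) {
  anchors <- sort(unique(pro$time))
  if (!length(anchors)) return(NULL)
  do.call(rbind, lapply(anchors, function(a) aggregate_window(series, a, window_s)))
}

#' Detect the least-active 5-hour (L5) rest window in a noon-to-noon span
#'
#' Candidate 5-h windows start at 1-min resolution; a candidate must have
#' a step total of at most `max_steps` (100) and a lying fraction of at
#' least `min_lying` (80%, over the posture samples present, so wear gaps
#' do not dilute the denominator). Overlapping runs of candidates are
#' merged and resolved to the window maximising the lying fraction, with
#' ties broken by lower step total and then earlier start. The search span
#' runs noon to noon so that nocturnal rest is not bisected at midnight.
#'
#' Candidate windows are confined to the recorded span and must contain at
#' least `min_present` of their nominal posture samples, so a window
#' cannot be declared "rest" on a sliver of data at a recording edge.
#'
#' @param steps,posture cleaned 1 Hz [sample_series()].
#' @param span_start,span_end search span (seconds); typically
#'   `noon(day)` to `noon(day+1)`.
#' @param window_s window length (default 5 h).
#' @param max_steps,min_lying candidate thresholds.
#' @param min_present minimum fraction of nominal posture samples a
#'   candidate window must contain.
#' @return One-row data.frame (`participant_id`, `start`, `end`,
#'   `step_total`, `lying_frac`) or `NULL` when no candidate exists.
#' @export
detect_l5 <- function(steps, posture, span_start, span_end,
                      window_s = 5 * 3600, max_steps = 100, min_lying = 0.80,
                      min_present = 0.5) {
  if (span_end - span_start < window_s) return(NULL)
  pw <- series_window(posture, span_start, span_end)
  sw <- series_window(steps, span_start, span_end)
  if (!length(pw$time)) return(NULL)
  lo_t <- max(span_start, min(pw$time) - 1)
  hi_t <- min(span_end, max(pw$time))
  if (hi_t - lo_t < window_s) return(NULL)
  starts <- seq(lo_t, hi_t - window_s, by = 60)
  # cumulative sums over the span-restricted samples
  cs_steps <- c(0, cumsum(sw$value))
  lying <- as.numeric(pw$value == posture_codes()[["lying"]])
  cs_lying <- c(0, cumsum(lying))
  # windows are half-open (start, start + w]
  s_lo <- findInterval(starts, sw$time) + 1L
  s_hi <- findInterval(starts + window_s, sw$time)
  step_tot <- cs_steps[s_hi + 1L] - cs_steps[s_lo]
  p_lo <- findInterval(starts, pw$time) + 1L
  p_hi <- findInterval(starts + window_s, pw$time)
  p_n <- p_hi - p_lo + 1L
  lying_frac <- ifelse(p_n > 0, (cs_lying[p_hi + 1L] - cs_lying[p_lo]) / p_n, NA)
  ok <- which(!is.na(lying_frac) & p_n >= min_present * window_s *
                posture$nominal_rate & step_tot <= max_steps &
                lying_frac >= min_lying)
  if (!length(ok)) return(NULL)
  # winner: max lying fraction, then min steps, then earliest start
  # (the global winner is necessarily its overlap-run's winner)
  best <- ok[order(-lying_frac[ok], step_tot[ok], starts[ok])][1]
  data.frame(participant_id = posture$participant_id,
             start = starts[best], end = starts[best] + window_s,
             step_total = step_tot[best], lying_frac = lying_frac[best])
}

#' Detect L5 windows for every day of a recording
#'
#' @param steps,posture cleaned 1 Hz series.
#' @param days integer day indices (0-based); default all full spans.
#' @param ... passed to [detect_l5()].
#' @return data.frame of detected windows (possibly 0 rows).
#' @export
detect_l5_all <- function(steps, posture, days = NULL, ...) {
  if (is.null(days)) {
    if (!length(posture$time)) return(NULL)
    d0 <- floor((min(posture$time) - 43200) / 86400)
    d1 <- floor((max(posture$time) - 43200) / 86400)
    days <- seq(d0, d1)
  }
  out <- lapply(days, function(d)
    detect_l5(steps, posture, d * 86400 + 43200, (d + 1) * 86400 + 43200, ...))
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' L5 normalization parameters
#'
#' For each raw channel, the mean and SD (n-1 estimator) of its samples
#' inside the L5 window; additionally the window-level HRV features, used
#' both for rest-state group summaries and for normalizing HRV feature
#' aggregates across windows. Channels absent from the window yield NA
#' parameters.
#'
#' @param l5 one row from [detect_l5()].
#' @param series cleaned series list.
#' @return One-row data.frame: `<mod>_mu`, `<mod>_sigma` per channel plus
#'   the window's HRV features (prefixed `hrv_`), `start`, `end`.
#' @export
l5_params <- function(l5, series) {
  out <- list(participant_id = l5$participant_id, start = l5$start, end = l5$end)
  for (m in c("hr", "rr_interval", "resp_rate", "skin_t")) {
    w <- series_window(series[[m]], l5$start, l5$end)
    if (length(w$value) >= 2) {
      out[[paste0(m, "_mu")]] <- mean(w$value)
      out[[paste0(m, "_sigma")]] <- stats::sd(w$value)
    } else {
      out[[paste0(m, "_mu")]] <- NA_real_
      out[[paste0(m, "_sigma")]] <- NA_real_
    }
  }
  wrr <- series_window(series$rr_interval, l5$start, l5$end)
  hf <- hrv_features(wrr)
  names(hf) <- paste0("l5_", names(hf))
  as.data.frame(c(out, hf), stringsAsFactors = FALSE)
}

# Feature -> (reference mu/sigma source, coverage column) mapping used by
# normalization and the association filters.
feature_map <- function() {
  raw <- expand.grid(m = c("hr", "rr_interval", "resp_rate", "skin_t"),
                     s = c("mean", "sd", "min", "max"), stringsAsFactors = FALSE)
  raw_feats <- paste0(raw$m, "_", raw$s)
  data.frame(
    feature = c(raw_feats, hrv_feature_names()),
    channel = c(raw$m, rep("rr_interval", length(hrv_feature_names()))),
    kind = c(rep("raw", length(raw_feats)), rep("hrv", length(hrv_feature_names()))),
    stringsAsFactors = FALSE)
}

#' Normalize feature aggregates against L5 rest parameters
#'
#' Each aggregate `x` becomes `(x - mu_L5) / sigma_L5`. Raw-channel
#' aggregates use the channel's in-window mean/SD; HRV feature aggregates
#' use the distribution of the window-level HRV feature across the
#' participant's L5 windows. Variant `"a"` takes the parameters from the
#' nearest L5 window ending before the aggregate window starts (aggregates
#' with no previous L5 window are excluded); variant `"b"` averages mu and
#' sigma over all of the participant's L5 windows. Features with
#' `sigma_L5 = 0` or missing parameters are set NA.
#'
#' @param aggs aggregate table from [build_aggregates()].
#' @param l5p L5 parameter table from [l5_params()] (one row per window).
#' @param variant `"a"` (latest previous window) or `"b"`
#'   (participant-mean parameters).
#' @return data.frame shaped like `aggs` with normalized feature columns
#'   (coverage columns and identifiers untouched) plus `norm_variant`.
#' @export
normalize_aggregates <- function(aggs, l5p, variant = c("b", "a")) {
  variant <- match.arg(variant)
  if (is.null(aggs) || !nrow(aggs)) return(NULL)
  if (is.null(l5p) || !nrow(l5p)) return(NULL)
  fm <- feature_map()
  fm <- fm[fm$feature %in% names(aggs), ]
  out <- aggs
  keep <- rep(TRUE, nrow(aggs))
  for (i in seq_len(nrow(aggs))) {
    if (variant == "a") {
      prev <- which(l5p$end <= aggs$anchor_time[i] - 7200)
      if (!length(prev)) { keep[i] <- FALSE; next }
      ref <- l5p[prev[which.max(l5p$end[prev])], ]
    }
    for (k in seq_len(nrow(fm))) {
      f <- fm$feature[k]
      x <- aggs[[f]][i]
      if (fm$kind[k] == "raw") {
        if (variant == "a") {
          mu <- ref[[paste0(fm$channel[k], "_mu")]]
          sg <- ref[[paste0(fm$channel[k], "_sigma")]]
        } else {
          mu <- mean(l5p[[paste0(fm$channel[k], "_mu")]], na.rm = TRUE)
          sg <- mean(l5p[[paste0(fm$channel[k], "_sigma")]], na.rm = TRUE)
        }
      } else {
        vals <- l5p[[paste0("l5_", f)]]
        sg <- stats::sd(vals[!is.na(vals)])
        mu <- if (variant == "a") ref[[paste0("l5_", f)]] else mean(vals, na.rm = TRUE)
      }
      out[[f]][i] <- if (is.null(mu) || is.null(sg) || !length(mu) || is.na(mu) ||
                         is.na(sg) || sg == 0) NA_real_ else (x - mu) / sg
    }
  }
  out <- out[keep, , drop = FALSE]
  if (nrow(out)) out$norm_variant <- variant
  out
}

#' Agreement between detected L5 windows and reported sleep
#'
#' Compares each detected L5 window with the participant's repaired
#' self-reported sleep interval for the same night: the fraction of L5
#' windows entirely within the reported sleep time, the fractions whose
#' start/end fall within it, and the same three fractions with a
#' `tol_min`-minute tolerance.
#'
#' @param l5 data.frame of L5 windows (`start`, `end` seconds).
#' @param sleep data.frame of reported sleep intervals (`start`, `end`).
#' @param tol_min tolerance in minutes for the relaxed criterion.
#' @return One-row data.frame of agreement fractions and the number of
#'   compared windows.
#' @export
l5_sleep_agreement <- function(l5, sleep, tol_min = 30) {
  if (is.null(l5) || !nrow(l5) || is.null(sleep) || !nrow(sleep))
    return(data.frame(n = 0L, within = NA_real_, start_within = NA_real_,
                      end_within = NA_real_, within_tol = NA_real_,
                      start_within_tol = NA_real_, end_within_tol = NA_real_))
  tol <- tol_min * 60
  # match each L5 window to the sleep interval with maximal overlap
  res <- t(vapply(seq_len(nrow(l5)), function(i) {
    ov <- pmin(l5$end[i], sleep$end) - pmax(l5$start[i], sleep$start)
    j <- which.max(ov)
    if (ov[j] <= 0) return(rep(NA_real_, 6))
    c(l5$start[i] >= sleep$start[j] && l5$end[i] <= sleep$end[j],
      l5$start[i] >= sleep$start[j] && l5$start[i] <= sleep$end[j],
      l5$end[i] >= sleep$start[j] && l5$end[i] <= sleep$end[j],
      l5$start[i] >= sleep$start[j] - tol && l5$end[i] <= sleep$end[j] + tol,
      l5$start[i] >= sleep$start[j] - tol && l5$start[i] <= sleep$end[j] + tol,
      l5$end[i] >= sleep$start[j] - tol && l5$end[i] <= sleep$end[j] + tol)
  }, numeric(6)))
  ok <- stats::complete.cases(res)
  data.frame(n = sum(ok), within = mean(res[ok, 1]),
             start_within = mean(res[ok, 2]), end_within = mean(res[ok, 3]),
             within_tol = mean(res[ok, 4]), start_within_tol = mean(res[ok, 5]),
             end_within_tol = mean(res[ok, 6]))
}
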
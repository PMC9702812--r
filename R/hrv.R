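#' Malik-rule normal-to-normal (NN) correction of an R-to-R segment
#'
#' Ectopic beats and residual artefacts are removed from a cleaned R-to-R
#' segment before HRV analysis: scanning in time order, an interval that
#' deviates by more than `tol` (default 20%) from the previous *accepted*
#' interval is replaced by linear interpolation in time between that
#' accepted interval and the next interval that is itself within `tol` of
#' it (interpolation is beat-index based: the timestamps of a corrupted run
#' are distorted by the very artefact being repaired). Measuring against
#' the accepted (not raw previous) interval prevents a drifting artefact
#' run from legitimising itself. A trailing run with no acceptable
#' successor is dropped.
#'
#' @param rr an R-to-R [sample_series()] segment (values in ms) or a
#'   two-column list with `time`/`value`.
#' @param tol fractional deviation tolerance.
#' @return `list(time, value, replaced)` — the NN series and the count of
#'   replaced intervals. Fewer than 3 input intervals is an error (segment
#'   rejected).
#' @export
malik_correct <- function(rr, tol = 0.20) {
  t <- rr$time; v <- rr$value
  n <- length(v)
  if (n < 3) stop("segment rejected: fewer than 3 R-to-R intervals")
  out <- v
  replaced <- 0L
  drop_from <- NA_integer_
  prev <- v[1]
  i <- 2L
  while (i <= n) {
    if (abs(v[i] - prev) / prev <= tol) {
      prev <- out[i]
      i <- i + 1L
      next
    }
    j <- i + 1L
    while (j <= n && abs(v[j] - prev) / prev > tol) j <- j + 1L
    if (j > n) {                      # boundary: no acceptable successor
      drop_from <- i
      break
    }
    idx <- i:(j - 1L)
    out[idx] <- prev + (v[j] - prev) * (idx - (i - 1L)) / (j - (i - 1L))
    replaced <- replaced + length(idx)
    prev <- v[j]
    i <- j + 1L
  }
  keep <- if (is.na(drop_from)) seq_len(n) else seq_len(drop_from - 1L)
  list(time = t[keep], value = out[keep], replaced = replaced)
}

#' Time-domain HRV features
#'
#' Means, dispersion and difference statistics of the NN tachogram.
#' Standard deviations use the unbiased (n-1) estimator; NN50/NN20 count
#' absolute successive differences strictly greater than 50/20 ms; the
#' HRV HR block is computed on the beatwise instantaneous rate 60000/NN.
#'
#' @param nn NN series from [malik_correct()] (or any list with `value` ms).
#' @return Named list: nn_mean, nn_cv, nn_sd, nn_median, nn_range, rmssd,
#'   cvsd, sdsd, nn50, nn20, pnn50, pnn20, hrv_hr_mean, hrv_hr_sd,
#'   hrv_hr_min, hrv_hr_max.
#' @export
hrv_time_domain <- function(nn) {
  v <- nn$value
  if (length(v) < 3) stop("insufficient intervals for time-domain features")
  d <- diff(v)
  hr <- 60000 / v
  list(nn_mean = mean(v), nn_cv = stats::sd(v) / mean(v), nn_sd = stats::sd(v),
       nn_median = stats::median(v), nn_range = max(v) - min(v),
       rmssd = sqrt(mean(d^2)),
       cvsd = sqrt(mean(d^2)) / mean(v),
       sdsd = stats::sd(d),
       nn50 = sum(abs(d) > 50), nn20 = sum(abs(d) > 20),
       pnn50 = 100 * mean(abs(d) > 50), pnn20 = 100 * mean(abs(d) > 20),
       hrv_hr_mean = mean(hr), hrv_hr_sd = stats::sd(hr),
       hrv_hr_min = min(hr), hrv_hr_max = max(hr))
}

#' Frequency-domain HRV features
#'
#' The irregular NN tachogram is interpolated to an even 4 Hz grid (cubic
#' spline), linearly detrended, and analysed with a Welch periodogram
#' (256-s Hann segments, 50% overlap). Band powers (ms^2) are integrated
#' over VLF 0.003--0.04 Hz, LF 0.04--0.15 Hz and HF 0.15--0.40 Hz; total
#' power is their sum; LFnu = LF/(LF+HF) and HFnu = HF/(LF+HF).
#'
#' Segments shorter than `min_duration` seconds, or whose interpolation
#' grid has more than `max_gap_frac` of its points further than `gap_tol`
#' seconds from any observed beat, yield all-NA features.
#'
#' @param nn NN series (`time` s at beats, `value` ms).
#' @param fs interpolation grid rate (Hz).
#' @param min_duration minimum segment span in seconds (default 300 = 5 min).
#' @param gap_tol,max_gap_frac gap tolerance; see Description.
#' @return Named list: vlf, lf, hf, total_power, lf_hf, lfnu, hfnu.
#' @export
hrv_freq_domain <- function(nn, fs = 4, min_duration = 300,
                            gap_tol = 5, max_gap_frac = 0.20) {
  na <- list(vlf = NA_real_, lf = NA_real_, hf = NA_real_,
             total_power = NA_real_, lf_hf = NA_real_,
             lfnu = NA_real_, hfnu = NA_real_)
  t <- nn$time; v <- nn$value
  if (length(v) < 4 || (max(t) - min(t)) < min_duration) return(na)
  grid <- seq(min(t), max(t), by = 1 / fs)
  # gap screen: distance from each grid point to the nearest beat
  nearest <- findInterval(grid, t)
  lo <- pmax(nearest, 1L)
  hi <- pmin(nearest + 1L, length(t))
  dist <- pmin(abs(grid - t[lo]), abs(grid - t[hi]))
  if (mean(dist > gap_tol) > max_gap_frac) return(na)
  x <- stats::spline(t, v, xout = grid, method = "fmm")$y
  x <- detrend_linear(x)
  ps <- welch_psd(x, fs = fs, nperseg = min(256 * fs, length(x)))
  band <- function(lo, hi) {
    sel <- ps$freq > lo & ps$freq <= hi
    sum(ps$psd[sel]) * (ps$freq[2] - ps$freq[1])
  }
  vlf <- band(0.003, 0.04); lf <- band(0.04, 0.15); hf <- band(0.15, 0.40)
  list(vlf = vlf, lf = lf, hf = hf, total_power = vlf + lf + hf,
       lf_hf = if (hf > 0) lf / hf else NA_real_,
       lfnu = if (lf + hf > 0) lf / (lf + hf) else NA_real_,
       hfnu = if (lf + hf > 0) hf / (lf + hf) else NA_real_)
}

#' Geometric and non-linear (Poincare) HRV features
#'
#' Triangular index uses the NN histogram with the conventional 1/128-s
#' (7.8125 ms) bin width: the number of intervals divided by the modal bin
#' count. Poincare descriptors use SD1 = sqrt(var(diff NN)/2) and
#' SD2 = sqrt(2 var(NN) - var(diff NN)/2) (unbiased variances), with
#' CSI = SD2/SD1, CVI = log10((4 SD1)(4 SD2)) and the modified sympathetic
#' index mCSI = (4 SD2)^2 / (4 SD1) (longitudinal^2 / transverse). When
#' SD1 = 0 the sympathetic indices are undefined and reported NA.
#'
#' @param nn NN series (`value` ms).
#' @param min_n minimum intervals for the triangular index.
#' @return Named list: triangular_index, csi, mcsi, cvi, sd1, sd2, sd2_sd1.
#' @export
hrv_geometric_nonlinear <- function(nn, min_n = 20) {
  v <- nn$value
  d <- diff(v)
  if (length(v) < 3) stop("insufficient intervals for non-linear features")
  tri <- NA_real_
  if (length(v) >= min_n) {
    bw <- 1000 / 128
    counts <- tabulate(floor(v / bw) + 1L)
    tri <- length(v) / max(counts)
  }
  vd <- stats::var(d)
  vn <- stats::var(v)
  sd1 <- sqrt(vd / 2)
  sd2 <- sqrt(max(0, 2 * vn - vd / 2))
  if (sd1 > 0) {
    csi <- sd2 / sd1
    mcsi <- (4 * sd2)^2 / (4 * sd1)
  } else {
    csi <- NA_real_; mcsi <- NA_real_
  }
  cvi <- if (sd1 > 0 && sd2 > 0) log10((4 * sd1) * (4 * sd2)) else NA_real_
  list(triangular_index = tri, csi = csi, mcsi = mcsi, cvi = cvi,
       sd1 = sd1, sd2 = sd2, sd2_sd1 = if (sd1 > 0) sd2 / sd1 else NA_real_)
}

#' Full HRV feature battery on one R-to-R segment
#'
#' Applies [malik_correct()] and computes all time-domain,
#' frequency-domain, geometric and non-linear features. Segments that are
#' rejected (fewer than 3 intervals) yield all-NA features.
#'
#' @param rr R-to-R segment (`time`/`value`).
#' @param ... passed to [hrv_freq_domain()].
#' @return Named list of all features plus `nn_replaced` (Malik
#'   replacement count).
#' @export
hrv_features <- function(rr, ...) {
  if (length(rr$value) < 3) {
    feats <- c(hrv_feature_names(), "nn_replaced")
    return(stats::setNames(as.list(rep(NA_real_, length(feats))), feats))
  }
  nn <- malik_correct(rr)
  c(hrv_time_domain(nn), hrv_freq_domain(nn, ...),
    hrv_geometric_nonlinear(nn), list(nn_replaced = nn$replaced))
}

#' Names of the HRV feature columns
#' @return Character vector of feature names in canonical order.
#' @export
hrv_feature_names <- function() {
  c("nn_mean", "nn_cv", "nn_sd", "nn_median", "nn_range", "rmssd", "cvsd",
    "sdsd", "nn50", "nn20", "pnn50", "pnn20", "hrv_hr_mean", "hrv_hr_sd",
    "hrv_hr_min", "hrv_hr_max", "vlf", "lf", "hf", "total_power", "lf_hf",
    "lfnu", "hfnu", "triangular_index", "csi", "mcsi", "cvi", "sd1", "sd2",
    "sd2_sd1")
}
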
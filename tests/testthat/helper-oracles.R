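# Independent brute-force oracles and fixture builders shared across tests.
# Oracles deliberately use direct per-sample recomputation (explicit loops,
# stats::lm, textbook formulas) rather than the package's vectorised paths.

mk_series <- function(value, time = seq_along(value) * 4, modality = "hr",
                      id = "P1", rate = 0.25) {
  sample_series(id, modality, time, value, rate)
}

# Recompute-every-window contextual outlier scan: for each sample, the mean
# of all other samples within the time-centred window.
contextual_oracle <- function(time, value, window_s, threshold) {
  n <- length(value)
  out <- logical(n)
  for (i in seq_len(n)) {
    nb <- which(abs(time - time[i]) <= window_s / 2)
    nb <- nb[nb != i]
    if (!length(nb)) next
    m <- mean(value[nb])
    if (m > 0 && abs(value[i] - m) / m > threshold) out[i] <- TRUE
  }
  which(out)
}

# Full three-class cleaning oracle (invalid -> range -> contextual), on a
# sorted/deduplicated series.
cleaning_oracle <- function(time, value, modality, config = cleaning_config()) {
  inv <- which(value == invalid_sentinel() | is.na(value))
  keep1 <- setdiff(seq_along(value), inv)
  r <- config$accepted_range[[modality]]
  rng <- keep1[value[keep1] < r[1] | value[keep1] > r[2]]
  keep2 <- setdiff(keep1, rng)
  ctx_local <- contextual_oracle(time[keep2], value[keep2],
                                 config$contextual_window[[modality]] * 60,
                                 config$contextual_threshold[[modality]])
  list(invalid = inv, range = rng, contextual = keep2[ctx_local],
       surviving = setdiff(keep2, keep2[ctx_local]))
}

# Exhaustive 1-min-start L5 scan with direct per-window sums.
l5_oracle <- function(steps, posture, span_start, span_end, window_s = 18000,
                      max_steps = 100, min_lying = 0.80, min_present = 0.5) {
  lo_t <- max(span_start, min(posture$time) - 1)
  hi_t <- min(span_end, max(posture$time))
  if (hi_t - lo_t < window_s) return(NULL)
  starts <- seq(lo_t, hi_t - window_s, by = 60)
  best <- NULL
  for (s in starts) {
    psel <- posture$time > s & posture$time <= s + window_s
    if (sum(psel) < min_present * window_s * posture$nominal_rate) next
    lf <- mean(posture$value[psel] == posture_codes()[["lying"]])
    ssel <- steps$time > s & steps$time <= s + window_s
    st <- sum(steps$value[ssel])
    if (st > max_steps || lf < min_lying) next
    if (is.null(best) || lf > best$lf ||
        (lf == best$lf && st < best$st)) best <- list(start = s, lf = lf, st = st)
  }
  best
}

# Linear state-machine walk-bout scan (bridge gaps <= bridge_s seconds of
# non-walking or missing samples).
walks_oracle <- function(posture, steps, min_dur = 360, min_cad = 60, bridge_s = 3) {
  wt <- posture$time[posture$value == posture_codes()[["walking"]]]
  res <- list()
  if (!length(wt)) return(res)
  st <- wt[1]; prev <- wt[1]
  flush <- function(st, en) {
    dur <- en - st + 1
    tot <- sum(steps$value[steps$time >= st & steps$time <= en])
    if (dur >= min_dur && tot / (dur / 60) >= min_cad)
      res[[length(res) + 1]] <<- list(start = st, end = en, steps = tot)
  }
  for (t in wt[-1]) {
    if (t - prev > bridge_s + 1) { flush(st, prev); st <- t }
    prev <- t
  }
  flush(st, prev)
  res
}

# Tiny noise-free cohort configuration for fast deterministic tests.
quiet_config <- function(...) {
  args <- list(wear_gap_rate = 0, pro_dropout = 0, sleep_shift_rate = 0,
               outlier_rates = lapply(cohort_config()$outlier_rates,
                                      function(x) x * 0))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

# Hand-built 1 Hz posture/steps day with one walking bout and optional rest.
mk_activity <- function(total_s, walk_start, walk_len, cadence = 100,
                        gap_at = NULL, gap_len = 0, id = "P1") {
  t <- seq_len(total_s)
  post <- rep(posture_codes()[["sitting"]], total_s)
  steps <- numeric(total_s)
  idx <- (walk_start + 1):(walk_start + walk_len)
  post[idx] <- posture_codes()[["walking"]]
  steps[idx] <- cadence / 60
  if (!is.null(gap_at)) {
    gidx <- (gap_at + 1):(gap_at + gap_len)
    post[gidx] <- posture_codes()[["standing"]]
    steps[gidx] <- 0
  }
  list(posture = sample_series(id, "posture", t, post, 1),
       steps = sample_series(id, "steps", t, steps, 1))
}
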
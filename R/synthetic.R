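#' Synthetic cohort configuration
#'
#' Defines the simulated study conditions: cohort sizes for the three
#' participant categories (healthy, NDD, IMID), days of wear per
#' participant, circadian and noise structure of the physiological
#' channels, planted group effects, outlier-injection rates and PRO
#' behaviour. The defaults emulate the feasibility-study conditions: a
#' 5-day wear period, four PRO slots per day, nightly rest of roughly
#' 23:00--07:00, two sustained daily walks, wear gaps confined to the
#' daytime, and outlier rates matching the contamination levels observed
#' in real patch data (a few tenths of a percent for the ECG-derived
#' channels, ~2% range outliers for skin temperature).
#'
#' @param n_healthy,n_ndd,n_imid participants per group.
#' @param days_per_participant wear days per participant.
#' @param seed master RNG seed; fixed seed implies identical output.
#' @param hr_baseline_by_group resting heart-rate baseline (beats/min).
#' @param hrr_shift_by_group planted heart-rate-recovery shift (beats/min)
#'   relative to `hrr_base`.
#' @param fatigue_effect_beta daytime heart-rate increase per latent
#'   fatigue unit (beats/min).
#' @param outlier_rates per-modality named vectors
#'   `c(invalid=, range=, contextual=)` of injection fractions.
#' @param pro_noise_sd Likert-scale noise SD on PRO responses.
#' @param wear_gap_rate fraction of each day the patch is not worn
#'   (daytime gaps; must be <= 0.4 so gaps fit outside rest and walks).
#' @param pro_dropout probability a scheduled PRO slot is skipped.
#' @param sleep_shift_rate probability a reported bedtime suffers the
#'   12-hour clock-entry error.
#' @param hrr_base,hrr_sd,hrr_age_beta planted HRR model: base value
#'   (beats/min), between-participant SD, and linear age slope
#'   (beats/min per year, centred at age 50).
#' @param hrr_fatigue_beta_by_group per-group HRR change per unit of mean
#'   latent fatigue (beats/min; default 0 = no coupling).
#' @param fatigue_mean,fatigue_within_sd,fatigue_between_sd latent daily
#'   fatigue model (Likert units).
#' @param circadian_amp,acrophase_h heart-rate cosinor amplitude
#'   (beats/min) and acrophase (local hour of the maximum).
#' @param walk_times_h,walk_duration_min,walk_cadence planted daily walks:
#'   local start hours, duration (min) and cadence (steps/min).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_healthy = 3, n_ndd = 3, n_imid = 3,
    days_per_participant = 5,
    seed = 1,
    hr_baseline_by_group = c(healthy = 62, ndd = 68, imid = 66),
    hrr_shift_by_group = c(healthy = 0, ndd = -10, imid = -5),
    fatigue_effect_beta = 5,
    outlier_rates = list(
      hr          = c(invalid = 0,     range = 0,     contextual = 0.002),
      rr_interval = c(invalid = 0.001, range = 0.003, contextual = 0.001),
      resp_rate   = c(invalid = 0,     range = 0,     contextual = 0.001),
      skin_t      = c(invalid = 0,     range = 0.023, contextual = 0),
      steps       = c(invalid = 0,     range = 0,     contextual = 0),
      posture     = c(invalid = 0,     range = 0,     contextual = 0)),
    pro_noise_sd = 0.7,
    wear_gap_rate = 0.22,
    pro_dropout = 0.15,
    sleep_shift_rate = 0.05,
    hrr_base = 30, hrr_sd = 5, hrr_age_beta = -0.2,
    hrr_fatigue_beta_by_group = c(healthy = 0, ndd = 0, imid = 0),
    fatigue_mean = 2, fatigue_within_sd = 1, fatigue_between_sd = 0.8,
    circadian_amp = 8, acrophase_h = 15,
    walk_times_h = c(10.33, 16.5), walk_duration_min = 8, walk_cadence = 100) {
  stopifnot(n_healthy >= 0, n_ndd >= 0, n_imid >= 0, days_per_participant >= 0,
            wear_gap_rate >= 0, wear_gap_rate <= 0.4,
            pro_dropout >= 0, pro_dropout <= 1,
            sleep_shift_rate >= 0, sleep_shift_rate <= 1)
  for (m in names(outlier_rates))
    stopifnot(all(outlier_rates[[m]] >= 0), all(outlier_rates[[m]] <= 1))
  structure(as.list(environment()), class = "cohort_config")
}

GROUPS <- c("healthy", "ndd", "imid")

#' Generate one participant's multi-day recording
#'
#' Produces the six sensor channels (heart rate, beat-by-beat R-to-R,
#' respiratory rate, skin temperature at 0.25 Hz except R-to-R; steps and
#' posture at 1 Hz), the coupled PRO table, and the ground truth used by
#' the test-suite oracles. Guarantees, before outlier injection: every
#' value inside the accepted physiological ranges; a nightly lying bout of
#' at least 5 h with (essentially) zero steps; at least one daytime walk of
#' >= 6 min at cadence >= 60 steps/min followed by >= 1 min of zero steps
#' during which heart rate falls by the participant's planted HRR; and PRO
#' values equal to the discretised latent fatigue plus noise, clipped to
#' the 0--6 Likert range.
#'
#' @param config a [cohort_config()].
#' @param group `"healthy"`, `"ndd"` or `"imid"`.
#' @param seed participant RNG stream seed.
#' @param participant_id identifier; default derived from the group.
#' @param age,sex demographics (years; 0/1). Drawn if missing.
#' @return `list(series, pro, truth)`.
#' @export
generate_participant <- function(config, group, seed, participant_id = NULL,
                                 age = NULL, sex = NULL) {
  if (!group %in% GROUPS) stop("invalid group label: ", group)
  with_seed(seed, {
    D <- config$days_per_participant
    T_end <- D * 86400
    if (is.null(participant_id)) participant_id <- paste0(toupper(substr(group, 1, 1)), seed %% 1000)
    if (is.null(age)) age <- round(stats::runif(1, 25, 75))
    if (is.null(sex)) sex <- stats::rbinom(1, 1, 0.5)

    # latent daily fatigue: participant offset + AR(1) day-to-day variation
    u <- stats::rnorm(1, 0, config$fatigue_between_sd)
    eps <- stats::rnorm(D, 0, config$fatigue_within_sd)
    ar <- as.numeric(stats::filter(eps, 0.4, method = "recursive"))
    fatigue <- pmin(6, pmax(0, config$fatigue_mean + u + ar))

    # planted heart-rate recovery for this participant
    hrr_true <- config$hrr_base + config$hrr_shift_by_group[[group]] +
      config$hrr_age_beta * (age - 50) +
      config$hrr_fatigue_beta_by_group[[group]] * (mean(fatigue) - config$fatigue_mean) +
      stats::rnorm(1, 0, config$hrr_sd)
    hrr_true <- min(60, max(8, hrr_true))

    # nightly rest intervals (bed ~23:00, wake ~07:00), first morning asleep
    bed <- 23 + stats::rnorm(D, 0, 0.4)
    wake <- 7 + stats::rnorm(D, 0, 0.4)
    # morning of day 1, the D-1 full nights, and the final truncated night
    rest <- data.frame(start = 0, end = wake[1] * 3600)
    if (D > 1) {
      k <- seq_len(D - 1)
      rest <- rbind(rest, data.frame(start = (k - 1) * 86400 + bed[k] * 3600,
                                     end = k * 86400 + wake[k + 1] * 3600))
    }
    rest <- rbind(rest, data.frame(start = (D - 1) * 86400 + bed[D] * 3600,
                                   end = T_end))

    # planted walks: per day at the configured local hours (small jitter)
    wt <- config$walk_times_h
    walk_start <- as.vector(outer(wt * 3600, (seq_len(D) - 1) * 86400, `+`)) +
      stats::runif(length(wt) * D, -600, 600)
    walk_start <- sort(round(walk_start))
    walk_len <- config$walk_duration_min * 60
    walks <- data.frame(start = walk_start, end = walk_start + walk_len)

    # 1 Hz posture and steps -------------------------------------------------
    sec <- seq_len(T_end)                    # sample at time t = 1..T
    posture <- rep(posture_codes()[["sitting"]], T_end)
    hod <- ((sec - 1) %% 86400) / 3600       # local hour of day
    # standing blocks: ~20% of daytime in 5-15 min blocks
    n_stand <- 6L * D
    st0 <- stats::runif(n_stand, 0, T_end - 900)
    stl <- stats::runif(n_stand, 300, 900)
    for (k in seq_len(n_stand)) {
      idx <- max(1, round(st0[k])):min(T_end, round(st0[k] + stl[k]))
      posture[idx] <- posture_codes()[["standing"]]
    }
    # lying during rest, with brief sitting interruptions (~2%)
    for (k in seq_len(nrow(rest))) {
      idx <- max(1, floor(rest$start[k]) + 1):min(T_end, floor(rest$end[k]))
      posture[idx] <- posture_codes()[["lying"]]
      n_int <- max(0L, round(length(idx) * 0.02 / 45))
      if (n_int > 0) {
        i0 <- sample(idx, n_int)
        for (s in i0) posture[s:min(max(idx), s + 44)] <- posture_codes()[["sitting"]]
      }
    }
    steps <- integer(T_end)
    # ambient daytime stepping (sparse, non-bout)
    day_awake <- posture != posture_codes()[["lying"]]
    steps[day_awake] <- stats::rbinom(sum(day_awake), 1, 0.01)
    # short strolls that fail the 6-min walk gate
    n_stroll <- 2L * D
    str0 <- stats::runif(n_stroll, 0, T_end - 200)
    for (k in seq_len(n_stroll)) {
      idx <- max(1, round(str0[k])):min(T_end, round(str0[k]) + round(stats::runif(1, 60, 170)))
      if (any(posture[idx] == posture_codes()[["lying"]])) next
      posture[idx] <- posture_codes()[["walking"]]
      steps[idx] <- stats::rbinom(length(idx), 1, 0.75) + stats::rbinom(length(idx), 1, 0.75)
    }
    # planted walks + post-walk rest (2 min seated, zero steps)
    cad_p <- config$walk_cadence / 60 / 2    # per-second mean split over 2 bernoullis
    for (k in seq_len(nrow(walks))) {
      idx <- (walks$start[k] + 1):walks$end[k]
      posture[idx] <- posture_codes()[["walking"]]
      steps[idx] <- stats::rbinom(length(idx), 1, cad_p) + stats::rbinom(length(idx), 1, cad_p)
      ridx <- (walks$end[k] + 1):min(T_end, walks$end[k] + 120)
      posture[ridx] <- posture_codes()[["sitting"]]
      steps[ridx] <- 0L
    }
    walks$steps <- vapply(seq_len(nrow(walks)), function(k)
      sum(steps[(walks$start[k] + 1):walks$end[k]]), numeric(1))

    # heart rate at 0.25 Hz --------------------------------------------------
    t_hr <- seq(4, T_end, by = 4)
    day_of <- pmin(D, floor((t_hr - 1) / 86400) + 1)
    hod_hr <- ((t_hr - 1) %% 86400) / 3600
    act_eff <- c(-3, 0, 5, 25)[posture[t_hr]]  # lying, sitting, standing, walking
    hr_det <- config$hr_baseline_by_group[[group]] +
      config$circadian_amp * cos(2 * pi * (hod_hr - config$acrophase_h) / 24) +
      config$fatigue_effect_beta * fatigue[day_of] + act_eff
    innov <- stats::rnorm(length(t_hr), 0, 0.5)
    noise <- as.numeric(stats::filter(innov, 0.95, method = "recursive"))
    hr <- hr_det + noise
    # recovery decay in the post-walk minute: first sample holds the walk
    # peak, the last has fallen by the planted HRR; low noise (smooth
    # parasympathetic reactivation), flat second minute
    for (k in seq_len(nrow(walks))) {
      te <- walks$end[k]
      peak <- hr_det[findInterval(te, t_hr)]
      ridx <- which(t_hr > te & t_hr <= te + 60)
      s <- t_hr[ridx] - te
      hr[ridx] <- peak - hrr_true * (s - 4) / 56 + stats::rnorm(length(ridx), 0, 0.2)
      fidx <- which(t_hr > te + 60 & t_hr <= te + 120)
      hr[fidx] <- peak - hrr_true + stats::rnorm(length(fidx), 0, 0.3)
    }
    hr <- pmin(190, pmax(35, hr))

    # beat-by-beat R-to-R from the instantaneous heart rate ------------------
    grid1 <- seq_len(T_end)
    hr1 <- stats::approx(t_hr, hr, xout = grid1, rule = 2)$y
    beats_cum <- cumsum(hr1 / 60)
    beat_t <- stats::approx(beats_cum, grid1,
                            xout = seq(ceiling(min(beats_cum)), floor(max(beats_cum))))$y
    rr_val <- diff(beat_t) * 1000 + stats::rnorm(length(beat_t) - 1, 0, 15)
    rr_t <- beat_t[-1]
    rr_val <- pmin(1990, pmax(310, rr_val))

    # respiratory rate and skin temperature ----------------------------------
    resp <- 14 + 1.5 * cos(2 * pi * (hod_hr - 16) / 24) +
      as.numeric(stats::filter(stats::rnorm(length(t_hr), 0, 0.4), 0.9,
                               method = "recursive"))
    resp <- pmin(40, pmax(6, resp))
    skin <- 33.5 + 0.8 * cos(2 * pi * (hod_hr - 3) / 24) +
      as.numeric(stats::filter(stats::rnorm(length(t_hr), 0, 0.05), 0.9,
                               method = "recursive"))
    skin <- pmin(39.5, pmax(28.5, skin))

    # daytime wear gaps -------------------------------------------------------
    gaps <- plan_wear_gaps(D, config$wear_gap_rate)

    series <- list(
      hr = sample_series(participant_id, "hr", t_hr, hr),
      rr_interval = sample_series(participant_id, "rr_interval", rr_t, rr_val, 1),
      resp_rate = sample_series(participant_id, "resp_rate", t_hr, resp),
      skin_t = sample_series(participant_id, "skin_t", t_hr, skin),
      steps = sample_series(participant_id, "steps", sec, steps),
      posture = sample_series(participant_id, "posture", sec, posture))
    if (nrow(gaps)) series <- lapply(series, drop_gap_samples, gaps = gaps)

    # outlier injection -------------------------------------------------------
    outlier_idx <- list()
    for (m in names(series)) {
      inj <- inject_outliers(series[[m]], config$outlier_rates[[m]])
      series[[m]] <- inj$series
      outlier_idx[[m]] <- inj$indices
    }

    pro <- generate_pro(config, participant_id, D, fatigue, rest, bed, wake)

    truth <- list(participant_id = participant_id, group = group, age = age,
                  sex = sex, fatigue = fatigue, rest_intervals = rest,
                  walk_bouts = walks, hrr = hrr_true, gap_intervals = gaps,
                  outlier_idx = outlier_idx)
    list(series = series, pro = pro, truth = truth)
  })
}

# Place wear-gap blocks in daytime regions that never touch the nightly
# rest (22:00-08:00) or the planted walks/recoveries; exact total length
# wear_gap_rate * 86400 per day.
plan_wear_gaps <- function(days, rate) {
  if (rate <= 0 || days == 0)
    return(data.frame(start = numeric(0), end = numeric(0)))
  regions <- rbind(c(8.1, 9.9), c(11.1, 15.4), c(17.3, 21.9)) * 3600
  caps <- regions[, 2] - regions[, 1]
  out <- list()
  for (d in seq_len(days) - 1) {
    need <- rate * 86400
    share <- caps / sum(caps) * need
    for (r in seq_len(nrow(regions))) {
      len <- min(share[r], caps[r] - 60)
      if (len <= 0) next
      s0 <- d * 86400 + stats::runif(1, regions[r, 1], regions[r, 2] - len)
      out[[length(out) + 1]] <- data.frame(start = s0, end = s0 + len)
    }
  }
  do.call(rbind, out)
}

drop_gap_samples <- function(series, gaps) {
  keep <- rep(TRUE, length(series$time))
  for (k in seq_len(nrow(gaps)))
    keep <- keep & !(series$time > gaps$start[k] & series$time <= gaps$end[k])
  sample_series(series$participant_id, series$modality,
                series$time[keep], series$value[keep], series$nominal_rate)
}

# PRO table: one row per (day, slot, item), with Bernoulli slot dropout,
# responses coupled to the latent fatigue, and sleep times subject to the
# 12-h entry error.
generate_pro <- function(config, participant_id, days, fatigue, rest, bed, wake) {
  likert <- function(x) pmin(6, pmax(0, round(x + stats::rnorm(length(x), 0, config$pro_noise_sd))))
  rows <- list()
  sched <- pro_schedule()
  for (d in seq_len(days) - 1) {
    f <- fatigue[d + 1]
    for (slot in c(9, 13, 17, 21)) {
      if (stats::runif(1) < config$pro_dropout) next
      t_sub <- d * 86400 + slot * 3600 + stats::runif(1, 0, 1800)
      add <- function(item, value) rows[[length(rows) + 1]] <<- data.frame(
        participant_id = participant_id, day = d, slot = slot,
        time = t_sub, item = item, value = value, stringsAsFactors = FALSE)
      for (it in names(sched)) {
        if (!slot %in% sched[[it]]) next
        val <- switch(it,
          physical_fatigue = likert(f),
          mental_fatigue = likert(0.8 * f + 0.5),
          anxiousness = likert(1 + 0.2 * f),
          depression = likert(1 + 0.2 * f),
          pain = likert(1 + 0.3 * f),
          sleepiness = likert(1 + 0.6 * f),
          sleep_quality = likert(4 - 0.5 * f),
          activity_physical = likert(3 - 0.3 * f),
          activity_mental = likert(3 - 0.2 * f),
          bed_time = if (d == 0) NULL else {
            b <- (bed[d] + stats::rnorm(1, 0, 0.15)) %% 24
            if (stats::runif(1) < config$sleep_shift_rate && b >= 12) b - 12 else b
          },
          wake_time = if (d == 0) NULL else (wake[d + 1] + stats::rnorm(1, 0, 0.15)) %% 24)
        if (!is.null(val)) add(it, val)
      }
    }
  }
  if (!length(rows))
    return(data.frame(participant_id = character(0), day = integer(0),
                      slot = numeric(0), time = numeric(0),
                      item = character(0), value = numeric(0)))
  do.call(rbind, rows)
}

#' Inject synthetic outliers of the three cleaning classes
#'
#' Invalid-class samples are set to the manufacturer sentinel; range-class
#' samples are pushed outside the accepted physiological range;
#' contextual-class samples are multiplied so that they deviate from their
#' sliding-window mean by more than the contextual threshold while staying
#' inside the accepted range. Injection sites are disjoint across classes.
#'
#' @param series a clean [sample_series()].
#' @param rates named fractions `c(invalid=, range=, contextual=)`.
#' @param config a [cleaning_config()] supplying ranges/thresholds.
#' @return `list(series, indices)` where `indices` is a list of injected
#'   sample indices per class.
#' @export
inject_outliers <- function(series, rates = c(invalid = 0, range = 0, contextual = 0),
                            config = cleaning_config()) {
  stopifnot(all(rates >= 0), all(rates <= 1))
  n <- length(series$time)
  empty <- list(invalid = integer(0), range = integer(0), contextual = integer(0))
  if (n == 0 || sum(rates) == 0) return(list(series = series, indices = empty))
  v <- series$value
  n_inv <- round(rates[["invalid"]] * n)
  n_rng <- round(rates[["range"]] * n)
  n_ctx <- round(rates[["contextual"]] * n)
  pick <- sample.int(n, min(n, n_inv + n_rng + n_ctx))
  idx <- list(invalid = pick[seq_len(n_inv)],
              range = pick[n_inv + seq_len(n_rng)],
              contextual = pick[n_inv + n_rng + seq_len(n_ctx)])
  v[idx$invalid] <- invalid_sentinel()
  rng <- config$accepted_range[[series$modality]]
  if (length(idx$range)) {
    if (is.null(rng)) stop("range injection needs an accepted range for ", series$modality)
    below <- stats::runif(length(idx$range)) < 0.5
    v[idx$range] <- ifelse(below, rng[1] * stats::runif(length(idx$range), 0.3, 0.9),
                           rng[2] * stats::runif(length(idx$range), 1.05, 1.3))
  }
  if (length(idx$contextual)) {
    thr <- config$contextual_threshold[[series$modality]]
    mult <- 1 + thr + stats::runif(length(idx$contextual), 0.25, 0.55)
    up <- v[idx$contextual] * mult
    v[idx$contextual] <- ifelse(up <= rng[2], up, v[idx$contextual] / mult)
  }
  list(series = sample_series(series$participant_id, series$modality,
                              series$time, v, series$nominal_rate),
       indices = idx)
}

#' Generate a full synthetic cohort
#'
#' Participant RNG streams are derived independently from the master seed,
#' so regenerating one participant never alters another. Deterministic per
#' (config, seed).
#'
#' @param config a [cohort_config()].
#' @return `list(participants, truth, config)`: named participant bundles
#'   (each `list(series, pro, truth)`), a cohort-level participant table
#'   (id, group, age, sex, planted hrr), and the config.
#' @export
generate_cohort <- function(config = cohort_config()) {
  groups <- rep(GROUPS, c(config$n_healthy, config$n_ndd, config$n_imid))
  n <- length(groups)
  ids <- sprintf("%s%02d", toupper(substr(groups, 1, 1)),
                 stats::ave(seq_len(n), groups, FUN = seq_along))
  seeds <- derive_seeds(config$seed, max(1, n))
  participants <- list()
  ptab <- list()
  for (i in seq_len(n)) {
    b <- generate_participant(config, groups[i], seeds[i], participant_id = ids[i])
    participants[[ids[i]]] <- b
    ptab[[i]] <- data.frame(participant_id = ids[i], group = groups[i],
                            age = b$truth$age, sex = b$truth$sex,
                            hrr_true = b$truth$hrr, stringsAsFactors = FALSE)
  }
  list(participants = participants,
       truth = list(participant_table = do.call(rbind, ptab)),
       config = config)
}

#' Simulate participant-level planted HRR values only
#'
#' Draws (group, age, sex, hrr) per participant from the same planted-HRR
#' model the full signal generator uses, without synthesising signals.
#' Intended for group-comparison calibration studies (power, type-I error)
#' where only the participant-level outcome matters.
#'
#' @param config a [cohort_config()] (group sizes, shifts, SDs, age slope).
#' @param seed RNG seed.
#' @return data.frame: participant_id, group, age, sex, hrr.
#' @export
simulate_hrr_cohort <- function(config = cohort_config(), seed = config$seed) {
  with_seed(seed, {
    groups <- rep(GROUPS, c(config$n_healthy, config$n_ndd, config$n_imid))
    n <- length(groups)
    age <- round(stats::runif(n, 25, 75))
    sex <- stats::rbinom(n, 1, 0.5)
    hrr <- config$hrr_base + unname(unlist(config$hrr_shift_by_group[groups])) +
      config$hrr_age_beta * (age - 50) + stats::rnorm(n, 0, config$hrr_sd)
    data.frame(participant_id = sprintf("P%03d", seq_len(n)), group = groups,
               age = age, sex = sex, hrr = hrr, stringsAsFactors = FALSE)
  })
}
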
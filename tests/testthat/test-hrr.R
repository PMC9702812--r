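test_that("walk detection applies duration, cadence and 3-s bridging gates", {
  # 7-min walk with one 2-s interruption and 480 steps: one bout
  a <- mk_activity(3000, walk_start = 600, walk_len = 420, cadence = 480 / 7,
                   gap_at = 800, gap_len = 2)
  w <- detect_walks(a$posture, a$steps)
  expect_equal(nrow(w), 1)
  expect_equal(w$duration_min, 7)
  expect_equal(w$cadence, w$step_total / 7)
  expect_gt(w$cadence, 60)
  expect_equal(w$interruption_s, 2)
  # 5 min 59 s fails the duration gate
  short <- mk_activity(3000, 600, 359)
  expect_equal(nrow(detect_walks(short$posture, short$steps)), 0)
  # cadence 50 fails the cadence gate
  slow <- mk_activity(3000, 600, 480, cadence = 50)
  expect_equal(nrow(detect_walks(slow$posture, slow$steps)), 0)
  # a 3-s posture change is bridged; 4 s splits the run
  b3 <- mk_activity(3000, 600, 420, gap_at = 800, gap_len = 3)
  expect_equal(nrow(detect_walks(b3$posture, b3$steps)), 1)
  b4 <- mk_activity(3000, 600, 420, gap_at = 800, gap_len = 4)
  expect_equal(nrow(detect_walks(b4$posture, b4$steps)), 0)  # both halves < 6 min
})

test_that("walk detection agrees with the linear state-machine oracle", {
  set.seed(501)
  for (rep in 1:10) {
    n <- 20000
    post <- rep(posture_codes()[["sitting"]], n)
    # random walking runs of 2-10 min with occasional 1-5 s interruptions
    pos <- cumsum(stats::runif(8, 1200, 2400))
    for (p in pos[pos < n - 700]) {
      len <- round(stats::runif(1, 120, 600))
      post[p:(p + len)] <- posture_codes()[["walking"]]
      if (stats::runif(1) < 0.7) {
        g0 <- p + sample.int(len - 10, 1)
        post[g0:(g0 + sample.int(5, 1) - 1)] <- posture_codes()[["standing"]]
      }
    }
    steps <- ifelse(post == posture_codes()[["walking"]],
                    stats::rbinom(n, 2, 0.6), 0)
    ps <- sample_series("P1", "posture", seq_len(n), post, 1)
    ss <- sample_series("P1", "steps", seq_len(n), steps, 1)
    got <- detect_walks(ps, ss)
    want <- walks_oracle(ps, ss)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$start, vapply(want, `[[`, numeric(1), "start"))
      expect_equal(got$end, vapply(want, `[[`, numeric(1), "end"))
      expect_equal(got$step_total, vapply(want, `[[`, numeric(1), "steps"))
    }
  }
})

test_that("rest-window gates: full HR coverage, zero steps, no walking resumption", {
  a <- mk_activity(3000, 600, 420)
  walk <- detect_walks(a$posture, a$steps)
  t_hr <- seq(4, 3000, by = 4)
  hr_v <- rep(80, length(t_hr))
  rest_idx <- which(t_hr > walk$end & t_hr <= walk$end + 60)
  hr_v[rest_idx] <- seq(120, 85, length.out = length(rest_idx))
  hr <- sample_series("P1", "hr", t_hr, hr_v)
  obs <- detect_rest_and_hrr(walk, hr, a$steps, a$posture)
  expect_equal(obs$hrr, 35)                        # max - min = 120 - 85
  # 14 of 15 samples: rejected
  hr14 <- sample_series("P1", "hr", t_hr[-rest_idx[3]], hr_v[-rest_idx[3]])
  expect_null(detect_rest_and_hrr(walk, hr14, a$steps, a$posture))
  # one step in the rest minute: rejected
  st <- a$steps; st$value[walk$end + 30] <- 1
  expect_null(detect_rest_and_hrr(walk, hr, st, a$posture))
  # walking resuming inside the window: rejected
  po <- a$posture; po$value[walk$end + 30] <- posture_codes()[["walking"]]
  expect_null(detect_rest_and_hrr(walk, hr, a$steps, po))
  # alternative recovery definition: onset minus minimum
  obs2 <- detect_rest_and_hrr(walk, hr, a$steps, a$posture, method = "onset_min")
  expect_equal(obs2$hrr, 120 - 85)
})

test_that("representative recovery is the maximum, earliest on ties", {
  obs <- data.frame(walk_start = c(1, 2, 3), walk_end = c(10, 20, 30),
                    duration_min = 7, cadence = 80,
                    rest_start = c(100, 200, 300), rest_end = c(160, 260, 360),
                    hrr = c(20, 35, 28))
  expect_equal(representative_hrr(obs)$hrr, 35)
  tie <- obs; tie$hrr <- c(30, 30, 10)
  expect_equal(representative_hrr(tie)$rest_start, 100)
  expect_equal(representative_hrr(obs[2, ])$hrr, 35)
  expect_null(representative_hrr(obs[0, ]))
})

test_that("planted recovery values are re-detected from the raw signals", {
  cfg <- quiet_config(n_healthy = 2, n_ndd = 1, n_imid = 1, days_per_participant = 1)
  co <- generate_cohort(cfg)
  for (id in names(co$participants)) {
    b <- co$participants[[id]]
    cl <- clean_bundle(b$series)
    obs <- participant_hrr(cl$series)
    expect_gte(nrow(obs), 1)
    rep_ <- representative_hrr(obs)
    expect_equal(rep_$hrr, b$truth$hrr, tolerance = 2 / b$truth$hrr)
  }
})

test_that("ANCOVA matches the matrix-algebra oracle on a 3x5 toy table", {
  toy <- data.frame(
    group = rep(c("healthy", "ndd", "imid"), each = 5),
    hrr = c(32, 35, 30, 38, 33, 22, 25, 20, 24, 23, 27, 29, 24, 28, 26),
    age = c(45, 52, 61, 38, 49, 55, 63, 47, 58, 51, 42, 57, 66, 50, 44),
    sex = c(0, 1, 0, 1, 1, 0, 0, 1, 1, 0, 1, 0, 0, 1, 1))
  got <- ancova_groups(toy)
  # oracle: Type II group SS via nested least squares
  X_full <- stats::model.matrix(~ group + age + sex, toy)
  X_red <- stats::model.matrix(~ age + sex, toy)
  rss <- function(X) sum(stats::lsfit(X, toy$hrr, intercept = FALSE)$residuals^2)
  ss_g <- rss(X_red) - rss(X_full)
  df_res <- nrow(toy) - ncol(X_full)
  f_or <- (ss_g / 2) / (rss(X_full) / df_res)
  expect_equal(got$f, f_or, tolerance = 1e-8)
  expect_equal(got$eta_partial[["group"]], ss_g / (ss_g + rss(X_full)),
               tolerance = 1e-8)
  expect_equal(unname(got$p), stats::pf(f_or, 2, df_res, lower.tail = FALSE),
               tolerance = 1e-8)
  # Tukey table: 3 adjusted pairwise comparisons on adjusted means
  expect_equal(nrow(got$tukey), 3)
  expect_true(all(got$tukey$p.value <= 1))
  # dropping the covariates reduces the model to one-way ANOVA
  one <- ancova_groups(toy, tukey = FALSE, covariates = character(0))
  grand <- mean(toy$hrr)
  ssb <- sum(tapply(toy$hrr, toy$group, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum((toy$hrr - stats::ave(toy$hrr, toy$group))^2)
  expect_equal(one$f, (ssb / 2) / (ssw / 12), tolerance = 1e-8)
  # degenerate designs fail loudly
  expect_error(ancova_groups(toy[toy$group != "ndd" | toy$age < 50, ][1:6, ]),
               "groups")
})

test_that("fatigue split flags only groups with planted fatigue-HRR coupling", {
  set.seed(909)
  mk <- function(group, coupling, n = 12) {
    fat <- stats::runif(n, 0, 5)
    data.frame(participant_id = sprintf("%s%02d", group, 1:n), group = group,
               hrr = 30 + coupling * fat + stats::rnorm(n, 0, 1), fatigue = fat)
  }
  tab <- rbind(mk("healthy", -6), mk("ndd", 0), mk("imid", 0))
  pro <- data.frame(participant_id = tab$participant_id, day = 0, slot = 9,
                    time = 1, item = "physical_fatigue", value = tab$fatigue)
  out <- fatigue_split(tab[, c("participant_id", "group", "hrr")], pro)
  expect_true(out$significant[out$group == "healthy"])
  # under no coupling, flags appear at about the alpha rate
  flags <- vapply(1:400, function(i) {
    tb <- mk("ndd", 0, n = 10)
    pr <- data.frame(participant_id = tb$participant_id, day = 0, slot = 9,
                     time = 1, item = "physical_fatigue", value = tb$fatigue)
    fs <- fatigue_split(tb[, c("participant_id", "group", "hrr")], pr)
    nrow(fs) == 1 && fs$significant
  }, logical(1))
  expect_lt(mean(flags), 0.10)
  # groups below the minimum size or with constant fatigue are skipped
  tiny <- mk("healthy", -6, n = 3)
  pro_t <- data.frame(participant_id = tiny$participant_id, day = 0, slot = 9,
                      time = 1, item = "physical_fatigue", value = tiny$fatigue)
  expect_equal(nrow(fatigue_split(tiny[, c("participant_id", "group", "hrr")], pro_t)), 0)
  flat <- mk("imid", 0, n = 8); flat$fatigue <- 2
  pro_f <- data.frame(participant_id = flat$participant_id, day = 0, slot = 9,
                      time = 1, item = "physical_fatigue", value = 2)
  expect_equal(nrow(fatigue_split(flat[, c("participant_id", "group", "hrr")], pro_f)), 0)
})
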
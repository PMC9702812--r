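mk_bundle <- function(hr_vals, t_hr = seq(4, length(hr_vals) * 4, by = 4), id = "P1") {
  n <- length(hr_vals)
  rrt <- seq(1, max(t_hr))
  list(hr = sample_series(id, "hr", t_hr, hr_vals),
       resp_rate = sample_series(id, "resp_rate", t_hr, rep(15, n)),
       skin_t = sample_series(id, "skin_t", t_hr, rep(33, n)),
       rr_interval = sample_series(id, "rr_interval", rrt, rep(1000, length(rrt)), 1),
       steps = sample_series(id, "steps", rrt, rep(0, length(rrt)), 1),
       posture = sample_series(id, "posture", rrt,
                               rep(posture_codes()[["sitting"]], length(rrt)), 1))
}

test_that("2-h window aggregates cover (anchor - 2h, anchor] with coverage", {
  # constant HR 60 over a full 2-h window
  s <- mk_bundle(rep(60, 1800))
  a <- aggregate_window(s, anchor_time = 7200)
  expect_equal(a$hr_mean, 60)
  expect_equal(a$hr_sd, 0)
  expect_equal(a$hr_min, 60)
  expect_equal(a$hr_max, 60)
  expect_equal(a$hr_coverage, 1)
  expect_equal(a$rr_interval_coverage, 1, tolerance = 0.01)
  # window half-open at the start: the sample at anchor-7200 is excluded
  expect_equal(nrow(a), 1)
  # half-empty window -> coverage 0.5, aggregates on what is present
  s2 <- mk_bundle(rep(c(50, 70), 450))
  a2 <- aggregate_window(s2, anchor_time = 7200)
  expect_equal(a2$hr_coverage, 0.5)
  expect_equal(a2$hr_mean, 60)
  expect_equal(a2$hr_min, 50)
  expect_equal(a2$hr_max, 70)
  # empty window: NA aggregates, coverage 0
  a3 <- aggregate_window(s, anchor_time = 30000)
  expect_true(is.na(a3$hr_mean))
  expect_equal(a3$hr_coverage, 0)
})

test_that("L5 detection obeys the step and lying thresholds with stated tie-breaks", {
  lay <- posture_codes()[["lying"]]; sit <- posture_codes()[["sitting"]]
  walk <- posture_codes()[["walking"]]
  total <- 36 * 3600
  t <- seq_len(total)
  # 6-h pure lying night (22:00-04:00) inside an otherwise active record
  post <- rep(sit, total); post[t > 22 * 3600 & t <= 28 * 3600] <- lay
  st <- rep(2, total); st[post == lay] <- 0
  posture <- sample_series("P1", "posture", t, post, 1)
  steps <- sample_series("P1", "steps", t, st, 1)
  l5 <- detect_l5(steps, posture, 12 * 3600, 36 * 3600)
  expect_false(is.null(l5))
  expect_gte(l5$start, 22 * 3600 - 60)
  expect_lte(l5$start, 23 * 3600 + 60)   # 5-h window inside the 6-h night
  expect_lte(l5$step_total, 100)
  expect_gte(l5$lying_frac, 0.8)
  # all-day walking -> no window
  day <- 86400
  td <- seq_len(day)
  post2 <- rep(walk, day); st2 <- rep(2, day)
  expect_null(detect_l5(sample_series("P1", "steps", td, st2, 1),
                        sample_series("P1", "posture", td, post2, 1),
                        0, day))
  # of two candidate plateaus the higher lying fraction wins
  post3 <- rep(sit, day)
  post3[td > 1 * 3600 & td <= 7 * 3600] <- lay                 # pure block
  idx <- td > 14 * 3600 & td <= 20 * 3600
  post3[idx] <- ifelse(td[idx] %% 10 == 0, sit, lay)           # 90% lying
  st3 <- rep(0, day)
  l53 <- detect_l5(sample_series("P1", "steps", td, st3, 1),
                   sample_series("P1", "posture", td, post3, 1), 0, day)
  expect_lte(l53$end, 7 * 3600 + 60)
  expect_equal(l53$lying_frac, 1)
})

test_that("L5 detection agrees with the exhaustive 1-min scan on generated days", {
  cfg <- quiet_config(days_per_participant = 2)
  for (seed in c(31, 32)) {
    b <- generate_participant(cfg, "healthy", seed = seed)
    for (d in 0:1) {
      got <- detect_l5(b$series$steps, b$series$posture,
                       d * 86400 + 43200, (d + 1) * 86400 + 43200)
      want <- l5_oracle(b$series$steps, b$series$posture,
                        d * 86400 + 43200, (d + 1) * 86400 + 43200)
      expect_equal(got$start, want$start)
      expect_equal(got$lying_frac, want$lf)
      expect_equal(got$step_total, want$st)
    }
  }
})

test_that("L5 parameters use the n-1 SD estimator and tolerate missing channels", {
  cfg <- quiet_config(days_per_participant = 1)
  b <- generate_participant(cfg, "healthy", seed = 17)
  l5 <- detect_l5_all(b$series$steps, b$series$posture)[1, ]
  # constant / alternating closed forms
  n <- 1000
  s <- list(hr = sample_series("P1", "hr", seq_len(n) * 4 + l5$start, rep(55, n)),
            rr_interval = sample_series("P1", "rr_interval",
                                        seq_len(n) + l5$start, rep(1000, n), 1),
            resp_rate = sample_series("P1", "resp_rate",
                                      seq_len(n) * 4 + l5$start,
                                      rep(c(50, 60), n / 2)),
            skin_t = sample_series("P1", "skin_t", numeric(0), numeric(0)))
  p <- l5_params(l5, s)
  expect_equal(p$hr_mu, 55)
  expect_equal(p$hr_sigma, 0)
  expect_equal(p$resp_rate_mu, 55)
  expect_equal(p$resp_rate_sigma, sqrt(25 * n / (n - 1)))  # 5.0025 at n = 1000
  expect_true(is.na(p$skin_t_mu))
})

test_that("normalization follows x_norm = (x - mu)/sigma with the variant rules", {
  aggs <- data.frame(participant_id = "P1", anchor_time = c(40000, 130000),
                     hr_mean = c(60, 65), hr_coverage = 1)
  l5p <- data.frame(participant_id = "P1", start = c(5000, 95000),
                    end = c(23000, 113000), hr_mu = c(60, 70), hr_sigma = c(5, 5))
  # variant b: participant-mean parameters mu = 65, sigma = 5
  nb <- normalize_aggregates(aggs, l5p, "b")
  expect_equal(nb$hr_mean, c(-1, 0))
  # variant a: nearest previous window
  na_ <- normalize_aggregates(aggs, l5p, "a")
  expect_equal(na_$hr_mean, c(0, -1))
  # x = mu -> 0 and x = mu + sigma -> 1
  aggs2 <- data.frame(participant_id = "P1", anchor_time = 40000,
                      hr_mean = 65, hr_coverage = 1)
  expect_equal(normalize_aggregates(aggs2, l5p, "b")$hr_mean, 0)
  aggs3 <- aggs2; aggs3$hr_mean <- 70
  expect_equal(normalize_aggregates(aggs3, l5p, "b")$hr_mean, 1)
  # variant a excludes aggregates with no earlier L5 window
  early <- data.frame(participant_id = "P1", anchor_time = 10000,
                      hr_mean = 60, hr_coverage = 1)
  expect_equal(nrow(normalize_aggregates(early, l5p, "a")), 0)
  expect_equal(nrow(normalize_aggregates(early, l5p, "b")), 1)
  # zero sigma flags the feature as missing
  l5p0 <- l5p; l5p0$hr_sigma <- 0
  expect_true(is.na(normalize_aggregates(aggs2, l5p0, "b")$hr_mean))
})

test_that("an L5 window's own samples self-normalize to mean 0, SD 1", {
  cfg <- quiet_config(days_per_participant = 1)
  b <- generate_participant(cfg, "ndd", seed = 23)
  l5 <- detect_l5_all(b$series$steps, b$series$posture)[1, ]
  p <- l5_params(l5, b$series)
  w <- series_window(b$series$hr, l5$start, l5$end)
  z <- (w$value - p$hr_mu) / p$hr_sigma
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
})

test_that("detected L5 windows align with reported sleep on synthetic nights", {
  cfg <- quiet_config(days_per_participant = 3)
  b <- generate_participant(cfg, "imid", seed = 41)
  l5 <- detect_l5_all(b$series$steps, b$series$posture)
  truth <- b$truth$rest_intervals
  agr <- l5_sleep_agreement(l5, data.frame(start = truth$start, end = truth$end))
  expect_gte(agr$within_tol, 0.95)
  expect_equal(agr$n, nrow(l5))
})
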
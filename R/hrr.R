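#' Detect sustained free-living walking bouts
#'
#' Maximal runs of walking-classified posture samples (1 Hz), bridging
#' interruptions — non-walking postures or missing samples — of up to
#' `bridge_s` seconds (3 s). A bout is kept if it lasts at least
#' `min_duration_min` minutes (6) and its mean cadence (total steps over
#' duration) is at least `min_cadence` steps/min (60). No upper duration
#' limit is applied.
#'
#' @param posture,steps cleaned 1 Hz [sample_series()].
#' @param min_duration_min,min_cadence,bridge_s gate parameters.
#' @return data.frame of bouts: `start`, `end` (timestamps of the first and
#'   last walking sample), `duration_min`, `step_total`, `cadence`,
#'   `interruption_s`; 0 rows when none qualify.
#' @export
detect_walks <- function(posture, steps, min_duration_min = 6,
                         min_cadence = 60, bridge_s = 3) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration_min = numeric(0), step_total = numeric(0),
                      cadence = numeric(0), interruption_s = numeric(0))
  wt <- posture$time[posture$value == posture_codes()[["walking"]]]
  if (!length(wt)) return(empty)
  # walking samples more than bridge_s + 1 apart cannot be bridged
  brk <- which(diff(wt) > bridge_s + 1)
  s_idx <- c(1L, brk + 1L); e_idx <- c(brk, length(wt))
  st <- wt[s_idx]; en <- wt[e_idx]
  dur <- en - st + 1
  cs <- c(0, cumsum(steps$value))
  # steps are summed over the closed bout span [start, end]
  lo <- findInterval(st, steps$time, left.open = TRUE) + 1L
  hi <- findInterval(en, steps$time)
  step_tot <- cs[hi + 1L] - cs[lo]
  cad <- step_tot / (dur / 60)
  n_walk <- (e_idx - s_idx) + 1L
  keep <- dur >= min_duration_min * 60 & cad >= min_cadence
  data.frame(start = st, end = en, duration_min = dur / 60,
             step_total = step_tot, cadence = cad,
             interruption_s = dur - n_walk)[keep, , drop = FALSE]
}

#' Extract heart-rate recovery after a walking bout
#'
#' The rest window is the 60 s immediately following the walk's end. The
#' observation is valid only under 100% heart-rate coverage (all
#' `60 * rate` nominal samples present — 15 at 0.25 Hz), zero steps, and
#' no walking posture inside the window. The recovery value is, by
#' default, the maximum difference in the heart-rate signal within the
#' window (`max - min`); the alternative reading — first sample of the
#' rest window minus the window minimum — is available as
#' `method = "onset_min"`.
#'
#' @param walk one row from [detect_walks()].
#' @param hr cleaned heart-rate series (0.25 Hz).
#' @param steps,posture cleaned 1 Hz series.
#' @param rest_s rest window length (s).
#' @param method `"max_min"` (default) or `"onset_min"`.
#' @return One-row data.frame (`walk_start`, `walk_end`, `duration_min`,
#'   `cadence`, `rest_start`, `rest_end`, `hrr`) or `NULL` when any gate
#'   fails.
#' @export
detect_rest_and_hrr <- function(walk, hr, steps, posture, rest_s = 60,
                                method = c("max_min", "onset_min")) {
  method <- match.arg(method)
  r0 <- walk$end; r1 <- walk$end + rest_s
  w <- series_window(hr, r0, r1)
  if (length(w$value) < round(rest_s * hr$nominal_rate)) return(NULL)
  sw <- series_window(steps, r0, r1)
  if (sum(sw$value) > 0) return(NULL)
  pw <- series_window(posture, r0, r1)
  if (any(pw$value == posture_codes()[["walking"]])) return(NULL)
  hrr <- switch(method, max_min = max(w$value) - min(w$value),
                onset_min = w$value[1] - min(w$value))
  data.frame(walk_start = walk$start, walk_end = walk$end,
             duration_min = walk$duration_min, cadence = walk$cadence,
             rest_start = r0, rest_end = r1, hrr = hrr)
}

#' All heart-rate-recovery observations for one participant
#'
#' @param series cleaned series list (`hr`, `steps`, `posture`).
#' @param ... passed to [detect_walks()] / [detect_rest_and_hrr()].
#' @param method recovery definition, see [detect_rest_and_hrr()].
#' @return data.frame of observations (0 rows when none).
#' @export
participant_hrr <- function(series, method = "max_min", ...) {
  walks <- detect_walks(series$posture, series$steps, ...)
  out <- list()
  for (i in seq_len(nrow(walks))) {
    o <- detect_rest_and_hrr(walks[i, ], series$hr, series$steps,
                             series$posture, method = method)
    if (!is.null(o)) out[[length(out) + 1]] <- o
  }
  if (!length(out))
    return(data.frame(walk_start = numeric(0), walk_end = numeric(0),
                      duration_min = numeric(0), cadence = numeric(0),
                      rest_start = numeric(0), rest_end = numeric(0),
                      hrr = numeric(0)))
  do.call(rbind, out)
}

#' Representative heart-rate recovery
#'
#' The highest observed recovery; ties resolved to the earliest
#' observation.
#'
#' @param obs observation table from [participant_hrr()].
#' @return The selected row, or `NULL` when there are no observations.
#' @export
representative_hrr <- function(obs) {
  if (is.null(obs) || !nrow(obs)) return(NULL)
  obs[order(-obs$hrr, obs$rest_start), ][1, , drop = FALSE]
}

#' Group comparison of heart-rate recovery by ANCOVA
#'
#' One-way, two-sided ANCOVA of the representative recovery values on
#' participant group with age and sex as covariates:
#' `hrr ~ group + age + sex`. The group effect is tested with a Type II F
#' test; effect sizes are partial eta^2 = SS_term / (SS_term + SS_residual)
#' per term. Post hoc pairwise differences use Tukey's HSD on the
#' covariate-adjusted group means (studentized-range adjustment over the
#' three comparisons).
#'
#' @param data data.frame with columns `hrr`, `group`, `age`, `sex`.
#'   Rows with missing covariates are excluded listwise.
#' @param tukey compute the post hoc table (skip for speed in
#'   simulation loops).
#' @param covariates covariate columns to adjust for; an empty vector
#'   reduces the model to a one-way ANOVA.
#' @return `list(f, p, eta_partial, tukey, n_by_group, model)`.
#' @export
ancova_groups <- function(data, tukey = TRUE, covariates = c("age", "sex")) {
  data <- data[stats::complete.cases(data[, c("hrr", "group", covariates)]), ]
  data$group <- factor(data$group)
  if (nlevels(data$group) < 2 || any(table(data$group) < 2))
    stop("need >= 2 groups with n >= 2 each")
  fml <- stats::reformulate(c("group", covariates), response = "hrr")
  fit <- stats::lm(fml, data = data)
  if (fit$rank < length(stats::coef(fit))) stop("rank-deficient ANCOVA design")
  aov2 <- car::Anova(fit, type = 2)
  ss <- aov2[, "Sum Sq"]
  names(ss) <- rownames(aov2)
  ss_res <- ss[["Residuals"]]
  terms <- setdiff(rownames(aov2), "Residuals")
  eta <- vapply(terms, function(tm) ss[[tm]] / (ss[[tm]] + ss_res), numeric(1))
  tk <- NULL
  # the studentized-range distribution degenerates below 3 residual df
  if (tukey && stats::df.residual(fit) >= 3) {
    emm <- emmeans::emmeans(fit, "group")
    tk <- as.data.frame(summary(emmeans::contrast(emm, method = "pairwise"),
                                adjust = "tukey"))
  }
  list(f = aov2["group", "F value"], p = aov2["group", "Pr(>F)"],
       eta_partial = eta, tukey = tk,
       n_by_group = table(data$group), model = fit)
}

#' High/low-fatigue split of heart-rate recovery within groups
#'
#' Within each participant group, participants are median-split on their
#' mean physical-fatigue PRO score; recovery values of the high and low
#' halves are compared with a two-sided Welch t test. Groups with fewer
#' than `min_n` participants, or with all-identical fatigue (undefined
#' split), are skipped.
#'
#' @param hrr_table data.frame: `participant_id`, `group`, `hrr`.
#' @param pro rbind-ed PRO tables (needs `physical_fatigue` rows).
#' @param min_n minimum participants per group.
#' @param alpha significance level.
#' @return data.frame per group: mean fatigue, split sizes, mean recovery
#'   high/low, t, p, significant; 0 rows when every group is skipped.
#' @export
fatigue_split <- function(hrr_table, pro, min_n = 4, alpha = 0.05) {
  pf <- pro[pro$item == "physical_fatigue", ]
  mf <- tapply(pf$value, pf$participant_id, mean)
  hrr_table$fatigue <- as.numeric(mf[hrr_table$participant_id])
  res <- list()
  for (g in unique(hrr_table$group)) {
    d <- hrr_table[hrr_table$group == g & !is.na(hrr_table$fatigue), ]
    if (nrow(d) < min_n) next
    med <- stats::median(d$fatigue)
    hi <- d$fatigue > med
    lo <- d$fatigue <= med
    if (!any(hi) || !any(lo) || length(unique(d$fatigue)) < 2) next
    if (sum(hi) < 2 || sum(lo) < 2) next
    tt <- stats::t.test(d$hrr[hi], d$hrr[lo])
    res[[length(res) + 1]] <- data.frame(
      group = g, mean_fatigue = mean(d$fatigue), n_high = sum(hi),
      n_low = sum(lo), hrr_high = mean(d$hrr[hi]), hrr_low = mean(d$hrr[lo]),
      t = unname(tt$statistic), p = tt$p.value,
      significant = tt$p.value < alpha, stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(group = character(0), mean_fatigue = numeric(0),
                      n_high = integer(0), n_low = integer(0),
                      hrr_high = numeric(0), hrr_low = numeric(0),
                      t = numeric(0), p = numeric(0), significant = logical(0)))
  do.call(rbind, res)
}
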
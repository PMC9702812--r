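#' Pipeline configuration
#'
#' Collects every stage's tunable parameters in one validated object: the
#' synthetic-cohort settings (or an input directory of per-modality CSVs),
#' the cleaning configuration, normalization variant, significance level
#' and heart-rate-recovery definition. All thresholds default to the
#' values of the underlying study protocol (accepted ranges, 30%/50%
#' contextual thresholds, 1/3/5-min windows, 100 steps and 80% lying for
#' L5, 70% coverage and 3-pair inclusion filters, 6-min/60-steps-per-min/
#' 3-s walking gates, alpha 0.05).
#'
#' @param cohort a [cohort_config()] describing the data to simulate.
#' @param cleaning a [cleaning_config()].
#' @param variant normalization variant(s) to run: subset of `c("b","a")`.
#' @param alpha significance level.
#' @param hrr_method recovery definition, see [detect_rest_and_hrr()].
#' @param seed master seed (defaults to the cohort seed).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), cleaning = cleaning_config(),
                            variant = c("b", "a"), alpha = 0.05,
                            hrr_method = "max_min", seed = cohort$seed) {
  variant <- match.arg(variant, c("b", "a"), several.ok = TRUE)
  stopifnot(inherits(cohort, "cohort_config"), inherits(cleaning, "cleaning_config"),
            alpha > 0, alpha < 1)
  structure(list(cohort = cohort, cleaning = cleaning, variant = variant,
                 alpha = alpha, hrr_method = hrr_method, seed = seed),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> clean -> quality -> aggregate/L5 -> normalize ->
#' associate -> heart-rate recovery on a synthetic cohort (or on a
#' pre-generated cohort bundle), returning a report bundle whose elements
#' are the per-stage tables. Deterministic per (config, seed): rerunning
#' with the same configuration yields an identical report hash.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-generated [generate_cohort()] bundle; when
#'   missing it is simulated from `config$cohort`.
#' @return A list of class `pipeline_report`: `cleaning`, `coverage`,
#'   `pro_coverage`, `aggregates`, `l5`, `l5_sleep`, `rmcorr` (per
#'   variant), `hrr_observations`, `hrr_representative`, `ancova`,
#'   `fatigue_split`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  if (!length(cohort$participants)) stop("stage simulate: empty cohort")
  ptab <- cohort$truth$participant_table
  groups <- stats::setNames(ptab$group, ptab$participant_id)

  cleaning <- list(); coverage <- list(); pro_cov <- list()
  aggs <- list(); l5_all <- list(); l5p_by_id <- list(); pro_all <- list()
  hrr_obs <- list(); hrr_rep <- list(); sleep_all <- list()
  norm <- stats::setNames(vector("list", length(config$variant)), config$variant)

  for (id in names(cohort$participants)) {
    b <- cohort$participants[[id]]
    cl <- clean_bundle(b$series, config$cleaning)
    cleaning[[id]] <- cbind(participant_id = id, cl$report)
    s <- cl$series

    rep_sleep <- repair_sleep_times(b$pro, config$cleaning$max_sleep_h)
    pro <- rep_sleep$pro[!rep_sleep$pro$sleep_unusable, , drop = FALSE]
    pro_all[[id]] <- pro

    # coverage (daily, midnight-to-midnight) and PRO coverage on wear days
    for (m in c("hr", "resp_rate", "skin_t")) {
      cv <- coverage_daily(s[[m]])
      coverage[[paste(id, m)]] <- cv$daily
    }
    cv_rr <- coverage_daily(s$rr_interval, method = "rr")
    coverage[[paste(id, "rr")]] <- cv_rr$daily
    wear_days <- unique(floor((s$hr$time - 1e-9) / 86400))
    pro_cov[[id]] <- cbind(participant_id = id, coverage_pro(pro, wear_days))

    # windows: 2-h aggregates anchored at PRO submissions; daily L5
    ag <- build_aggregates(s, pro)
    if (!is.null(ag)) aggs[[id]] <- ag
    l5 <- detect_l5_all(s$steps, s$posture)
    if (!is.null(l5)) {
      l5_all[[id]] <- l5
      l5p <- do.call(rbind, lapply(seq_len(nrow(l5)), function(i)
        l5_params(l5[i, ], s)))
      l5p_by_id[[id]] <- l5p
      for (v in config$variant) {
        nm <- normalize_aggregates(ag, l5p, v)
        if (!is.null(nm) && nrow(nm)) norm[[v]][[id]] <- nm
      }
      sleep_all[[id]] <- reported_sleep_intervals(pro)
    }

    # heart-rate recovery
    obs <- participant_hrr(s, method = config$hrr_method)
    if (nrow(obs)) {
      hrr_obs[[id]] <- cbind(participant_id = id, obs)
      hrr_rep[[id]] <- cbind(participant_id = id, representative_hrr(obs))
    }
  }

  pro_bound <- do.call(rbind, pro_all)
  norm_bound <- lapply(norm, function(nl) if (length(nl)) do.call(rbind, nl) else NULL)
  rmc <- lapply(norm_bound, function(nb) {
    if (is.null(nb)) return(NULL)
    correlation_matrix(nb, pro_bound, groups, alpha = config$alpha)
  })

  l5_sleep <- l5_sleep_agreement(do.call(rbind, l5_all), do.call(rbind, sleep_all))

  hrr_tab <- do.call(rbind, hrr_rep)
  anc <- NULL; fsplit <- NULL
  if (!is.null(hrr_tab) && nrow(hrr_tab)) {
    hrr_tab <- merge(hrr_tab, ptab[, c("participant_id", "group", "age", "sex")],
                     by = "participant_id")
    if (nlevels(factor(hrr_tab$group)) >= 2 && all(table(hrr_tab$group) >= 2)) {
      # small cohorts can make a covariate collinear with the group factor
      # (e.g. all-male patient groups); fall back to fewer covariates
      for (covs in list(c("age", "sex"), "age", character(0))) {
        anc <- tryCatch(ancova_groups(hrr_tab, covariates = covs),
                        error = function(e) NULL)
        if (!is.null(anc)) break
      }
    }
    fsplit <- fatigue_split(hrr_tab, pro_bound)
  }

  report <- list(cleaning = do.call(rbind, cleaning),
                 coverage = do.call(rbind, coverage),
                 pro_coverage = do.call(rbind, pro_cov),
                 aggregates = do.call(rbind, aggs),
                 l5 = do.call(rbind, l5_all),
                 l5_sleep = l5_sleep,
                 normalized = norm_bound,
                 pro = pro_bound,
                 rmcorr = rmc,
                 hrr_observations = do.call(rbind, hrr_obs),
                 hrr_representative = hrr_tab,
                 ancova = anc,
                 fatigue_split = fsplit,
                 participant_table = ptab)
  report$config_hash <- object_hash(list(config, report))
  class(report) <- "pipeline_report"
  report
}

# Absolute reported sleep intervals from repaired bed/wake PRO rows:
# bedtime hours >= 12 belong to the previous calendar day.
reported_sleep_intervals <- function(pro) {
  beds <- pro[pro$item == "bed_time", ]
  wakes <- pro[pro$item == "wake_time", ]
  if (!nrow(beds)) return(NULL)
  m <- merge(beds[, c("day", "value")], wakes[, c("day", "value")],
             by = "day", suffixes = c("_bed", "_wake"))
  if (!nrow(m)) return(NULL)
  start <- ifelse(m$value_bed >= 12, (m$day - 1) * 86400 + m$value_bed * 3600,
                  m$day * 86400 + m$value_bed * 3600)
  end <- m$day * 86400 + m$value_wake * 3600
  data.frame(day = m$day, start = start, end = end)[end > start, , drop = FALSE]
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  participants: %d\n", nrow(x$participant_table)))
  if (!is.null(x$coverage))
    cat(sprintf("  mean daily coverage: %.1f%%\n", 100 * mean(x$coverage$coverage)))
  if (!is.null(x$l5))
    cat(sprintf("  L5 windows: %d (within reported sleep +/-30 min: %.1f%%)\n",
                nrow(x$l5), 100 * x$l5_sleep$within_tol))
  for (v in names(x$rmcorr)) {
    rc <- x$rmcorr[[v]]
    if (!is.null(rc))
      cat(sprintf("  rmcorr (variant %s): %d cells, %d significant\n",
                  v, nrow(rc), sum(rc$significant)))
  }
  if (!is.null(x$ancova))
    cat(sprintf("  HRR ANCOVA: F = %.2f, p = %.4g, partial eta2(group) = %.3f\n",
                x$ancova$f, x$ancova$p, x$ancova$eta_partial[["group"]]))
  cat(sprintf("  config hash: %s\n", x$config_hash))
  invisible(x)
}
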
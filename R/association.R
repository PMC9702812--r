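#' Repeated-measures correlation
#'
#' Estimates the common within-participant linear association between two
#' repeatedly measured variables by removing between-participant
#' differences in level: in the analysis-of-covariance formulation
#' (participant as factor, `x` as covariate) the correlation is
#' `r = sign(slope) * sqrt(SS_x / (SS_x + SS_error))`, which equals the
#' Pearson correlation of the within-participant-centred observations. The
#' error degrees of freedom are `n_pairs - n_participants - 1`; the
#' p-value comes from `F(1, df)`, and the 95% CI from the Fisher
#' z-transform with `1/sqrt(df - 3)` standard error.
#'
#' @param participant factor/character of participant ids, one per pair.
#' @param x,y numeric observations.
#' @param min_pairs minimum pairs per participant; participants below it
#'   are excluded before estimation.
#' @return One-row data.frame: `r`, `df`, `p`, `ci_lo`, `ci_hi`,
#'   `n_pairs`, `n_participants`. `r` is NA when there is no
#'   within-participant variance in `x` or fewer than 2 participants
#'   survive.
#' @export
rmcorr <- function(participant, x, y, min_pairs = 3) {
  ok <- stats::complete.cases(participant, x, y)
  participant <- as.character(participant)[ok]; x <- x[ok]; y <- y[ok]
  cnt <- table(participant)
  keep <- participant %in% names(cnt)[cnt >= min_pairs]
  participant <- participant[keep]; x <- x[keep]; y <- y[keep]
  n <- length(x)
  k <- length(unique(participant))
  bad <- data.frame(r = NA_real_, df = NA_real_, p = NA_real_,
                    ci_lo = NA_real_, ci_hi = NA_real_,
                    n_pairs = n, n_participants = k)
  if (k < 2) return(bad)
  xc <- x - stats::ave(x, participant)
  yc <- y - stats::ave(y, participant)
  sxx <- sum(xc^2); syy <- sum(yc^2); sxy <- sum(xc * yc)
  if (sxx <= 0 || syy <= 0) return(bad)
  df <- n - k - 1
  if (df < 1) return(bad)
  r <- sign(sxy) * sqrt(sxy^2 / (sxx * syy))
  f <- if (r^2 < 1) r^2 / (1 - r^2) * df else Inf
  p <- stats::pf(f, 1, df, lower.tail = FALSE)
  if (df > 3 && abs(r) < 1) {
    z <- atanh(r); se <- 1 / sqrt(df - 3)
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  } else ci <- c(NA_real_, NA_real_)
  data.frame(r = r, df = df, p = p, ci_lo = ci[1], ci_hi = ci[2],
             n_pairs = n, n_participants = k)
}

#' Pair normalized feature aggregates with PRO responses
#'
#' Joins the normalized aggregate table to Likert PRO responses on
#' (participant, submission time) and applies the inclusion filters:
#' rows whose feature coverage is below `min_coverage` (70%) are dropped
#' (boundary kept: coverage exactly 0.70 survives), and participants with
#' fewer than `min_pairs` surviving pairs for a given feature-PRO
#' combination are excluded inside [rmcorr()].
#'
#' @param norm normalized aggregates ([normalize_aggregates()]) for one or
#'   more participants (rbind-ed), with coverage columns.
#' @param pro rbind-ed PRO tables.
#' @param feature feature column name.
#' @param item PRO item name.
#' @param min_coverage coverage threshold.
#' @return data.frame with `participant_id`, `x` (feature), `y` (PRO).
#' @export
filter_pairs <- function(norm, pro, feature, item, min_coverage = 0.70) {
  if (is.null(norm) || !nrow(norm)) return(NULL)
  fm <- feature_map()
  cov_col <- paste0(fm$channel[fm$feature == feature], "_coverage")
  pr <- pro[pro$item == item, c("participant_id", "time", "value")]
  m <- merge(norm[, c("participant_id", "anchor_time", feature, cov_col)],
             pr, by.x = c("participant_id", "anchor_time"),
             by.y = c("participant_id", "time"))
  m <- m[!is.na(m[[feature]]) & !is.na(m[[cov_col]]) &
           m[[cov_col]] >= min_coverage, ]
  if (!nrow(m)) return(NULL)
  data.frame(participant_id = m$participant_id, x = m[[feature]], y = m$value)
}

#' Repeated-measures correlation matrix over groups, features and PROs
#'
#' One [rmcorr()] result per (group, feature, PRO item) cell, as a
#' heat-map-ready long table with raw-p significance flags (no multiple
#' testing correction by default, matching the cellwise alpha flagging
#' convention; Benjamini-Hochberg flags can be added on top).
#'
#' @param norm rbind-ed normalized aggregates.
#' @param pro rbind-ed PRO tables.
#' @param groups named character: participant_id -> group label.
#' @param features feature columns to test (default: all mapped features
#'   present).
#' @param items PRO items to test (default: Likert items present).
#' @param alpha significance level.
#' @param bh also add a Benjamini-Hochberg adjusted flag column.
#' @param min_coverage,min_pairs inclusion filters, see [filter_pairs()].
#' @return Long data.frame: group, feature, item, r, df, p, ci_lo, ci_hi,
#'   n_pairs, n_participants, significant (+ `significant_bh`).
#' @export
correlation_matrix <- function(norm, pro, groups, features = NULL, items = NULL,
                               alpha = 0.05, bh = FALSE,
                               min_coverage = 0.70, min_pairs = 3) {
  if (is.null(features)) {
    fm <- feature_map()
    features <- fm$feature[fm$feature %in% names(norm)]
  }
  if (is.null(items)) {
    clock <- c("bed_time", "wake_time")
    items <- setdiff(unique(pro$item), clock)
  }
  res <- list()
  for (g in unique(groups)) {
    ids <- names(groups)[groups == g]
    ng <- norm[norm$participant_id %in% ids, , drop = FALSE]
    pg <- pro[pro$participant_id %in% ids, , drop = FALSE]
    for (f in features) for (it in items) {
      pairs <- filter_pairs(ng, pg, f, it, min_coverage)
      row <- if (is.null(pairs)) rmcorr(character(0), numeric(0), numeric(0))
             else rmcorr(pairs$participant_id, pairs$x, pairs$y, min_pairs)
      res[[length(res) + 1]] <- cbind(
        data.frame(group = g, feature = f, item = it, stringsAsFactors = FALSE),
        row)
    }
  }
  out <- do.call(rbind, res)
  out$significant <- !is.na(out$p) & out$p < alpha
  if (bh) {
    padj <- stats::p.adjust(out$p, method = "BH")
    out$significant_bh <- !is.na(padj) & padj < alpha
  }
  out
}
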
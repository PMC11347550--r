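#' Harrell's concordance index
#'
#' Over comparable pairs (`t_i < t_j` with subject i experiencing the
#' event), a pair is concordant when the earlier failure carries the higher
#' score (higher score = higher risk); tied scores receive half credit. A
#' Noether-type normal-approximation confidence interval is attached.
#'
#' @param scores risk scores (higher = higher risk).
#' @param times,events survival times and 0/1 event indicators.
#' @param conf confidence level (default 0.95).
#' @return list with `c_index`, `se`, `ci` (length 2), `n_pairs`.
#' @export
harrell_c <- function(scores, times, events, conf = 0.95) {
  n <- length(scores)
  if (n < 2 || sum(events) < 1)
    stop("invalid input: need n >= 2 and at least one event")
  lt <- outer(times, times, "<")
  comparable <- lt & (events == 1)
  m <- sum(comparable)
  if (m == 0) stop("undefined C: no comparable pairs")
  sd_ <- outer(scores, scores, "-")
  conc <- sum(comparable & sd_ > 0) + 0.5 * sum(comparable & sd_ == 0)
  cidx <- conc / m
  se <- sqrt(cidx * (1 - cidx) / m)
  z <- qnorm(1 - (1 - conf) / 2)
  list(c_index = cidx, se = se,
       ci = c(max(0, cidx - z * se), min(1, cidx + z * se)), n_pairs = m)
}

# Kaplan-Meier survival value at time u; left = TRUE gives the left limit
km_surv_at <- function(km, u, left = FALSE) {
  tms <- km$table$time
  keep <- if (left) tms < u else tms <= u + 1e-12
  if (!any(keep)) return(1)
  km$table$surv[max(which(keep))]
}

#' Kaplan-Meier estimate of the survival function
#'
#' Product-limit estimator; the median is the smallest observed event time
#' at which the estimate drops to 0.5 or below (`NA` when never reached).
#'
#' @param times,events survival times and 0/1 event indicators.
#' @return an object of class `km_estimate`: `table` (time, n_risk, n_event,
#'   n_censor, surv at each distinct time), `median`, `n`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) >= 1, length(times) == length(events))
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(u) sum(times >= u), 0)
  n_event <- vapply(ut, function(u) sum(times == u & events == 1), 0)
  n_censor <- vapply(ut, function(u) sum(times == u & events == 0), 0)
  surv <- cumprod(1 - n_event / n_risk)
  tab <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, surv = surv)
  med_idx <- which(surv <= 0.5 + 1e-12 & n_event > 0)
  med <- if (length(med_idx)) ut[min(med_idx)] else NA_real_
  structure(list(table = tab, median = med, n = length(times)),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("km_estimate: n = %d, median survival = %s\n", x$n,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' IPCW time-dependent (cumulative/dynamic) AUC at a horizon
#'
#' Cases are subjects with an observed event by the horizon, controls those
#' still under observation beyond it. Case contributions are weighted by the
#' inverse Kaplan-Meier estimate of the censoring survival at their event
#' time (Uno-type weights); with no censoring this reduces exactly to the
#' Mann-Whitney statistic of the score for the binary endpoint. The naive
#' unweighted estimator is available with `ipcw = FALSE`.
#'
#' @param scores risk scores (higher = higher risk).
#' @param times,events survival times and 0/1 event indicators.
#' @param horizon evaluation time within the observed range.
#' @param ipcw apply inverse-probability-of-censoring weights (default TRUE).
#' @return the AUC estimate (scalar).
#' @export
time_dependent_auc <- function(scores, times, events, horizon, ipcw = TRUE) {
  cases <- which(times <= horizon & events == 1)
  ctrls <- which(times > horizon)
  if (length(cases) == 0 || length(ctrls) == 0)
    stop("undefined AUC: need at least one case and one control at the horizon")
  if (ipcw) {
    km_c <- km_estimate(times, 1 - events) # censoring distribution
    wi <- vapply(times[cases], function(u)
      1 / max(km_surv_at(km_c, u, left = TRUE), 1e-12), 0)
  } else {
    wi <- rep(1, length(cases))
  }
  cmp <- outer(scores[cases], scores[ctrls], "-")
  ind <- (cmp > 0) + 0.5 * (cmp == 0)
  sum(wi * rowSums(ind)) / (sum(wi) * length(ctrls))
}

#' Log-rank test and hazard ratio for a two-group stratification
#'
#' The log-rank statistic is the standard observed-minus-expected chi-square
#' with one degree of freedom; the hazard ratio (second level vs first,
#' i.e. high vs low for [stratify()] output) and its Wald confidence
#' interval come from a univariate Cox fit on the group indicator.
#'
#' @param times,events survival times and 0/1 event indicators.
#' @param groups two-level factor (or coercible); the hazard ratio is for
#'   the second level relative to the first.
#' @param conf confidence level (default 0.95).
#' @return list with `p` (log-rank), `chisq`, `hr`, `ci`, `n` per group.
#' @export
logrank_and_hr <- function(times, events, groups, conf = 0.95) {
  g <- as.factor(groups)
  if (nlevels(g) != 2) stop("invalid input: exactly two groups required")
  if (any(table(g) == 0)) stop("invalid input: both groups must be nonempty")
  ind <- as.numeric(g == levels(g)[2])
  ev_times <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (u in ev_times) {
    at <- times >= u
    n_all <- sum(at); n1 <- sum(at & ind == 1)
    d <- sum(times == u & events == 1)
    d1 <- sum(times == u & events == 1 & ind == 1)
    O <- O + d1
    E <- E + d * n1 / n_all
    if (n_all > 1)
      V <- V + d * (n1 / n_all) * (1 - n1 / n_all) * (n_all - d) / (n_all - 1)
  }
  chisq <- if (V > 0) (O - E)^2 / V else 0
  p <- if (V > 0) pchisq(chisq, df = 1, lower.tail = FALSE) else 1
  fit <- fit_cox(matrix(ind, ncol = 1, dimnames = list(NULL, "group_high")),
                 times, events)
  z <- qnorm(1 - (1 - conf) / 2)
  b <- fit$coefficients[[1]]; se <- fit$se[[1]]
  list(p = p, chisq = chisq, hr = exp(b),
       ci = exp(c(b - z * se, b + z * se)),
       n = as.vector(table(g)))
}

#' Stratify scores into low/high risk groups at a cutoff
#'
#' High risk iff `score > cutoff` (strictly); scores at the cutoff are
#' low risk. In the pipeline the cutoff is the median training-set score,
#' frozen before evaluation on other splits.
#'
#' @param scores numeric risk scores.
#' @param cutoff finite cutoff value.
#' @return factor with levels `low`, `high`.
#' @export
stratify <- function(scores, cutoff) {
  if (!is.finite(cutoff)) stop("invalid input: cutoff must be finite")
  factor(ifelse(scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Point-scale nomogram for a fitted Cox model
#'
#' Maps each covariate's contribution range (over the data the model was
#' fitted on) to a 0-100 point scale where 100 points equal the largest
#' single-covariate range. Total points are affinely equivalent to the
#' linear predictor, and survival at a horizon is
#' `exp(-Lambda0(h))^exp(lp)` with the Breslow baseline hazard, so the
#' points path reproduces the direct Cox prediction exactly.
#'
#' @param fit a `cox_fit` with at least one covariate.
#' @param horizons numeric vector of evaluation times (days), all within the
#'   fitted baseline hazard's support.
#' @return an object of class `nomogram`: per-covariate `table`
#'   (beta, reference value, points at the range ends), `points_per_lp`,
#'   `lp_offset`, `horizons`, plus the fitted baseline hazard.
#' @export
nomogram <- function(fit, horizons) {
  stopifnot(inherits(fit, "cox_fit"))
  if (any(horizons > fit$max_time))
    stop("horizon beyond the baseline hazard's support")
  cf <- fit$coefficients
  rng <- fit$x_range
  lo_contrib <- pmin(cf * rng[1, ], cf * rng[2, ])
  hi_contrib <- pmax(cf * rng[1, ], cf * rng[2, ])
  widths <- hi_contrib - lo_contrib
  maxw <- max(widths)
  if (maxw <= 0) stop("nomogram: no covariate varies over the data")
  tab <- data.frame(covariate = names(cf), beta = unname(cf),
                    min = rng[1, ], max = rng[2, ],
                    points_min = unname((cf * rng[1, ] - lo_contrib) / maxw * 100),
                    points_max = unname((cf * rng[2, ] - lo_contrib) / maxw * 100))
  structure(list(table = tab, max_width = maxw,
                 lp_offset = sum(lo_contrib),
                 baseline_cumhaz = fit$baseline_cumhaz,
                 max_time = fit$max_time, horizons = horizons,
                 coefficients = cf),
            class = "nomogram")
}

#' @rdname nomogram
#' @param nom a `nomogram`.
#' @param x named covariate values for one patient.
#' @return `nomogram_points()`: list with per-covariate `points` and `total`.
#' @export
nomogram_points <- function(nom, x) {
  cf <- nom$coefficients
  xv <- vapply(names(cf), function(nm) as.numeric(x[[nm]]), 0)
  lo <- pmin(cf * nom$table$min, cf * nom$table$max)
  pts <- (cf * xv - lo) / nom$max_width * 100
  list(points = pts, total = sum(pts))
}

#' @rdname nomogram
#' @param total_points summed points for a patient.
#' @param horizon evaluation time.
#' @return `nomogram_survival()`: predicted survival probability.
#' @export
nomogram_survival <- function(nom, total_points, horizon) {
  if (horizon > nom$max_time) stop("horizon beyond the baseline hazard's support")
  lp <- total_points / 100 * nom$max_width + nom$lp_offset
  keep <- nom$baseline_cumhaz$time <= horizon + 1e-12
  L0 <- if (any(keep)) nom$baseline_cumhaz$cumhaz[max(which(keep))] else 0
  exp(-L0)^exp(lp)
}

#' Direct Cox survival prediction at a horizon
#'
#' @param fit a `cox_fit`.
#' @param x named covariate values for one patient.
#' @param horizon evaluation time within the fitted support.
#' @return predicted survival probability `exp(-Lambda0(h))^exp(beta'x)`.
#' @export
cox_survival <- function(fit, x, horizon) {
  stopifnot(inherits(fit, "cox_fit"))
  if (horizon > fit$max_time) stop("horizon beyond the baseline hazard's support")
  cf <- fit$coefficients
  lp <- sum(cf * vapply(names(cf), function(nm) as.numeric(x[[nm]]), 0))
  keep <- fit$baseline_cumhaz$time <= horizon + 1e-12
  L0 <- if (any(keep)) fit$baseline_cumhaz$cumhaz[max(which(keep))] else 0
  exp(-L0)^exp(lp)
}

#' Calibration of predicted survival probabilities against Kaplan-Meier
#'
#' Groups patients into quantile bins of the predicted survival probability
#' at the horizon and contrasts the bin's mean prediction with the observed
#' Kaplan-Meier estimate (with a Greenwood confidence interval). Bins that
#' cannot be formed from tied predictions reduce the bin count with a
#' warning.
#'
#' @param predicted_surv predicted survival probabilities at `horizon`.
#' @param times,events observed survival outcomes.
#' @param horizon evaluation time.
#' @param n_bins number of quantile bins (default 3, suited to small
#'   validation splits).
#' @return data frame with `n`, `mean_predicted`, `observed`, `lower`,
#'   `upper` per bin.
#' @export
calibration_curve <- function(predicted_surv, times, events, horizon, n_bins = 3L) {
  n <- length(predicted_surv)
  if (n < n_bins * 5) stop("invalid input: need at least 5 patients per bin")
  repeat {
    brk <- unique(quantile(predicted_surv, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(brk) >= n_bins + 1L || n_bins == 1L) break
    n_bins <- n_bins - 1L
    warning("reducing calibration bins to ", n_bins, " (tied predictions)")
  }
  bins <- if (length(brk) <= 2L) rep(1L, n) else
    cut(predicted_surv, brk, include.lowest = TRUE, labels = FALSE)
  out <- lapply(sort(unique(bins)), function(b) {
    sel <- bins == b
    km <- km_estimate(times[sel], events[sel])
    s_obs <- km_surv_at(km, horizon)
    tab <- km$table[km$table$time <= horizon + 1e-12 & km$table$n_event > 0, , drop = FALSE]
    gw <- s_obs^2 * sum(tab$n_event / (tab$n_risk * (tab$n_risk - tab$n_event)))
    half <- 1.96 * sqrt(max(gw, 0))
    data.frame(n = sum(sel), mean_predicted = mean(predicted_surv[sel]),
               observed = s_obs,
               lower = max(0, s_obs - half), upper = min(1, s_obs + half))
  })
  do.call(rbind, out)
}

#' Compare model-based and size-based risk stratification
#'
#' Runs [logrank_and_hr()] twice on the same patients: once for the model's
#' cutoff stratification and once for the size-based progression labels,
#' reporting the pairs side by side (no test between the two hazard ratios).
#'
#' @param scores model risk scores.
#' @param cutoff stratification cutoff (training-set median).
#' @param progression_labels 0/1 size-based progression calls.
#' @param times,events survival outcomes.
#' @return list with elements `model` and `size`, each a [logrank_and_hr()]
#'   result.
#' @export
compare_stratifiers <- function(scores, cutoff, progression_labels, times, events) {
  if (length(progression_labels) != length(scores))
    stop("both groupings must cover the same patients")
  model_groups <- stratify(scores, cutoff)
  size_groups <- factor(ifelse(progression_labels == 1, "high", "low"),
                        levels = c("low", "high"))
  list(model = logrank_and_hr(times, events, model_groups),
       size = logrank_and_hr(times, events, size_groups))
}
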
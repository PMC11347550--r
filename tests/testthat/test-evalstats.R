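test_that("harrell_c handles perfect, reversed, and tied-score toy cases", {
  expect_equal(harrell_c(c(3, 2, 1), c(1, 2, 3), c(1, 1, 1))$c_index, 1)
  expect_equal(harrell_c(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1))$c_index, 0)
  # pairs: (1,2) tied scores -> 0.5, (1,3) and (2,3) concordant
  h <- harrell_c(c(2, 2, 1), c(1, 2, 3), c(1, 1, 0))
  expect_equal(h$c_index, 2.5 / 3)
  expect_true(h$ci[1] <= h$c_index && h$c_index <= h$ci[2])
  expect_error(harrell_c(c(1, 2), c(1, 2), c(0, 0)), "at least one event")
})

test_that("harrell_c on negated tie-free scores is 1 - C", {
  set.seed(14)
  for (r in 1:10) {
    d <- sim_surv(40)
    h <- harrell_c(d$x, d$times, d$events)
    expect_equal(harrell_c(-d$x, d$times, d$events)$c_index, 1 - h$c_index,
                 tolerance = 1e-12)
  }
})

test_that("km_estimate matches hand products and degenerate cases", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$table$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)
  km1 <- km_estimate(5, 0) # single censored patient
  expect_equal(km1$table$surv, 1)
  expect_true(is.na(km1$median))
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$table$surv, c(2/3, 2/3, 0)) # risk set {3} alone at t = 3
  # no censoring: KM equals the empirical survival function
  set.seed(3)
  tt <- sort(runif(30))
  km3 <- km_estimate(tt, rep(1, 30))
  expect_equal(km3$table$surv, 1 - seq_len(30) / 30)
})

test_that("survival statistics agree with the reference implementation", {
  skip_if_not_installed("survival")
  set.seed(99)
  checked <- 0
  for (r in 1:50) {
    d <- sim_surv(sample(20:45, 1))
    if (sum(d$events) < 3 || sum(d$events) > length(d$x) - 2) next
    h <- harrell_c(d$x, d$times, d$events)
    ref_c <- survival::concordance(
      survival::Surv(d$times, d$events) ~ d$x, reverse = TRUE)$concordance
    expect_equal(h$c_index, ref_c, tolerance = 1e-6)
    km <- km_estimate(d$times, d$events)
    sf <- summary(survival::survfit(survival::Surv(d$times, d$events) ~ 1),
                  times = km$table$time)
    expect_equal(km$table$surv, sf$surv, tolerance = 1e-6)
    g <- factor(ifelse(d$x > median(d$x), "high", "low"), c("low", "high"))
    if (min(table(g, d$events)[, "1"]) < 1) next
    lrh <- tryCatch(logrank_and_hr(d$times, d$events, g),
                    error = function(e) NULL)
    if (is.null(lrh)) next
    sd_ <- survival::survdiff(survival::Surv(d$times, d$events) ~ g)
    expect_equal(lrh$p, sd_$pvalue, tolerance = 1e-6)
    cph <- survival::coxph(survival::Surv(d$times, d$events) ~ I(g == "high"),
                           ties = "breslow")
    expect_equal(lrh$hr, unname(exp(stats::coef(cph))), tolerance = 1e-6)
    checked <- checked + 1
  }
  expect_gte(checked, 30)
})

test_that("logrank_and_hr on duplicated groups gives hr 1 and p 1", {
  times <- c(3, 5, 8, 11, 14, 3, 5, 8, 11, 14)
  events <- c(1, 0, 1, 1, 0, 1, 0, 1, 1, 0)
  g <- rep(c("low", "high"), each = 5)
  res <- logrank_and_hr(times, events, factor(g, c("low", "high")))
  expect_equal(res$hr, 1, tolerance = 1e-8)
  expect_equal(res$p, 1, tolerance = 1e-8)
})

test_that("fully separated groups give small p and large hr", {
  times <- c(1:8, 101:108)
  events <- rep(1, 16)
  g <- factor(rep(c("high", "low"), each = 8), c("low", "high"))
  res <- logrank_and_hr(times, events, g)
  expect_lt(res$p, 0.01)
  expect_gt(res$hr, 1)
})

test_that("time-dependent AUC: no-censoring equals Mann-Whitney; separation gives 1", {
  set.seed(21)
  n <- 60
  sc <- rnorm(n)
  tt <- rexp(n, exp(sc) / 5)
  h <- quantile(tt, 0.4)
  lab <- tt <= h
  mw <- mean(outer(sc[lab], sc[!lab], ">") + 0.5 * outer(sc[lab], sc[!lab], "=="))
  expect_identical(time_dependent_auc(sc, tt, rep(1, n), h), mw)
  # all case scores above all control scores
  sc2 <- ifelse(lab, 10 + rnorm(n), rnorm(n))
  expect_equal(time_dependent_auc(sc2, tt, rep(1, n), h), 1)
  expect_error(time_dependent_auc(sc, tt, rep(1, n), max(tt) + 1), "control")
})

test_that("stratification uses a strict cutoff and the training median halves odd cohorts", {
  expect_identical(as.character(stratify(c(0.66, 0.67, 0.1), 0.66)),
                   c("low", "high", "low"))
  expect_true(all(stratify(c(-1, -2), 0) == "low"))
  set.seed(6)
  sc <- rnorm(21)
  g <- stratify(sc, median(sc))
  expect_equal(sum(g == "high"), 10) # (n - 1) / 2 above the median
})

test_that("nomogram points round-trip to the direct Cox prediction", {
  set.seed(41)
  n <- 120
  x1 <- rbinom(n, 1, 0.4); x2 <- rnorm(n); x3 <- runif(n, 0, 3)
  lp <- 0.8 * x1 - 0.5 * x2 + 0.3 * x3
  tt <- rexp(n, exp(lp) / 200); ce <- runif(n, 0, 600)
  times <- pmin(tt, ce); events <- as.integer(tt <= ce)
  fit <- fit_cox(cbind(x1 = x1, x2 = x2, x3 = x3), times, events)
  h <- unname(quantile(times, 0.5))
  nom <- nomogram(fit, horizons = h)
  # single-covariate nomogram: points span exactly 0..100
  fit1 <- fit_cox(matrix(x2, ncol = 1, dimnames = list(NULL, "x2")), times, events)
  nom1 <- nomogram(fit1, horizons = h)
  expect_equal(sort(c(nom1$table$points_min, nom1$table$points_max)),
               c(0, 100), tolerance = 1e-9)
  # baseline patient: lp = 0 gives exp(-Lambda0(h))
  zero <- list(x1 = 0, x2 = 0, x3 = 0)
  keep <- fit$baseline_cumhaz$time <= h
  expect_equal(cox_survival(fit, zero, h),
               exp(-fit$baseline_cumhaz$cumhaz[max(which(keep))]))
  for (i in sample(n, 10)) {
    x <- list(x1 = x1[i], x2 = x2[i], x3 = x3[i])
    np <- nomogram_points(nom, x)
    expect_equal(nomogram_survival(nom, np$total, h), cox_survival(fit, x, h),
                 tolerance = 1e-6)
  }
  expect_error(nomogram(fit, horizons = max(times) + 1), "support")
})

test_that("calibration is tight for the true model and detects anti-calibration", {
  set.seed(52)
  n <- 1000
  x <- rnorm(n)
  lp <- 0.8 * x
  rate <- exp(lp) / 300
  tt <- rexp(n, rate); ce <- runif(n, 0, 900)
  times <- pmin(tt, ce); events <- as.integer(tt <= ce)
  h <- 300
  pred <- exp(-rate * h) # true exponential survival at the horizon
  cal <- calibration_curve(pred, times, events, h, n_bins = 3)
  expect_equal(nrow(cal), 3)
  expect_lt(max(abs(cal$mean_predicted - cal$observed)), 0.1)
  anti <- calibration_curve(1 - pred, times, events, h, n_bins = 3)
  fitslope <- stats::coef(stats::lm(anti$observed ~ anti$mean_predicted))[2]
  expect_lt(fitslope, 0)
  const <- calibration_curve(rep(0.5, n), times, events, h, n_bins = 3)
  expect_equal(nrow(const), 1) # single effective bin
  expect_equal(const$observed, km_surv_at_horizon <- {
    km <- km_estimate(times, events)
    tab <- km$table
    tab$surv[max(which(tab$time <= h))]
  })
})

test_that("informative model groups beat random progression labels in nearly all replicates", {
  set.seed(71)
  better <- 0; valid <- 0
  for (r in 1:100) {
    d <- sim_surv(100, beta = 1.2)
    prog <- rbinom(100, 1, 0.4) # uninformative size-based call
    cmp <- tryCatch(
      compare_stratifiers(d$x, median(d$x), prog, d$times, d$events),
      error = function(e) NULL)
    if (is.null(cmp)) next
    valid <- valid + 1
    if (cmp$model$hr > cmp$size$hr) better <- better + 1
  }
  expect_gte(valid, 90)
  expect_gte(better / valid, 0.9)
})

test_that("compare_stratifiers reports identical pairs for identical groupings", {
  set.seed(61)
  d <- sim_surv(80)
  cutoff <- median(d$x)
  prog <- as.integer(d$x > cutoff)
  res <- compare_stratifiers(d$x, cutoff, prog, d$times, d$events)
  expect_equal(res$model$hr, res$size$hr, tolerance = 1e-10)
  expect_equal(res$model$p, res$size$p, tolerance = 1e-10)
})
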
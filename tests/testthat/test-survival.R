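test_that("Kaplan-Meier estimates match hand product-limit computations", {
  km <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(km$survival, c(0.5, 0))
  expect_equal(km$median, 1)

  # censored record after the event leaves the curve at 0.5 -> median 1
  km2 <- km_estimate(c(1, 2), c(1, 0))
  expect_equal(km2$times, 1)
  expect_equal(km2$survival, 0.5)
  expect_equal(km2$median, 1)

  # events at 1,3,5 with censors at 2,4,6:
  # S(1)=5/6, S(3)=5/6*3/4=0.625, S(5)=0.625*1/2=0.3125
  km3 <- km_estimate(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(km3$times, c(1, 3, 5))
  expect_equal(km3$survival, c(5 / 6, 0.625, 0.3125), tolerance = 1e-12)
  expect_equal(km3$at_risk, c(6, 4, 2))
  expect_equal(km3$median, 5)

  # median undefined when the curve never reaches 0.5
  km4 <- km_estimate(c(1, 2, 3, 4), c(1, 0, 0, 0))
  expect_true(is.na(km4$median))
})

test_that("without censoring the KM curve is the empirical survivor function", {
  times <- withr::with_seed(7, stats::rexp(40, 0.1))
  km <- km_estimate(times, rep(1, 40))
  for (i in seq_along(km$times)) {
    expect_equal(km$survival[i], mean(times > km$times[i]),
                 tolerance = 1e-12)
  }
})

test_that("log-rank is zero for identical groups and symmetric in labels", {
  g <- data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1))
  same <- logrank(g, g)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  a <- two_arm_cohort(30, 0.4, seed = 11)
  x <- a[a$arm == "a", ]; y <- a[a$arm == "b", ]
  expect_equal(logrank(x, y)$chi2, logrank(y, x)$chi2, tolerance = 1e-12)
  expect_equal(gbw_test(x, y)$chi2, gbw_test(y, x)$chi2, tolerance = 1e-12)
})

test_that("log-rank matches survdiff and an independent O/E/V tabulation", {
  dat <- two_arm_cohort(50, 0.3, seed = 13, censor = 0.3)
  x <- dat[dat$arm == "a", ]; y <- dat[dat$arm == "b", ]
  mine <- logrank(x, y)

  sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = dat)
  expect_equal(mine$chi2, unname(sd$chisq), tolerance = 1e-9)

  oracle <- oracle_weighted_logrank_chi2(dat$time, dat$event,
                                         dat$arm == "a")
  expect_equal(mine$chi2, oracle, tolerance = 1e-9)
})

test_that("Gehan-Breslow-Wilcoxon matches its oracle and degenerates to log-rank", {
  dat <- two_arm_cohort(50, 0.3, seed = 17, censor = 0.3)
  x <- dat[dat$arm == "a", ]; y <- dat[dat$arm == "b", ]
  oracle <- oracle_weighted_logrank_chi2(dat$time, dat$event,
                                         dat$arm == "a", gehan = TRUE)
  expect_equal(gbw_test(x, y)$chi2, oracle, tolerance = 1e-9)

  # single event time: the at-risk weight cancels out of the statistic
  a1 <- data.frame(time = c(5, 5, 5), event = c(1, 1, 0))
  b1 <- data.frame(time = c(5, 5), event = c(1, 0))
  expect_equal(gbw_test(a1, b1)$chi2, logrank(a1, b1)$chi2,
               tolerance = 1e-12)
})

test_that("survival tests are invariant to time-unit rescaling", {
  dat <- two_arm_cohort(30, 0.5, seed = 19, censor = 0.2)
  x <- dat[dat$arm == "a", ]; y <- dat[dat$arm == "b", ]
  xs <- transform(x, time = time * 30.44)  # months -> days
  ys <- transform(y, time = time * 30.44)
  expect_equal(logrank(x, y)$chi2, logrank(xs, ys)$chi2, tolerance = 1e-12)
  expect_equal(gbw_test(x, y)$chi2, gbw_test(xs, ys)$chi2,
               tolerance = 1e-12)
})

test_that("hazard ratio is ~1 for identical groups and reciprocal under swap", {
  g <- two_arm_cohort(40, 1, seed = 23)[, c("time", "event")]
  hr_same <- hazard_ratio(g, g)
  expect_equal(hr_same$hr, 1, tolerance = 1e-6)
  expect_true(hr_same$ci_low <= 1 && 1 <= hr_same$ci_high)

  dat <- two_arm_cohort(40, 0.5, seed = 29, censor = 0.2)
  x <- dat[dat$arm == "a", ]; y <- dat[dat$arm == "b", ]
  h1 <- hazard_ratio(x, y)
  h2 <- hazard_ratio(y, x)
  expect_equal(h1$hr, 1 / h2$hr, tolerance = 1e-9)
})

test_that("a group with no events yields a flagged degenerate estimate", {
  ref <- data.frame(time = c(1, 2, 3), event = c(1, 1, 1))
  none <- data.frame(time = c(4, 5, 6), event = c(0, 0, 0))
  h <- hazard_ratio(ref, none)
  expect_true(h$degenerate)
  expect_equal(h$hr, 0)
  h2 <- hazard_ratio(none, ref)
  expect_equal(h2$hr, Inf)
})

test_that("cutoff scan enumerates candidates between the quartiles only", {
  co <- generate_survival_cohort(cohort_gen_config(
    n_patients = 120, true_hr = 0.4, censor_rate = 0.2, seed = 31))
  scan <- best_cutoff_scan(co)
  q <- stats::quantile(co$expression, c(0.25, 0.75), names = FALSE)
  expect_true(all(scan$candidates >= q[1] & scan$candidates <= q[2]))
  expect_equal(scan$best_p, min(scan$scan$p, na.rm = TRUE))
  expect_true(scan$hr$hr < 1)  # high expression planted protective
})

test_that("with a bimodal gap the best cutoff falls inside the gap", {
  # expression separated at [2, 8]; hazard differs only across the gap
  co <- withr::with_seed(37, {
    high <- rep(c(FALSE, TRUE), each = 60)
    tibble::tibble(
      patient = sprintf("P%03d", 1:120),
      time = stats::rexp(120, 0.03 * ifelse(high, 0.3, 1)),
      event = 1L,
      expression = ifelse(high, stats::runif(120, 8, 10),
                          stats::runif(120, 0, 2)))
  })
  scan <- best_cutoff_scan(co)
  # the chosen split recovers the planted gap grouping (cutoffs adjacent
  # to the gap differ by a single patient and are statistically
  # indistinguishable, so we assert group agreement, not the exact value)
  planted_high <- co$expression >= 8
  expect_gte(mean(scan$groups == planted_high), 0.95)
  expect_lt(scan$best_p, 1e-6)
})

test_that("two distinct expression values enumerate both candidates", {
  co <- withr::with_seed(41, tibble::tibble(
    patient = sprintf("P%02d", 1:40),
    time = stats::rexp(40, c(rep(0.1, 20), rep(0.02, 20))),
    event = 1L,
    expression = rep(c(1, 2), each = 20)))
  scan <- best_cutoff_scan(co)
  expect_equal(scan$scan$cutoff, 2)  # cutoff 1 leaves an empty low group
  expect_equal(scan$best_cutoff, 2)
})

test_that("degenerate cohorts are rejected", {
  co <- tibble::tibble(patient = as.character(1:10), time = 1:10,
                       event = 1L, expression = 5)
  expect_error(best_cutoff_scan(co), "constant expression")
  expect_error(best_cutoff_scan(co[1:5, ]), "at least 8")
})

test_that("null cutoff scans are anticonservative, as documented", {
  best_p <- vapply(1:20, function(i) {
    co <- generate_survival_cohort(cohort_gen_config(
      n_patients = 364, true_hr = 1, censor_rate = 0.3, seed = 5000 + i))
    best_cutoff_scan(co)$best_p
  }, numeric(1))
  # min over many correlated cutoff tests inflates the nominal 5% rate
  expect_gt(mean(best_p < 0.05), 0.15)
})

test_that("permutation correction tempers the null best-p", {
  co <- generate_survival_cohort(cohort_gen_config(
    n_patients = 80, true_hr = 1, censor_rate = 0.2, seed = 43))
  scan <- best_cutoff_scan(co, n_perm = 30, seed = 7)
  expect_gt(scan$perm_p, scan$best_p)
})

test_that("survival tables round-trip through the TSV reader", {
  co <- generate_survival_cohort(cohort_gen_config(
    n_patients = 30, true_hr = 0.5, censor_rate = 0.2, seed = 47))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(co[, c("patient", "time", "event", "expression", "sex")],
                   path, progress = FALSE)
  back <- read_survival_table(path)
  expect_equal(back$time, co$time)
  expect_equal(back$event, co$event)
})
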
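#' Read a survival table
#'
#' Tab-delimited with header `patient<TAB>time<TAB>event<TAB>expression`
#' and an optional `sex` column (`M`/`F`). Times are in months; `event`
#' is 1 for an observed event and 0 for censoring.
#'
#' @param path Path to the TSV file.
#' @return A tibble with the columns above.
#' @export
read_survival_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    patient = readr::col_character(),
    time = readr::col_double(),
    event = readr::col_integer(),
    expression = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  stopifnot(all(c("patient", "time", "event", "expression") %in% names(tab)))
  if (any(tab$time < 0)) stop("negative survival times")
  if (!all(tab$event %in% c(0L, 1L))) stop("event must be 0 or 1")
  tab
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator \eqn{S(t) = \prod_{t_i \le t} (1 - d_i/n_i)}
#' over the distinct event times, with records censored at an event time
#' counted as still at risk at that time. The median is the smallest
#' event time with \eqn{S(t) \le 0.5}, `NA` if the curve never reaches
#' 0.5. Fitted via [survival::survfit()].
#'
#' @param time Nonnegative follow-up times (months).
#' @param event Event indicator (1 event, 0 censored).
#' @return A list of class `km_curve` with `times` (distinct event
#'   times), `survival`, `at_risk`, `events`, `median`, and `n`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event),
            all(time >= 0), all(event %in% c(0, 1)))
  if (all(time == 0) && all(event == 0)) {
    stop("degenerate curve: all times zero with no events")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  is_event <- fit$n.event > 0
  times <- fit$time[is_event]
  surv <- fit$surv[is_event]
  med <- if (any(surv <= 0.5)) times[which(surv <= 0.5)[1]] else NA_real_
  structure(
    list(times = times, survival = surv,
         at_risk = fit$n.risk[is_event], events = fit$n.event[is_event],
         median = med, n = length(time)),
    class = "km_curve"
  )
}

#' Write a Kaplan-Meier curve as TSV
#'
#' @param km A `km_curve` from [km_estimate()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(km, path) {
  readr::write_tsv(tibble::tibble(
    time = km$times, survival = km$survival,
    at_risk = km$at_risk, events = km$events
  ), path, progress = FALSE)
  invisible(path)
}

# Weighted log-rank O/E/V tabulation over pooled distinct event times.
# weight_fn maps the total number at risk n_i to the weight at that time:
# 1 for the Mantel-Haenszel log-rank, n_i for Gehan-Breslow-Wilcoxon.
weighted_logrank <- function(a, b, weight_fn, method) {
  for (g in list(a, b)) {
    stopifnot(is.data.frame(g), all(c("time", "event") %in% names(g)))
    if (nrow(g) == 0) stop("empty group in survival comparison")
  }
  time <- c(a$time, b$time)
  event <- c(a$event, b$event)
  in_a <- rep(c(TRUE, FALSE), c(nrow(a), nrow(b)))
  if (sum(event) == 0) stop("no events in pooled data")

  event_times <- sort(unique(time[event == 1]))
  # at-risk and event counts at each distinct event time, overall and in a
  n_i <- vapply(event_times, function(t) sum(time >= t), numeric(1))
  n_ai <- vapply(event_times, function(t) sum(time >= t & in_a), numeric(1))
  idx <- match(time[event == 1], event_times)
  d_i <- tabulate(idx, nbins = length(event_times))
  d_ai <- tabulate(idx[in_a[event == 1]], nbins = length(event_times))

  w <- vapply(n_i, weight_fn, numeric(1))
  oe <- d_ai - d_i * n_ai / n_i
  v <- ifelse(n_i > 1,
              d_i * (n_ai / n_i) * (1 - n_ai / n_i) * (n_i - d_i) / (n_i - 1),
              0)
  num <- sum(w * oe)
  den <- sum(w^2 * v)
  o_a <- sum(d_ai)
  e_a <- sum(d_i * n_ai / n_i)
  chi2 <- if (den > 0) num^2 / den else 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  structure(
    list(chi2 = chi2, p = p, method = method,
         observed_a = o_a, expected_a = e_a),
    class = "group_comparison"
  )
}

#' Log-rank (Mantel-Haenszel) test
#'
#' Compares event incidence between two groups across the pooled distinct
#' event times: \eqn{\chi^2 = (\sum (O_a - E_a))^2 / \sum V} on 1 df,
#' where at each event time \eqn{O_a} and \eqn{E_a} are the observed and
#' expected events in group `a` and \eqn{V} the hypergeometric variance.
#'
#' @param a,b Data frames with columns `time` and `event`.
#' @return A list with `chi2`, `p`, `method`, `observed_a`, `expected_a`.
#' @export
logrank <- function(a, b) {
  weighted_logrank(a, b, function(n_i) 1, "logrank")
}

#' Gehan-Breslow-Wilcoxon test
#'
#' Weighted log-rank variant weighting each event time by the total
#' number at risk, which emphasizes early survival differences. With a
#' single event time the weights cancel and the statistic equals the
#' log-rank test exactly.
#'
#' @inheritParams logrank
#' @return As [logrank()], with `method = "gbw"`.
#' @export
gbw_test <- function(a, b) {
  weighted_logrank(a, b, function(n_i) n_i, "gbw")
}

#' Hazard ratio of one group versus a reference
#'
#' Univariate proportional-hazards estimate for the two-group comparison,
#' fitted by partial-likelihood Newton iteration with Breslow tie
#' handling (via [survival::coxph()]). The returned `hr` is the hazard of
#' `comparison` relative to `reference`; the 95% confidence interval is
#' `exp(log hr +/- 1.96 SE)` from the observed information. When either
#' group has no events the estimate is degenerate (0 or `Inf`) and
#' returned with `degenerate = TRUE` instead of an error.
#'
#' @param reference,comparison Data frames with columns `time`, `event`.
#' @return A list with `hr`, `ci_low`, `ci_high`, `p` (Wald),
#'   `log_hr`, `se`, `degenerate`.
#' @export
hazard_ratio <- function(reference, comparison) {
  for (g in list(reference, comparison)) {
    stopifnot(is.data.frame(g), all(c("time", "event") %in% names(g)))
    if (nrow(g) == 0) stop("empty group in hazard-ratio estimation")
  }
  if (sum(comparison$event) == 0 || sum(reference$event) == 0) {
    hr <- if (sum(comparison$event) == 0) 0 else Inf
    return(list(hr = hr, ci_low = NA_real_, ci_high = NA_real_,
                p = NA_real_, log_hr = log(hr), se = NA_real_,
                degenerate = TRUE))
  }
  dat <- data.frame(
    time = c(reference$time, comparison$time),
    event = c(reference$event, comparison$event),
    grp = rep(c(0, 1), c(nrow(reference), nrow(comparison)))
  )
  fit <- survival::coxph(survival::Surv(time, event) ~ grp, data = dat,
                         ties = "breslow")
  log_hr <- unname(stats::coef(fit)[1])
  se <- sqrt(unname(fit$var[1, 1]))
  list(hr = exp(log_hr),
       ci_low = exp(log_hr - 1.96 * se),
       ci_high = exp(log_hr + 1.96 * se),
       p = 2 * stats::pnorm(-abs(log_hr / se)),
       log_hr = log_hr, se = se, degenerate = FALSE)
}

#' Best-cutoff dichotomization of an expression marker
#'
#' Scans every distinct observed expression value between the lower and
#' upper quartiles (inclusive; quartiles by linear interpolation) as a
#' candidate cutoff. For each candidate `v`, patients split into low
#' (`expression < v`) and high (`expression >= v`) groups and a survival
#' test is run; the best cutoff minimizes the p-value, ties resolved
#' toward the smaller cutoff. The hazard ratio at the best cutoff is
#' reported for the high- versus low-expression group.
#'
#' Because the best cutoff is the minimum over many tests, the raw
#' `best_p` is anticonservative; set `n_perm > 0` to obtain a
#' permutation-corrected p-value (expression values permuted against
#' time/event, min-p null distribution).
#'
#' @param cohort Data frame with columns `time`, `event`, `expression`.
#' @param test `"logrank"` (default) or `"gbw"`.
#' @param n_perm Number of permutations for the corrected p-value
#'   (0 = skip).
#' @param seed Seed for the permutation null (only used when
#'   `n_perm > 0`).
#' @return A list of class `cutoff_scan` with `candidates`, `scan`
#'   (tibble: `cutoff`, `p`, `n_low`, `n_high`), `best_cutoff`, `best_p`,
#'   `hr` (hazard-ratio list, high vs low), `groups` (logical vector
#'   `high` at the best cutoff), and `perm_p` (or `NA`).
#' @export
best_cutoff_scan <- function(cohort, test = c("logrank", "gbw"),
                             n_perm = 0, seed = 1) {
  test <- match.arg(test)
  stopifnot(is.data.frame(cohort),
            all(c("time", "event", "expression") %in% names(cohort)))
  if (nrow(cohort) < 8) stop("need at least 8 patients for a cutoff scan")
  expr <- cohort$expression
  if (length(unique(expr)) < 2) stop("constant expression: no cutoff exists")

  test_fn <- if (test == "logrank") logrank else gbw_test
  q <- stats::quantile(expr, c(0.25, 0.75), names = FALSE)  # type 7

  scan_once <- function(expr) {
    cands <- sort(unique(expr[expr >= q[1] & expr <= q[2]]))
    rows <- lapply(cands, function(v) {
      high <- expr >= v
      if (!any(high) || all(high)) return(NULL)
      lo <- cohort[!high, c("time", "event")]
      hi <- cohort[high, c("time", "event")]
      p <- tryCatch(test_fn(lo, hi)$p, error = function(e) NA_real_)
      tibble::tibble(cutoff = v, p = p,
                     n_low = sum(!high), n_high = sum(high))
    })
    dplyr::bind_rows(rows)
  }

  scan <- scan_once(expr)
  usable <- scan[!is.na(scan$p), , drop = FALSE]
  if (nrow(usable) == 0) stop("no usable cutoff candidate between quartiles")
  best_i <- which(usable$p == min(usable$p))[1]  # ties: smaller cutoff first
  best_cutoff <- usable$cutoff[best_i]
  best_p <- usable$p[best_i]
  high <- expr >= best_cutoff
  hr <- hazard_ratio(cohort[!high, c("time", "event")],
                     cohort[high, c("time", "event")])

  perm_p <- NA_real_
  if (n_perm > 0) {
    obs <- best_p
    perm_min <- withr::with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        sc <- scan_once(sample(expr))
        min(sc$p, na.rm = TRUE)
      }, numeric(1))
    })
    perm_p <- (1 + sum(perm_min <= obs)) / (n_perm + 1)
  }

  structure(
    list(candidates = scan$cutoff, scan = scan,
         best_cutoff = best_cutoff, best_p = best_p,
         hr = hr, groups = high, quartiles = q, test = test,
         perm_p = perm_p),
    class = "cutoff_scan"
  )
}
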
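#' Overlapping cohort age groups
#'
#' Splits the cohort into the three overlapping analysis groups:
#' *infants* (under 12 months of age: a one-year-old is not an infant,
#' so the cut is strict), *minors* (age <= 18 years, the trio-sequenced
#' stratum), and the *full* cohort. A sibling-pair case is counted by
#' its analysis age (the younger proband).
#'
#' @param cases case table from [read_case_table()].
#' @return named list of case `data.frame`s: `infants`, `minors`, `full`.
#' @export
age_groups <- function(cases) {
  inc <- cases[cases$include_in_cohort, , drop = FALSE]
  list(infants = inc[inc$age_months < 12, , drop = FALSE],
       minors = inc[inc$age_months <= 18 * 12, , drop = FALSE],
       full = inc)
}

#' Combined forensic/molecular diagnostic-yield table
#'
#' The 2x2 contingency of molecular-autopsy (MA) status against
#' forensic-autopsy (FA) status across the cohort, with margins and
#' percentages of the total.
#'
#' @param cases case table; every case must carry both statuses.
#' @return a list of class `yield_table`: `counts` (2x2 matrix, rows
#'   MA +/-, columns FA +/-), `percent`, `n`, `ma_positive`,
#'   `fa_positive`.
#' @export
yield_table <- function(cases) {
  inc <- cases[cases$include_in_cohort, , drop = FALSE]
  bad <- is.na(inc$ma_status) | is.na(inc$fa_status)
  if (any(bad))
    stop("missing autopsy status for case(s): ",
         paste(inc$case_id[bad], collapse = ", "))
  ma <- factor(inc$ma_status, levels = c("positive", "negative"))
  fa <- factor(inc$fa_status, levels = c("positive", "negative"))
  counts <- table(ma, fa)
  counts <- matrix(as.integer(counts), 2, 2,
                   dimnames = list(MA = c("positive", "negative"),
                                   FA = c("positive", "negative")))
  structure(list(counts = counts,
                 percent = 100 * counts / nrow(inc),
                 n = nrow(inc),
                 ma_positive = sum(counts[1, ]),
                 fa_positive = sum(counts[, 1])),
            class = "yield_table")
}

#' @export
print.yield_table <- function(x, ...) {
  cat("Combined diagnostic yield (n =", x$n, "):\n")
  print(x$counts)
  cat(sprintf("MA positive: %d (%.0f%%); FA positive: %d (%.0f%%)\n",
              x$ma_positive, 100 * x$ma_positive / x$n,
              x$fa_positive, 100 * x$fa_positive / x$n))
  invisible(x)
}

#' Temporal histograms of deaths
#'
#' Histograms of death times by weekday (ISO convention, Monday first),
#' hour of day (0--23) and month, plus the fraction of timed deaths
#' inside a clock window (default 08:00--20:00, inclusive start and
#' exclusive end). Cases without a timestamp are counted in `n_unknown`.
#'
#' @param cases case table with a `death_time` column (`POSIXct`).
#' @param window_start,window_end clock window in hours.
#' @return list with `by_weekday`, `by_hour`, `by_month`,
#'   `window_fraction`, `n_timed`, `n_unknown`.
#' @export
temporal_histograms <- function(cases, window_start = 8, window_end = 20) {
  inc <- cases[cases$include_in_cohort, , drop = FALSE]
  t <- inc$death_time
  timed <- !is.na(t)
  t <- t[timed]
  wd_names <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  # %u gives ISO weekday 1 (Monday) .. 7 (Sunday)
  wd <- factor(as.integer(format(t, "%u")), levels = 1:7, labels = wd_names)
  hr <- factor(as.integer(format(t, "%H")), levels = 0:23)
  mo <- factor(as.integer(format(t, "%m")), levels = 1:12,
               labels = month.abb)
  hours <- as.integer(format(t, "%H")) + as.integer(format(t, "%M")) / 60
  list(by_weekday = stats::setNames(as.integer(table(wd)), wd_names),
       by_hour = stats::setNames(as.integer(table(hr)), 0:23),
       by_month = stats::setNames(as.integer(table(mo)), month.abb),
       window_fraction = if (length(hours) == 0) NA_real_
         else mean(hours >= window_start & hours < window_end),
       n_timed = sum(timed),
       n_unknown = sum(!timed))
}

#' Exact binomial day-clustering test
#'
#' Upper-tail probability that at least `k` of `n` deaths fall on a
#' designated set of `d` out of 7 equiprobable weekdays:
#' `P = sum_{i=k}^{n} C(n, i) (d/7)^i (1 - d/7)^(n-i)`.
#' This is the exact test behind the observation that a cluster of
#' infant deaths on two midweek days is unlikely under a uniform
#' weekday distribution.
#'
#' @param k observed deaths on the designated days.
#' @param n deaths in the stratum.
#' @param d number of designated days (1--7).
#' @return list of class `temporal_test`: `n`, `k`, `d`, `p_value`.
#' @export
binomial_day_cluster_test <- function(k, n, d) {
  if (length(k) != 1 || length(n) != 1 || length(d) != 1 ||
      is.na(k) || is.na(n) || is.na(d) ||
      k < 0 || k > n || d < 1 || d > 7)
    stop("binomial_day_cluster_test: require 0 <= k <= n and 1 <= d <= 7")
  p <- stats::pbinom(k - 1, n, d / 7, lower.tail = FALSE)
  structure(list(n = as.integer(n), k = as.integer(k), d = as.integer(d),
                 p_value = p),
            class = "temporal_test")
}

#' @export
print.temporal_test <- function(x, ...) {
  cat(sprintf(
    "Exact binomial day-cluster test: %d of %d deaths on %d of 7 days, p = %.4g\n",
    x$k, x$n, x$d, x$p_value))
  invisible(x)
}

#' Cohort demographics
#'
#' Sex, race and site counts, optionally restricted to cases whose id
#' matches a site pattern.
#'
#' @param cases case table.
#' @param site_filter optional regular expression on `case_id`.
#' @return list with `n`, `sex` (named counts), `race`, `site`.
#' @export
demographics <- function(cases, site_filter = NULL) {
  inc <- cases[cases$include_in_cohort, , drop = FALSE]
  if (!is.null(site_filter))
    inc <- inc[grepl(site_filter, inc$case_id), , drop = FALSE]
  sex <- table(factor(inc$sex, levels = c("female", "male")))
  race <- if (nrow(inc) == 0) integer(0) else
    table(ifelse(is.na(inc$race), "NA", inc$race))
  site <- if (nrow(inc) == 0) integer(0) else table(inc$site_label)
  list(n = nrow(inc),
       sex = stats::setNames(as.integer(sex), names(sex)),
       race = stats::setNames(as.integer(race), names(race)),
       site = stats::setNames(as.integer(site), names(site)))
}
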
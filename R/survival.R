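# Kaplan-Meier estimation, log-rank comparison of signature strata, and
# median-survival reporting.

check_records <- function(records) {
  stopifnot(all(c("time", "event") %in% names(records)))
  if (!nrow(records)) stopf("empty survival table")
  if (any(!is.finite(records$time) | records$time <= 0))
    stopf("survival times must be positive and finite")
  if (!all(records$event %in% c(0, 1))) stopf("event must be 0 or 1")
  records
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with deaths preceding censorings at tied times.
#' Median survival is the first time at which the curve drops to 0.5 or
#' below, and is reported as `NA` (undefined) when the curve never reaches
#' it.
#'
#' @param records data.frame `time` (months), `event` (0/1).
#' @return list with `curve` (data.frame `time`, `n_risk`, `n_event`,
#'   `surv`) and `median`.
#' @export
km_estimate <- function(records) {
  check_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv)
  med <- curve$time[curve$surv <= 0.5]
  list(curve = curve,
       median = if (length(med)) min(med) else NA_real_)
}

#' Log-rank test across strata
#'
#' Standard observed-vs-expected log-rank statistic with hypergeometric
#' variance at each event time; chi-square with (groups - 1) df.
#'
#' @param records data.frame `time`, `event`, `stratum`.
#' @return list `chisq`, `df`, `p_value`, `n_per_stratum`,
#'   `events_per_stratum`.
#' @export
logrank_test <- function(records) {
  check_records(records)
  if (!"stratum" %in% names(records)) stopf("records need a stratum column")
  strata <- unique(records$stratum)
  if (length(strata) < 2) stopf("need >= 2 strata for a log-rank test")
  if (sum(records$event) < 1) stopf("no events")
  sd_fit <- survival::survdiff(
    survival::Surv(time, event) ~ stratum, data = records)
  df <- length(sd_fit$n) - 1
  list(chisq = unname(sd_fit$chisq), df = df,
       p_value = pchisq(sd_fit$chisq, df, lower.tail = FALSE),
       n_per_stratum = as.vector(sd_fit$n),
       events_per_stratum = as.vector(sd_fit$obs))
}

#' Prognostic survival report for signature strata
#'
#' Joins per-sample scores with survival records, stratifies into
#' signature-high/low quartiles ([stratify_quantiles()]), estimates a KM
#' curve per stratum, and compares high vs low by log-rank (the mid stratum
#' is set aside, mirroring the binary high/low comparisons).
#'
#' @param scores named numeric vector of signature scores.
#' @param records data.frame `sample`, `time`, `event`.
#' @param hi_frac,lo_frac stratification fractions (default quartiles).
#' @return list `strata` (sample, score, stratum), `km` (named list of KM
#'   estimates for high and low), `medians`, `logrank`.
#' @export
survival_report <- function(scores, records, hi_frac = 0.25,
                            lo_frac = 0.25) {
  stopifnot(all(c("sample", "time", "event") %in% names(records)))
  shared <- intersect(names(scores), records$sample)
  if (!length(shared)) stopf("no samples shared between scores and survival")
  loss <- 1 - length(shared) / length(scores)
  if (loss > 0.1) warnf("join lost %.0f%% of scored samples", 100 * loss)
  strata <- stratify_quantiles(scores[shared], hi_frac, lo_frac)
  rec <- records[match(strata$sample, records$sample), ]
  rec$stratum <- strata$stratum
  hilo <- rec[rec$stratum %in% c("high", "low"), ]
  km <- lapply(split(hilo, hilo$stratum), km_estimate)
  list(strata = strata,
       km = km,
       medians = vapply(km, function(k) k$median, numeric(1)),
       logrank = logrank_test(hilo))
}
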
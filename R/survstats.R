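#' High/low stratification by mean odds
#'
#' Samples with odds strictly above the mean are `high`; the rest
#' (including odds exactly at the mean) are `low`. When all odds coincide,
#' everything is `low` and a warning is emitted. Because the mean scales
#' with the values, strata are invariant under positive rescaling of the
#' odds.
#'
#' @param odds Numeric vector of per-sample odds.
#' @return Character vector of `"high"`/`"low"`.
#' @export
stratify_by_mean_odds <- function(odds) {
  if (length(odds) < 2) stop("need at least 2 samples", call. = FALSE)
  if (length(unique(odds)) == 1) {
    warning("all odds identical; every sample assigned to the low stratum")
  }
  ifelse(odds > mean(odds), "high", "low")
}

#' Kaplan-Meier product-limit fit
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @return Data frame with `time`, `n_risk`, `n_event`, `surv` (the step
#'   function evaluated at the observed event times).
#' @export
km_fit <- function(time, event) {
  if (any(time < 0)) stop("negative times", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Observed-minus-expected statistic over the pooled event times with the
#' hypergeometric variance, referred to chi-square with 1 df.
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Two-level group labels aligned with `time`.
#' @return List with `chisq` and `p.value`.
#' @export
logrank_test <- function(time, event, group) {
  if (length(unique(group)) != 2) stop("exactly two groups required",
                                       call. = FALSE)
  if (sum(event) == 0) stop("no events; log-rank test undefined",
                            call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chisq = sd$chisq, p.value = stats::pchisq(sd$chisq, df = 1,
                                                 lower.tail = FALSE))
}

#' Cox proportional-hazards ratio for a binary grouping
#'
#' Partial-likelihood fit with the Efron tie correction. The hazard ratio
#' is reported for the low stratum relative to the high stratum (HR > 1
#' means the low-score group progresses or dies faster), with a 95% Wald
#' confidence interval. A group without events produces a monotone
#' likelihood: the fit is flagged unconverged and the HR reported as an
#' infinite sentinel.
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Labels aligned with `time`; `reference` names the baseline
#'   level (default `"high"`).
#' @param reference Baseline group level.
#' @return List with `b` (log hazard), `hr`, `ci` (length-2), `se`,
#'   `p.value`, `converged`, and `zph_p` (proportional-hazards diagnostic
#'   p-value; never gates the estimate).
#' @export
cox_hr_binary <- function(time, event, group, reference = "high") {
  lv <- unique(group)
  if (length(lv) != 2) stop("exactly two groups required", call. = FALSE)
  if (!reference %in% lv) reference <- lv[1]
  ind <- as.numeric(group != reference)
  ev_by <- tapply(event, ind, sum)
  if (length(ev_by) < 2 || any(ev_by == 0)) {
    return(list(b = Inf, hr = Inf, ci = c(NA_real_, NA_real_),
                se = NA_real_, p.value = NA_real_, converged = FALSE,
                zph_p = NA_real_))
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ ind, ties = "efron",
                         control = survival::coxph.control(
                           eps = 1e-10, toler.chol = 1e-12, iter.max = 50))
  b <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  zph_p <- tryCatch(survival::cox.zph(fit)$table[1, "p"],
                    error = function(e) NA_real_)
  list(b = b, hr = exp(b), ci = exp(b + c(-1.96, 1.96) * se), se = se,
       p.value = 2 * stats::pnorm(-abs(b / se)),
       converged = TRUE, zph_p = zph_p)
}

#' Survival report for a stratified prediction table
#'
#' Kaplan-Meier fits per stratum, the two-sided log-rank test, and the Cox
#' hazard ratio (low vs high) for one endpoint.
#'
#' @param pred Prediction table from [score_cohort()] (needs `sample_id`,
#'   `stratum`).
#' @param samples Sample table with the endpoint columns.
#' @param endpoint `"pfs"` or `"os"`.
#' @return List with `km` (per-stratum step tables), `logrank`, `cox`,
#'   and `n` per stratum; `NULL` when the endpoint is unavailable or a
#'   stratum is empty.
#' @export
survival_report <- function(pred, samples, endpoint = c("pfs", "os")) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_days"); ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol) %in% names(samples))) return(NULL)
  m <- merge(pred, samples[, c("sample_id", tcol, ecol)], by = "sample_id")
  m <- m[!is.na(m[[tcol]]) & !is.na(m[[ecol]]), , drop = FALSE]
  if (length(unique(m$stratum)) < 2 || sum(m[[ecol]]) == 0) return(NULL)
  km <- lapply(split(m, m$stratum), function(d) km_fit(d[[tcol]], d[[ecol]]))
  list(km = km,
       logrank = logrank_test(m[[tcol]], m[[ecol]], m$stratum),
       cox = cox_hr_binary(m[[tcol]], m[[ecol]], m$stratum,
                           reference = "high"),
       n = table(m$stratum))
}
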
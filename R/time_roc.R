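## Kaplan-Meier survival probability at time t (product-limit over events <= t)
km_at <- function(time, event, t) {
  if (!length(time)) return(NA_real_)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- c(1, fit$surv)
  tt <- c(0, fit$time)
  s[max(which(tt <= t))]
}

#' Time-dependent ROC of a risk score
#'
#' Cumulative-case / dynamic-control ROC at a horizon: cases are subjects with
#' an event by the horizon, controls those still event-free, with censoring
#' handled by Kaplan-Meier weighting of the case/control probabilities within
#' score strata (the classical survival-ROC construction). For each cutoff c,
#' with `S_c(t)` the KM survival at `t` among subjects scoring above `c`:
#' `TPR(c) = (1 - S_c(t)) P(X > c) / (1 - S(t))` and
#' `FPR(c) = S_c(t) P(X > c) / S(t)`. The AUC is the trapezoid over the curve
#' and the reported optimal cutoff maximizes Youden's J = TPR - FPR. With no
#' censoring before the horizon this reduces exactly to the (tie-corrected)
#' Mann-Whitney AUC of the scores against event-by-horizon labels, and the
#' AUC is invariant under strictly increasing transforms of the scores.
#'
#' @param scores numeric risk scores.
#' @param clin clinical table aligned to `scores` (by name when `scores` is
#'   named, else by position).
#' @param horizon time point (same units as `os_time`), within follow-up.
#' @return list with `horizon`, `curve` (data.frame `cutoff`, `fpr`, `tpr`),
#'   `auc`, and `cutoff_star`.
#' @export
time_roc <- function(scores, clin, horizon) {
  check_clinical_table(clin)
  if (!is.null(names(scores))) {
    m <- match(clin$sample, names(scores))
    if (anyNA(m)) stop_key("risk scores missing for some clinical samples")
    scores <- scores[m]
  }
  time <- clin$os_time
  event <- clin$os_event
  if (horizon <= 0 || horizon > max(time)) {
    stop_validation("horizon must be positive and within follow-up range")
  }
  if (sum(event == 1 & time <= horizon) < 1L) {
    stop_validation("no events before the horizon")
  }
  n <- length(scores)
  S_t <- km_at(time, event, horizon)
  cuts <- c(-Inf, sort(unique(scores)))
  tpr <- fpr <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    sel <- scores > cuts[i]
    p_above <- mean(sel)
    if (!any(sel)) {
      tpr[i] <- 0; fpr[i] <- 0
      next
    }
    S_c <- km_at(time[sel], event[sel], horizon)
    tpr[i] <- (1 - S_c) * p_above / (1 - S_t)
    fpr[i] <- S_c * p_above / S_t
  }
  tpr <- pmin(pmax(tpr, 0), 1)
  fpr <- pmin(pmax(fpr, 0), 1)
  # trapezoid along the ROC path (descending cutoff = ascending fpr)
  ord <- rev(seq_along(cuts))
  auc <- sum(diff(fpr[ord]) * (tpr[ord][-1L] + tpr[ord][-length(ord)]) / 2)
  j <- tpr - fpr
  cutoff_star <- cuts[which.max(j)]
  list(horizon = horizon,
       curve = data.frame(cutoff = cuts, fpr = fpr, tpr = tpr),
       auc = auc,
       cutoff_star = cutoff_star)
}
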
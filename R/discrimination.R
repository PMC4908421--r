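## Weighted Mann-Whitney kernel: sum_i sum_j w_pos[i] w_neg[j]
## (I(s_pos_i > s_neg_j) + 0.5 I(=)) / (sum w_pos * sum w_neg),
## computed in O(n log n) by sorting the pooled scores.
weighted_auc <- function(scores, w_pos, w_neg) {
  W_pos <- sum(w_pos); W_neg <- sum(w_neg)
  if (W_pos <= 0 || W_neg <= 0) stop("need positive case and control mass")
  o <- order(scores)
  s <- scores[o]; wp <- w_pos[o]; wn <- w_neg[o]
  ## collapse tied score values
  grp <- cumsum(!duplicated(s))
  wp_g <- rowsum(wp, grp); wn_g <- rowsum(wn, grp)
  cum_neg_below <- c(0, cumsum(wn_g))[seq_along(wn_g)]
  num <- sum(wp_g * (cum_neg_below + 0.5 * wn_g))
  num / (W_pos * W_neg)
}

#' Harrell's concordance index under right censoring
#'
#' Over all patient pairs whose ordering is determinable (the shorter follow-up
#' time ends in an event, and the times differ), the fraction in which the
#' higher risk score belongs to the earlier failure; risk ties count one half.
#'
#' @param risk Per-patient risk score (higher = riskier).
#' @param time Follow-up time.
#' @param event Event indicator (1/TRUE = event).
#' @return Concordance in [0, 1]; errors when no usable pairs exist.
#' @export
harrells_c <- function(risk, time, event) {
  stopifnot(length(risk) == length(time), length(time) == length(event))
  event <- as.logical(event)
  n <- length(risk)
  num <- 0; den <- 0
  ## i indexes the (potentially) earlier failure
  for (i in which(event)) {
    usable <- time > time[i]          # strict: tied times not determinable
    if (!any(usable)) next
    den <- den + sum(usable)
    num <- num + sum(risk[i] > risk[usable]) + 0.5 * sum(risk[i] == risk[usable])
  }
  if (den == 0) stop("no usable pairs for concordance")
  num / den
}

#' Cumulative/dynamic time-dependent AUC
#'
#' Estimates P(risk_i > risk_j | T_i <= t < T_j) at a horizon t. Censoring is
#' handled by the Kaplan-Meier survival-function recursion: the case (event by
#' t) marker distribution puts the KM event mass at each failing subject's
#' marker, and the control (event-free past t) distribution is the empirical
#' marker distribution minus that cumulative event mass, normalised by S(t).
#' With no censoring this reduces exactly to the Mann-Whitney statistic on the
#' dichotomised outcome I(T <= t). Risk ties count one half.
#'
#' @param risk Risk score (higher = riskier).
#' @param time Follow-up time.
#' @param event Event indicator.
#' @param horizon The horizon t.
#' @return AUC(t); errors when there are no cases or no controls.
#' @export
cumulative_dynamic_auc <- function(risk, time, event, horizon) {
  event <- as.logical(event)
  n <- length(risk)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  surv_at <- stats::stepfun(sf$time, c(1, sf$surv))
  ## KM mass assigned to each subject failing at or before the horizon
  w_case <- numeric(n)
  ev_times <- sort(unique(time[event & time <= horizon]))
  for (tk in ev_times) {
    jump <- surv_at(tk - 1e-12) - surv_at(tk)
    died <- which(event & time == tk)
    w_case[died] <- jump / length(died)
  }
  S_t <- surv_at(horizon)
  if (sum(w_case) <= 0) stop("no cases by the horizon")
  if (S_t <= 0) stop("no controls beyond the horizon")
  ## control mass: empirical 1/n minus the event mass spent by the horizon
  w_ctrl <- rep(1 / n, n) - w_case
  weighted_auc(risk, w_case, w_ctrl)
}

#' Discrimination slope and integrated discrimination improvement
#'
#' The discrimination slope of a probability model is the mean predicted
#' probability among events minus the mean among non-events; the IDI of a new
#' model over an old one is the difference of their slopes.
#'
#' @param probabilities Predicted event probabilities.
#' @param labels Binary outcome labels (both classes must be present).
#' @return \code{discrimination_slope}: the slope. \code{idi}: the difference
#'   in slopes (new minus old).
#' @export
discrimination_slope <- function(probabilities, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both outcome classes must be present")
  mean(probabilities[labels]) - mean(probabilities[!labels])
}

#' @rdname discrimination_slope
#' @param p_new,p_old Predicted probabilities from the new and old model.
#' @export
idi <- function(p_new, p_old, labels) {
  discrimination_slope(p_new, labels) - discrimination_slope(p_old, labels)
}

#' Binary AUC (Mann-Whitney with half-ties)
#'
#' @param scores Predicted scores (any monotone scale).
#' @param labels Binary labels.
#' @return The AUC.
#' @export
auc_binary <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both classes must be present")
  weighted_auc(scores, as.numeric(labels), as.numeric(!labels))
}

#' Discrimination report for a model pair
#'
#' Compares two Cox models (e.g. the extended clinical model against the
#' age/sex/stage model) on the same records: Harrell's C and the
#' cumulative/dynamic AUC at the horizon for each model's linear predictor,
#' and the IDI computed from predicted event probabilities by the horizon.
#' Patients censored before the horizon carry no observable horizon status and
#' are excluded from the slope/IDI computation (count reported).
#'
#' @param fit_new,fit_ref \code{cox_fit} objects fitted on \code{records}.
#' @param records Evaluation records.
#' @param horizon Years (default 5).
#' @param outcome "all_cause" or "crc".
#' @return list with per-model C and AUC(t), slopes, IDI, and the number of
#'   patients excluded from the slope computation.
#' @export
compare_discrimination <- function(fit_new, fit_ref, records, horizon = 5,
                                   outcome = c("all_cause", "crc")) {
  outcome <- match.arg(outcome)
  ev <- outcome_event(records, outcome)
  covs <- union(fit_new$covariates, fit_ref$covariates)
  keep <- stats::complete.cases(records[, c("time", covs), drop = FALSE])
  rec <- records[keep, , drop = FALSE]
  ev <- ev[keep]
  lp_new <- stats::predict(fit_new$model, newdata = rec, type = "lp", reference = "zero")
  lp_ref <- stats::predict(fit_ref$model, newdata = rec, type = "lp", reference = "zero")
  p_new <- predict_risk(fit_new, rec, horizon)
  p_ref <- predict_risk(fit_ref, rec, horizon)
  known <- ev | rec$time >= horizon   # status by horizon observable
  label5 <- ev & rec$time <= horizon
  slope_new <- discrimination_slope(p_new[known], label5[known])
  slope_ref <- discrimination_slope(p_ref[known], label5[known])
  list(
    harrells_c = c(new = harrells_c(lp_new, rec$time, ev),
                   reference = harrells_c(lp_ref, rec$time, ev)),
    auc_t = c(new = cumulative_dynamic_auc(lp_new, rec$time, ev, horizon),
              reference = cumulative_dynamic_auc(lp_ref, rec$time, ev, horizon)),
    slopes = c(new = slope_new, reference = slope_ref),
    idi = slope_new - slope_ref,
    horizon = horizon,
    n_excluded_slope = sum(!known))
}
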
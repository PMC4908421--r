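#' Cox-specific outcome view
#'
#' Sets the analysis event flag for CRC-specific mortality: deaths from
#' non-CRC causes become right-censored observations at their death time.
#'
#' @param records Cohort records with \code{event_all} and \code{event_crc}.
#' @return The records with a logical \code{event} column (the CRC view).
#' @export
crc_outcome_view <- function(records) {
  if (any(records$event_crc & !records$event_all))
    stop("event_crc implies event_all; records violate this")
  records$event <- records$event_crc
  records
}

outcome_event <- function(records, outcome = c("all_cause", "crc")) {
  outcome <- match.arg(outcome)
  if (outcome == "crc") crc_outcome_view(records)$event else records$event_all
}

#' Fit a Cox proportional-hazards model
#'
#' Thin, validating front end to \code{survival::coxph} with Efron tie
#' handling: complete cases only (dropped-row count reported), explicit errors
#' for zero events, constant covariates and monotone-likelihood separation
#' (any |coefficient| above 20 on the log-HR scale), Wald 95\% intervals and
#' p-values, and a Breslow baseline cumulative hazard evaluated at covariates
#' equal to zero.
#'
#' @param records data.frame with \code{time} plus outcome flags.
#' @param covariates Character vector of covariate column names (may be
#'   empty: intercept-only model, baseline hazard only).
#' @param outcome "all_cause" or "crc" (non-CRC deaths censored).
#' @param ties Tie method, default "efron".
#' @param time,event Optional explicit column names; \code{event} overrides
#'   \code{outcome}.
#' @return A \code{cox_fit}: coefficients, covariance, HRs with 95\% CI, Wald
#'   p, partial log-likelihoods, n / events / dropped counts, Breslow baseline,
#'   and the underlying \code{coxph} object.
#' @export
fit_cox <- function(records, covariates, outcome = c("all_cause", "crc"),
                    ties = "efron", time = "time", event = NULL) {
  if (is.null(event)) {
    ev <- outcome_event(records, outcome)
  } else {
    ev <- as.logical(records[[event]])
  }
  dat <- records
  dat$.time <- dat[[time]]
  dat$.event <- as.numeric(ev)
  if (any(dat$.time < 0, na.rm = TRUE)) stop("negative follow-up time")
  keep <- stats::complete.cases(dat[, c(".time", ".event", covariates), drop = FALSE])
  n_dropped <- sum(!keep)
  dat <- dat[keep, , drop = FALSE]
  if (n_dropped > 0)
    message("fit_cox: dropped ", n_dropped, " incomplete case(s)")
  if (sum(dat$.event) < 1) stop("no events in the analysis data")
  for (v in covariates) {
    col <- dat[[v]]
    if (length(unique(col[!is.na(col)])) < 2)
      stop("covariate '", v, "' is constant in the analysis data")
  }
  rhs <- if (length(covariates))
    paste(sprintf("`%s`", covariates), collapse = " + ") else "1"
  form <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  fit <- survival::coxph(form, data = dat, ties = ties,
                         control = survival::coxph.control(eps = 1e-11,
                                                           toler.chol = 1e-13,
                                                           iter.max = 50),
                         model = TRUE, x = TRUE)
  coefs <- stats::coef(fit)
  if (is.null(coefs)) coefs <- numeric(0)
  if (length(coefs) && any(abs(coefs) > 20)) {
    bad <- names(coefs)[abs(coefs) > 20]
    stop("monotone partial likelihood (perfect separation) for: ",
         paste(bad, collapse = ", "))
  }
  se <- if (length(coefs)) sqrt(diag(as.matrix(stats::vcov(fit)))) else numeric(0)
  structure(list(
    coefficients = coefs,
    se = se,
    vcov = if (length(coefs)) as.matrix(stats::vcov(fit)) else matrix(0, 0, 0),
    hr = exp(coefs),
    ci_lower = exp(coefs - 1.96 * se),
    ci_upper = exp(coefs + 1.96 * se),
    p = if (length(coefs)) 2 * stats::pnorm(-abs(coefs / se)) else numeric(0),
    loglik = fit$loglik[length(fit$loglik)],
    loglik_null = fit$loglik[1],
    n = fit$n, n_events = fit$nevent, n_dropped = n_dropped,
    baseline_cumhaz = survival::basehaz(fit, centered = FALSE),
    covariates = covariates, ties = ties,
    data = dat, model = fit), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat("Cox model (", x$ties, " ties): n = ", x$n, ", events = ", x$n_events,
      if (x$n_dropped) paste0(", dropped = ", x$n_dropped), "\n", sep = "")
  if (length(x$coefficients)) {
    tab <- data.frame(HR = x$hr, lower = x$ci_lower, upper = x$ci_upper, p = x$p)
    print(round(tab, digits))
  } else cat("  (baseline hazard only)\n")
  invisible(x)
}

#' Predicted event probability by a horizon
#'
#' \code{1 - exp(-H0(horizon) * exp(linear predictor))} with the Breslow
#' baseline cumulative hazard; a horizon beyond the last observed time uses
#' the last step of the baseline (reported via a message).
#'
#' @param fit A \code{cox_fit}.
#' @param newdata Records to predict for (default: the fitting data).
#' @param horizon Years from diagnosis.
#' @return Per-patient event probability by \code{horizon}.
#' @export
predict_risk <- function(fit, newdata = fit$data, horizon = 5) {
  stopifnot(inherits(fit, "cox_fit"))
  bh <- fit$baseline_cumhaz
  if (horizon > max(bh$time))
    message("horizon beyond last observed time; using last baseline step")
  H0 <- stats::stepfun(bh$time, c(0, bh$hazard))(horizon)
  lp <- if (length(fit$coefficients))
    stats::predict(fit$model, newdata = newdata, type = "lp", reference = "zero")
  else rep(0, nrow(newdata))
  1 - exp(-H0 * exp(lp))
}

#' Proportional-hazards and linearity diagnostics
#'
#' PH is tested per covariate by correlating scaled Schoenfeld residuals with
#' the rank of event time (\code{survival::cox.zph}, transform "rank");
#' linearity of each continuous covariate is screened by a likelihood-ratio
#' test of the fitted model against one with that covariate cut into
#' quartiles.
#'
#' @param fit A \code{cox_fit} with at least one covariate.
#' @return list with \code{ph} (data.frame covariate / chisq / p, including
#'   GLOBAL) and \code{linearity} (data.frame covariate / lrt / p).
#' @export
ph_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$n_events < 2) stop("diagnostics undefined with fewer than 2 events")
  if (!length(fit$coefficients)) stop("no covariates to test")
  zp <- survival::cox.zph(fit$model, transform = "rank")
  ph <- data.frame(covariate = rownames(zp$table),
                   chisq = zp$table[, "chisq"], p = zp$table[, "p"],
                   row.names = NULL, stringsAsFactors = FALSE)
  cont <- fit$covariates[vapply(fit$covariates, function(v) {
    col <- fit$data[[v]]
    is.numeric(col) && length(unique(col)) > 4
  }, TRUE)]
  lin <- lapply(cont, function(v) {
    dat <- fit$data
    qs <- unique(stats::quantile(dat[[v]], c(0.25, 0.5, 0.75)))
    dat$.quart <- cut(dat[[v]], c(-Inf, qs, Inf))
    others <- setdiff(fit$covariates, v)
    rhs1 <- paste(c(sprintf("`%s`", others), sprintf("`%s`", v)), collapse = " + ")
    rhs2 <- paste(c(sprintf("`%s`", others), ".quart"), collapse = " + ")
    f1 <- survival::coxph(stats::as.formula(
      paste("survival::Surv(.time, .event) ~", rhs1)), data = dat, ties = fit$ties)
    f2 <- survival::coxph(stats::as.formula(
      paste("survival::Surv(.time, .event) ~", rhs2)), data = dat, ties = fit$ties)
    lrt <- 2 * (f2$loglik[2] - f1$loglik[2])
    df <- length(stats::coef(f2)) - length(stats::coef(f1))
    data.frame(covariate = v, lrt = lrt,
               p = stats::pchisq(max(lrt, 0), df = max(df, 1), lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  list(ph = ph, linearity = do.call(rbind, c(lin, list(make.row.names = FALSE))))
}
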
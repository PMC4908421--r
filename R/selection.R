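#' Bootstrap boosted-regression importance ranking of glycan traits
#'
#' For each bootstrap resample of the cohort (with replacement, cohort size),
#' fits a gradient-boosted Cox model of depth-1 trees (stumps) on the trait
#' matrix, extracts per-trait relative influence (split gain, normalised to
#' sum to 100 per model), and averages across bootstraps. The stopping
#' iteration can be chosen on inner cross-validation folds of each resample;
#' by default a fixed conservative iteration count is used.
#'
#' @param traits data.frame with \code{sample_id} plus trait columns.
#' @param records Cohort records with outcomes.
#' @param outcome "all_cause" or "crc".
#' @param n_boot Number of bootstrap resamples (the study protocol used 1000;
#'   desk-scale runs use fewer).
#' @param seed Integer seed.
#' @param eta Boosting learning rate.
#' @param nrounds Boosting iterations when not tuned.
#' @param inner_folds If >= 2, choose the stopping iteration per resample by
#'   inner cross-validated partial-likelihood loss with early stopping.
#' @return An \code{importance_ranking}: data.frame (trait, importance,
#'   frequency) sorted by decreasing aggregate importance, ties broken
#'   lexicographically.
#' @export
bootstrap_importance <- function(traits, records, outcome = c("all_cause", "crc"),
                                 n_boot = 100, seed = 1, eta = 0.01,
                                 nrounds = 2000, inner_folds = 0) {
  outcome <- match.arg(outcome)
  if (n_boot < 1) stop("n_boot must be at least 1")
  trait_names <- setdiff(names(traits), "sample_id")
  dat <- merge(records, traits, by = "sample_id", sort = FALSE)
  ev <- outcome_event(dat, outcome)
  if (!any(ev)) stop("no events for the chosen outcome")
  x <- as.matrix(dat[, trait_names, drop = FALSE])
  colnames(x) <- trait_names
  y <- ifelse(ev, dat$time, -dat$time)  # xgboost survival:cox encoding
  set.seed(seed)
  imp <- matrix(0, n_boot, length(trait_names),
                dimnames = list(NULL, trait_names))
  params <- list(objective = "survival:cox", max_depth = 1, eta = eta,
                 nthread = 1)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(x), replace = TRUE)
    if (!any(y[idx] > 0)) next  # resample without events carries no signal
    dtrain <- xgboost::xgb.DMatrix(x[idx, , drop = FALSE], label = y[idx],
                                   nthread = 1)
    rounds <- nrounds
    if (inner_folds >= 2) {
      cv <- xgboost::xgb.cv(params, dtrain, nrounds = nrounds,
                            nfold = inner_folds, early_stopping_rounds = 20,
                            verbose = 0)
      rounds <- cv$best_iteration
    }
    booster <- xgboost::xgb.train(params, dtrain, nrounds = rounds, verbose = 0)
    it <- xgboost::xgb.importance(model = booster)
    if (!is.null(it) && nrow(it)) {
      g <- it$Gain / sum(it$Gain) * 100
      imp[b, it$Feature] <- g
    }
  }
  agg <- colMeans(imp)
  freq <- colMeans(imp > 0)
  if (all(agg == 0)) {
    warning("no splits in any bootstrap model; returning uniform order")
    ord <- order(trait_names)
  } else {
    ord <- order(-agg, trait_names)
  }
  structure(list(
    table = data.frame(trait = trait_names[ord], importance = agg[ord],
                       frequency = freq[ord], row.names = NULL,
                       stringsAsFactors = FALSE),
    n_boot = n_boot, seed = seed), class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, n = 10, ...) {
  cat("bootstrap importance ranking (", x$n_boot, " resamples)\n", sep = "")
  print(utils::head(x$table, n))
  invisible(x)
}

#' Forward selection of ranked glycans by likelihood-ratio test
#'
#' Walks the importance ranking once, adding a trait to the current Cox model
#' when twice the gain in partial log-likelihood exceeds the chi-squared(1)
#' critical value at \code{alpha}; stops after a configurable number of
#' consecutive failures.
#'
#' @param ranking An \code{importance_ranking} (or character vector of trait
#'   names in rank order).
#' @param traits data.frame with \code{sample_id} plus trait columns.
#' @param records Cohort records.
#' @param base_covariates Clinical covariates of the base model.
#' @param outcome "all_cause" or "crc".
#' @param alpha LLR significance level for adding a trait.
#' @param max_failures Consecutive non-significant candidates tolerated
#'   before stopping (default 1).
#' @return list with \code{selected} (ordered traits), \code{steps}
#'   (trait, llr, p, added), and \code{fit} (final \code{cox_fit}).
#' @export
forward_llr_select <- function(ranking, traits, records, base_covariates,
                               outcome = c("all_cause", "crc"), alpha = 0.05,
                               max_failures = 1) {
  outcome <- match.arg(outcome)
  ranked <- if (inherits(ranking, "importance_ranking"))
    ranking$table$trait else as.character(ranking)
  dat <- merge(records, traits, by = "sample_id", sort = FALSE)
  ## one complete-case universe across base + all candidates, so log-likelihoods nest
  keep <- stats::complete.cases(dat[, c("time", base_covariates, ranked),
                                    drop = FALSE])
  dat <- dat[keep, , drop = FALSE]
  current <- fit_cox(dat, base_covariates, outcome = outcome)
  selected <- character(0)
  steps <- list()
  failures <- 0L
  for (tr in ranked) {
    cand <- tryCatch(
      suppressMessages(fit_cox(dat, c(base_covariates, selected, tr),
                               outcome = outcome)),
      error = function(e) NULL)
    if (is.null(cand)) {
      steps[[tr]] <- data.frame(trait = tr, llr = NA_real_, p = NA_real_,
                                added = FALSE, stringsAsFactors = FALSE)
      failures <- failures + 1L
      if (failures > max_failures) break
      next
    }
    llr <- 2 * (cand$loglik - current$loglik)
    p <- stats::pchisq(max(llr, 0), df = 1, lower.tail = FALSE)
    add <- p < alpha
    steps[[tr]] <- data.frame(trait = tr, llr = llr, p = p, added = add,
                              stringsAsFactors = FALSE)
    if (add) {
      selected <- c(selected, tr)
      current <- cand
      failures <- 0L
    } else {
      failures <- failures + 1L
      if (failures > max_failures) break
    }
  }
  list(selected = selected,
       steps = do.call(rbind, c(steps, list(make.row.names = FALSE))),
       fit = current)
}

#' L1-penalised Cox: validation deviance with and without glycans
#'
#' Outer cross-validation comparing two model families on identical validation
#' folds: clinical covariates alone (unpenalised Cox) versus clinical
#' covariates (unpenalised) plus L1-penalised glycan terms, with the penalty
#' chosen by inner cross-validated partial-likelihood deviance. Reports the
#' per-fold validation deviances and a paired-difference t-interval.
#'
#' @param records Cohort records.
#' @param clinical_covariates Clinical covariate names.
#' @param traits data.frame with \code{sample_id} plus glycan columns.
#' @param outcome "all_cause" or "crc".
#' @param folds Outer folds (>= 2).
#' @param inner_folds Inner folds for the penalty choice.
#' @param seed Integer seed.
#' @return list with \code{per_fold} (fold, dev_clinical, dev_glycoclinical,
#'   difference), totals, the mean difference and its 95\% CI.
#' @export
l1_cox_deviance_compare <- function(records, clinical_covariates, traits,
                                    outcome = c("all_cause", "crc"),
                                    folds = 5, inner_folds = 5, seed = 1) {
  outcome <- match.arg(outcome)
  if (folds < 2) stop("folds must be at least 2")
  dat <- merge(records, traits, by = "sample_id", sort = FALSE)
  trait_names <- setdiff(names(traits), "sample_id")
  keep <- stats::complete.cases(dat[, c("time", clinical_covariates, trait_names)])
  dat <- dat[keep, , drop = FALSE]
  ev <- outcome_event(dat, outcome)
  xc <- stats::model.matrix(
    stats::as.formula(paste("~", paste(sprintf("`%s`", clinical_covariates),
                                       collapse = "+"))), data = dat)[, -1, drop = FALSE]
  xg <- as.matrix(dat[, trait_names, drop = FALSE])
  x <- cbind(xc, xg)
  pf <- c(rep(0, ncol(xc)), rep(1, ncol(xg)))
  y <- survival::Surv(dat$time, as.numeric(ev))
  set.seed(seed)
  ## stratify outer folds on event status
  fold_id <- integer(nrow(dat))
  for (cls in unique(ev)) {
    idx <- sample(which(ev == cls))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  per_fold <- list()
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (sum(ev[!tr]) == 0 || sum(ev[tr]) == 0) {
      warning("fold ", f, " has no events; skipped")
      next
    }
    cvfit <- glmnet::cv.glmnet(x[tr, , drop = FALSE], y[tr],
                               family = "cox", penalty.factor = pf,
                               nfolds = inner_folds, standardize = TRUE)
    lp_g <- drop(stats::predict(cvfit, newx = x[!tr, , drop = FALSE],
                                s = "lambda.min"))
    clin_fit <- survival::coxph(y[tr] ~ xc[tr, , drop = FALSE], ties = "breslow")
    lp_c <- drop(xc[!tr, , drop = FALSE] %*% stats::coef(clin_fit))
    dev_c <- glmnet::coxnet.deviance(pred = lp_c, y = y[!tr])
    dev_g <- glmnet::coxnet.deviance(pred = lp_g, y = y[!tr])
    per_fold[[length(per_fold) + 1L]] <-
      data.frame(fold = f, dev_clinical = dev_c, dev_glycoclinical = dev_g,
                 difference = dev_c - dev_g)
  }
  per_fold <- do.call(rbind, per_fold)
  d <- per_fold$difference
  se <- stats::sd(d) / sqrt(length(d))
  ci <- mean(d) + c(-1, 1) * stats::qt(0.975, df = length(d) - 1) * se
  list(per_fold = per_fold,
       deviance_clinical = sum(per_fold$dev_clinical),
       deviance_glycoclinical = sum(per_fold$dev_glycoclinical),
       mean_difference = mean(d), ci95 = ci)
}
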
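#' Label rapid progressors within a stage
#'
#' A rapid progressor is a patient who died of CRC with follow-up time in the
#' lower tertile of CRC-death times within their stage. The cutoff is the
#' empirical 33.33rd percentile (linear interpolation, quantile type 7) of the
#' stage's CRC-death times; all other patients in the stage (CRC deaths above
#' the cutoff, other-cause deaths, censored) are labelled not-rapid. Stages
#' with fewer than 3 CRC deaths are skipped with an explicit reason, mirroring
#' the stage-1 behaviour of the study.
#'
#' @param records Cohort records.
#' @param stage AJCC stage (1-4) to label within.
#' @return A \code{progressor_labels} list: \code{labels} (named logical over
#'   the stage's patients), \code{cutoff} (years), \code{stage}; or, when
#'   skipped, \code{skipped = TRUE} with the \code{reason}.
#' @export
label_rapid_progressors <- function(records, stage) {
  stopifnot(stage %in% 1:4)
  recs <- records[records$stage == stage, , drop = FALSE]
  crc_times <- recs$time[recs$event_crc]
  if (length(crc_times) < 3) {
    return(structure(list(stage = stage, skipped = TRUE,
                          reason = sprintf(
                            "only %d CRC death(s) in stage %d; need at least 3",
                            length(crc_times), stage)),
                     class = "progressor_labels"))
  }
  cutoff <- unname(stats::quantile(crc_times, 1 / 3, type = 7))
  labels <- recs$event_crc & recs$time <= cutoff
  names(labels) <- recs$sample_id
  structure(list(stage = stage, skipped = FALSE, cutoff = cutoff,
                 labels = labels), class = "progressor_labels")
}

#' Label 5-year CRC death
#'
#' Label 1: died of CRC within \code{horizon} years of diagnosis. Label 0:
#' followed event-free beyond the horizon, or died of another cause (the
#' outcome is CRC-specific). Patients censored before the horizon without an
#' event carry no observable label and are excluded via the eligibility mask.
#'
#' @param records Cohort records.
#' @param horizon Years (default 5).
#' @return list with \code{labels} (named logical), \code{eligible} (named
#'   logical mask), and \code{n_excluded}.
#' @export
label_five_year_crc_death <- function(records, horizon = 5) {
  eligible <- records$event_all | records$time >= horizon
  labels <- records$event_crc & records$time <= horizon
  names(labels) <- names(eligible) <- records$sample_id
  list(labels = labels, eligible = eligible, n_excluded = sum(!eligible))
}

#' Exact Wilcoxon signed-rank test for paired differences
#'
#' Two-sided by default. Zero differences are dropped (standard signed-rank
#' convention); ties in the absolute differences receive average ranks. With
#' untied ranks and at most \code{exact_limit} pairs the null distribution of
#' the positive-rank sum is computed exactly by convolution over the sign
#' assignments; with ties the tie-corrected normal approximation is used.
#' All differences zero yields p = 1 with a warning.
#'
#' @param d Paired differences.
#' @param two_sided Two-sided (default) or greater-than-zero one-sided test.
#' @param exact_limit Largest n for the exact null (default 25).
#' @return list with \code{p}, \code{statistic} (positive-rank sum),
#'   \code{n} (non-zero pairs), \code{exact} flag.
#' @export
wilcoxon_signed_rank <- function(d, two_sided = TRUE, exact_limit = 25) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; signed-rank statistic undefined")
    return(list(p = 1, statistic = NA_real_, n = 0L, exact = FALSE))
  }
  r <- rank(abs(d), ties.method = "average")
  W <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0
  if (!ties && n <= exact_limit) {
    ## null distribution of W+ by convolution over ranks 1..n
    counts <- 1
    for (k in seq_len(n)) {
      new <- c(counts, numeric(k))
      new[(k + 1):length(new)] <- new[(k + 1):length(new)] + counts
      counts <- new
    }
    total <- 2^n
    probs <- counts / total
    w_vals <- 0:(n * (n + 1) / 2)
    p_ge <- sum(probs[w_vals >= W])
    p_le <- sum(probs[w_vals <= W])
    p <- if (two_sided) min(1, 2 * min(p_ge, p_le)) else p_ge
    return(list(p = p, statistic = W, n = n, exact = TRUE))
  }
  ## tie-corrected normal approximation
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (W - mu) / sqrt(sigma2)
  p <- if (two_sided) 2 * stats::pnorm(-abs(z)) else stats::pnorm(z, lower.tail = FALSE)
  list(p = min(1, p), statistic = W, n = n, exact = FALSE)
}

#' Paired with/without-glycans model comparison
#'
#' Pairs cross-validated AUCs of matched model configurations with and
#' without glycan features and tests whether the AUC differences are centred
#' at zero by the Wilcoxon signed-rank test. Mode "W" uses all configurations;
#' mode "Wd" first collapses to one configuration per model class (the
#' disparate subset, discarding e.g. the quadratic and cubic SVM variants).
#'
#' @param cv_with,cv_without data.frames with columns \code{config_id},
#'   \code{model_class}, \code{disparate}, \code{merged_auc} (as produced by
#'   \code{\link{run_cv}} summaries), matched one-to-one on \code{config_id}.
#' @param mode "W" or "Wd".
#' @param two_sided Sidedness of the Wilcoxon test (default two-sided).
#' @return A \code{glycan_comparison}: per-configuration AUC pairs and
#'   differences, the Wilcoxon p, the median AUC gain, mode and pair count.
#' @export
compare_with_without_glycans <- function(cv_with, cv_without, mode = c("W", "Wd"),
                                         two_sided = TRUE) {
  mode <- match.arg(mode)
  m <- merge(cv_with[, c("config_id", "model_class", "disparate", "merged_auc")],
             cv_without[, c("config_id", "merged_auc")],
             by = "config_id", suffixes = c("_with", "_without"))
  if (nrow(m) != nrow(cv_with) || nrow(m) != nrow(cv_without))
    stop("configurations are not matched one-to-one")
  if (mode == "Wd") m <- m[m$disparate, , drop = FALSE]
  m$difference <- m$merged_auc_with - m$merged_auc_without
  wt <- wilcoxon_signed_rank(m$difference, two_sided = two_sided)
  structure(list(table = m, mode = mode, p = wt$p, statistic = wt$statistic,
                 exact = wt$exact, n_pairs = nrow(m),
                 median_gain = stats::median(m$difference)),
            class = "glycan_comparison")
}

#' @export
print.glycan_comparison <- function(x, ...) {
  cat(sprintf("with/without-glycans comparison (%s, %d pairs): p = %.4g, median AUC gain = %.3f\n",
              x$mode, x$n_pairs, x$p, x$median_gain))
  invisible(x)
}

#' Positive predictive value at a probability threshold
#'
#' @param predictions Predicted event probabilities.
#' @param labels Binary labels.
#' @param threshold Decision threshold (default 0.5).
#' @return TP / (TP + FP); errors when nothing is predicted positive.
#' @export
ppv_at_threshold <- function(predictions, labels, threshold = 0.5) {
  pos <- predictions >= threshold
  if (!any(pos)) stop("no predicted positives at threshold ", threshold)
  sum(pos & as.logical(labels)) / sum(pos)
}
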
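#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over one scan family. Wrapper over
#' \code{stats::p.adjust(method = "BH")} with input validation.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Model specification for the association scan
#'
#' Three adjustment sets from the study design: Model I is the crude trait
#' model; Model II adjusts for age, sex and AJCC stage; Model III further
#' adjusts for BMI, time from operation to blood draw, operation type and CRP
#' (as the 10 mg/l indicator). Scans run on the whole cohort, excluding stage
#' 4, or within one stage (in which case stage leaves the adjustment set).
#'
#' @param model "I", "II" or "III".
#' @param outcome "all_cause" or "crc".
#' @param subset "whole", "exclude_stage4", or a single stage 1-4.
#' @return A \code{model_spec} list.
#' @export
model_spec <- function(model = c("II", "I", "III"),
                       outcome = c("all_cause", "crc"),
                       subset = "whole") {
  model <- match.arg(model)
  outcome <- match.arg(outcome)
  if (!(identical(subset, "whole") || identical(subset, "exclude_stage4") ||
        (length(subset) == 1 && subset %in% 1:4)))
    stop("subset must be 'whole', 'exclude_stage4' or a stage 1-4")
  covs <- switch(model,
                 I = character(0),
                 II = c("age", "sex", "stage"),
                 III = c("age", "sex", "stage", "bmi", "op_to_sample",
                         "op_type", "crp_gt10"))
  if (is.numeric(subset)) covs <- setdiff(covs, "stage")
  structure(list(model = model, outcome = outcome, subset = subset,
                 covariates = covs), class = "model_spec")
}

apply_subset <- function(records, subset) {
  if (identical(subset, "whole")) return(records)
  if (identical(subset, "exclude_stage4")) return(records[records$stage != 4, ])
  records[records$stage == subset, ]
}

#' Per-trait Cox association scan
#'
#' Fits one Cox model per retained trait (trait plus the specification's
#' adjustment covariates, stage as a factor) on the chosen cohort subset, and
#' adjusts the Wald p-values by Benjamini-Hochberg across the scanned trait
#' family. Traits that fail to fit (separation, degeneracy) are reported with
#' the failure reason and excluded from the BH family.
#'
#' @param traits data.frame from \code{\link{cohort_traits}} (or any table
#'   with \code{sample_id} plus trait columns).
#' @param records Cohort records.
#' @param spec A \code{\link{model_spec}}.
#' @param transform "blom" rank-normal transform applied to each trait within
#'   the analysis subset (hazard ratios per SD), or "none".
#' @return data.frame: trait, model, outcome, subset, n, n_events, hr,
#'   ci_lower, ci_upper, p, q, note.
#' @export
association_scan <- function(traits, records, spec = model_spec(),
                             transform = c("blom", "none")) {
  transform <- match.arg(transform)
  stopifnot(inherits(spec, "model_spec"))
  trait_names <- setdiff(names(traits), "sample_id")
  empty <- data.frame(trait = character(0), model = character(0),
                      outcome = character(0), subset = character(0),
                      n = integer(0), n_events = integer(0), hr = numeric(0),
                      ci_lower = numeric(0), ci_upper = numeric(0),
                      p = numeric(0), q = numeric(0), note = character(0),
                      stringsAsFactors = FALSE)
  if (!length(trait_names)) return(empty)
  recs <- apply_subset(records, spec$subset)
  recs <- merge(recs, traits, by = "sample_id", sort = FALSE)
  if ("stage" %in% spec$covariates) recs$stage <- factor(recs$stage)
  rows <- lapply(trait_names, function(tr) {
    dat <- recs
    if (transform == "blom") {
      v <- tryCatch(rank_normal_transform(dat[[tr]]), error = function(e) NULL)
      if (is.null(v))
        return(data.frame(trait = tr, hr = NA_real_, ci_lower = NA_real_,
                          ci_upper = NA_real_, p = NA_real_, n = NA_integer_,
                          n_events = NA_integer_,
                          note = "degenerate trait", stringsAsFactors = FALSE))
      dat[[tr]] <- v
    }
    fit <- tryCatch(
      suppressMessages(fit_cox(dat, c(tr, spec$covariates), outcome = spec$outcome)),
      error = function(e) conditionMessage(e))
    if (is.character(fit))
      return(data.frame(trait = tr, hr = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p = NA_real_, n = NA_integer_,
                        n_events = NA_integer_, note = fit,
                        stringsAsFactors = FALSE))
    i <- 1L  # the trait enters the formula first
    data.frame(trait = tr, hr = fit$hr[i], ci_lower = fit$ci_lower[i],
               ci_upper = fit$ci_upper[i], p = fit$p[i], n = fit$n,
               n_events = fit$n_events, note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$model <- spec$model
  out$outcome <- spec$outcome
  out$subset <- as.character(spec$subset)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_adjust(out$p[ok])
  rownames(out) <- NULL
  out[, names(empty)]
}
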
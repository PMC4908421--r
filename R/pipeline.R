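#' Run the full prognostic pipeline
#'
#' Chains the analysis stages on one dataset: total-area normalisation,
#' trait derivation, robustness QC and filtering, Cox association scans for
#' the configured model specifications, clinical-model discrimination
#' (Harrell's C, cumulative/dynamic AUC, IDI of the extended clinical model
#' over age/sex/stage), boosted-regression glycan selection with forward LLR
#' refit, and the stage-stratified rapid-progressor comparison of models with
#' and without glycans. Writes every report as delimited text or JSON into
#' \code{output_dir} together with a manifest holding versions, seeds and
#' patient counts at every exclusion step, so rows reconcile across stages.
#' Reruns with the same configuration are byte-identical.
#'
#' @param config Config list (see \code{\link{read_pipeline_config}}) or a
#'   path to a YAML config.
#' @param output_dir Report directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("glycosurv")),
                   seed = config$seed, counts = list())
  stage_name <- "input"
  tryCatch({
    if (isTRUE(config$simulate)) {
      stage_name <- "simulate"
      sim <- simulate_cohort(config$generator, seed = config$seed)
      peak_table <- sim$peak_table
      records <- sim$cohort
      write_peak_table(peak_table, file.path(output_dir, "peak_table.tsv"))
      write_clinical_table(records, file.path(output_dir, "clinical_table.tsv"))
    } else {
      peak_table <- read_peak_table(config$peak_table)
      records <- read_clinical_table(config$clinical_table)
    }
    ann <- if (!is.null(config$annotation))
      validate_annotation(utils::read.delim(config$annotation)) else gp_annotation()
    defs <- if (!is.null(config$trait_definitions))
      read_trait_definitions(config$trait_definitions) else NULL
    manifest$counts$wells_input <- nrow(peak_table)
    manifest$counts$patients_input <- nrow(records)

    stage_name <- "normalize"
    norm <- normalize_total_area(peak_table)
    manifest$counts$wells_analysable <- nrow(norm)
    manifest$counts$wells_excluded_zero_area <- nrow(peak_table) - nrow(norm)

    stage_name <- "traits"
    tm <- derive_traits(norm, defs = defs, annotation = ann)
    tm <- compute_robustness(tm)
    tm <- filter_robust(tm, config$robustness_threshold)
    manifest$counts$traits_total <- ncol(tm$values)
    manifest$counts$traits_retained <- sum(tm$retained)
    write_delim_exact(data.frame(trait = names(tm$robustness),
                                 robustness = unname(tm$robustness),
                                 retained = unname(tm$retained)),
                      file.path(output_dir, "robustness.tsv"))
    traits <- cohort_traits(tm, retained_only = TRUE, transform = "none")
    write_delim_exact(traits, file.path(output_dir, "traits.tsv"))

    stage_name <- "association_scan"
    specs <- config$scans
    if (is.null(specs))
      specs <- list(list(model = "II", outcome = "all_cause", subset = "whole"),
                    list(model = "II", outcome = "crc", subset = "whole"))
    scan_results <- lapply(specs, function(s) {
      sp <- model_spec(s$model, s$outcome,
                       if (is.null(s$subset)) "whole" else s$subset)
      association_scan(traits, records, sp, transform = config$transform)
    })
    scans <- do.call(rbind, scan_results)
    write_delim_exact(scans, file.path(output_dir, "association_scan.tsv"))
    grDevices::png(file.path(output_dir, "manhattan.png"), width = 900, height = 480)
    plot_manhattan(scans)
    grDevices::dev.off()

    stage_name <- "discrimination"
    clin_iii <- c("age", "sex", "stage", "bmi", "crp_gt10")
    clin_ii <- c("age", "sex", "stage")
    rec_f <- records
    rec_f$stage <- factor(rec_f$stage)
    fit3 <- suppressMessages(fit_cox(rec_f, clin_iii))
    fit2 <- suppressMessages(fit_cox(rec_f, clin_ii))
    manifest$counts$patients_model_iii <- fit3$n
    manifest$counts$patients_dropped_model_iii <- fit3$n_dropped
    disc <- compare_discrimination(fit3, fit2, rec_f, horizon = config$horizon)
    jsonlite::write_json(disc, file.path(output_dir, "discrimination.json"),
                         auto_unbox = TRUE, digits = NA)

    stage_name <- "selection"
    traits_t <- cohort_traits(tm, retained_only = TRUE, transform = config$transform)
    ranking <- bootstrap_importance(traits_t, records, n_boot = config$n_boot,
                                    seed = config$seed, eta = 0.05, nrounds = 200)
    sel <- forward_llr_select(ranking, traits_t, rec_f, clin_iii,
                              alpha = config$alpha)
    write_delim_exact(merge(ranking$table, sel$steps, by = "trait",
                            all.x = TRUE, sort = FALSE),
                      file.path(output_dir, "selection.tsv"))

    stage_name <- "progression"
    zoo <- default_model_zoo()
    prog <- list()
    for (st in sort(unique(records$stage))) {
      lab <- label_rapid_progressors(records, st)
      if (lab$skipped) {
        prog[[paste0("stage", st)]] <- list(skipped = TRUE, reason = lab$reason)
        next
      }
      recs_st <- records[records$stage == st, , drop = FALSE]
      y <- as.integer(lab$labels[recs_st$sample_id])
      if (sum(y) < config$cv_folds || sum(1 - y) < config$cv_folds) {
        prog[[paste0("stage", st)]] <- list(
          skipped = TRUE,
          reason = "cross-validation was not possible due to the small number of events")
        next
      }
      clin_x <- stats::model.matrix(~ age + sex + crp_gt10, data = recs_st)[, -1]
      gly_x <- as.matrix(traits_t[match(recs_st$sample_id, traits_t$sample_id),
                                  -1, drop = FALSE])
      cv_wo <- run_cv(zoo, clin_x, y, n_runs = config$cv_runs,
                      n_folds = config$cv_folds, seed = config$seed)
      cv_wi <- run_cv(zoo, cbind(clin_x, gly_x), y, n_runs = config$cv_runs,
                      n_folds = config$cv_folds, seed = config$seed)
      cmp_w <- compare_with_without_glycans(cv_wi$summary, cv_wo$summary, "W")
      cmp_wd <- compare_with_without_glycans(cv_wi$summary, cv_wo$summary, "Wd")
      prog[[paste0("stage", st)]] <- list(
        skipped = FALSE, cutoff_years = lab$cutoff, n = length(y),
        n_rapid = sum(y), auc = cmp_w$table, p_w = cmp_w$p, p_wd = cmp_wd$p,
        median_auc_gain = cmp_w$median_gain)
    }
    jsonlite::write_json(prog, file.path(output_dir, "progression_comparison.json"),
                         auto_unbox = TRUE, digits = NA)

    manifest$counts$patients_accounted <-
      manifest$counts$patients_input
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage_name, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(manifest)
}

#' Manhattan-style plot of association q-values
#'
#' Plots -log10(q) per trait for each scanned outcome, with the significance
#' line at the given q threshold.
#'
#' @param scans Scan results (possibly several row-bound scans).
#' @param q_threshold Significance threshold (default 0.05).
#' @export
plot_manhattan <- function(scans, q_threshold = 0.05) {
  ok <- !is.na(scans$q)
  scans <- scans[ok, , drop = FALSE]
  traits <- unique(scans$trait)
  xi <- match(scans$trait, traits)
  grp <- factor(paste(scans$outcome, scans$model))
  cols <- c("firebrick", "steelblue", "darkolivegreen", "orange")[as.integer(grp)]
  graphics::plot(xi, -log10(scans$q), pch = 19, col = cols,
                 xaxt = "n", xlab = "", ylab = expression(-log[10](q)),
                 main = "Glycan trait associations")
  graphics::axis(1, at = seq_along(traits), labels = traits, las = 2,
                 cex.axis = 0.6)
  graphics::abline(h = -log10(q_threshold), lty = 2)
  graphics::legend("topright", legend = levels(grp), col =
                     c("firebrick", "steelblue", "darkolivegreen", "orange")[seq_along(levels(grp))],
                   pch = 19, cex = 0.8)
  invisible(NULL)
}
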
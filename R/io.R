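fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, "")
  out
}

write_delim_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- fmt_num(out[[j]])
    else if (is.logical(out[[j]]))
      out[[j]] <- as.integer(out[[j]])
    else {
      out[[j]] <- as.character(out[[j]])
      out[[j]][is.na(out[[j]])] <- ""
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a glycan peak table
#'
#' Tab-delimited UTF-8, "." decimal separator, empty cells for missing; one
#' row per well with columns \code{sample_id}, \code{plate_id},
#' \code{is_standard}, \code{GP1..GP24}. Numbers are written with enough
#' digits for bit-exact round trips. Malformed numeric cells are reported
#' with their row and column; a missing peak column or a duplicated
#' non-standard sample id is an error.
#'
#' @param path File path.
#' @param peaks Expected peak columns.
#' @return \code{read_peak_table}: the validated peak table.
#' @export
read_peak_table <- function(path, peaks = paste0("GP", 1:24)) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  missing <- setdiff(c("sample_id", "plate_id", "is_standard", peaks), names(raw))
  if (length(missing))
    stop("peak table is missing columns: ", paste(missing, collapse = ", "))
  for (col in peaks) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & raw[[col]] != "")
    if (length(bad))
      stop(sprintf("malformed numeric cell at row %d, column %s: '%s'",
                   bad[1], col, raw[[col]][bad[1]]))
    if (any(is.na(v)))
      stop("missing peak area at row ", which(is.na(v))[1], ", column ", col)
    raw[[col]] <- v
  }
  raw$is_standard <- raw$is_standard %in% c("1", "TRUE", "true")
  validate_peak_table(raw, peaks)
}

#' @rdname read_peak_table
#' @param x Peak table to write.
#' @export
write_peak_table <- function(x, path) {
  write_delim_exact(as.data.frame(x), path)
}

clinical_columns <- c("sample_id", "age", "sex", "stage", "site", "bmi",
                      "crp", "crp_gt10", "op_type", "op_to_sample",
                      "time", "event_all", "event_crc")

#' Read / write a clinical/outcome table
#'
#' One row per patient: demographics, AJCC stage (1-4), tumour site, BMI
#' (may be missing), CRP with the 10 mg/l indicator, operation type and
#' operation-to-sampling time, follow-up time in years from diagnosis, and
#' the all-cause / CRC-cause death flags. Violations of the record invariants
#' (negative time, CRC death without all-cause death, stage outside 1-4) are
#' errors.
#'
#' @param path File path.
#' @return \code{read_clinical_table}: validated records data.frame.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(clinical_columns, names(df))
  if (length(missing))
    stop("clinical table is missing columns: ", paste(missing, collapse = ", "))
  df$sex <- factor(df$sex, levels = c("M", "F"))
  df$site <- factor(df$site, levels = c("colon", "rectum"))
  df$op_type <- factor(df$op_type, levels = c("elective", "emergency"))
  df$crp_gt10 <- as.logical(df$crp_gt10)
  df$event_all <- as.logical(df$event_all)
  df$event_crc <- as.logical(df$event_crc)
  validate_clinical(df)
}

#' @rdname read_clinical_table
#' @param records Records to write.
#' @export
write_clinical_table <- function(records, path) {
  write_delim_exact(records[, clinical_columns], path)
}

validate_clinical <- function(df) {
  if (!all(df$stage %in% 1:4)) stop("stage must be 1, 2, 3 or 4")
  if (any(df$time < 0)) stop("negative follow-up time")
  if (any(df$event_crc & !df$event_all))
    stop("event_crc = 1 with event_all = 0 violates the record invariant")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id")
  df
}

#' Load a pipeline configuration from YAML
#'
#' The configuration either names input files (\code{peak_table},
#' \code{clinical_table}, optional \code{annotation},
#' \code{trait_definitions}) or requests simulation (\code{simulate: true}
#' with generator fields). Analysis settings: robustness threshold, transform,
#' model specifications, discrimination horizon, selection settings
#' (\code{n_boot}, \code{alpha}), CV geometry, and mandatory seeds for every
#' stochastic stage. Referenced paths must exist at load time.
#'
#' @param path YAML file path.
#' @return Config list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg, dir = dirname(path))
}

validate_pipeline_config <- function(cfg, dir = ".") {
  defaults <- list(simulate = FALSE, robustness_threshold = 20,
                   transform = "blom", horizon = 5,
                   n_boot = 100, alpha = 0.05,
                   cv_runs = 3, cv_folds = 10, inner_folds = 5,
                   seed = NULL)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$seed)) stop("config must name a seed")
  if (isTRUE(cfg$simulate)) {
    gen_fields <- intersect(names(cfg), names(formals(generator_config)))
    cfg$generator <- do.call(generator_config, cfg[gen_fields])
  } else {
    for (p in c("peak_table", "clinical_table")) {
      if (is.null(cfg[[p]])) stop("config must name ", p, " (or simulate: true)")
      if (!file.exists(cfg[[p]])) {
        alt <- file.path(dir, cfg[[p]])
        if (!file.exists(alt)) stop("path does not exist: ", cfg[[p]])
        cfg[[p]] <- alt
      }
    }
  }
  cfg
}
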
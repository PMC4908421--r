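#' Validate a glycan peak table
#'
#' A peak table has one row per chromatogram well: \code{sample_id},
#' \code{plate_id}, \code{is_standard} (technical-replicate flag) and one
#' non-negative area column per peak.
#'
#' @param x data.frame to validate.
#' @param peaks Expected peak column names (default \code{GP1..GP24}).
#' @return \code{x}, invisibly coerced (is_standard to logical).
#' @export
validate_peak_table <- function(x, peaks = paste0("GP", 1:24)) {
  meta <- c("sample_id", "plate_id", "is_standard")
  missing <- setdiff(c(meta, peaks), names(x))
  if (length(missing))
    stop("peak table is missing columns: ", paste(missing, collapse = ", "))
  x$is_standard <- as.logical(x$is_standard)
  areas <- as.matrix(x[peaks])
  if (!is.numeric(areas) || any(!is.finite(areas)))
    stop("peak areas must all be finite numbers")
  if (any(areas < 0))
    stop("peak areas must be non-negative")
  dup <- duplicated(x$sample_id[!x$is_standard])
  if (any(dup))
    stop("duplicated non-standard sample_id: ",
         paste(unique(x$sample_id[!x$is_standard][dup]), collapse = ", "))
  attr(x, "peaks") <- peaks
  x
}

peak_columns <- function(x) {
  p <- attr(x, "peaks")
  if (is.null(p)) p <- grep("^GP[0-9]+$", names(x), value = TRUE)
  p
}

#' Total-area normalisation of glycan peak areas
#'
#' Divides every peak area by the total area of its chromatogram and rescales
#' to percent, so each analysable row sums to 100. Technical standards are
#' normalised identically to cohort samples. Rows whose areas sum to zero are
#' not analysable; they are dropped with a warning naming the wells.
#'
#' @param x Peak table (see \code{\link{validate_peak_table}}).
#' @param peaks Peak column names.
#' @return The peak table on the percent scale.
#' @export
normalize_total_area <- function(x, peaks = peak_columns(x)) {
  x <- validate_peak_table(x, peaks)
  areas <- as.matrix(x[peaks])
  totals <- rowSums(areas)
  bad <- totals <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with zero total area excluded: ",
            paste(utils::head(x$sample_id[bad], 5), collapse = ", "))
    x <- x[!bad, , drop = FALSE]
    areas <- areas[!bad, , drop = FALSE]
    totals <- totals[!bad]
  }
  x[peaks] <- 100 * areas / totals
  attr(x, "peaks") <- peaks
  x
}

#' Derive glycan traits from a normalised peak table
#'
#' Each trait is \code{scale * sum(numerator areas) / sum(denominator areas)}
#' per sample. Measured peak percentages pass through unchanged (their
#' denominator is the whole glycome, which sums to 100 after normalisation);
#' neutral percentages use the neutral peak subset as denominator. A zero
#' denominator for a sample yields a missing trait value for that sample.
#'
#' @param x Normalised peak table.
#' @param defs Trait definitions (default built from \code{annotation}).
#' @param annotation Peak annotation used when \code{defs} is NULL.
#' @return A \code{trait_matrix}: list with \code{values} (samples x traits),
#'   \code{sample_id}, \code{plate_id}, \code{is_standard}, \code{definitions},
#'   and empty QC slots (\code{robustness}, \code{retained}).
#' @export
derive_traits <- function(x, defs = NULL, annotation = gp_annotation()) {
  peaks <- peak_columns(x)
  if (is.null(defs)) defs <- default_trait_definitions(annotation)
  areas <- as.matrix(x[peaks])
  values <- matrix(NA_real_, nrow(areas), length(defs),
                   dimnames = list(x$sample_id, names(defs)))
  n_zero_den <- 0L
  for (j in seq_along(defs)) {
    d <- defs[[j]]
    unknown <- setdiff(c(d$numerator, d$denominator), peaks)
    if (length(unknown))
      stop("trait '", d$name, "' references unknown peaks: ",
           paste(unknown, collapse = ", "))
    num <- rowSums(areas[, d$numerator, drop = FALSE])
    den <- rowSums(areas[, d$denominator, drop = FALSE])
    zero <- den <= 0
    n_zero_den <- n_zero_den + sum(zero)
    v <- d$scale * num / den
    v[zero] <- NA_real_
    values[, j] <- v
  }
  if (n_zero_den > 0)
    message(n_zero_den, " trait value(s) set missing due to zero denominators")
  structure(list(values = values, sample_id = x$sample_id,
                 plate_id = x$plate_id, is_standard = as.logical(x$is_standard),
                 definitions = defs, robustness = NULL, retained = NULL),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat("trait_matrix:", sum(!x$is_standard), "cohort samples,",
      sum(x$is_standard), "standard wells,", ncol(x$values), "traits\n")
  if (!is.null(x$retained))
    cat("  retained after robustness filter:", sum(x$retained), "\n")
  invisible(x)
}

#' Robustness: share of experimental variance in a trait
#'
#' On every plate the assay carries technical standards that are biologically
#' identical, so their spread reflects experimental noise alone. Robustness of
#' a trait is \code{100 * Var(standards) / Var(cohort)} (unbiased sample
#' variances): the percentage of the cohort variation attributable to
#' experimental variation. Lower is better.
#'
#' @param standard_values Trait values over all standard wells (pooled across
#'   plates).
#' @param cohort_values Trait values over all cohort samples.
#' @return The robustness percentage; \code{NA} if the cohort variance is zero
#'   or either side has fewer than 2 non-missing values.
#' @export
robustness <- function(standard_values, cohort_values) {
  s <- standard_values[!is.na(standard_values)]
  v <- cohort_values[!is.na(cohort_values)]
  if (length(s) < 2 || length(v) < 2)
    stop("robustness needs at least 2 standard wells and 2 cohort samples")
  vc <- stats::var(v)
  if (vc == 0) return(NA_real_)
  100 * stats::var(s) / vc
}

#' Compute robustness for every trait in a trait matrix
#'
#' @param tm A \code{trait_matrix} containing both cohort samples and standard
#'   wells (values already normalised and derived).
#' @return The trait matrix with the \code{robustness} vector filled in.
#' @export
compute_robustness <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  if (sum(tm$is_standard) < 2)
    stop("robustness needs at least 2 standard wells")
  std <- tm$values[tm$is_standard, , drop = FALSE]
  coh <- tm$values[!tm$is_standard, , drop = FALSE]
  tm$robustness <- vapply(seq_len(ncol(tm$values)), function(j) {
    tryCatch(robustness(std[, j], coh[, j]), error = function(e) NA_real_)
  }, 0)
  names(tm$robustness) <- colnames(tm$values)
  tm
}

#' Filter traits by robustness
#'
#' Retains traits whose robustness is strictly below the threshold ("below
#' 20\%" is the study rule, so boundary values are excluded). Traits with
#' undefined robustness are not retained.
#'
#' @param tm Trait matrix with robustness computed.
#' @param threshold Robustness threshold in percent (default 20).
#' @return The trait matrix with the logical \code{retained} slot filled in.
#' @export
filter_robust <- function(tm, threshold = 20) {
  stopifnot(inherits(tm, "trait_matrix"))
  if (ncol(tm$values) == 0) {
    tm$retained <- logical(0)
    return(tm)
  }
  if (is.null(tm$robustness)) stop("compute robustness first")
  tm$retained <- !is.na(tm$robustness) & tm$robustness < threshold
  tm
}

#' Blom rank-normal transform
#'
#' Replaces values by normal quantiles of Blom-adjusted ranks,
#' \code{qnorm((rank - 3/8) / (n + 1/4))}, with average ranks for ties.
#' Missing values stay missing; the transform is computed over the non-missing
#' values only. The result is centred near zero with unit-like spread, so Cox
#' hazard ratios on transformed traits are per (approximately) one SD.
#'
#' @param values Numeric vector.
#' @return Transformed vector of the same length.
#' @export
rank_normal_transform <- function(values) {
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) < 2) stop("rank-normal transform needs at least 2 values")
  if (length(unique(v)) == 1) stop("degenerate trait: all values identical")
  n <- length(v)
  out <- values
  out[ok] <- stats::qnorm((rank(v, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  out
}

#' Extract the cohort-sample trait table
#'
#' @param tm Trait matrix.
#' @param retained_only Keep only robustness-retained traits.
#' @param transform "blom" for rank-normal, "none" for raw values.
#' @return data.frame with \code{sample_id} and one column per trait.
#' @export
cohort_traits <- function(tm, retained_only = TRUE, transform = c("none", "blom")) {
  transform <- match.arg(transform)
  v <- tm$values[!tm$is_standard, , drop = FALSE]
  if (retained_only) {
    if (is.null(tm$retained)) stop("robustness filter has not been applied")
    v <- v[, tm$retained, drop = FALSE]
  }
  if (transform == "blom")
    v <- apply(v, 2, rank_normal_transform)
  out <- data.frame(sample_id = tm$sample_id[!tm$is_standard], v,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
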
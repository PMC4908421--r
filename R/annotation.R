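#' Peak annotation for the 24-peak IgG N-glycome
#'
#' Loads the packaged GP1-GP24 structural annotation: for every chromatographic
#' peak the number of galactoses (0/1/2), the number of terminal sialic acids
#' (0/1/2), and flags for core fucose (F) and bisecting GlcNAc (B). A peak is
#' \emph{neutral} iff it carries no sialic acid. The mapping follows the
#' standard 24-peak hydrophilic-interaction UPLC convention for total IgG and
#' is deliberately kept in a single overridable table
#' (\code{inst/extdata/gp24_annotation.tsv}) so that a re-analysis with a
#' different peak assignment only has to swap that file.
#'
#' @param path Path to an annotation TSV. Defaults to the packaged table.
#' @return A data.frame with columns \code{peak}, \code{structure},
#'   \code{galactose_count}, \code{sialic_acid_count}, \code{core_fucose},
#'   \code{bisecting_glcnac} and the derived logical \code{neutral}.
#' @export
gp_annotation <- function(path = system.file("extdata", "gp24_annotation.tsv",
                                             package = "glycosurv")) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(ann)
}

#' Validate a peak annotation table
#'
#' @param ann Annotation data.frame (see \code{\link{gp_annotation}}).
#' @return The annotation with the \code{neutral} column filled in; errors if
#'   a peak is duplicated, a count is outside its range, or the neutral flag
#'   (when present) disagrees with the sialic-acid count.
#' @export
validate_annotation <- function(ann) {
  required <- c("peak", "galactose_count", "sialic_acid_count",
                "core_fucose", "bisecting_glcnac")
  missing <- setdiff(required, names(ann))
  if (length(missing))
    stop("annotation is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(ann$peak))
    stop("annotation lists a peak more than once: ",
         paste(unique(ann$peak[duplicated(ann$peak)]), collapse = ", "))
  if (!all(ann$galactose_count %in% 0:2))
    stop("galactose_count must be 0, 1 or 2")
  if (!all(ann$sialic_acid_count %in% 0:2))
    stop("sialic_acid_count must be 0, 1 or 2")
  ann$core_fucose <- as.logical(ann$core_fucose)
  ann$bisecting_glcnac <- as.logical(ann$bisecting_glcnac)
  neutral <- ann$sialic_acid_count == 0
  if (!is.null(ann$neutral) && !identical(as.logical(ann$neutral), neutral))
    stop("neutral flag disagrees with sialic_acid_count == 0")
  ann$neutral <- neutral
  ann
}

## Peak subset selector: each argument restricts the set; NULL means "any".
peaks_with <- function(ann, gal = NULL, sia = NULL, fuc = NULL, bis = NULL,
                       neutral = NULL) {
  keep <- rep(TRUE, nrow(ann))
  if (!is.null(gal)) keep <- keep & ann$galactose_count %in% gal
  if (!is.null(sia)) keep <- keep & ann$sialic_acid_count %in% sia
  if (!is.null(fuc)) keep <- keep & ann$core_fucose == fuc
  if (!is.null(bis)) keep <- keep & ann$bisecting_glcnac == bis
  if (!is.null(neutral)) keep <- keep & ann$neutral == neutral
  ann$peak[keep]
}

trait_definition <- function(name, numerator, denominator, scale = 100) {
  if (!length(numerator) || !length(denominator))
    stop("trait '", name, "': numerator and denominator must be non-empty")
  if (scale == 100 && !all(numerator %in% denominator))
    stop("trait '", name, "': percentage traits require numerator within denominator")
  structure(list(name = name, numerator = numerator,
                 denominator = denominator, scale = scale),
            class = "trait_definition")
}

#' Default trait definitions for the IgG glycome
#'
#' Builds, from a peak annotation, the standard trait panel: the 24 measured
#' peak percentages (total glycome), the neutral-glycome peak percentages
#' (\code{GPkn}), the galactosylation partition \code{G0n}/\code{G1n}/\code{G2n},
#' core-fucosylation and bisecting-GlcNAc traits of neutral glycans, and the
#' sialylation ratios of fucosylated structures. Percentage traits carry
#' \code{scale = 100} with numerator peaks a subset of denominator peaks; pure
#' ratios (e.g. \code{FBS1/FS1}) carry \code{scale = 1}.
#'
#' @param ann Peak annotation (default packaged 24-peak table).
#' @return A named list of trait definitions.
#' @export
default_trait_definitions <- function(ann = gp_annotation()) {
  all_peaks <- ann$peak
  N <- peaks_with(ann, neutral = TRUE)
  defs <- list()
  ## traits whose defining peak sets are absent from the annotation (e.g.
  ## bisected structures in a reduced custom panel) are skipped, not errors
  add <- function(name, num, den, scale = 100) {
    if (!length(num) || !length(den)) return(invisible(NULL))
    defs[[name]] <<- trait_definition(name, num, den, scale)
  }
  for (p in all_peaks) add(p, p, all_peaks)
  for (p in N) add(paste0(p, "n"), p, N)
  for (g in 0:2)
    add(sprintf("G%dn", g), peaks_with(ann, gal = g, neutral = TRUE), N)
  Fn  <- peaks_with(ann, fuc = TRUE,  bis = FALSE, neutral = TRUE)
  FBn <- peaks_with(ann, fuc = TRUE,  bis = TRUE,  neutral = TRUE)
  Bn  <- peaks_with(ann, fuc = FALSE, bis = TRUE,  neutral = TRUE)
  add("Fn", Fn, N)
  add("FBn", FBn, N)
  add("Bn", Bn, N)
  for (g in 0:1) {
    Gg <- peaks_with(ann, gal = g, neutral = TRUE)
    add(sprintf("FG%dn/G%dn", g, g),
        peaks_with(ann, gal = g, fuc = TRUE, bis = FALSE, neutral = TRUE), Gg)
    add(sprintf("FBG%dn/G%dn", g, g),
        peaks_with(ann, gal = g, fuc = TRUE, bis = TRUE, neutral = TRUE), Gg)
  }
  add("FBn/Fn", FBn, Fn, scale = 1)
  add("FBn/Fn.total", FBn, c(Fn, FBn))
  add("Fn/(Bn+FBn)", Fn, c(Bn, FBn), scale = 1)
  ## sialylation of fucosylated structures (total glycome)
  FGS  <- peaks_with(ann, gal = 1:2, sia = 1:2, fuc = TRUE, bis = FALSE)
  FnoB <- peaks_with(ann, fuc = TRUE, bis = FALSE)
  FG   <- peaks_with(ann, gal = 1:2, sia = 0, fuc = TRUE, bis = FALSE)
  FBGS <- peaks_with(ann, gal = 1:2, sia = 1:2, fuc = TRUE, bis = TRUE)
  FB   <- peaks_with(ann, fuc = TRUE, bis = TRUE)
  FBG  <- peaks_with(ann, gal = 1:2, sia = 0, fuc = TRUE, bis = TRUE)
  add("FGS/(FG+FGS)", FGS, c(FG, FGS))
  add("FGS/(F+FG+FGS)", FGS, FnoB)
  add("FBGS/(FBG+FBGS)", FBGS, c(FBG, FBGS))
  add("FBGS/(FB+FBG+FBGS)", FBGS, FB)
  add("FG2S1/(FG2+FG2S1+FG2S2)",
      peaks_with(ann, gal = 2, sia = 1, fuc = TRUE, bis = FALSE),
      peaks_with(ann, gal = 2, fuc = TRUE, bis = FALSE))
  add("FBG2S1/(FBG2+FBG2S1+FBG2S2)",
      peaks_with(ann, gal = 2, sia = 1, fuc = TRUE, bis = TRUE),
      peaks_with(ann, gal = 2, fuc = TRUE, bis = TRUE))
  ## bisecting GlcNAc in sialylated structures (pure ratios / proportions)
  FS1  <- peaks_with(ann, sia = 1, fuc = TRUE, bis = FALSE)
  FBS1 <- peaks_with(ann, sia = 1, fuc = TRUE, bis = TRUE)
  FS2  <- peaks_with(ann, sia = 2, fuc = TRUE, bis = FALSE)
  FBS2 <- peaks_with(ann, sia = 2, fuc = TRUE, bis = TRUE)
  add("FBS.total/FS.total", c(FBS1, FBS2), c(FS1, FS2), scale = 1)
  add("FBS1/FS1", FBS1, FS1, scale = 1)
  add("FBS1/(FS1+FBS1)", FBS1, c(FS1, FBS1), scale = 1)
  add("FBS2/FS2", FBS2, FS2, scale = 1)
  add("FBS2/(FS2+FBS2)", FBS2, c(FS2, FBS2), scale = 1)
  defs
}

#' Write / read trait definitions as a delimited text config
#'
#' Serialised as TSV with comma-joined peak sets so a trait panel can be
#' audited and overridden outside R.
#'
#' @param defs Named list of trait definitions.
#' @param path File path.
#' @return \code{read_trait_definitions} returns the named list of definitions.
#' @export
write_trait_definitions <- function(defs, path) {
  df <- data.frame(
    name = vapply(defs, `[[`, "", "name"),
    scale = vapply(defs, `[[`, 0, "scale"),
    numerator = vapply(defs, function(d) paste(d$numerator, collapse = ","), ""),
    denominator = vapply(defs, function(d) paste(d$denominator, collapse = ","), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_definitions
#' @export
read_trait_definitions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  defs <- lapply(seq_len(nrow(df)), function(i)
    trait_definition(df$name[i],
                     strsplit(df$numerator[i], ",", fixed = TRUE)[[1]],
                     strsplit(df$denominator[i], ",", fixed = TRUE)[[1]],
                     df$scale[i]))
  names(defs) <- df$name
  defs
}
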
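#' Numeric thresholds governing the de novo gene screen
#'
#' Collects every tunable numeric constant used across the screen in one
#' validated object, so that a single `thresholds` argument travels through
#' the ORF assessment, polarization, QC, rate, and reporting stages.
#'
#' @param min_protein_aa Minimum human protein length in amino acids for a
#'   candidate to enter the screen. Default 100.
#' @param intact_fraction An outgroup ORF encoding at least this fraction of
#'   the human protein counts as intact enough, and the candidate is
#'   discarded. Default 0.80; the boundary itself (exactly 0.80) counts as
#'   intact enough.
#' @param qc_window_aa Width, in aligned amino-acid columns, of the sliding
#'   window used by the alignment quality filter. Default 5.
#' @param qc_max_similarity A window whose identity fraction is less than or
#'   equal to this value fails the alignment quality filter. Default 0.20.
#' @param max_lineage_rate Genes whose fitted human or chimpanzee branch
#'   length (substitutions/site) exceeds this value are discarded from rate
#'   summaries. Default 0.1.
#' @param norm_scale Multiplier applied to normalized expression levels for
#'   display (the conventional 1e8, i.e. levels are reported on a 1e-8
#'   scale). Default 1e8.
#' @param divergence_my_low,divergence_my_high Bounds, in millions of years,
#'   on the human-chimpanzee divergence time used in birth-rate arithmetic.
#'   Defaults 5 and 6.
#'
#' @return A named list of class `"screen_thresholds"`.
#' @examples
#' th <- screen_thresholds()
#' th$intact_fraction
#' @export
screen_thresholds <- function(min_protein_aa = 100,
                              intact_fraction = 0.80,
                              qc_window_aa = 5,
                              qc_max_similarity = 0.20,
                              max_lineage_rate = 0.1,
                              norm_scale = 1e8,
                              divergence_my_low = 5,
                              divergence_my_high = 6) {
  th <- list(
    min_protein_aa = min_protein_aa,
    intact_fraction = intact_fraction,
    qc_window_aa = qc_window_aa,
    qc_max_similarity = qc_max_similarity,
    max_lineage_rate = max_lineage_rate,
    norm_scale = norm_scale,
    divergence_my_low = divergence_my_low,
    divergence_my_high = divergence_my_high
  )
  for (nm in names(th)) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      stop("threshold `", nm, "` must be a single positive number", call. = FALSE)
    }
  }
  if (th$intact_fraction >= 1) stop("`intact_fraction` must lie in (0, 1)", call. = FALSE)
  if (th$qc_max_similarity >= 1) stop("`qc_max_similarity` must lie in (0, 1)", call. = FALSE)
  if (th$divergence_my_low > th$divergence_my_high) {
    stop("`divergence_my_low` must not exceed `divergence_my_high`", call. = FALSE)
  }
  th$min_protein_aa <- as.integer(th$min_protein_aa)
  th$qc_window_aa <- as.integer(th$qc_window_aa)
  structure(th, class = "screen_thresholds")
}

#' @export
print.screen_thresholds <- function(x, ...) {
  cat("<screen_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_thresholds <- function(th) {
  if (inherits(th, "screen_thresholds")) return(th)
  if (is.null(th)) return(screen_thresholds())
  if (is.list(th)) return(do.call(screen_thresholds, th))
  stop("`thresholds` must be a screen_thresholds object or a named list", call. = FALSE)
}
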
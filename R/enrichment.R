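#' Cumulative X:autosome motif-density enrichment curve
#'
#' For each ln(P) threshold t, counts motif hits with `ln_p <= t` on
#' X-class chromosomes and on pooled autosomes, converts the counts to
#' per-bp densities by dividing by the total base pairs of each class,
#' and reports the X:A density ratio. Autosomes are pooled into a single
#' density, not averaged per chromosome. Where no autosomal hit passes a
#' threshold the ratio is undefined and flagged, never reported as
#' infinity.
#'
#' @param hits Hit data.frame from [scan_genome()].
#' @param chrom_class Named character vector mapping every chromosome to
#'   `"X"` or `"autosome"`.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param thresholds Numeric ln(P) grid.
#' @return A data.frame of class `enrichment_curve` with columns
#'   `threshold`, `x_count`, `a_count`, `x_density`, `a_density`,
#'   `ratio`, `defined`.
#' @export
xa_enrichment <- function(hits, chrom_class, chrom_lengths, thresholds) {
  chroms <- unique(hits$chrom)
  missing_cls <- setdiff(chroms, names(chrom_class))
  if (length(missing_cls) > 0L) {
    stop("chromosomes missing from chrom_class: ",
         paste(missing_cls, collapse = ", "))
  }
  missing_len <- setdiff(names(chrom_class), names(chrom_lengths))
  if (length(missing_len) > 0L) {
    stop("chromosomes missing from chrom_lengths: ",
         paste(missing_len, collapse = ", "))
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  bad <- setdiff(unique(chrom_class), c("X", "autosome"))
  if (length(bad) > 0L) {
    stop("chrom_class values must be 'X' or 'autosome', got: ",
         paste(bad, collapse = ", "))
  }
  x_bp <- sum(chrom_lengths[names(chrom_class)[chrom_class == "X"]])
  a_bp <- sum(chrom_lengths[names(chrom_class)[chrom_class == "autosome"]])
  if (x_bp <= 0 || a_bp <= 0) stop("each chromosome class must have > 0 bp")
  on_x <- chrom_class[hits$chrom] == "X"
  curve <- data.frame(threshold = thresholds)
  curve$x_count <- vapply(thresholds, function(t) {
    sum(on_x & hits$ln_p <= t)
  }, integer(1L))
  curve$a_count <- vapply(thresholds, function(t) {
    sum(!on_x & hits$ln_p <= t)
  }, integer(1L))
  curve$x_density <- curve$x_count / x_bp
  curve$a_density <- curve$a_count / a_bp
  curve$defined <- curve$a_count > 0L
  curve$ratio <- ifelse(curve$defined, curve$x_density / curve$a_density, NA_real_)
  class(curve) <- c("enrichment_curve", "data.frame")
  attr(curve, "x_bp") <- x_bp
  attr(curve, "a_bp") <- a_bp
  curve
}

#' Default ln(P) threshold grid for an enrichment curve
#'
#' 0.25-step grid from -9 down to the matrix's maximum theoretical ln(P).
#'
#' @param matrix A [motif_matrix()].
#' @param from Most permissive threshold (default -9).
#' @param by Step (default 0.25).
#' @return Decreasing numeric vector of thresholds.
#' @export
default_threshold_grid <- function(matrix, from = -9, by = 0.25) {
  seq(from, max_theoretical_ln_p(matrix), by = -abs(by))
}

#' Tabulate (and optionally plot) an enrichment curve
#'
#' Writes one row per threshold with counts, densities, the X:A ratio
#' and the defined flag. The plot mirrors the cumulative-enrichment
#' presentation: ln(P) threshold on x, X:A ratio on y.
#'
#' @param curve An `enrichment_curve` from [xa_enrichment()].
#' @param path Optional TSV output path.
#' @param plot Draw a ggplot of the curve (requires ggplot2). Suppressed
#'   with a warning when no threshold has a defined ratio.
#' @return The curve as a plain data.frame (invisibly when `path` is
#'   given); the ggplot object is attached as attribute `"plot"` when
#'   drawn.
#' @export
enrichment_report <- function(curve, path = NULL, plot = FALSE) {
  if (nrow(curve) == 0L) stop("empty enrichment curve")
  tab <- as.data.frame(curve)
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (plot) {
    if (!any(tab$defined)) {
      warning("no threshold has a defined X:A ratio; plot suppressed")
    } else if (requireNamespace("ggplot2", quietly = TRUE)) {
      def <- tab[tab$defined, ]
      p <- ggplot2::ggplot(def, ggplot2::aes(x = threshold, y = ratio)) +
        ggplot2::geom_point() +
        ggplot2::geom_line() +
        ggplot2::scale_x_reverse() +
        ggplot2::labs(x = "ln(P) threshold", y = "X:A motif density ratio")
      attr(tab, "plot") <- p
    } else {
      warning("ggplot2 not available; plot skipped")
    }
  }
  if (is.null(path)) tab else invisible(tab)
}
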
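#' Log2 transform an intensity matrix
#'
#' @param m an `intensity_matrix` with strictly positive values.
#' @return The transformed `intensity_matrix`.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  bad <- which(m$values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop_fmt("non-positive value at protein '%s', sample '%s'",
             rownames(m$values)[bad[1L, 1L]], colnames(m$values)[bad[1L, 2L]])
  m$values <- log2(m$values)
  append_provenance(m, "log2")
}

#' Quantile normalization
#'
#' Forces every sample (column) to share the identical value distribution:
#' each column's order statistics are replaced by the across-column mean of
#' order statistics; ties receive the mean of their tied target quantiles,
#' preserving within-column ranks.
#'
#' @param m an `intensity_matrix` with at least two samples.
#' @return The normalized `intensity_matrix`.
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (ncol(m$values) < 2L)
    stop_fmt("quantile normalization needs at least 2 samples")
  v <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(v) <- dimnames(m$values)
  m$values <- v
  append_provenance(m, "quantile")
}

#' Loess normalization against the mean reference array
#'
#' For each sample, fits a locally weighted regression of the difference
#' from the row-wise mean array (M) on the average intensity (A) and
#' subtracts the fitted intensity-dependent trend — the single-channel
#' variant of MA-plot loess normalization, run on log2-scale data.
#'
#' @param m an `intensity_matrix` on log2 scale, at least two samples.
#' @param span loess span, a fraction in (0, 1].
#' @param iterations number of normalization passes.
#' @return The normalized `intensity_matrix`.
#' @export
loess_normalize <- function(m, span = 0.3, iterations = 4L) {
  stopifnot(inherits(m, "intensity_matrix"))
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1)
    stop_fmt("`span` must be in (0, 1]")
  if (!is_count(iterations) || iterations < 1)
    stop_fmt("`iterations` must be a positive integer")
  if (ncol(m$values) < 2L)
    stop_fmt("loess normalization needs at least 2 samples")
  v <- limma::normalizeCyclicLoess(m$values, span = span,
                                   iterations = as.integer(iterations),
                                   method = "fast")
  dimnames(v) <- dimnames(m$values)
  m$values <- v
  append_provenance(m, sprintf("loess(span=%g, iterations=%d)", span, iterations))
}

#' Apply a named normalization method
#'
#' Convenience dispatcher used by the command-line pipeline: `"quantile"`,
#' `"loess"` or `"none"`, optionally preceded by a log2 transform.
#'
#' @param m an `intensity_matrix`.
#' @param method one of `"quantile"`, `"loess"`, `"none"`.
#' @param log2 apply [log2_transform()] first (default `TRUE`; skipped if
#'   provenance already records it).
#' @param span,iterations passed to [loess_normalize()].
#' @export
normalize_matrix <- function(m, method = c("quantile", "loess", "none"),
                             log2 = TRUE, span = 0.3, iterations = 4L) {
  method <- match.arg(method)
  if (log2 && !"log2" %in% m$provenance) m <- log2_transform(m)
  switch(method,
         quantile = quantile_normalize(m),
         loess = loess_normalize(m, span = span, iterations = iterations),
         none = m)
}

#' Per-array quality-control summary
#'
#' One row per array: flagged-spot count, median foreground and background,
#' and the design's lot/day labels — enough to eyeball batch structure
#' before any modelling.
#'
#' @param scans named list of `array_scan`.
#' @param design a `study_design`.
#' @return A data frame, one row per array in design order.
#' @export
qc_summary <- function(scans, design) {
  design <- study_design(as.data.frame(design))
  rows <- lapply(design$sample_id, function(sid) {
    s <- scans[[sid]]
    if (is.null(s)) stop_fmt("no scan for sample_id '%s'", sid)
    data.frame(sample_id = sid,
               n_spots = nrow(s$spots),
               n_flagged = sum(s$spots$flags < 0),
               median_foreground = stats::median(s$spots$f_median),
               median_background = stats::median(s$spots$b_median),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$group <- design$group
  out$lot <- design$lot
  out$day <- design$day %||% NA
  out
}
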
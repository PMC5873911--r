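#' Shared bin filter: mappability then low-GC quantile
#'
#' Removes bins with mappability exactly 0, then — among the bins that
#' survive — bins whose GC lies strictly below the 0.08 quantile of the
#' remaining GC values. The resulting kept set is shared by every sample of a
#' run, so all downstream vectors stay on one grid.
#'
#' @param samples List of `binned_coverage` objects (used to check that all
#'   samples share the grid; may be empty).
#' @param mappability Per-bin mappability.
#' @param gc Per-bin GC fraction.
#' @param gc_quantile Lower GC quantile to drop (default 0.08).
#' @return Integer vector of kept bin indices, with attributes
#'   `removed_mappability` and `removed_gc` (counts per rule).
#' @export
filter_bins <- function(samples, mappability, gc, gc_quantile = 0.08) {
  n <- length(mappability)
  if (length(gc) != n) stopf("gc and mappability tracks differ in length")
  for (s in samples) {
    if (length(s$values) != n) {
      stopf("sample '%s' is not on the shared bin grid", s$sample_id)
    }
  }
  keep <- mappability != 0
  n_map <- sum(!keep)
  thr <- stats::quantile(gc[keep], gc_quantile, names = FALSE)
  low_gc <- keep & (gc < thr)          # strictly below the quantile
  keep <- keep & !low_gc
  if (!any(keep)) stopf("bin filtering removed every bin")
  out <- which(keep)
  attr(out, "removed_mappability") <- n_map
  attr(out, "removed_gc") <- sum(low_gc)
  attr(out, "gc_threshold") <- thr
  out
}

#' Quantile-normalize corrected coverage across samples
#'
#' Classic quantile normalization: each sample's sorted values are replaced
#' by the across-sample mean of sorted values and put back in original bin
#' order, so every sample ends with an identical marginal distribution. Ties
#' receive averaged ranks. Backed by `limma::normalizeQuantiles`.
#'
#' @param mat Numeric matrix, one column per sample, rows = kept bins (all
#'   samples on the shared kept-bin set).
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stopf("quantile normalization needs >= 2 samples")
  bad <- which(!is.finite(mat), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("non-finite value in sample %s at bin %d",
          colnames(mat)[bad[1, 2]] %||% bad[1, 2], bad[1, 1])
  }
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}
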
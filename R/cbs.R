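#' Circular binary segmentation of a per-arm ratio vector
#'
#' Recursive changepoint detection on one chromosome arm. At every step the
#' arc `(i, j]` of the current segment maximizing the standardized
#' mean-difference statistic against its complement is found by an exhaustive
#' scan; the split is accepted if its permutation p-value falls below
#' `alpha`, and the search recurses into the resulting subsegments. Adjacent
#' segments are then merged back ("undo") while the difference between their
#' means is less than `undo_sd` standard errors of that difference, i.e.
#' `undo_sd * sd_res * sqrt(1/n1 + 1/n2)`, with the per-bin residual SD
#' `sd_res` estimated robustly as the MAD of bin values minus segment means.
#'
#' @param x Numeric vector of (log2 ratio) values for one arm.
#' @param alpha Permutation p-value cutoff for accepting a split
#'   (default 0.01).
#' @param undo_sd Minimum separation, in residual SDs, for neighbouring
#'   segments to stay split (default 3).
#' @param nperm Maximum permutations per split test (default 1000; sequential
#'   early stopping in both directions).
#' @param min_perm Minimum permutations before an early "significant" stop.
#' @return Data frame with one row per segment: `start`, `end` (1-based bin
#'   indices into `x`), `n_bins`, `mean`.
#' @seealso [cbs_max_stat()] for the bare statistic, [segment_arms()] for the
#'   genome-wide profile.
#' @export
cbs_segment <- function(x, alpha = 0.01, undo_sd = 3, nperm = 1000,
                        min_perm = 100) {
  if (length(x) < 1) stopf("empty arm vector")
  if (nperm < 100) warnf("nperm < 100 gives unstable permutation p-values")
  n <- length(x)

  cuts <- integer(0)  # cut positions: segment boundary after bin `cut`
  recurse <- function(s, e) {
    m <- e - s + 1
    if (m < 4) return(invisible(NULL))
    if (diff(range(x[s:e])) < 1e-12) return(invisible(NULL))  # constant
    res <- .cpp_cbs_split(x[s:e], as.integer(nperm), alpha,
                          as.integer(min_perm))
    if (!isTRUE(res$signif)) return(invisible(NULL))
    i <- res$i; j <- res$j     # 0-based cut points within the segment
    new_cuts <- as.integer(c(if (i > 0) s + i - 1, if (j < m) s + j - 1))
    cuts <<- c(cuts, new_cuts)
    bounds <- sort(unique(c(s - 1, new_cuts, e)))
    for (b in seq_len(length(bounds) - 1)) {
      recurse(bounds[b] + 1, bounds[b + 1])
    }
    invisible(NULL)
  }
  recurse(1L, n)

  segs <- cuts_to_segments(x, sort(unique(cuts)))
  if (nrow(segs) > 1) {
    sd_res <- stats::mad(x - rep(segs$mean, segs$n_bins))
    segs <- undo_merge(x, segs, undo_sd * sd_res)
  }
  segs
}

# Merge-decision threshold for one adjacent pair: undo_sd SEs of the
# difference between the two segment means.
pair_threshold <- function(scale, n1, n2) scale * sqrt(1 / n1 + 1 / n2)

cuts_to_segments <- function(x, cuts) {
  n <- length(x)
  starts <- c(1L, as.integer(cuts) + 1L)
  ends <- c(as.integer(cuts), n)
  data.frame(
    start = starts, end = ends, n_bins = ends - starts + 1L,
    mean = vapply(seq_along(starts),
                  function(i) mean(x[starts[i]:ends[i]]), numeric(1)))
}

# Merge adjacent segments whose mean difference is below undo_sd standard
# errors of that difference; most similar pair (in SE units) first,
# recomputing bin-weighted means as we go. `scale` = undo_sd * sd_res.
undo_merge <- function(x, segs, scale) {
  repeat {
    if (nrow(segs) < 2) return(segs)
    n <- segs$n_bins
    thr <- pair_threshold(scale, n[-nrow(segs)], n[-1])
    d <- abs(diff(segs$mean)) / thr
    d[!is.finite(d)] <- 0       # zero scale with equal means: merge
    k <- which.min(d)
    if (d[k] >= 1) return(segs)
    merged <- segs[k, ]
    merged$end <- segs$end[k + 1]
    merged$n_bins <- merged$end - merged$start + 1L
    merged$mean <- mean(x[merged$start:merged$end])
    segs <- rbind(if (k > 1) segs[seq_len(k - 1), ], merged,
                  if (k + 1 < nrow(segs)) segs[seq(k + 2, nrow(segs)), ])
    rownames(segs) <- NULL
  }
}

#' Maximum CBS arc statistic of a vector
#'
#' Exhaustive scan over all arcs `(i, j]` of the standardized mean-difference
#' statistic `|mean(arc) - mean(rest)| / sqrt(1/k + 1/(n-k))`. Exposed so the
#' split statistic can be validated directly.
#'
#' @param x Numeric vector.
#' @return List with `stat` and the maximizing cut points `i`, `j` (0-based;
#'   the arc is `x[(i+1):j]`).
#' @export
cbs_max_stat <- function(x) {
  .cpp_max_arc(as.numeric(x))
}

#' Anchor segment means at the diploid mode
#'
#' Shifts every segment mean by a constant so that the mode of the
#' bin-weighted segment-mean distribution sits at 0. The mode is taken as the
#' segment mean maximizing a bin-weighted Gaussian kernel density evaluated
#' at the observed means, which anchors the dominant (diploid) copy level
#' rather than the global average — robust to genomes with a large aberrant
#' fraction.
#'
#' @param profile A segment profile ([segment_arms()]) or a plain segment
#'   data frame with `mean` and `n_bins` columns.
#' @param bw Kernel bandwidth on the log2 scale (default 0.1).
#' @return The profile with shifted means; the applied shift is recorded in
#'   attribute `shift` (and in `$shift` for `segment_profile` objects).
#' @export
postsegment_normalize <- function(profile, bw = 0.1) {
  segs <- if (inherits(profile, "segment_profile")) profile$segments else profile
  if (is.null(segs) || nrow(segs) == 0) stopf("empty segment profile")
  m <- segs$mean
  w <- segs$n_bins / sum(segs$n_bins)
  dens <- vapply(m, function(mi) sum(w * stats::dnorm(m - mi, sd = bw)),
                 numeric(1))
  shift <- -m[which.max(dens)]
  segs$mean <- segs$mean + shift
  if (inherits(profile, "segment_profile")) {
    profile$segments <- segs
    profile$shift <- shift
    attr(profile, "shift") <- shift
    return(profile)
  }
  attr(segs, "shift") <- shift
  segs
}
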
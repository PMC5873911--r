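#' Per-bin log2 tumor/control ratio
#'
#' `log2((tumor + eps) / (control + eps))`, median-centred across the genome
#' so the global scale is absorbed. Negative corrected values (possible after
#' residual re-centring) are clipped at zero before the pseudo-count is
#' added.
#'
#' @param tumor,control Numeric vectors on the same kept-bin grid.
#' @param eps Pseudo-count; default half the smallest positive coverage
#'   increment observed in the pair (0.5 for integer counts).
#' @return Numeric vector of median-centred log2 ratios.
#' @export
compute_log_ratio <- function(tumor, control, eps = NULL) {
  if (length(tumor) != length(control)) {
    stopf("tumor and control are not on the same bin grid")
  }
  v <- c(tumor, control)
  if (is.null(eps)) {
    pos <- v[v > 0]
    eps <- if (length(pos)) 0.5 * min(pos) else 0.5
  }
  lr <- log2((pmax(tumor, 0) + eps) / (pmax(control, 0) + eps))
  lr - stats::median(lr)
}

#' Segment a genome-wide ratio vector arm by arm
#'
#' Runs [cbs_segment()] on the kept bins of every chromosome arm and
#' assembles the genome-wide segment profile. Segments tile the kept bins of
#' each arm; reported coordinates are the original (pre-filter) genome
#' positions of the first and last kept bin in each segment.
#'
#' @param ratio Log2 ratios on the kept bins (same order as `kept`).
#' @param kept Kept-bin index vector from [filter_bins()] (indices into the
#'   model bin grid).
#' @param model Genome model supplying the grid.
#' @param ... Passed to [cbs_segment()] (`alpha`, `undo_sd`, `nperm`).
#' @return An object of class `segment_profile`: list with `segments`
#'   (data.frame: chrom, start, end in 1-based inclusive bp, n_bins, mean,
#'   plus kept-bin bookkeeping), `ratio`, `kept`, and `shift` (0 until
#'   [postsegment_normalize()]).
#' @export
segment_arms <- function(ratio, kept, model, ...) {
  if (length(ratio) != length(kept)) {
    stopf("ratio vector and kept-bin set differ in length")
  }
  bins <- model$bins[kept, , drop = FALSE]
  seg_list <- list()
  for (ch in model$chrom_names) {
    idx <- which(bins$chrom == ch)
    if (length(idx) == 0) {
      warnf("arm %s has no kept bins; skipped", ch)
      next
    }
    segs <- cbs_segment(ratio[idx], ...)
    segs$chrom <- ch
    # genome coordinates of the first/last kept bin of each segment
    segs$start <- bins$start0[idx[segs$start]] + 1
    segs$end <- bins$end0[idx[segs$end]]
    segs$first_kept <- idx[1] - 1L   # offset of this arm in the kept vector
    seg_list[[ch]] <- segs[, c("chrom", "start", "end", "n_bins", "mean",
                               "first_kept")]
  }
  profile <- list(
    segments = do.call(rbind, seg_list),
    ratio = ratio,
    kept = kept,
    shift = 0
  )
  rownames(profile$segments) <- NULL
  class(profile) <- "segment_profile"
  profile
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("Segment profile: %d segments over %d kept bins (shift %.3f)\n",
              nrow(x$segments), length(x$kept), x$shift))
  print(utils::head(x$segments[, c("chrom", "start", "end", "n_bins", "mean")],
                    10))
  if (nrow(x$segments) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
summary.segment_profile <- function(object, ...) {
  s <- object$segments
  data.frame(chrom = unique(s$chrom),
             n_segments = as.integer(table(s$chrom)[unique(s$chrom)]),
             n_bins = as.integer(tapply(s$n_bins, s$chrom, sum)[unique(s$chrom)]))
}

#' Canonical log2 levels of the five copy-number states
#'
#' Double deletion is represented by the capped level log2(0.5/2) = -2.
#' @keywords internal
STATE_LEVELS <- c(`-2` = -2, `-1` = -1, `0` = 0,
                  `1` = log2(3 / 2), `2` = 1)

#' Call discrete copy-number states on a normalized segment profile
#'
#' Each segment is assigned the state whose canonical log2 level
#' (-2, -1, 0, log2(3/2), >= 1 for "high amplification") is nearest to the
#' segment mean. To leave the diploid state the absolute mean must also
#' exceed `max(call_margin, 2 * noise_sd / sqrt(n_bins))`, which suppresses
#' calls that a segment's own sampling noise could explain. Only non-diploid
#' segments are returned.
#'
#' @param profile A [segment_arms()] profile, normally after
#'   [postsegment_normalize()].
#' @param noise_sd Per-bin residual SD of the ratios; by default the MAD of
#'   bin ratios minus segment means.
#' @param call_margin Minimum absolute mean to leave diploid (default 0.25,
#'   below the 0 / +1 midpoint of ~0.29).
#' @param sample_id Optional sample label attached to the calls.
#' @return Data frame of class `cnv_calls`: sample_id, chrom, start, end
#'   (1-based inclusive, snapped to bin edges), state in {-2, -1, 1, 2}
#'   (2 = ">= +2"), n_bins, mean.
#' @export
call_states <- function(profile, noise_sd = NULL, call_margin = 0.25,
                        sample_id = NA_character_) {
  stopifnot(inherits(profile, "segment_profile"))
  segs <- profile$segments
  if (is.null(noise_sd)) {
    noise_sd <- stats::mad(profile$ratio -
                             rep(segs$mean, segs$n_bins) - profile$shift)
  }
  lev <- STATE_LEVELS
  state <- vapply(seq_len(nrow(segs)), function(i) {
    m <- segs$mean[i]
    if (abs(m) <= max(call_margin, 2 * noise_sd / sqrt(segs$n_bins[i]))) {
      return(0L)
    }
    as.integer(names(lev)[which.min(abs(lev - m))])
  }, integer(1))
  out <- segs[state != 0L,
              c("chrom", "start", "end", "n_bins", "mean"), drop = FALSE]
  out$state <- state[state != 0L]
  out$sample_id <- rep(sample_id, nrow(out))
  out <- out[, c("sample_id", "chrom", "start", "end", "state", "n_bins",
                 "mean")]
  rownames(out) <- NULL
  class(out) <- c("cnv_calls", "data.frame")
  out
}

#' Tumor/control copy-number calling pipeline
#'
#' The end-to-end comparison of one tumor sample against its matched control:
#' per-sample GC correction ([fit_gc_correction()]), shared bin filtering
#' ([filter_bins()]) with optional interval masking, quantile normalization
#' of the pair, median-centred log2 ratio, arm-wise circular binary
#' segmentation, diploid-mode anchoring ([postsegment_normalize()]) and
#' five-state calling ([call_states()]).
#'
#' @param tumor,control Raw `binned_coverage` objects on the model grid.
#' @param model Genome model.
#' @param mask Optional data frame of intervals (chrom, start0, end0) —
#'   typically UR plus repeat intervals; any bin overlapping a mask interval
#'   by >= 1 bp is dropped before segmentation. Reported call coordinates
#'   remain original genome positions.
#' @param alpha,undo_sd,nperm Segmentation tuning, see [cbs_segment()].
#' @param call_margin See [call_states()].
#' @param gc_k Spline basis dimension for the GC fit.
#' @return An object of class `cnv_fit`: list with `calls` (a `cnv_calls`
#'   frame), `profile` (normalized `segment_profile`), `kept`, `noise_sd`,
#'   `tumor_id`, `control_id`, `masked`.
#' @export
call_cnvs <- function(tumor, control, model, mask = NULL,
                      alpha = 0.01, undo_sd = 3, nperm = 1000,
                      call_margin = 0.25, gc_k = 10) {
  stopifnot(inherits(tumor, "binned_coverage"),
            inherits(control, "binned_coverage"))
  bins <- model$bins
  fit_t <- fit_gc_correction(tumor, bins$gc, bins$mappability, k = gc_k)
  fit_c <- fit_gc_correction(control, bins$gc, bins$mappability, k = gc_k)

  kept <- filter_bins(list(tumor, control), bins$mappability, bins$gc)
  if (!is.null(mask) && nrow(mask) > 0) {
    masked_bins <- IRanges::overlapsAny(bins_to_granges(model),
                                        intervals_to_granges(mask))
    kept <- kept[!masked_bins[kept]]
    if (!length(kept)) stopf("mask removed every kept bin")
  }

  mat <- cbind(tumor = fit_t$corrected$values[kept],
               control = fit_c$corrected$values[kept])
  qn <- quantile_normalize(mat)
  ratio <- compute_log_ratio(qn[, "tumor"], qn[, "control"])

  profile <- segment_arms(ratio, kept, model, alpha = alpha,
                          undo_sd = undo_sd, nperm = nperm)
  profile <- postsegment_normalize(profile)
  noise_sd <- stats::mad(ratio - rep(profile$segments$mean,
                                     profile$segments$n_bins))
  calls <- call_states(profile, noise_sd = noise_sd,
                       call_margin = call_margin,
                       sample_id = tumor$sample_id)
  out <- list(calls = calls, profile = profile, kept = kept,
              noise_sd = noise_sd, tumor_id = tumor$sample_id,
              control_id = control$sample_id,
              masked = !is.null(mask) && nrow(mask) > 0)
  class(out) <- "cnv_fit"
  out
}

#' @export
print.cnv_fit <- function(x, ...) {
  cat(sprintf("CNV fit: %s vs %s%s\n", x$tumor_id, x$control_id,
              if (x$masked) " (UR/repeat-masked)" else ""))
  cat(sprintf("  %d segments on %d kept bins; noise SD %.3f; shift %.3f\n",
              nrow(x$profile$segments), length(x$kept), x$noise_sd,
              x$profile$shift))
  st <- table(factor(x$calls$state, levels = c(-2, -1, 1, 2)))
  cat(sprintf("  %d calls (-2: %d, -1: %d, +1: %d, >=+2: %d)\n",
              nrow(x$calls), st["-2"], st["-1"], st["1"], st["2"]))
  invisible(x)
}

#' @export
summary.cnv_fit <- function(object, ...) {
  calls <- object$calls
  data.frame(
    sample_id = object$tumor_id,
    n_calls = nrow(calls),
    n_gain = sum(calls$state > 0),
    n_loss = sum(calls$state < 0),
    mb_gain = sum((calls$end - calls$start + 1)[calls$state > 0]) / 1e6,
    mb_loss = sum((calls$end - calls$start + 1)[calls$state < 0]) / 1e6)
}

#' @export
plot.cnv_fit <- function(x, model = NULL, ...) {
  segs <- x$profile$segments
  n <- length(x$profile$ratio)
  graphics::plot(seq_len(n), x$profile$ratio + x$profile$shift,
                 pch = ".", col = "grey60", xlab = "kept bin",
                 ylab = "log2 ratio (diploid-anchored)",
                 ylim = c(-2.5, 2.5), ...)
  pos <- 0
  for (i in seq_len(nrow(segs))) {
    graphics::segments(pos + 1, segs$mean[i], pos + segs$n_bins[i],
                       segs$mean[i], col = "red", lwd = 2)
    pos <- pos + segs$n_bins[i]
  }
  graphics::abline(h = STATE_LEVELS, lty = 3, col = "blue")
  invisible(x)
}

#' Re-call CNVs after masking under-replicated and repeat regions
#'
#' Runs the calling pipeline twice for a tumor/control pair: once on the full
#' filtered grid and once after dropping every bin that overlaps the mask
#' (UR plus repeat intervals by default). In polytene-control data the first
#' run shows spurious gains over URs; the masked run is the cleaned map.
#'
#' @param tumor,control Raw `binned_coverage` objects.
#' @param model Genome model.
#' @param masks Mask intervals; default the model's UR plus repeat intervals.
#' @param ... Passed to [call_cnvs()].
#' @return List with elements `unmasked` and `masked`, each a `cnv_fit`.
#' @export
mask_and_recall <- function(tumor, control, model,
                            masks = rbind(model$ur_intervals[, c("chrom", "start0", "end0")],
                                          model$repeat_intervals[, c("chrom", "start0", "end0")]),
                            ...) {
  list(unmasked = call_cnvs(tumor, control, model, mask = NULL, ...),
       masked = call_cnvs(tumor, control, model, mask = masks, ...))
}

#' Infer sample sex from coverage
#'
#' Males carry one X and one Y: the X/autosome mean-coverage ratio sits near
#' 0.5 and the repeat-free Y proxy region (kl-2-like) near 0.5; females show
#' an X/autosome ratio near 1 and essentially no Y coverage. Calls `male`
#' when X/A < 0.75 and Y/A > 0.25, `female` when X/A > 0.75 and Y/A < 0.25,
#' and `ambiguous` otherwise (including the exact 0.75 boundary).
#'
#' @param control_cov Raw `binned_coverage` for the sample (any sample works;
#'   the host-larva control is the conventional choice).
#' @param model Genome model; its `y_region` is the Y proxy interval.
#' @return An object of class `sex_call`: list with `sample_id`, `sex`,
#'   `x_autosome_ratio`, `y_region_ratio`.
#' @export
infer_sex <- function(control_cov, model) {
  stopifnot(inherits(control_cov, "binned_coverage"))
  bins <- model$bins
  ok <- bins$mappability > 0
  x_idx <- which(bins$chrom == "X" & ok)
  if (!length(x_idx)) stopf("no mappable X bins in the model")
  autosomes <- setdiff(model$chrom_names, c("X", "Y"))
  a_idx <- which(bins$chrom %in% autosomes & ok)
  y_gr <- intervals_to_granges(model$y_region)
  y_idx <- which(IRanges::overlapsAny(bins_to_granges(model), y_gr) & ok)

  a_mean <- mean(control_cov$values[a_idx])
  x_ratio <- mean(control_cov$values[x_idx]) / a_mean
  y_ratio <- if (length(y_idx)) mean(control_cov$values[y_idx]) / a_mean else 0

  sex <- if (x_ratio < 0.75 && y_ratio > 0.25) "male"
         else if (x_ratio > 0.75 && y_ratio < 0.25) "female"
         else "ambiguous"
  structure(list(sample_id = control_cov$sample_id, sex = sex,
                 x_autosome_ratio = x_ratio, y_region_ratio = y_ratio),
            class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("Sex call for '%s': %s (X/A = %.3f, Y/A = %.3f)\n",
              x$sample_id, x$sex, x$x_autosome_ratio, x$y_region_ratio))
  invisible(x)
}
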
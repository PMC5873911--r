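# CNV catalog summaries: interval arithmetic, per-sample/cohort tables,
# per-arm rates, and passage-to-passage turnover.

#' Overlap length of two genomic intervals
#'
#' Intervals are 1-based inclusive (the convention of textual CNV reports,
#' e.g. "chr3R:20994001-27965000").
#'
#' @param a,b Length-3 lists/vectors `(chrom, start, end)` or data frame rows
#'   with those columns.
#' @return Overlap length in bp; 0 if disjoint, and 0 with a warning if the
#'   intervals sit on different chromosomes.
#' @export
interval_overlap_length <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  ga <- as.character(a[[1]]); gb <- as.character(b[[1]])
  if (ga != gb) {
    warnf("intervals on different chromosomes (%s vs %s); overlap is 0", ga, gb)
    return(0)
  }
  max(0, min(as.numeric(a[[3]]), as.numeric(b[[3]])) -
        max(as.numeric(a[[2]]), as.numeric(b[[2]])) + 1)
}

calls_to_granges <- function(calls) {
  GenomicRanges::GRanges(calls$chrom,
                         IRanges::IRanges(calls$start, calls$end))
}

#' Summarize a CNV catalog
#'
#' Per sample: count per state, total calls, Mb covered by gains and by
#' losses, and number of annotated genes overlapped (>= 1 bp) by gains and by
#' losses (each gene counted once per sample per direction). Cohort level:
#' per-group (e.g. tumor type) means +/- SD of the per-sample totals, and the
#' overall amplification:deletion ratio.
#'
#' @param calls A `cnv_calls` data frame (or rbind of several), with
#'   `sample_id` set.
#' @param model Genome model providing `gene_intervals`.
#' @param groups Optional named vector mapping sample_id to a group label
#'   (e.g. tumor type) for the cohort table.
#' @return List with `per_sample`, `cohort` (NULL if no groups), `amp_del_ratio`.
#' @export
summarize_catalog <- function(calls, model, groups = NULL) {
  samples <- unique(calls$sample_id)
  gene_gr <- intervals_to_granges(model$gene_intervals)
  per_sample <- do.call(rbind, lapply(samples, function(sid) {
    cc <- calls[calls$sample_id == sid, , drop = FALSE]
    gains <- cc[cc$state > 0, , drop = FALSE]
    losses <- cc[cc$state < 0, , drop = FALSE]
    genes_hit <- function(x) {
      if (!nrow(x)) return(0L)
      length(unique(S4Vectors::subjectHits(
        GenomicRanges::findOverlaps(calls_to_granges(x), gene_gr))))
    }
    data.frame(
      sample_id = sid,
      n_minus2 = sum(cc$state == -2), n_minus1 = sum(cc$state == -1),
      n_plus1 = sum(cc$state == 1), n_plus2 = sum(cc$state == 2),
      n_total = nrow(cc),
      mb_gain = sum(gains$end - gains$start + 1) / 1e6,
      mb_loss = sum(losses$end - losses$start + 1) / 1e6,
      genes_amplified = genes_hit(gains),
      genes_deleted = genes_hit(losses),
      stringsAsFactors = FALSE)
  }))
  if (is.null(per_sample)) {
    per_sample <- data.frame(sample_id = character(), n_minus2 = integer(),
                             n_minus1 = integer(), n_plus1 = integer(),
                             n_plus2 = integer(), n_total = integer(),
                             mb_gain = numeric(), mb_loss = numeric(),
                             genes_amplified = integer(),
                             genes_deleted = integer())
  }
  n_amp <- sum(calls$state > 0)
  n_del <- sum(calls$state < 0)
  cohort <- NULL
  if (!is.null(groups) && nrow(per_sample)) {
    g <- groups[per_sample$sample_id]
    cohort <- do.call(rbind, lapply(split(per_sample, g), function(d) {
      data.frame(group = g[match(d$sample_id[1], per_sample$sample_id)],
                 n_samples = nrow(d),
                 mean_cnvs = mean(d$n_total), sd_cnvs = stats::sd(d$n_total),
                 stringsAsFactors = FALSE)
    }))
    rownames(cohort) <- NULL
  }
  list(per_sample = per_sample, cohort = cohort,
       amp_del_ratio = if (n_del > 0) n_amp / n_del else NA_real_,
       n_amplifications = n_amp, n_deletions = n_del)
}

#' CNVs per Mb of kept euchromatin, by arm and sex
#'
#' Rates use the kept-bin length of each arm (the euchromatic, mappable,
#' GC-filtered fraction) as the denominator.
#'
#' @param calls `cnv_calls` data frame with sample_id.
#' @param model Genome model.
#' @param kept Kept-bin index vector ([filter_bins()]).
#' @param sex Named vector mapping sample_id to "male"/"female" (optional).
#' @return List with `per_sample_arm` (sample x arm rates) and `by_sex`
#'   (mean +/- SD per arm per sex; NULL without `sex`).
#' @export
cnv_rate_per_mb <- function(calls, model, kept, sex = NULL) {
  bins <- model$bins[kept, , drop = FALSE]
  kept_mb <- tapply(bins$end0 - bins$start0, bins$chrom, sum) / 1e6
  arms <- names(kept_mb)[kept_mb > 0]
  samples <- unique(calls$sample_id)
  rows <- list()
  for (sid in samples) {
    for (ch in arms) {
      n <- sum(calls$sample_id == sid & calls$chrom == ch)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, chrom = ch, n_cnvs = n,
        kept_mb = unname(kept_mb[ch]),
        rate = n / unname(kept_mb[ch]), stringsAsFactors = FALSE)
    }
  }
  per <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), chrom = character(),
               n_cnvs = integer(), kept_mb = numeric(), rate = numeric())
  by_sex <- NULL
  if (!is.null(sex) && nrow(per)) {
    per$sex <- sex[per$sample_id]
    by_sex <- stats::aggregate(rate ~ chrom + sex, data = per,
                               FUN = function(v) c(mean = mean(v),
                                                   sd = stats::sd(v)))
    by_sex <- cbind(by_sex[c("chrom", "sex")], as.data.frame(by_sex$rate))
  }
  list(per_sample_arm = per, by_sex = by_sex)
}

#' CNV turnover between consecutive time points
#'
#' A call at the later time point is "passed on" if it overlaps a same-sign
#' call (gain with gain, loss with loss, regardless of magnitude) at the
#' earlier time point by at least `min_overlap` bp (inclusive threshold).
#'
#' @param calls_prev,calls_next `cnv_calls` frames for the two time points of
#'   one line.
#' @param min_overlap Minimum shared bp (default 1000).
#' @return Data frame with one row per class (`dup`, `del`): `n_prev`,
#'   `n_next`, `n_passed` (calls at next overlapping prev), `n_new`, `n_lost`.
#' @export
cnv_turnover <- function(calls_prev, calls_next, min_overlap = 1000) {
  one_class <- function(sgn) {
    prev <- calls_prev[sign(calls_prev$state) == sgn, , drop = FALSE]
    nxt <- calls_next[sign(calls_next$state) == sgn, , drop = FALSE]
    passed <- 0L
    if (nrow(prev) && nrow(nxt)) {
      hits <- GenomicRanges::findOverlaps(calls_to_granges(nxt),
                                          calls_to_granges(prev),
                                          minoverlap = min_overlap)
      passed <- length(unique(S4Vectors::queryHits(hits)))
    }
    data.frame(class = if (sgn > 0) "dup" else "del",
               n_prev = nrow(prev), n_next = nrow(nxt),
               n_passed = passed, n_new = nrow(nxt) - passed,
               n_lost = nrow(prev) - if (nrow(prev) && nrow(nxt)) {
                 length(unique(S4Vectors::subjectHits(
                   GenomicRanges::findOverlaps(calls_to_granges(nxt),
                                               calls_to_granges(prev),
                                               minoverlap = min_overlap))))
               } else 0L,
               stringsAsFactors = FALSE)
  }
  rbind(one_class(1), one_class(-1))
}

#' Score called CNVs against a known truth set
#'
#' Matches calls to true lesions of the same sign (gain with gain, loss with
#' loss) requiring at least `min_reciprocal` reciprocal overlap (the shared
#' length must cover that fraction of both intervals). Reports recall
#' (matched truth / truth) and precision (matched calls / calls).
#'
#' @param calls `cnv_calls` data frame (1-based inclusive coordinates).
#' @param truth Data frame of true lesions with chrom, start0, end0 (0-based
#'   half-open, as emitted by [simulate_lineage()]) and state.
#' @param min_reciprocal Minimum reciprocal overlap fraction (default 0.5).
#' @return List with `recall`, `precision`, `n_truth`, `n_calls`,
#'   `n_truth_matched`, `n_calls_matched`.
#' @export
cnv_recovery <- function(calls, truth, min_reciprocal = 0.5) {
  n_truth <- nrow(truth); n_calls <- nrow(calls)
  if (n_truth == 0 || n_calls == 0) {
    return(list(recall = if (n_truth == 0) NA_real_ else 0,
                precision = if (n_calls == 0) NA_real_ else 0,
                n_truth = n_truth, n_calls = n_calls,
                n_truth_matched = 0L, n_calls_matched = 0L))
  }
  call_gr <- calls_to_granges(calls)
  truth_gr <- intervals_to_granges(truth)
  hits <- GenomicRanges::findOverlaps(call_gr, truth_gr)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  same_sign <- sign(calls$state[q]) == sign(truth$state[s])
  ov <- IRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(call_gr)[q], GenomicRanges::ranges(truth_gr)[s]))
  ok <- same_sign &
    ov >= min_reciprocal * IRanges::width(GenomicRanges::ranges(call_gr)[q]) &
    ov >= min_reciprocal * IRanges::width(GenomicRanges::ranges(truth_gr)[s])
  list(recall = length(unique(s[ok])) / n_truth,
       precision = length(unique(q[ok])) / n_calls,
       n_truth = n_truth, n_calls = n_calls,
       n_truth_matched = length(unique(s[ok])),
       n_calls_matched = length(unique(q[ok])))
}
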
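# Somatic SNP statistics: filtering, six-class substitution spectrum,
# clustering and region-enrichment binomial tests, exome mutation rates,
# passage turnover and the read-orientation oxidation-artifact check.

BASES <- c("A", "C", "G", "T")
SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Filter a somatic SNP table
#'
#' Removes variants inside mask intervals (transposable elements and
#' low-complexity sequence, typically), rejects malformed records (alleles
#' outside A/C/G/T, ref equal to alt, multi-base alleles), and — only when
#' `min_aaf` is given — drops variants below the alternative-allele-fraction
#' threshold used for exome-rate analyses. Spectrum analyses pass
#' `min_aaf = NULL` so low-AAF variants are retained there.
#'
#' @param variants Data frame with chrom, pos, ref, alt (and aaf if the AAF
#'   filter is requested).
#' @param masks Optional mask intervals (chrom, start0, end0).
#' @param min_aaf Optional AAF threshold (the exome-rate analyses use 0.1);
#'   `NULL` disables the filter.
#' @return The retained rows, with attribute `removed` giving counts per rule
#'   (`malformed`, `mask`, `aaf`).
#' @export
filter_snps <- function(variants, masks = NULL, min_aaf = NULL) {
  ok <- variants$ref %in% BASES & variants$alt %in% BASES &
    variants$ref != variants$alt
  removed <- c(malformed = sum(!ok))
  v <- variants[ok, , drop = FALSE]

  if (!is.null(masks) && nrow(masks) > 0 && nrow(v) > 0) {
    gr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
    hit <- IRanges::overlapsAny(gr, intervals_to_granges(masks))
    removed <- c(removed, mask = sum(hit))
    v <- v[!hit, , drop = FALSE]
  } else {
    removed <- c(removed, mask = 0L)
  }

  if (!is.null(min_aaf)) {
    keep <- v$aaf >= min_aaf
    removed <- c(removed, aaf = sum(!keep))
    v <- v[keep, , drop = FALSE]
  } else {
    removed <- c(removed, aaf = 0L)
  }
  attr(v, "removed") <- removed
  v
}

#' Six-class substitution spectrum
#'
#' Collapses the twelve raw substitutions to the six pyrimidine-reference
#' classes (a G>T is counted as C>A, etc., since both report the same
#' base-pair change) and returns counts and fractions.
#'
#' @param variants Data frame with ref and alt single-base columns.
#' @return List with `counts` (named six-vector), `fractions` (named
#'   six-vector; all `NA` with a flag for empty input), `n_skipped`
#'   (non-SNV records).
#' @export
substitution_spectrum <- function(variants) {
  ref <- as.character(variants$ref)
  alt <- as.character(variants$alt)
  is_snv <- ref %in% BASES & alt %in% BASES & ref != alt
  n_skipped <- sum(!is_snv)
  ref <- ref[is_snv]; alt <- alt[is_snv]
  purine <- ref %in% c("A", "G")
  ref[purine] <- COMPLEMENT[ref[purine]]
  alt[purine] <- COMPLEMENT[alt[purine]]
  cls <- paste0(ref, ">", alt)
  counts <- vapply(SPECTRUM_CLASSES, function(k) sum(cls == k), numeric(1))
  total <- sum(counts)
  fractions <- if (total > 0) counts / total else
    stats::setNames(rep(NA_real_, 6), SPECTRUM_CLASSES)
  list(counts = counts, fractions = fractions, n = total,
       n_skipped = n_skipped, empty = total == 0)
}

#' Binomial SNP clustering test
#'
#' For each SNP, counts the SNPs within a window centred on it (50 kb total,
#' i.e. +/- 25 kb, including the focal SNP) and computes the upper-tail
#' binomial probability of observing that many under uniform placement:
#' `P(X >= k)` with `X ~ Binomial(N_total, window / n_eff)`, where `n_eff` is
#' the effective genome size (positions with enough read support to call a
#' SNP). Overlapping significant windows are merged into reported regions.
#'
#' @param variants Data frame with chrom, pos.
#' @param window Window size in bp (default 50000).
#' @param n_eff Effective genome size in bp (must be >= the SNP count).
#' @param alpha Significance threshold on the raw p-value (default 0.001; no
#'   multiple-testing correction, but see `bonferroni`).
#' @param bonferroni Multiply p-values by the SNP count before thresholding
#'   (off by default).
#' @return List with `results` (per-SNP: chrom, pos, k, p_value,
#'   significant) and `regions` (merged significant windows: chrom, start,
#'   end, n_snps).
#' @export
cluster_test <- function(variants, window = 50000, n_eff, alpha = 0.001,
                         bonferroni = FALSE) {
  if (missing(n_eff) || is.null(n_eff) || n_eff <= 0) {
    stopf("n_eff (effective genome size) must be positive")
  }
  N <- nrow(variants)
  if (n_eff < N) stopf("n_eff smaller than the number of SNPs")
  if (N == 0) {
    return(list(results = data.frame(chrom = character(), pos = integer(),
                                     k = integer(), p_value = numeric(),
                                     significant = logical()),
                regions = data.frame(chrom = character(), start = numeric(),
                                     end = numeric(), n_snps = integer())))
  }
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  half <- window / 2
  p_hit <- window / n_eff
  k <- integer(N)
  idx <- 0
  for (ch in unique(v$chrom)) {
    pos <- v$pos[v$chrom == ch]
    lo <- findInterval(pos - half - 1e-9, pos)       # strictly below window
    hi <- findInterval(pos + half + 1e-9, pos)
    k[idx + seq_along(pos)] <- hi - lo
    idx <- idx + length(pos)
  }
  p <- stats::pbinom(k - 1, N, p_hit, lower.tail = FALSE)
  if (bonferroni) p <- pmin(1, p * N)
  res <- data.frame(chrom = v$chrom, pos = v$pos, k = k, p_value = p,
                    significant = p <= alpha, stringsAsFactors = FALSE)

  regions <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), n_snps = integer(),
                        stringsAsFactors = FALSE)
  sig <- res[res$significant, , drop = FALSE]
  if (nrow(sig)) {
    gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      sig$chrom, IRanges::IRanges(pmax(1, sig$pos - half), sig$pos + half)))
    regions <- granges_to_intervals(gr)
    names(regions) <- c("chrom", "start", "end")
    regions$start <- regions$start + 1
    all_gr <- GenomicRanges::GRanges(res$chrom,
                                     IRanges::IRanges(res$pos, res$pos))
    regions$n_snps <- GenomicRanges::countOverlaps(gr, all_gr)
  }
  list(results = res, regions = regions)
}

#' Exact binomial region-enrichment test
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`: the chance
#' that at least `k` of a chromosome's `n` SNPs fall in a region expected to
#' hold a fraction `p0` of them under uniform placement. Small tails are
#' accumulated in log space for numerical stability.
#'
#' @param k Observed SNPs in the region.
#' @param n Total SNPs on the chromosome.
#' @param p0 Expected fraction under the null (0 < p0 < 1).
#' @return The upper-tail p-value.
#' @export
region_enrichment_test <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  if (k == 0) return(1)
  # log-space tail sum: log P(X >= k) via logsumexp over the pmf
  lp <- stats::dbinom(k:n, n, p0, log = TRUE)
  m <- max(lp)
  exp(m + log(sum(exp(lp - m))))
}

#' SNPs per Mb of callable exome
#'
#' Counts variants falling in exome intervals and divides by the callable
#' exome size in Mb. Callers should apply the AAF >= 0.1 filter first
#' ([filter_snps()]). Also reports the exonic fraction of all variants and
#' the protein-affecting fraction among exonic ones (from `region_class`).
#'
#' @param variants Filtered variant data frame (chrom, pos, region_class).
#' @param exome_intervals Exome intervals (chrom, start0, end0).
#' @param callable_exome_bp Size of the sufficiently covered exome in bp.
#' @return List with `rate_per_mb`, `n_exonic`, `exonic_fraction`,
#'   `protein_affecting_fraction`.
#' @export
exome_rate <- function(variants, exome_intervals, callable_exome_bp) {
  if (callable_exome_bp <= 0) stopf("callable exome size must be positive")
  n <- nrow(variants)
  if (n == 0) {
    return(list(rate_per_mb = 0, n_exonic = 0L, exonic_fraction = NA_real_,
                protein_affecting_fraction = NA_real_))
  }
  gr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  in_ex <- IRanges::overlapsAny(gr, intervals_to_granges(exome_intervals))
  n_ex <- sum(in_ex)
  prot <- if (n_ex > 0 && !is.null(variants$region_class)) {
    mean(variants$region_class[in_ex] == "exonic-nonsyn")
  } else NA_real_
  list(rate_per_mb = n_ex / (callable_exome_bp / 1e6),
       n_exonic = n_ex,
       exonic_fraction = n_ex / n,
       protein_affecting_fraction = prot)
}

#' SNP turnover between time points
#'
#' SNPs are identified by exact (chrom, pos, ref, alt) match.
#'
#' @param set_prev,set_next Variant data frames at the earlier/later time
#'   point.
#' @return List with `n_prev`, `n_next`, `n_passed`, `n_new`, and
#'   `fraction_passed` (`NA` for an empty earlier set).
#' @export
snp_turnover <- function(set_prev, set_next) {
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  kp <- unique(key(set_prev)); kn <- unique(key(set_next))
  n_passed <- length(intersect(kp, kn))
  list(n_prev = length(kp), n_next = length(kn), n_passed = n_passed,
       n_new = length(setdiff(kn, kp)),
       fraction_passed = if (length(kp)) n_passed / length(kp) else NA_real_)
}

#' Read-orientation oxidation-artifact check
#'
#' 8-oxo-dG damage introduced during sample processing produces C>A calls
#' whose alt-supporting reads are skewed toward one read-pair orientation.
#' This pools the alt-orientation counts of all C>A-class variants (G>T
#' records are strand-flipped so orientation refers to the pyrimidine
#' strand), tests the pooled F1R2/F2R1 balance against 0.5 with an exact
#' two-sided binomial test, and flags the sample when the imbalance is
#' significant (p < `alpha`) in the configured artifact direction.
#'
#' @param variants Data frame with ref, alt, f1r2, f2r1.
#' @param alpha Significance threshold (default 0.01).
#' @param artifact_direction Orientation whose excess marks the artifact
#'   (`"f1r2"` default, `"f2r1"` configurable).
#' @return List with `status` (`"ok"`, `"flagged"`, `"no_data"`, or
#'   `"skipped"` when counts are missing), `p_value`, `f1r2`, `f2r1`.
#' @export
orientation_bias_check <- function(variants, alpha = 0.01,
                                   artifact_direction = c("f1r2", "f2r1")) {
  artifact_direction <- match.arg(artifact_direction)
  if (is.null(variants$f1r2) || is.null(variants$f2r1) ||
      all(is.na(variants$f1r2))) {
    warnf("orientation counts missing; oxidation check skipped")
    return(list(status = "skipped", p_value = NA_real_,
                f1r2 = NA_integer_, f2r1 = NA_integer_))
  }
  ca <- variants$ref == "C" & variants$alt == "A"
  gt <- variants$ref == "G" & variants$alt == "T"
  if (!any(ca | gt)) {
    return(list(status = "no_data", p_value = NA_real_,
                f1r2 = 0L, f2r1 = 0L))
  }
  # orientation relative to the pyrimidine strand: swap counts for G>T
  f1 <- sum(variants$f1r2[ca]) + sum(variants$f2r1[gt])
  f2 <- sum(variants$f2r1[ca]) + sum(variants$f1r2[gt])
  if (f1 + f2 == 0) {
    return(list(status = "no_data", p_value = NA_real_, f1r2 = 0L, f2r1 = 0L))
  }
  p <- stats::binom.test(f1, f1 + f2, 0.5)$p.value
  skewed <- if (artifact_direction == "f1r2") f1 > f2 else f2 > f1
  list(status = if (p < alpha && skewed) "flagged" else "ok",
       p_value = p, f1r2 = f1, f2r1 = f2)
}
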
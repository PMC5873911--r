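#' Simulation configuration for synthetic tumor-allograft genomes
#'
#' Bundles every tunable of the synthetic-data generator: genome geometry,
#' sequencing depth and noise, GC bias, polytene under-replication of the
#' host-larva control, and the per-passage birth/retention dynamics of somatic
#' lesions across rounds of allograft.
#'
#' @param seed Integer seed; all generator functions are deterministic given
#'   the configuration (sub-seeds are derived per sample).
#' @param line Line label used in sample ids (e.g. `"mbtL1"`).
#' @param chrom_lengths Named vector of arm lengths in bp. The default is a
#'   compact six-arm genome (X, 2L, 2R, 3L, 3R, 4) totalling 20 Mb, plus a
#'   short repeat-free Y proxy region standing in for the kl-2 gene region.
#' @param bin_size Bin width in bp for the fixed coverage grid (default 1000).
#' @param depth Mean reads per diploid bin in the tumor samples.
#' @param gc_bias_coeffs Coefficients `c(b0, b1, b2)` of the smooth log-scale
#'   GC bias curve `b0 + b1*(gc - mean(gc)) + b2*(gc - mean(gc))^2`.
#' @param overdispersion Negative-binomial size parameter for bin counts
#'   (larger = closer to Poisson).
#' @param ur_factor Multiplier in (0, 1] applied to control coverage inside
#'   under-replicated intervals, emulating incomplete endoreplication of
#'   polytene larval tissue.
#' @param ur_fraction,repeat_fraction Fractions of the non-Y genome covered by
#'   under-replicated and repeat intervals.
#' @param map_zero_fraction Fraction of bins with mappability 0.
#' @param gc_mean,gc_sd Target mean and SD of the per-bin GC track.
#' @param gc_smooth Logical; smooth the GC track so neighbouring bins are
#'   correlated (moving average over `gc_smooth_window` bins).
#' @param gc_smooth_window Smoothing window in bins.
#' @param cnv_rate_per_passage,snp_rate_per_passage Expected number of new
#'   CNVs / SNPs born at each recorded passage transition (Poisson); the T0
#'   set is one such birth event.
#' @param retention_prob Probability that an existing lesion survives one
#'   recorded passage transition (see [simulate_lineage()]).
#' @param cnv_size_law Two-element range (bp); CNV lengths are log-uniform on
#'   it.
#' @param cnv_state_probs Named probabilities over copy-number states
#'   `c("-2", "-1", "1", "2")`; single-copy gains are the commonest class.
#' @param spectrum Named six-class substitution probabilities over
#'   `c("C>A","C>G","C>T","T>A","T>C","T>G")` (pyrimidine-reference classes;
#'   must sum to 1).
#' @param aaf_beta Beta(a, b) parameters for simulated alternative allele
#'   fractions.
#' @param orientation_prob Probability that an alt-supporting read is F1R2;
#'   0.5 is unbiased, values away from 0.5 emulate the 8-oxo-dG oxidation
#'   artifact signature.
#' @param sex `"male"` or `"female"` donor larva (scales X and Y coverage).
#' @param timepoints Integer passages at which tumor gDNA is sampled
#'   (default `c(0, 5, 10)` for T0/T5/T10).
#' @param split_at Optional passage after which the line is split into two
#'   sublines A and B that evolve independently (e.g. 9), or `NA` for none.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       line = "simL1",
                       chrom_lengths = c(X = 4e6, `2L` = 3.5e6, `2R` = 3.5e6,
                                         `3L` = 3.5e6, `3R` = 4.5e6, `4` = 1e6,
                                         Y = 2e5),
                       bin_size = 1000L,
                       depth = 50,
                       gc_bias_coeffs = c(0, 1.0, -10),
                       overdispersion = 20,
                       ur_factor = 0.3,
                       ur_fraction = 0.10,
                       repeat_fraction = 0.05,
                       map_zero_fraction = 0.02,
                       gc_mean = 0.45,
                       gc_sd = 0.05,
                       gc_smooth = TRUE,
                       gc_smooth_window = 10L,
                       cnv_rate_per_passage = 4,
                       snp_rate_per_passage = 15,
                       retention_prob = 0.5,
                       cnv_size_law = c(1e4, 1e6),
                       cnv_state_probs = c(`-2` = 0.04, `-1` = 0.42,
                                           `1` = 0.50, `2` = 0.04),
                       spectrum = c(`C>A` = 0.30, `C>G` = 0.10, `C>T` = 0.25,
                                    `T>A` = 0.10, `T>C` = 0.15, `T>G` = 0.10),
                       aaf_beta = c(2, 4),
                       orientation_prob = 0.5,
                       sex = c("male", "female"),
                       timepoints = c(0L, 5L, 10L),
                       split_at = NA) {
  sex <- match.arg(sex)
  cfg <- list(
    seed = as.integer(seed), line = line,
    chrom_lengths = chrom_lengths, bin_size = as.integer(bin_size),
    depth = depth, gc_bias_coeffs = gc_bias_coeffs,
    overdispersion = overdispersion,
    ur_factor = ur_factor, ur_fraction = ur_fraction,
    repeat_fraction = repeat_fraction,
    map_zero_fraction = map_zero_fraction,
    gc_mean = gc_mean, gc_sd = gc_sd,
    gc_smooth = isTRUE(gc_smooth),
    gc_smooth_window = as.integer(gc_smooth_window),
    cnv_rate_per_passage = cnv_rate_per_passage,
    snp_rate_per_passage = snp_rate_per_passage,
    retention_prob = retention_prob,
    cnv_size_law = cnv_size_law,
    cnv_state_probs = cnv_state_probs,
    spectrum = spectrum,
    aaf_beta = aaf_beta,
    orientation_prob = orientation_prob,
    sex = sex,
    timepoints = as.integer(sort(unique(timepoints))),
    split_at = split_at
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (any(cfg$chrom_lengths <= 0)) {
    stopf("invalid config: all chromosome lengths must be positive")
  }
  if (cfg$bin_size <= 0) stopf("invalid config: bin_size must be positive")
  if (abs(sum(cfg$spectrum) - 1) > 1e-8) {
    stopf("invalid config: substitution spectrum must sum to 1")
  }
  if (!setequal(names(cfg$spectrum),
                c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))) {
    stopf("invalid config: spectrum must name the six pyrimidine classes")
  }
  if (cfg$ur_factor <= 0 || cfg$ur_factor > 1) {
    stopf("invalid config: ur_factor must lie in (0, 1]")
  }
  rates <- c(cfg$cnv_rate_per_passage, cfg$snp_rate_per_passage)
  if (any(rates < 0)) stopf("invalid config: lesion rates must be >= 0")
  if (cfg$retention_prob < 0 || cfg$retention_prob > 1) {
    stopf("invalid config: retention_prob must lie in [0, 1]")
  }
  if (length(cfg$timepoints) == 0L) {
    stopf("invalid config: passage schedule must be non-empty")
  }
  if (abs(sum(cfg$cnv_state_probs) - 1) > 1e-8) {
    stopf("invalid config: cnv_state_probs must sum to 1")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic allograft simulation config\n")
  cat(sprintf("  line %s, sex %s, seed %d\n", x$line, x$sex, x$seed))
  cat(sprintf("  genome: %d arms, %.1f Mb, %d bp bins\n",
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6, x$bin_size))
  cat(sprintf("  depth %g, NB size %g, ur_factor %g\n",
              x$depth, x$overdispersion, x$ur_factor))
  cat(sprintf("  per passage: %g CNVs, %g SNPs, retention %g\n",
              x$cnv_rate_per_passage, x$snp_rate_per_passage,
              x$retention_prob))
  cat(sprintf("  timepoints: %s%s\n",
              paste0("T", x$timepoints, collapse = " "),
              if (!is.na(x$split_at)) sprintf(" (split at passage %s)",
                                              x$split_at) else ""))
  invisible(x)
}
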
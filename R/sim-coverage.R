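#' Simulate binned sequencing coverage for one sample
#'
#' Draws per-bin read counts from a negative binomial whose mean follows the
#' assay model: `depth * (copy/2) * exp(gc_bias(GC)) * mappability`, times the
#' under-replication factor in UR bins when the sample is the polytene
#' host-larva control. Sex scales the X (one copy in males) and the Y proxy
#' region (one copy in males, absent in females).
#'
#' @param model A [simulate_genome()] model.
#' @param config A [sim_config()] object.
#' @param cnvs Data frame of true CNVs carried by this sample (columns chrom,
#'   start0, end0, state), e.g. the rows of a [simulate_lineage()] truth for
#'   one sample; `NULL` for a lesion-free sample. Controls must carry none.
#' @param is_control Logical; apply the `ur_factor` depression inside UR
#'   intervals (endoreplicating larval control tissue).
#' @param sample_id Sample label; also keys the per-sample random stream.
#' @return A `binned_coverage` object: list with `sample_id`, `values`
#'   (per-bin mean coverage on the model grid) and `stage = "raw"`.
#' @export
simulate_coverage <- function(model, config, cnvs = NULL, is_control = FALSE,
                              sample_id = if (is_control) "control" else "tumor") {
  validate_sim_config(config)
  stopifnot(inherits(model, "genome_model"))
  if (is_control && !is.null(cnvs) && nrow(cnvs) > 0) {
    stopf("control samples must carry no somatic lesions")
  }
  bins <- model$bins
  copy <- rep(2, nrow(bins))
  if (config$sex == "male") {
    copy[bins$chrom == "X"] <- 1
    copy[bins$chrom == "Y"] <- 1
  } else {
    copy[bins$chrom == "Y"] <- 0
  }
  if (!is.null(cnvs) && nrow(cnvs) > 0) {
    hits <- GenomicRanges::findOverlaps(
      bins_to_granges(model), intervals_to_granges(cnvs))
    add <- pmin(cnvs$state[S4Vectors::subjectHits(hits)], 2L)
    copy[S4Vectors::queryHits(hits)] <-
      pmax(copy[S4Vectors::queryHits(hits)] + add, 0)
  }
  bias <- gc_bias_log(bins$gc, config$gc_bias_coeffs, center = mean(bins$gc))
  mu <- config$depth * (copy / 2) * exp(bias) * bins$mappability
  if (is_control && config$ur_factor < 1 && nrow(model$ur_intervals)) {
    in_ur <- IRanges::overlapsAny(bins_to_granges(model),
                                  intervals_to_granges(model$ur_intervals))
    mu[in_ur] <- mu[in_ur] * config$ur_factor
  }
  values <- with_seed(derive_seed(config$seed, paste0("cov:", sample_id)), {
    stats::rnbinom(length(mu), mu = mu, size = config$overdispersion)
  })
  binned_coverage(sample_id, as.numeric(values), "raw")
}

gc_bias_log <- function(gc, coeffs, center) {
  z <- gc - center
  coeffs[1] + coeffs[2] * z + coeffs[3] * z^2
}

binned_coverage <- function(sample_id, values, stage) {
  structure(list(sample_id = sample_id, values = values, stage = stage),
            class = "binned_coverage")
}

#' @export
print.binned_coverage <- function(x, ...) {
  cat(sprintf("Binned coverage '%s' (%s): %d bins, mean %.2f\n",
              x$sample_id, x$stage, length(x$values), mean(x$values)))
  invisible(x)
}

#' Simulate coverage for every sample of a lineage
#'
#' Convenience wrapper producing one [simulate_coverage()] track per sample in
#' a [simulate_lineage()] truth (tumors carry their true lesions; the control
#' is lesion-free and under-replicated in URs).
#'
#' @param model,config,truth Genome model, configuration and lineage truth.
#' @return Named list of `binned_coverage` objects, one per sample.
#' @export
simulate_cohort_coverage <- function(model, config, truth) {
  stopifnot(inherits(truth, "lineage_truth"))
  out <- lapply(seq_len(nrow(truth$samples)), function(i) {
    s <- truth$samples[i, ]
    if (s$role == "control") {
      simulate_coverage(model, config, is_control = TRUE,
                        sample_id = s$sample_id)
    } else {
      simulate_coverage(model, config,
                        cnvs = truth$cnvs[truth$cnvs$sample_id == s$sample_id, ,
                                          drop = FALSE],
                        sample_id = s$sample_id)
    }
  })
  names(out) <- truth$samples$sample_id
  out
}
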
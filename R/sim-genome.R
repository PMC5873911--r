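#' Simulate a genome model for the coverage pipeline
#'
#' Builds the fixed bin grid and annotation a run of the pipeline needs: arm
#' lengths, a smooth (spatially autocorrelated) per-bin GC track, per-bin
#' mappability with a configurable fraction of unmappable bins, and interval
#' sets for under-replicated regions (URs), repeats, genes and the exome. The
#' short Y arm doubles as a repeat-free kl-2-like proxy region used for sex
#' inference.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `genome_model` with elements `chrom_names`,
#'   `chrom_lengths`, `bin_size`, `bins` (data.frame: chrom, start0, end0, gc,
#'   mappability; 0-based half-open), interval data.frames `ur_intervals`,
#'   `repeat_intervals`, `gene_intervals`, `exome_intervals` (with `id`),
#'   `y_region`, and `n_eff` (bp of mappable genome).
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "genome"), {
    lens <- config$chrom_lengths
    bs <- config$bin_size
    bins <- do.call(rbind, lapply(names(lens), function(ch) {
      n <- ceiling(lens[[ch]] / bs)
      s <- (seq_len(n) - 1L) * bs
      data.frame(chrom = ch, start0 = s,
                 end0 = pmin(s + bs, lens[[ch]]),
                 stringsAsFactors = FALSE)
    }))

    # smooth GC track per arm: moving-average-filtered white noise rescaled
    # to the target mean/sd, clamped away from 0/1
    gc <- unlist(lapply(names(lens), function(ch) {
      n <- sum(bins$chrom == ch)
      z <- rnorm(n)
      if (config$gc_smooth && n > config$gc_smooth_window) {
        w <- config$gc_smooth_window
        z <- as.numeric(stats::filter(z, rep(1 / w, w), sides = 2))
        # fill filter edges with the nearest interior value
        idx <- which(!is.na(z))
        z[seq_len(idx[1] - 1)] <- z[idx[1]]
        z[seq(idx[length(idx)] + 1, length.out = n - idx[length(idx)])] <-
          z[idx[length(idx)]]
        z <- (z - mean(z)) / stats::sd(z)
      }
      z
    }), use.names = FALSE)
    bins$gc <- pmin(pmax(config$gc_mean + config$gc_sd * gc, 0.2), 0.7)

    bins$mappability <- 1
    n_zero <- round(config$map_zero_fraction * nrow(bins))
    if (n_zero > 0) {
      bins$mappability[sample.int(nrow(bins), n_zero)] <- 0
    }

    main_arms <- setdiff(names(lens), "Y")
    ur <- place_intervals(lens[main_arms], config$ur_fraction, bs,
                          len_range = c(5e4, 2e5))
    reps <- place_intervals(lens[main_arms], config$repeat_fraction, bs,
                            len_range = c(2e3, 2e4))
    ur$id <- if (nrow(ur)) sprintf("UR%03d", seq_len(nrow(ur))) else character()
    reps$id <- if (nrow(reps)) sprintf("rep%03d", seq_len(nrow(reps))) else character()

    genes <- tile_genes(lens[main_arms], gene_len = 5e3, spacing = 12e3)
    exome <- genes
    exome$end0 <- exome$start0 + round((genes$end0 - genes$start0) * 0.6)

    model <- list(
      chrom_names = names(lens),
      chrom_lengths = lens,
      bin_size = bs,
      bins = bins,
      ur_intervals = ur,
      repeat_intervals = reps,
      gene_intervals = genes,
      exome_intervals = exome,
      y_region = data.frame(chrom = "Y", start0 = 0,
                            end0 = unname(lens["Y"]),
                            id = "kl2_proxy", stringsAsFactors = FALSE),
      n_eff = sum((bins$end0 - bins$start0)[bins$mappability > 0])
    )
    class(model) <- "genome_model"
    model
  })
}

# Drop non-overlapping intervals onto arms (prob proportional to arm length)
# until `fraction` of the total arm length is covered. Interval boundaries
# snap to bin edges so masking operates on whole bins.
place_intervals <- function(lens, fraction, bin_size, len_range) {
  empty <- data.frame(chrom = character(), start0 = numeric(),
                      end0 = numeric(), stringsAsFactors = FALSE)
  if (fraction <= 0 || length(lens) == 0) return(empty)
  target <- fraction * sum(lens)
  placed <- empty
  covered <- 0
  tries <- 0
  while (covered < target && tries < 10000) {
    tries <- tries + 1
    ch <- sample(names(lens), 1, prob = lens / sum(lens))
    len <- min(round(runif(1, len_range[1], len_range[2])), lens[[ch]])
    len <- max(bin_size, round(len / bin_size) * bin_size)
    s <- floor(runif(1, 0, lens[[ch]] - len) / bin_size) * bin_size
    new <- c(s, s + len)
    same <- placed[placed$chrom == ch, , drop = FALSE]
    if (nrow(same) && any(pmax(same$start0, new[1]) < pmin(same$end0, new[2]))) {
      next
    }
    placed <- rbind(placed, data.frame(chrom = ch, start0 = new[1],
                                       end0 = new[2], stringsAsFactors = FALSE))
    covered <- covered + len
  }
  placed[order(placed$chrom, placed$start0), , drop = FALSE]
}

tile_genes <- function(lens, gene_len, spacing) {
  do.call(rbind, lapply(names(lens), function(ch) {
    starts <- seq(2e3, lens[[ch]] - gene_len - 1, by = spacing)
    data.frame(chrom = ch, start0 = starts, end0 = starts + gene_len,
               id = sprintf("%s_g%04d", ch, seq_along(starts)),
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Genome model:", length(x$chrom_names), "arms,",
      sprintf("%.2f Mb,", sum(x$chrom_lengths) / 1e6),
      nrow(x$bins), "bins of", x$bin_size, "bp\n")
  cat(sprintf("  GC %.3f +/- %.3f; %d unmappable bins\n",
              mean(x$bins$gc), stats::sd(x$bins$gc),
              sum(x$bins$mappability == 0)))
  cat(sprintf("  %d UR, %d repeat, %d gene intervals; mappable genome %.2f Mb\n",
              nrow(x$ur_intervals), nrow(x$repeat_intervals),
              nrow(x$gene_intervals), x$n_eff / 1e6))
  invisible(x)
}
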
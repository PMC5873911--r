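#' Simulate a tumor lineage across serial allograft passages
#'
#' Evolves one tumor line through its recorded passage schedule. Each
#' transition between consecutive recorded timepoints (e.g. T0 to T5) is one
#' evolution event: every existing lesion (CNV or SNP) survives it
#' independently with probability `retention_prob`, and new lesions are born
#' at Poisson rates `cnv_rate_per_passage` / `snp_rate_per_passage` (the
#' initial T0 set is one birth event). An optional split passage strictly
#' inside a transition (e.g. 9, inside T5 to T10) divides that transition in
#' two: a shared sub-step up to the split, then a clone into sublines A and
#' B that evolve the remainder independently — so the sublines share every
#' lesion born before the split and diverge afterwards.
#'
#' @param model A [simulate_genome()] model.
#' @param config A [sim_config()] object.
#' @return An object of class `lineage_truth` with elements `samples`
#'   (sample sheet: sample_id, line, timepoint, subline, role, donor_id,
#'   sex), `cnvs` (per-sample true CNVs: chrom, start0, end0, state, birth),
#'   `snps` (per-sample true SNPs: chrom, pos, ref, alt, aaf, f1r2, f2r1,
#'   birth, region_class) and `n_eff` (effective genome size in bp).
#' @export
simulate_lineage <- function(model, config) {
  validate_sim_config(config)
  stopifnot(inherits(model, "genome_model"))
  tps <- config$timepoints
  if (length(tps) == 0 || any(diff(tps) <= 0)) {
    stopf("passage schedule must be non-empty and increasing")
  }

  with_seed(derive_seed(config$seed, "lineage"), {
    split_at <- config$split_at

    lineages <- list(main = list(cnvs = empty_cnvs(), snps = empty_snps()))
    samples <- list()
    cnv_rows <- list()
    snp_rows <- list()
    counter <- new.env()
    counter$cnv <- 0L
    counter$snp <- 0L

    record <- function(lin_name, p) {
      sid <- sprintf("%s_T%d%s", config$line, p,
                     if (lin_name == "main") "" else lin_name)
      sub <- if (lin_name == "main") NA_character_ else lin_name
      samples[[length(samples) + 1L]] <<- data.frame(
        sample_id = sid, line = config$line, timepoint = p, subline = sub,
        role = "tumor", donor_id = config$line, sex = config$sex,
        stringsAsFactors = FALSE)
      st <- lineages[[lin_name]]
      if (nrow(st$cnvs)) cnv_rows[[length(cnv_rows) + 1L]] <<-
          cbind(sample_id = sid, st$cnvs, stringsAsFactors = FALSE)
      if (nrow(st$snps)) snp_rows[[length(snp_rows) + 1L]] <<-
          cbind(sample_id = sid, st$snps, stringsAsFactors = FALSE)
    }

    evolve <- function(st, birth_label, retain = TRUE) {
      if (retain) {
        st$cnvs <- retain_rows(st$cnvs, config$retention_prob)
        st$snps <- retain_rows(st$snps, config$retention_prob)
      }
      st$cnvs <- rbind(st$cnvs,
                       born_cnvs(model, config, birth_label, st$cnvs, counter))
      st$snps <- rbind(st$snps, born_snps(model, config, birth_label, counter))
      st
    }

    prev_t <- NULL
    for (t in tps) {
      if (is.null(prev_t)) {
        # initial lesion set at the first recorded timepoint
        lineages$main <- evolve(lineages$main, t, retain = FALSE)
      } else if (!is.na(split_at) && split_at > prev_t && split_at < t &&
                 !is.null(lineages$main)) {
        # shared sub-step up to the split, then independent remainders
        shared <- evolve(lineages$main, split_at)
        lineages <- list(A = evolve(shared, t), B = evolve(shared, t))
      } else {
        lineages <- lapply(lineages, evolve, birth_label = t)
      }
      for (ln in names(lineages)) record(ln, t)
      if (!is.na(split_at) && split_at == t && !is.null(lineages$main)) {
        lineages <- list(A = lineages$main, B = lineages$main)
      }
      prev_t <- t
    }

    samples <- do.call(rbind, samples)
    samples <- rbind(samples, data.frame(
      sample_id = sprintf("%s_host", config$line), line = config$line,
      timepoint = NA_integer_, subline = NA_character_, role = "control",
      donor_id = config$line, sex = config$sex, stringsAsFactors = FALSE))

    truth <- list(
      samples = samples,
      cnvs = if (length(cnv_rows)) do.call(rbind, cnv_rows) else
        cbind(sample_id = character(), empty_cnvs()),
      snps = if (length(snp_rows)) do.call(rbind, snp_rows) else
        cbind(sample_id = character(), empty_snps()),
      n_eff = model$n_eff,
      line = config$line,
      sex = config$sex
    )
    class(truth) <- "lineage_truth"
    truth
  })
}

empty_cnvs <- function() {
  data.frame(id = character(), chrom = character(), start0 = numeric(),
             end0 = numeric(), state = integer(), birth = integer(),
             stringsAsFactors = FALSE)
}

empty_snps <- function() {
  data.frame(id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), aaf = numeric(),
             f1r2 = integer(), f2r1 = integer(), birth = integer(),
             region_class = character(), stringsAsFactors = FALSE)
}

retain_rows <- function(df, p) {
  if (!nrow(df) || p >= 1) return(df)
  df[stats::runif(nrow(df)) < p, , drop = FALSE]
}

# New CNVs born at passage p: log-uniform sizes, bin-edge-snapped, placed so
# they do not overlap any CNV currently carried by the lineage. A placement
# that fails 100 resampling attempts is a configuration error.
born_cnvs <- function(model, config, p, current, counter) {
  n <- stats::rpois(1, config$cnv_rate_per_passage)
  if (n == 0) return(empty_cnvs())
  arms <- setdiff(model$chrom_names, "Y")
  lens <- model$chrom_lengths[arms]
  bs <- model$bin_size
  out <- empty_cnvs()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:100) {
      len <- exp(stats::runif(1, log(config$cnv_size_law[1]),
                              log(config$cnv_size_law[2])))
      len <- max(bs, round(len / bs) * bs)
      ok_arms <- arms[lens >= len + bs]
      if (!length(ok_arms)) next
      ch <- sample(ok_arms, 1, prob = lens[ok_arms] / sum(lens[ok_arms]))
      s <- floor(stats::runif(1, 0, lens[[ch]] - len) / bs) * bs
      cand <- c(s, s + len)
      others <- rbind(current, out)
      others <- others[others$chrom == ch, , drop = FALSE]
      if (nrow(others) &&
          any(pmax(others$start0, cand[1]) < pmin(others$end0, cand[2]))) {
        next
      }
      counter$cnv <- counter$cnv + 1L
      st <- as.integer(sample(names(config$cnv_state_probs), 1,
                              prob = config$cnv_state_probs))
      out <- rbind(out, data.frame(
        id = sprintf("cnv%05d", counter$cnv), chrom = ch,
        start0 = cand[1], end0 = cand[2], state = st, birth = p,
        stringsAsFactors = FALSE))
      placed <- TRUE
      break
    }
    if (!placed) {
      stopf("could not place a non-overlapping CNV after 100 attempts at passage %d", p)
    }
  }
  out
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

born_snps <- function(model, config, p, counter) {
  n <- stats::rpois(1, config$snp_rate_per_passage)
  if (n == 0) return(empty_snps())
  arms <- setdiff(model$chrom_names, "Y")
  lens <- model$chrom_lengths[arms]
  ch <- sample(arms, n, replace = TRUE, prob = lens / sum(lens))
  pos <- vapply(ch, function(c) sample.int(lens[[c]], 1), integer(1))
  cls <- sample(names(config$spectrum), n, replace = TRUE,
                prob = config$spectrum)
  ref <- substr(cls, 1, 1)
  alt <- substr(cls, 3, 3)
  flip <- stats::runif(n) < 0.5     # report the purine strand half the time
  ref[flip] <- COMPLEMENT[ref[flip]]
  alt[flip] <- COMPLEMENT[alt[flip]]
  aaf <- stats::rbeta(n, config$aaf_beta[1], config$aaf_beta[2])
  n_alt <- pmax(2L, stats::rpois(n, config$depth * aaf))
  f1r2 <- stats::rbinom(n, n_alt, config$orientation_prob)
  ids <- sprintf("snp%06d", counter$snp + seq_len(n))
  counter$snp <- counter$snp + n
  data.frame(id = ids, chrom = ch, pos = as.integer(pos), ref = ref,
             alt = alt, aaf = aaf, f1r2 = f1r2, f2r1 = n_alt - f1r2,
             birth = p,
             region_class = classify_positions(model, ch, pos),
             stringsAsFactors = FALSE)
}

# Generator-truth annotation class for SNP positions.
classify_positions <- function(model, chrom, pos) {
  n <- length(chrom)
  cls <- rep("intergenic", n)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  in_gene <- IRanges::overlapsAny(gr, intervals_to_granges(model$gene_intervals))
  in_ex <- IRanges::overlapsAny(gr, intervals_to_granges(model$exome_intervals))
  cls[in_gene] <- "intron"
  ex_idx <- which(in_ex)
  if (length(ex_idx)) {
    cls[ex_idx] <- ifelse(stats::runif(length(ex_idx)) < 0.7,
                          "exonic-nonsyn", "exonic-syn")
  }
  cls
}

#' @export
print.lineage_truth <- function(x, ...) {
  tum <- x$samples[x$samples$role == "tumor", ]
  cat(sprintf("Lineage truth for line %s (%s): %d tumor samples + control\n",
              x$line, x$sex, nrow(tum)))
  for (sid in tum$sample_id) {
    cat(sprintf("  %-14s %3d CNVs, %4d SNPs\n", sid,
                sum(x$cnvs$sample_id == sid), sum(x$snps$sample_id == sid)))
  }
  invisible(x)
}
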
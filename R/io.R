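# Plain-text interchange: bedGraph-like coverage TSVs, BED intervals,
# VCF v4.2 variant tables, sample sheets. All BED/coverage coordinates on
# disk are 0-based half-open; VCF positions are 1-based.

#' Write a complete synthetic fixture set
#'
#' Emits everything a pipeline run consumes: per-sample coverage TSVs,
#' per-sample truth CNV BEDs and truth SNP VCFs, a sample sheet, and genome
#' annotation (bin grid with GC/mappability plus UR/repeat/gene/exome BEDs).
#' All files round-trip losslessly through the package readers.
#'
#' @param dir Output directory (created if needed).
#' @param model A [simulate_genome()] model.
#' @param truth A [simulate_lineage()] truth.
#' @param coverages Named list of `binned_coverage` objects
#'   (e.g. [simulate_cohort_coverage()]).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_fixture_set <- function(dir, model, truth, coverages) {
  for (d in file.path(dir, c("coverage", "truth", "genome"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  paths <- list()

  for (sid in names(coverages)) {
    p <- file.path(dir, "coverage", paste0(sid, ".coverage.tsv"))
    write_coverage(coverages[[sid]], model, p)
    paths$coverage <- c(paths$coverage, p)
  }

  for (sid in unique(truth$cnvs$sample_id)) {
    p <- file.path(dir, "truth", paste0(sid, ".cnv.bed"))
    cn <- truth$cnvs[truth$cnvs$sample_id == sid, , drop = FALSE]
    cn <- cn[order(cn$chrom, cn$start0), , drop = FALSE]
    gr <- intervals_to_granges(cn)
    S4Vectors::mcols(gr)$name <- sprintf("state=%+d", cn$state)
    S4Vectors::mcols(gr)$score <- cn$birth
    rtracklayer::export(gr, p, format = "BED")
    paths$truth_cnv <- c(paths$truth_cnv, p)
  }

  for (sid in unique(truth$snps$sample_id)) {
    p <- file.path(dir, "truth", paste0(sid, ".snps.vcf"))
    write_variants_vcf(truth$snps[truth$snps$sample_id == sid, , drop = FALSE], p)
    paths$truth_snp <- c(paths$truth_snp, p)
  }

  p <- file.path(dir, "samples.tsv")
  utils::write.table(truth$samples, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$sample_sheet <- p

  p <- file.path(dir, "genome", "bins.tsv")
  utils::write.table(
    data.frame(chrom = model$bins$chrom, start = model$bins$start0,
               end = model$bins$end0, gc = model$bins$gc,
               mappability = model$bins$mappability),
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$bins <- p

  for (what in c("ur", "repeat", "gene", "exome")) {
    iv <- model[[paste0(what, "_intervals")]]
    p <- file.path(dir, "genome", paste0(what, ".bed"))
    gr <- intervals_to_granges(iv)
    if (length(gr)) S4Vectors::mcols(gr)$name <- iv$id
    rtracklayer::export(gr, p, format = "BED")
    paths[[paste0(what, "_bed")]] <- p
  }

  invisible(paths)
}

#' Write / read a binned coverage track
#'
#' Four-column bedGraph-like TSV (`chrom`, `start`, `end`, `mean_coverage`)
#' with 0-based half-open bins on the model grid.
#'
#' @param cov A `binned_coverage` object.
#' @param model The genome model supplying the bin grid.
#' @param path File path.
#' @return `write_coverage()`: the path, invisibly. `read_coverage()`: a
#'   `binned_coverage` object (the file's bin order must match the model
#'   grid).
#' @export
write_coverage <- function(cov, model, path) {
  df <- data.frame(chrom = model$bins$chrom, start = model$bins$start0,
                   end = model$bins$end0, mean_coverage = cov$values)
  tryCatch(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE),
    error = function(e) stopf("failed writing coverage to '%s': %s",
                              path, conditionMessage(e)))
  invisible(path)
}

#' @rdname write_coverage
#' @param sample_id Sample label for the returned object.
#' @export
read_coverage <- function(path, model, sample_id = basename(path)) {
  if (!file.exists(path)) stopf("coverage file not found: '%s'", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!identical(df$chrom, model$bins$chrom) ||
      !identical(as.numeric(df$start), as.numeric(model$bins$start0))) {
    stopf("bin grid in '%s' does not match the genome model", path)
  }
  binned_coverage(sub("\\.coverage\\.tsv$", "", sample_id),
                  as.numeric(df$mean_coverage), "raw")
}

#' Read a BED interval file
#'
#' @param path BED file path.
#' @return Data frame with `chrom`, `start0`, `end0` (0-based half-open) plus
#'   `name`/`score` columns when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("BED file not found: '%s'", path)
  gr <- rtracklayer::import(path, format = "BED")
  df <- granges_to_intervals(gr)
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$name)) df$name <- mc$name
  if (!is.null(mc$score)) df$score <- mc$score
  df
}

#' Write / read somatic variant tables as VCF v4.2
#'
#' INFO keys carried: `AAF` (alternative allele fraction), `F1R2`/`F2R1`
#' (alt-supporting read counts by read-pair orientation), `CLASS` (annotation
#' class), `BIRTH` (simulator birth passage, when known).
#'
#' @param snps Data frame with columns chrom, pos, ref, alt, aaf, f1r2, f2r1
#'   and optionally region_class, birth.
#' @param path File path.
#' @return `write_variants_vcf()`: the path, invisibly.
#'   `read_variants_vcf()`: a data frame in the same column layout.
#' @export
write_variants_vcf <- function(snps, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AAF,Number=1,Type=Float,Description=\"Alternative allele fraction\">",
    "##INFO=<ID=F1R2,Number=1,Type=Integer,Description=\"Alt reads in F1R2 orientation\">",
    "##INFO=<ID=F2R1,Number=1,Type=Integer,Description=\"Alt reads in F2R1 orientation\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Annotation class\">",
    "##INFO=<ID=BIRTH,Number=1,Type=Integer,Description=\"Birth passage (simulation truth)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ord <- order(snps$chrom, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  info <- sprintf("AAF=%.6g;F1R2=%d;F2R1=%d;CLASS=%s",
                  snps$aaf, snps$f1r2, snps$f2r1,
                  snps$region_class %||% rep("unknown", nrow(snps)))
  if (!is.null(snps$birth)) info <- sprintf("%s;BIRTH=%d", info, snps$birth)
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                  snps$chrom, snps$pos,
                  snps$id %||% rep(".", nrow(snps)),
                  snps$ref, snps$alt, info)
  tryCatch(writeLines(c(hdr, body), path),
           error = function(e) stopf("failed writing VCF to '%s': %s",
                                     path, conditionMessage(e)))
  invisible(path)
}

#' @rdname write_variants_vcf
#' @export
read_variants_vcf <- function(path) {
  if (!file.exists(path)) stopf("VCF file not found: '%s'", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), aaf = numeric(), f1r2 = integer(),
                      f2r1 = integer(), region_class = character(),
                      birth = integer(), stringsAsFactors = FALSE))
  }
  data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    aaf = as.numeric(vcfR::extract.info(v, "AAF")),
    f1r2 = as.integer(vcfR::extract.info(v, "F1R2")),
    f2r1 = as.integer(vcfR::extract.info(v, "F2R1")),
    region_class = as.character(vcfR::extract.info(v, "CLASS")),
    birth = suppressWarnings(as.integer(vcfR::extract.info(v, "BIRTH"))),
    stringsAsFactors = FALSE)
}

#' Read a sample sheet
#'
#' @param path TSV with columns sample_id, line, timepoint, role (and
#'   optionally subline, donor_id, sex).
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stopf("sample sheet not found: '%s'", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "line", "timepoint", "role")
  if (!all(need %in% names(df))) {
    stopf("sample sheet '%s' lacks columns: %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}
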
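# Internal helpers shared across the package.

#' @useDynLib tumorGI, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and a string key,
# so that each simulated sample gets its own independent, stable stream.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

# data.frame(chrom, start0, end0) [0-based half-open] -> GRanges [1-based].
intervals_to_granges <- function(df) {
  if (is.null(df) || nrow(df) == 0L) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start0 + 1L, end = df$end0)
  )
}

granges_to_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# GRanges view of a genome model's bin grid (1-based closed coordinates).
bins_to_granges <- function(model) {
  intervals_to_granges(model$bins[, c("chrom", "start0", "end0")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
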
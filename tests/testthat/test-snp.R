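# Somatic SNP filtering, spectrum, clustering, enrichment, rates,
# turnover and the orientation-bias check.

snp_frame <- function(chrom, pos, ref, alt, aaf = 0.3, f1r2 = 5L, f2r1 = 5L,
                      region_class = "intergenic") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             aaf = aaf, f1r2 = as.integer(f1r2), f2r1 = as.integer(f2r1),
             region_class = region_class, stringsAsFactors = FALSE)
}

test_that("SNP filtering applies mask, AAF and malformedness rules separately", {
  v <- snp_frame("2L", c(100, 5000, 9000, 12000),
                 ref = c("C", "G", "T", "C"),
                 alt = c("A", "T", "G", "C"),     # last: ref == alt
                 aaf = c(0.05, 0.4, 0.2, 0.3))
  mask <- data.frame(chrom = "2L", start0 = 4000, end0 = 6000)

  out <- filter_snps(v, masks = mask)
  rem <- attr(out, "removed")
  expect_identical(unname(rem["malformed"]), 1L)   # the C>C record
  expect_identical(unname(rem["mask"]), 1L)        # pos 5000
  expect_identical(unname(rem["aaf"]), 0L)         # AAF filter not requested
  expect_setequal(out$pos, c(100L, 9000L))

  # the AAF >= 0.1 rule drops the 0.05 record only when asked for
  out2 <- filter_snps(v, masks = mask, min_aaf = 0.1)
  expect_setequal(out2$pos, 9000L)
  expect_identical(unname(attr(out2, "removed")["aaf"]), 1L)

  # no-op configuration returns the well-formed input unchanged
  out3 <- filter_snps(v[1:3, ])
  expect_identical(nrow(out3), 3L)
})

test_that("substitution spectrum collapses strands to pyrimidine classes", {
  one <- substitution_spectrum(snp_frame("2L", 1, "G", "T"))
  expect_identical(unname(one$counts["C>A"]), 1)
  expect_identical(sum(one$counts), 1)

  # all twelve raw substitutions, twice each -> uniform six-class spectrum
  raw <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                     stringsAsFactors = FALSE)
  raw <- raw[raw$ref != raw$alt, ]
  v <- snp_frame("2L", seq_len(24), rep(raw$ref, 2), rep(raw$alt, 2))
  sp <- substitution_spectrum(v)
  expect_true(all(sp$counts == 4))
  expect_true(all(abs(sp$fractions - 1 / 6) < 1e-12))

  # reverse-complementing every record leaves the spectrum invariant
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v_rc <- v
  v_rc$ref <- comp[v$ref]; v_rc$alt <- comp[v$alt]
  expect_identical(substitution_spectrum(v_rc)$counts, sp$counts)

  empty <- substitution_spectrum(v[0, ])
  expect_true(empty$empty)
  expect_true(all(is.na(empty$fractions)))
})

test_that("cluster test flags dense spans and spares singletons", {
  # 10 SNPs packed into 5 kb plus 10 scattered, n_eff = 10 Mb
  pos <- c(seq(1e6, 1e6 + 4500, length.out = 10),
           seq(2e6, 8e6, length.out = 10))
  v <- snp_frame("3R", round(pos), "C", "A")
  res <- cluster_test(v, n_eff = 1e7)
  dense <- res$results$pos <= 1e6 + 5000
  expect_true(all(res$results$k[dense] >= 10))
  expect_true(all(res$results$p_value[dense] < 1e-3))
  expect_true(all(res$results$significant[dense]))
  # a lone SNP >= 50 kb from the rest carries k = 1 and stays unflagged
  lone <- res$results$pos == round(seq(2e6, 8e6, length.out = 10))[1]
  expect_identical(res$results$k[lone], 1L)
  expect_false(res$results$significant[lone])
  # the dense span merges into one reported region containing 10 SNPs
  expect_identical(nrow(res$regions), 1L)
  expect_identical(res$regions$n_snps, 10L)
})

test_that("cluster-test p-values are monotone non-increasing in k", {
  N <- 50; w <- 5e4; n_eff <- 1e8
  p <- stats::pbinom(0:20 - 1, N, w / n_eff, lower.tail = FALSE)
  expect_true(all(diff(p) <= 1e-15))
  expect_error(cluster_test(snp_frame("2L", 1, "C", "A"), n_eff = 0), "n_eff")
})

test_that("region enrichment reproduces closed-form and log-space tails", {
  # direct-summation oracle: P(X >= 2), X ~ Bin(10, 0.1)
  expect_equal(region_enrichment_test(2, 10, 0.1),
               1 - 0.9^10 - 10 * 0.1 * 0.9^9, tolerance = 1e-12)
  expect_identical(region_enrichment_test(0, 50, 0.1), 1)
  # the 3R hotspot: 23 of 134 SNPs in a region expected to hold 2%
  expect_lt(region_enrichment_test(23, 134, 0.02), 1e-12)
  # log-space accumulation agrees with naive summation wherever the
  # latter is representable
  set.seed(51)
  for (i in 1:20) {
    n <- sample(5:50, 1); k <- sample.int(n, 1); p0 <- runif(1, 0.05, 0.5)
    naive <- sum(stats::dbinom(k:n, n, p0))
    expect_equal(region_enrichment_test(k, n, p0), naive,
                 tolerance = 1e-10)
  }
})

test_that("exome rates follow the definition and annotate fractions", {
  m <- tiny_model()
  ex <- m$exome_intervals
  inside <- snp_frame(ex$chrom[1:36], ex$start0[1:36] + 10, "C", "T",
                      region_class = rep(c("exonic-nonsyn", "exonic-syn"),
                                         c(24, 12)))
  r <- exome_rate(inside, ex, callable_exome_bp = 1e7)
  expect_equal(r$rate_per_mb, 3.6)
  expect_identical(r$n_exonic, 36L)
  expect_equal(r$protein_affecting_fraction, 24 / 36)

  none <- exome_rate(inside[0, ], ex, callable_exome_bp = 1e7)
  expect_identical(none$rate_per_mb, 0)
  expect_error(exome_rate(inside, ex, callable_exome_bp = 0), "positive")
})

test_that("SNP turnover counts exact identity matches", {
  a <- snp_frame("2L", c(1, 2, 3), "C", "A")
  expect_equal(snp_turnover(a, a)$fraction_passed, 1)
  b <- snp_frame("2L", c(10, 20), "C", "A")
  expect_equal(snp_turnover(a, b)$fraction_passed, 0)
  expect_identical(snp_turnover(a, b)$n_new, 2L)
  # same position, different allele: not the same SNP
  c_ <- snp_frame("2L", c(1, 2, 3), "C", "G")
  expect_equal(snp_turnover(a, c_)$fraction_passed, 0)
})

test_that("orientation bias check flags one-sided C>A support only", {
  skewed <- snp_frame("2L", 1:20, "C", "A", f1r2 = 2L, f2r1 = 0L)
  res <- orientation_bias_check(skewed)
  expect_identical(res$status, "flagged")
  expect_lt(res$p_value, 0.01)

  balanced <- snp_frame("2L", 1:30, "C", "A", f1r2 = 1L, f2r1 = 1L)
  expect_identical(orientation_bias_check(balanced)$status, "ok")

  # G>T records are strand-flipped before pooling: an all-F1R2 G>T batch
  # pools as F2R1 and needs the opposite artifact direction to flag
  gt <- snp_frame("2L", 1:20, "G", "T", f1r2 = 2L, f2r1 = 0L)
  expect_identical(orientation_bias_check(gt)$status, "ok")
  expect_identical(orientation_bias_check(gt,
                                          artifact_direction = "f2r1")$status,
                   "flagged")

  no_ca <- snp_frame("2L", 1:5, "T", "C")
  expect_identical(orientation_bias_check(no_ca)$status, "no_data")

  missing <- snp_frame("2L", 1:5, "C", "A")
  missing$f1r2 <- NA_integer_
  expect_warning(res2 <- orientation_bias_check(missing), "skipped")
  expect_identical(res2$status, "skipped")
})
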
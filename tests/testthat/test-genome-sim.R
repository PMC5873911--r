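# Synthetic genome, lineage and coverage generator.

test_that("invalid configurations are rejected", {
  expect_error(sim_config(chrom_lengths = c(X = -1, Y = 1e5)), "positive")
  expect_error(sim_config(bin_size = 0), "bin_size")
  expect_error(sim_config(spectrum = c(`C>A` = 1, `C>G` = 0.5, `C>T` = 0,
                                       `T>A` = 0, `T>C` = 0, `T>G` = 0)),
               "sum to 1")
  expect_error(sim_config(ur_factor = 0), "ur_factor")
  expect_error(sim_config(retention_prob = 1.5), "retention_prob")
})

test_that("genome simulation is deterministic and honours degenerate fractions", {
  cfg <- tiny_cfg(seed = 5)
  m1 <- simulate_genome(cfg)
  m2 <- simulate_genome(cfg)
  expect_identical(m1, m2)

  cfg0 <- tiny_cfg(seed = 5, ur_fraction = 0)
  m0 <- simulate_genome(cfg0)
  expect_identical(nrow(m0$ur_intervals), 0L)
})

test_that("bin grid geometry matches arm lengths and intervals stay on-arm", {
  m <- tiny_model()
  for (ch in m$chrom_names) {
    n_expected <- ceiling(m$chrom_lengths[[ch]] / m$bin_size)
    expect_identical(sum(m$bins$chrom == ch), as.integer(n_expected))
  }
  for (iv in list(m$ur_intervals, m$repeat_intervals, m$gene_intervals,
                  m$exome_intervals)) {
    if (!nrow(iv)) next
    expect_true(all(iv$start0 >= 0))
    expect_true(all(iv$end0 <= m$chrom_lengths[iv$chrom]))
  }
  expect_true(all(m$bins$gc >= 0 & m$bins$gc <= 1))
})

test_that("smoothed GC track is spatially autocorrelated", {
  cfg <- sim_config(seed = 3)   # default genome: > 10^4 bins on one run
  m <- simulate_genome(cfg)
  gc <- m$bins$gc[m$bins$chrom == "3R"]
  ac1 <- stats::cor(gc[-1], gc[-length(gc)])
  expect_gt(ac1, 0.5)
})

test_that("lineage respects zero rates, certain retention and birth ordering", {
  cfg <- tiny_cfg(seed = 9, cnv_rate_per_passage = 0, snp_rate_per_passage = 0)
  tr <- simulate_lineage(tiny_model(), cfg)
  expect_identical(nrow(tr$cnvs), 0L)
  expect_identical(nrow(tr$snps), 0L)

  cfg1 <- tiny_cfg(seed = 9, retention_prob = 1, timepoints = c(0, 5),
                   snp_rate_per_passage = 30)
  tr1 <- simulate_lineage(tiny_model(), cfg1)
  t0 <- tr1$snps[tr1$snps$sample_id == "simL1_T0", "id"]
  t5 <- tr1$snps[tr1$snps$sample_id == "simL1_T5", "id"]
  expect_true(all(t0 %in% t5))

  # a lesion present at Tk was born at some passage <= k
  by_sample <- split(tr1$snps$birth, tr1$snps$sample_id)
  expect_true(all(by_sample$simL1_T0 <= 0))
  expect_true(all(by_sample$simL1_T5 <= 5))
})

test_that("retention over one transition matches the binomial expectation", {
  retained <- vapply(1:8, function(s) {
    cfg <- tiny_cfg(seed = s, snp_rate_per_passage = 200,
                    cnv_rate_per_passage = 0, retention_prob = 0.5,
                    timepoints = c(0, 5))
    tr <- simulate_lineage(tiny_model(), cfg)
    t0 <- tr$snps[tr$snps$sample_id == "simL1_T0", "id"]
    t5 <- tr$snps[tr$snps$sample_id == "simL1_T5", "id"]
    length(intersect(t0, t5)) / length(t0)
  }, numeric(1))
  # 99% CI half-width for the mean of 8 binomial fractions (n ~ 200, p = .5)
  expect_lt(abs(mean(retained) - 0.5), 2.58 * sqrt(0.25 / (8 * 200)) + 0.01)
})

test_that("split sublines share the pre-split lesion set when retention is certain", {
  cfg <- tiny_cfg(seed = 21, retention_prob = 1, split_at = 9,
                  snp_rate_per_passage = 25, cnv_rate_per_passage = 2)
  tr <- simulate_lineage(tiny_model(), cfg)
  a <- tr$snps[tr$snps$sample_id == "simL1_T10A" & tr$snps$birth < 9, "id"]
  b <- tr$snps[tr$snps$sample_id == "simL1_T10B" & tr$snps$birth < 9, "id"]
  expect_setequal(a, b)
  post_a <- tr$snps[tr$snps$sample_id == "simL1_T10A" & tr$snps$birth == 10, "id"]
  post_b <- tr$snps[tr$snps$sample_id == "simL1_T10B" & tr$snps$birth == 10, "id"]
  expect_length(intersect(post_a, post_b), 0)
})

test_that("per-sample true CNVs never overlap each other", {
  cfg <- tiny_cfg(seed = 31, cnv_rate_per_passage = 6,
                  cnv_size_law = c(2e4, 2e5))
  tr <- simulate_lineage(tiny_model(), cfg)
  for (sid in unique(tr$cnvs$sample_id)) {
    cc <- tr$cnvs[tr$cnvs$sample_id == sid, ]
    cc <- cc[order(cc$chrom, cc$start0), ]
    same <- cc$chrom[-1] == cc$chrom[-nrow(cc)]
    expect_true(all(cc$start0[-1][same] >= cc$end0[-nrow(cc)][same]))
  }
})

test_that("coverage follows the mean model", {
  # male X dosage: X/autosome mean ratio -> 0.5 without bias or lesions
  cfg <- tiny_cfg(seed = 13, gc_bias_coeffs = c(0, 0, 0), ur_factor = 1,
                  map_zero_fraction = 0, depth = 100, sex = "male")
  m <- simulate_genome(cfg)
  cov <- simulate_coverage(m, cfg, sample_id = "s1")
  x_mean <- mean(cov$values[m$bins$chrom == "X"])
  a_mean <- mean(cov$values[m$bins$chrom %in% c("2L", "2R", "3R")])
  expect_lt(abs(x_mean / a_mean - 0.5), 0.02)

  # a three-copy interval lifts the tumor/control ratio to 1.5
  cnv <- data.frame(chrom = "2L", start0 = 2e5, end0 = 6e5, state = 1L)
  tum <- simulate_coverage(m, cfg, cnvs = cnv, sample_id = "s2")
  ctl <- simulate_coverage(m, cfg, is_control = TRUE, sample_id = "s3")
  inside <- m$bins$chrom == "2L" & m$bins$start0 >= 2e5 & m$bins$end0 <= 6e5
  expect_lt(abs(mean(tum$values[inside]) / mean(ctl$values[inside]) - 1.5),
            0.05)

  # polytene control under-replication scales UR coverage by ur_factor
  cfg_ur <- tiny_cfg(seed = 14, gc_bias_coeffs = c(0, 0, 0), ur_factor = 0.3,
                     map_zero_fraction = 0, depth = 100)
  m_ur <- simulate_genome(cfg_ur)
  ctl_ur <- simulate_coverage(m_ur, cfg_ur, is_control = TRUE,
                              sample_id = "c")
  in_ur <- IRanges::overlapsAny(
    GenomicRanges::GRanges(m_ur$bins$chrom,
                           IRanges::IRanges(m_ur$bins$start0 + 1,
                                            m_ur$bins$end0)),
    GenomicRanges::GRanges(m_ur$ur_intervals$chrom,
                           IRanges::IRanges(m_ur$ur_intervals$start0 + 1,
                                            m_ur$ur_intervals$end0)))
  main <- m_ur$bins$chrom != "Y" & m_ur$bins$chrom != "X"
  ratio <- mean(ctl_ur$values[in_ur & main]) /
    mean(ctl_ur$values[!in_ur & main])
  expect_lt(abs(ratio - 0.3), 0.03)

  # determinism: same config and sample id -> identical draws
  expect_identical(simulate_coverage(m, cfg, sample_id = "s1")$values,
                   cov$values)
})

test_that("empirical bin means converge to the mean model at high depth", {
  cfg <- tiny_cfg(seed = 17, depth = 1e4, gc_bias_coeffs = c(0, 0, 0),
                  map_zero_fraction = 0, ur_factor = 1, sex = "female")
  m <- simulate_genome(cfg)
  cov <- simulate_coverage(m, cfg, sample_id = "deep")
  auto <- m$bins$chrom %in% c("2L", "2R", "3R")
  expect_lt(abs(mean(cov$values[auto]) / 1e4 - 1), 0.01)
})

test_that("control samples refuse somatic lesions", {
  cfg <- tiny_cfg()
  cnv <- data.frame(chrom = "2L", start0 = 0, end0 = 1e5, state = 1L)
  expect_error(simulate_coverage(tiny_model(), cfg, cnvs = cnv,
                                 is_control = TRUE), "control")
})
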
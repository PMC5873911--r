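# Catalog summaries, interval arithmetic, turnover and the rank-sum test.

test_that("overlap lengths reproduce the printed 3R interval arithmetic", {
  dup <- list("3R", 20994001, 27965000)   # largest duplication
  del <- list("3R", 17979001, 22092000)   # largest deletion
  expect_identical(interval_overlap_length(dup, del), 1098000)
  expect_identical(interval_overlap_length(del, del), 4113000)
  expect_identical(interval_overlap_length(dup, list("3R", 1, 100)), 0)
  expect_warning(ov <- interval_overlap_length(dup, list("2L", 1, 1e7)),
                 "different chromosomes")
  expect_identical(ov, 0)
})

test_that("overlap length is symmetric and bounded by the shorter interval", {
  set.seed(12)
  for (i in 1:25) {
    a <- sort(sample.int(1e6, 2)); b <- sort(sample.int(1e6, 2))
    ia <- list("2L", a[1], a[2]); ib <- list("2L", b[1], b[2])
    ov <- interval_overlap_length(ia, ib)
    expect_identical(ov, interval_overlap_length(ib, ia))
    expect_lte(ov, min(a[2] - a[1] + 1, b[2] - b[1] + 1))
    expect_gte(ov, 0)
  }
})

make_calls <- function(df, sample_id = "s") {
  df$sample_id <- sample_id
  df$n_bins <- (df$end - df$start + 1) %/% 1000
  df$mean <- ifelse(df$state > 0, 0.58, -1)
  class(df) <- c("cnv_calls", "data.frame")
  df
}

test_that("catalog summaries count states, megabases and genes", {
  m <- tiny_model()
  genes <- m$gene_intervals
  # one +1 call spanning genes 3..5 of arm 2L, one -1 spanning gene 8
  g <- genes[genes$chrom == "2L", ]
  amp <- data.frame(chrom = "2L", start = g$start0[3] + 1, end = g$end0[5],
                    state = 1L)
  del <- data.frame(chrom = "2L", start = g$start0[8] + 1, end = g$end0[8],
                    state = -1L)
  calls <- make_calls(rbind(amp, del))
  s <- summarize_catalog(calls, m)
  expect_identical(s$per_sample$genes_amplified, 3L)
  expect_identical(s$per_sample$genes_deleted, 1L)
  expect_identical(s$per_sample$n_plus1, 1L)
  expect_identical(s$per_sample$n_minus1, 1L)

  empty <- summarize_catalog(calls[0, ], m)
  expect_identical(nrow(empty$per_sample), 0L)
  expect_identical(empty$n_amplifications, 0L)
})

test_that("the cohort amplification:deletion ratio matches its definition", {
  # 354 amplifications vs 277 deletions
  calls <- make_calls(data.frame(
    chrom = "2L",
    start = seq(1, by = 2000, length.out = 631),
    end = seq(1000, by = 2000, length.out = 631),
    state = rep(c(1L, -1L), c(354, 277))))
  s <- summarize_catalog(calls, tiny_model())
  expect_identical(s$n_amplifications, 354L)
  expect_identical(s$n_deletions, 277L)
  expect_equal(round(s$amp_del_ratio, 1), 1.3)
})

test_that("per-arm CNV rates follow the definition", {
  m <- tiny_model()
  kept <- seq_len(nrow(m$bins))
  # 5 calls on 2L; 2L kept length here is its full arm
  calls <- make_calls(data.frame(
    chrom = "2L", start = seq(1, by = 1e5, length.out = 5),
    end = seq(5e4, by = 1e5, length.out = 5), state = 1L))
  rates <- cnv_rate_per_mb(calls, m, kept)
  arm <- rates$per_sample_arm
  expect_equal(arm$rate[arm$chrom == "2L"], 5 / 1.2)
  expect_equal(arm$rate[arm$chrom == "3R"], 0)

  empty <- cnv_rate_per_mb(calls[0, ], m, kept)
  expect_identical(nrow(empty$per_sample_arm), 0L)
})

test_that("turnover matching uses same-sign calls and the 1 kb threshold", {
  prev <- make_calls(data.frame(chrom = "2L", start = 10001, end = 30000,
                                state = 1L), "T0")
  same <- make_calls(data.frame(chrom = "2L", start = 10001, end = 30000,
                                state = 1L), "T5")
  t_id <- cnv_turnover(prev, same)
  expect_identical(t_id$n_passed[t_id$class == "dup"], 1L)
  expect_identical(t_id$n_new[t_id$class == "dup"], 0L)

  # 999 bp of overlap misses the threshold, 1000 bp meets it
  near <- make_calls(data.frame(chrom = "2L", start = 29002, end = 50000,
                                state = 1L), "T5")
  expect_identical(cnv_turnover(prev, near)$n_passed[1], 0L)
  at <- make_calls(data.frame(chrom = "2L", start = 29001, end = 50000,
                              state = 1L), "T5")
  expect_identical(cnv_turnover(prev, at)$n_passed[1], 1L)

  # a deletion never matches a duplication
  flip <- make_calls(data.frame(chrom = "2L", start = 10001, end = 30000,
                                state = -1L), "T5")
  tf <- cnv_turnover(prev, flip)
  expect_identical(tf$n_passed[tf$class == "dup"], 0L)
  expect_identical(tf$n_passed[tf$class == "del"], 0L)

  # magnitude change within the same sign still passes (+1 -> +2)
  up <- make_calls(data.frame(chrom = "2L", start = 10001, end = 30000,
                              state = 2L), "T5")
  expect_identical(cnv_turnover(prev, up)$n_passed[1], 1L)

  # anti-symmetry: lost = n_prev - n_passed
  tt <- cnv_turnover(prev, near)
  expect_identical(tt$n_lost, tt$n_prev - tt$n_passed)
})

test_that("rank-sum p-values match enumeration and the reference test", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(mann_whitney(c(5, 5, 5), c(5, 5))$p_value, 1)
  expect_equal(mann_whitney(1:3, 4:6)$p_value, 0.1)
  expect_equal(brute_mann_whitney(1:3, 4:6), 0.1)

  set.seed(31)
  for (i in 1:12) {
    n1 <- sample(2:8, 1); n2 <- sample(2:10, 1)
    a <- sample(1:12, n1, replace = TRUE)   # ties included
    b <- sample(1:12, n2, replace = TRUE)
    got <- mann_whitney(a, b)
    expect_identical(got$method, "exact")
    expect_equal(got$p_value, brute_mann_whitney(a, b), tolerance = 1e-12)
    if (!anyDuplicated(c(a, b))) {
      expect_equal(got$p_value,
                   stats::wilcox.test(a, b, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("exact and normal branches agree for moderate samples", {
  set.seed(41)
  for (i in 1:5) {
    a <- rnorm(9); b <- rnorm(9, 0.5)
    approx <- mann_whitney(a, b)                 # min(n) = 9 > 8 -> normal
    expect_identical(approx$method, "normal")
    expect_lt(abs(approx$p_value - brute_mann_whitney(a, b)), 0.02)
  }
})
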
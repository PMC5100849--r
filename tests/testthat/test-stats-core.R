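test_that("SNP calling applies summed min-count and per-sample coverage bounds", {
  sync <- make_sync(
    pos = c(10L, 20L, 30L, 40L, 50L),
    ref = c("A", "A", "A", "A", "A"),
    counts_list = list(cbind(A = c(99L, 199L, 100L, 3L, 96L),
                             T = c(101L, 1L, 100L, 4L, 100L),
                             C = c(0L, 0L, 0L, 0L, 4L),
                             G = c(0L, 0L, 0L, 0L, 0L))))
  calls <- call_snps(sync, min_count = 2, min_coverage = 10,
                     max_coverage = 500)
  # pos 20: second allele count 1 < 2 -> not a SNP
  # pos 40: coverage 7 < 10 -> excluded
  expect_equal(calls$pos, c(10L, 30L, 50L))
  expect_equal(calls$major[1], "T")
  expect_equal(calls$f_major[1], 101 / 200)
  expect_equal(calls$f_ref[1], 99 / 200)
  # pos 50: third allele C reaches min_count -> multiallelic flag
  expect_equal(calls$multiallelic, c(FALSE, FALSE, TRUE))

  # min_count is summed across samples (PoPoolation2 convention)
  sync2 <- make_sync(pos = 10L, ref = "A",
                     counts_list = list(cbind(A = 100L, T = 1L, C = 0L, G = 0L),
                                        cbind(A = 100L, T = 1L, C = 0L, G = 0L)))
  expect_equal(nrow(call_snps(sync2)), 1L)  # 1+1 = 2 passes
  sync3 <- make_sync(pos = 10L, ref = "A",
                     counts_list = list(cbind(A = 100L, T = 1L, C = 0L, G = 0L),
                                        cbind(A = 100L, T = 0L, C = 0L, G = 0L)))
  expect_equal(nrow(call_snps(sync3)), 0L)

  # calling is idempotent on its own output
  again <- call_snps(calls_as_sync(calls), min_count = 2,
                     min_coverage = 10, max_coverage = 500)
  expect_equal(again$pos, calls$pos)
  expect_equal(again$major, calls$major)
  expect_equal(again$f_ref, calls$f_ref)
})

test_that("allele frequencies are count ratios and sum to one over alleles", {
  sync <- make_sync(pos = 10L, ref = "A",
                    counts_list = list(cbind(A = 90L, T = 110L, C = 0L, G = 0L)))
  calls <- call_snps(sync)
  expect_equal(allele_frequency(calls, "A"), 0.45)
  expect_equal(allele_frequency(calls, "reference"), 0.45)
  expect_equal(allele_frequency(calls, "major"), 0.55)
  tot <- sum(vapply(c("A", "C", "G", "T"),
                    function(b) allele_frequency(calls, b), numeric(1)))
  expect_equal(tot, 1)
})

test_that("FST matches the pi-based formula, its bounds and symmetry", {
  expect_equal(fst_site(c(A = 100, T = 100), c(A = 100, T = 100)), 0)
  expect_equal(fst_site(c(A = 200, T = 0), c(A = 0, T = 200)), 1)
  # hand-computed oracle for (100A/100T) vs (150A/50T):
  # pa = (.5,.5), pb = (.75,.25), pt = (.625,.375)
  # pi_T = 1 - (0.390625 + 0.140625) = 0.46875
  # pi_S = (0.5 + 0.375)/2          = 0.4375
  # FST  = 0.03125 / 0.46875        = 1/15
  expect_equal(fst_site(c(A = 100, T = 100), c(A = 150, T = 50)), 1 / 15)
  expect_equal(fst_site(c(A = 150, T = 50), c(A = 100, T = 100)), 1 / 15)
  # monomorphic pooled site is undefined
  expect_true(is.na(fst_site(c(A = 10, T = 0), c(A = 20, T = 0))))
  # random-count property: always in [0,1], FST(a,a) = 0
  set.seed(7)
  for (i in 1:50) {
    a <- c(rmultinom(1, 200, c(0.4, 0.4, 0.1, 0.1)))
    b <- c(rmultinom(1, 150, c(0.25, 0.25, 0.25, 0.25)))
    f <- fst_site(a, b)
    expect_true(is.na(f) || (f >= 0 && f <= 1))
    expect_equal(fst_site(a, a), 0)
    expect_equal(fst_site(a, b), fst_site(b, a))
  }
})

test_that("Fisher scores match exhaustive hypergeometric enumeration", {
  expect_equal(fisher_site(c(10, 10), c(10, 10)), 0)
  # (10,0 / 0,10): the two extreme tables out of C(20,10) arrangements
  expect_equal(fisher_site(c(10, 0), c(0, 10)),
               -log10(2 / choose(20, 10)))
  expect_equal(fisher_site(c(0, 0), c(5, 5)), 0)  # empty margin
  # symmetry in sample order
  expect_equal(fisher_site(c(12, 3), c(4, 9)), fisher_site(c(4, 9), c(12, 3)))
  # property: random tables with margins <= 30 against the enumeration oracle
  set.seed(11)
  for (i in 1:300) {
    tb <- matrix(sample(0:15, 4, replace = TRUE), 2)
    expect_equal(fisher_site(tb[, 1], tb[, 2]), fisher_enum_neglog10(tb),
                 tolerance = 1e-8)
  }
})

test_that("CMH reduces to the single-stratum chi-square and matches mantelhaen", {
  tb <- matrix(c(90, 110, 110, 90), 2)
  expect_equal(cmh_site(list(tb)), cmh_single_det(tb))
  tb2 <- matrix(c(30, 5, 10, 22), 2)
  expect_equal(cmh_site(list(tb2)), cmh_single_det(tb2))
  # K = 2 strata against the stats implementation (continuity off)
  arr <- array(c(10, 5, 3, 12, 8, 7, 6, 9), dim = c(2, 2, 2))
  expect_equal(cmh_site(arr), mantelhaen.test(arr, correct = FALSE)$p.value)
  expect_equal(cmh_site(arr, correct = TRUE),
               mantelhaen.test(arr, correct = TRUE)$p.value)
  # permuting strata leaves the statistic unchanged
  expect_equal(cmh_site(arr), cmh_site(arr[, , 2:1]))
  # identical proportions across strata -> p = 1
  null_tb <- matrix(c(50, 50, 50, 50), 2)
  expect_equal(cmh_site(list(null_tb, null_tb, null_tb)), 1)
  # doubling all counts sharpens a fixed non-null effect
  eff <- matrix(c(60, 40, 40, 60), 2)
  expect_lt(cmh_site(list(2 * eff)), cmh_site(list(eff)))
  # all strata degenerate -> p = 1
  expect_equal(cmh_site(list(matrix(c(0, 0, 5, 5), 2))), 1)
})

test_that("tail quantiles are order statistics without interpolation", {
  expect_equal(tail_quantile(1:1000, 0.001), 1000)
  expect_equal(tail_quantile(1:1000, 0.01), 991)
  expect_equal(tail_quantile(rep(3.5, 50), 0.1), 3.5)
  expect_equal(tail_quantile(c(5, NA, 1, 9), 0.5), 5)
  expect_error(tail_quantile(numeric(0), 0.1))
})

test_that("pairwise tables agree with the per-site primitives", {
  sync <- make_sync(
    pos = c(10L, 20L, 30L),
    ref = c("A", "C", "G"),
    counts_list = list(cbind(A = c(100L, 0L, 5L), T = c(100L, 0L, 0L),
                             C = c(0L, 120L, 0L), G = c(0L, 80L, 195L)),
                       cbind(A = c(150L, 0L, 20L), T = c(50L, 0L, 0L),
                             C = c(0L, 110L, 0L), G = c(0L, 90L, 180L))))
  calls <- call_snps(sync)
  fst <- fst_pairwise(calls)
  fisher <- fisher_pairwise(calls)
  for (i in seq_len(nrow(calls))) {
    a <- attr(calls, "counts")[[1]][i, 1:4]
    b <- attr(calls, "counts")[[2]][i, 1:4]
    expect_equal(fst$stat[fst$pos == calls$pos[i]], fst_site(a, b))
    mm_a <- poolmapeval:::maj_min_counts(calls, 1)[i, ]
    mm_b <- poolmapeval:::maj_min_counts(calls, 2)[i, ]
    expect_equal(fisher$stat[fisher$pos == calls$pos[i]],
                 fisher_site(mm_a, mm_b))
  }
  # CMH over two replicate pairs matches cmh_site row-wise
  sync4 <- make_sync(
    pos = 10L, ref = "A",
    counts_list = list(cbind(A = 90L, T = 110L, C = 0L, G = 0L),
                       cbind(A = 120L, T = 80L, C = 0L, G = 0L),
                       cbind(A = 95L, T = 105L, C = 0L, G = 0L),
                       cbind(A = 130L, T = 70L, C = 0L, G = 0L)))
  calls4 <- call_snps(sync4)
  cmh <- cmh_pairwise(calls4, pairs = list(c(1, 2), c(3, 4)))
  tb1 <- matrix(c(110, 90, 80, 120), 2)  # rows = major(T)/minor(A)
  tb2 <- matrix(c(105, 95, 70, 130), 2)
  expect_equal(cmh$stat, cmh_site(list(tb1, tb2)))
})
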
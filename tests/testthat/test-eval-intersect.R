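# calls fixture: truth SNPs at 100/200/300 with controllable frequencies,
# plus optional false positives at non-multiple positions
eval_fixture <- function(f_ref = c(0.5, 0.5, 0.5), fp_pos = integer(0)) {
  pos <- c(100L, 200L, 300L, fp_pos)
  n <- length(pos)
  a_cnt <- as.integer(round(200 * c(f_ref, rep(0.5, length(fp_pos)))))
  counts <- cbind(A = a_cnt, T = 200L - a_cnt, C = 0L, G = 0L)
  make_sync(pos = pos, ref = rep("A", n), counts_list = list(counts),
            fwd = matrix(100L, n, 1))
}
truth_fixture <- data.frame(pos = c(100L, 200L, 300L),
                            ref = "A", alt = "T", true_freq = 0.5)

test_that("evaluation partitions TP/FP and applies the strict outlier rule", {
  calls <- call_snps(eval_fixture(fp_pos = c(151L, 252L)))
  ev <- evaluate_run(calls, truth_fixture)
  expect_equal(ev$n_true_positive, 3L)
  expect_equal(ev$n_false_positive, 2L)
  expect_equal(ev$n_extreme_outliers, 0L)
  expect_equal(ev$mean_ref_freq, 0.5)

  # |f - 0.5| must exceed 0.4 strictly: f = 0.9 is not an outlier,
  # f = 0.905 is, and so is f = 0.095
  calls2 <- call_snps(eval_fixture(f_ref = c(0.9, 0.905, 0.095)))
  ev2 <- evaluate_run(calls2, truth_fixture)
  expect_equal(ev2$n_extreme_outliers, 2L)

  # region restriction drops truth and calls outside the window
  ev3 <- evaluate_run(calls, truth_fixture, region = c(150, 310))
  expect_equal(ev3$n_truth, 2L)
  expect_equal(ev3$n_true_positive, 2L)
  expect_equal(ev3$n_false_positive, 2L)
})

test_that("intersection keeps shared sites at the least significant value", {
  a <- data.frame(chrom = "c", pos = c(10L, 20L, 30L), stat = c(5.0, 2.0, 0.1))
  b <- data.frame(chrom = "c", pos = c(20L, 30L, 40L), stat = c(1.2, 0.5, 9.0))
  ab <- intersect_results(a, b)
  expect_equal(ab$pos, c(20L, 30L))
  expect_equal(ab$stat, c(1.2, 0.1))
  # commutative and idempotent
  ba <- intersect_results(b, a)
  expect_equal(ab, ba[order(ba$pos), ], ignore_attr = TRUE)
  aa <- intersect_results(a, a)
  expect_equal(aa$stat, a$stat)
  # pointwise-min monotonicity pushes every tail quantile down
  set.seed(3)
  x <- data.frame(chrom = "c", pos = 1:500, stat = rexp(500))
  y <- data.frame(chrom = "c", pos = 1:500, stat = rexp(500))
  xy <- intersect_results(x, y)
  expect_true(all(xy$stat <= pmin(x$stat, y$stat)))
  for (q in c(0.001, 0.01, 0.1)) {
    expect_lte(tail_quantile(xy$stat, q), tail_quantile(x$stat, q))
    expect_lte(tail_quantile(xy$stat, q), tail_quantile(y$stat, q))
  }
})

test_that("strand-bias filter removes exactly floor(fraction * N), worst first", {
  n <- 57L
  pos <- seq(10L, by = 10L, length.out = n)
  counts <- cbind(A = rep(100L, n), T = rep(100L, n), C = 0L, G = 0L)
  fwd <- matrix(100L, n, 1)
  fwd[1] <- 200L   # all-forward site: SB = 0.5, removed first
  fwd[2] <- 160L   # SB = 0.3
  sync <- make_sync(pos = pos, ref = rep("A", n),
                    counts_list = list(counts), fwd = fwd)
  calls <- call_snps(sync)
  kept <- strand_bias_filter(calls, 0.10)
  expect_equal(nrow(kept), n - floor(0.10 * n))  # exactly 5 removed
  expect_false(pos[1] %in% kept$pos)
  expect_false(pos[2] %in% kept$pos)
  # perfectly balanced sites have SB = 0; removal among ties is by
  # genomic order, so the removed set is deterministic
  kept2 <- strand_bias_filter(calls, 0.10)
  expect_identical(kept$pos, kept2$pos)
  # strand information is required
  bare <- calls; attr(bare, "fwd") <- NULL
  expect_error(strand_bias_filter(bare, 0.1), "strand")
})

test_that("site-list filter keeps only listed coordinates", {
  calls <- call_snps(eval_fixture(fp_pos = c(151L, 252L)))
  kept <- site_list_filter(calls, truth_fixture$pos)
  expect_equal(kept$pos, truth_fixture$pos)
  expect_equal(nrow(site_list_filter(calls, integer(0))), 0L)
  # data.frame form with chrom
  kept2 <- site_list_filter(calls, data.frame(chrom = "sim", pos = 151L))
  expect_equal(kept2$pos, 151L)
  # output is always a subset of the input
  expect_true(all(kept$pos %in% calls$pos))
})

test_that("rank-sum ranking reproduces the worked example and its invariants", {
  # a run scoring ranks (2, 3, 1) across three criteria has rank-sum 6
  scores <- data.frame(
    tp = c(100, 120, 90),        # max is better
    outliers = c(5, 8, 2),       # min is better
    fst_q = c(0.01, 0.02, 0.03), # min is better
    row.names = c("runA", "runB", "runC"))
  rt <- rank_sum(scores, directions = c("max", "min", "min"))
  expect_equal(rt["runA", "rank_sum"], 2 + 2 + 1)
  expect_equal(rt["runB", "rank_sum"], 1 + 3 + 2)
  expect_equal(rt["runC", "rank_sum"], 3 + 1 + 3)
  # sorted ascending, best first
  expect_equal(rownames(rt)[1], "runA")
  # permuting criterion order leaves rank-sums unchanged
  rt2 <- rank_sum(scores[, c(3, 1, 2)], directions = c("min", "max", "min"))
  expect_equal(rt2[rownames(rt), "rank_sum"], rt$rank_sum)
  # a single run gets rank 1 everywhere: rank-sum = number of criteria
  rt1 <- rank_sum(scores[1, ], directions = c("max", "min", "min"))
  expect_equal(rt1$rank_sum, 3)
  # ties get average ranks
  rtt <- rank_sum(data.frame(a = c(1, 1), b = c(2, 3)),
                  directions = c("min", "min"))
  expect_equal(sort(rtt$a), c(1.5, 1.5))
  # missing scores are an error naming the run
  bad <- scores; bad[2, 2] <- NA
  expect_error(rank_sum(bad, c("max", "min", "min")), "runB")
})
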
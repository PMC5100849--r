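# a minimal alignment frame for constructed pileup cases
toy_aln <- function(rows, reflen = 60, chrom = "toy") {
  aln <- do.call(rbind, lapply(rows, function(r)
    data.frame(qname = r$name, flag = r$flag %||% 0L, rname = chrom,
               pos = r$pos, mapq = 60L, cigar = r$cigar, mpos = r$pos,
               tlen = 0L, seq = r$seq,
               qual = r$qual %||% strrep("I", nchar(r$seq)),
               stringsAsFactors = FALSE)))
  attr(aln, "sq") <- c(name = chrom, length = reflen)
  aln
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pileup counts each base at its reference position", {
  ref <- poolmapeval:::new_chassis("toy", strrep("A", 60))
  aln <- toy_aln(list(list(name = "r1", pos = 1L, cigar = "4M", seq = "ACGT")))
  sc <- pileup_counts(aln, ref)
  expect_equal(sc$pos, 1:4)
  expect_equal(sc$A, c(1L, 0L, 0L, 0L))
  expect_equal(sc$C, c(0L, 1L, 0L, 0L))
  expect_equal(sc$G, c(0L, 0L, 1L, 0L))
  expect_equal(sc$T, c(0L, 0L, 0L, 1L))
  expect_equal(sc$ref, rep("A", 4))
  expect_equal(sc$fwd, rep(1L, 4))  # unflagged read counts as forward
})

test_that("deletions tally at skipped positions and insertions count nowhere", {
  ref <- poolmapeval:::new_chassis("toy", strrep("A", 60))
  aln <- toy_aln(list(
    list(name = "d1", pos = 3L, cigar = "2M2D2M", seq = "GTAC"),
    list(name = "i1", pos = 20L, cigar = "2M3I2M", seq = "GGTTTCC")))
  sc <- pileup_counts(aln, ref)
  # 2M2D2M starting at 3: M at 3,4; del at 5,6; M at 7,8
  expect_equal(sc$del[sc$pos %in% 5:6], c(1L, 1L))
  expect_equal(sc$G[sc$pos == 3], 1L)
  expect_equal(sc$C[sc$pos == 8], 1L)
  # coverage (A+T+C+G) excludes the deletion tally
  expect_equal((sc$A + sc$T + sc$C + sc$G)[sc$pos %in% 5:6], c(0L, 0L))
  # insertion: 2M3I2M at 20 has reference footprint 20:23; the three
  # inserted bases are counted at no reference position
  expect_equal(sort(sc$pos[sc$pos >= 20]), 20:23)
  ins_region <- sc[sc$pos >= 20, ]
  expect_equal(sum(ins_region$A + ins_region$T + ins_region$C + ins_region$G), 4L)
  expect_equal(ins_region$C[ins_region$pos == 22], 1L)
})

test_that("base-quality threshold below the uniform quality changes nothing", {
  ts <- tiny_templates(len = 1200, indels = FALSE, seed = 101)
  cfg <- sim_config(read_length = 40, inner_distance_mean = 20,
                    n_pairs = 100, seed = 102)
  aln <- filter_alignments(oracle_align(simulate_pairs(ts, cfg), ts))
  a <- pileup_counts(aln, ts$reference, min_base_quality = 0)
  b <- pileup_counts(aln, ts$reference, min_base_quality = 30)
  expect_identical(a, b)
  # total counted bases never exceed total aligned bases
  total_bases <- sum(nchar(aln$seq))
  expect_lte(sum(a$A + a$T + a$C + a$G + a$N), total_bases)
})

test_that("sync format round-trips and parses the documented example", {
  tmp <- withr::local_tempfile(fileext = ".sync")
  writeLines("2R\t100\tA\t90:110:0:0:0:0", tmp)
  s <- read_sync(tmp)
  expect_equal(s$chrom, "2R")
  expect_equal(s$pos, 100L)
  expect_equal(unname(s$counts[[1]][1, "A"]), 90L)
  expect_equal(unname(s$counts[[1]][1, "T"]), 110L)

  # two-sample round trip preserving order and strand side-file
  sync <- make_sync(pos = c(10L, 20L), ref = c("A", "C"),
                    counts_list = list(cbind(A = c(5L, 0L), T = c(1L, 2L),
                                             C = c(0L, 9L), G = c(0L, 0L)),
                                       cbind(A = c(7L, 1L), T = c(0L, 0L),
                                             C = c(0L, 8L), G = c(2L, 0L))),
                    fwd = cbind(c(3L, 5L), c(4L, 4L)))
  out <- withr::local_tempfile(fileext = ".sync")
  write_sync(sync, out)
  back <- read_sync(out)
  expect_equal(back$pos, sync$pos)
  expect_equal(back$ref, sync$ref)
  expect_equal(unname(back$counts[[1]]), unname(sync$counts[[1]]))
  expect_equal(unname(back$counts[[2]]), unname(sync$counts[[2]]))
  expect_equal(unname(back$fwd), unname(sync$fwd))
  # malformed count block errors with the line number
  writeLines(c("2R\t1\tA\t1:2:3:4:5:6", "2R\t2\tA\t1:2:3"), out)
  expect_error(read_sync(out), "line 2")
})

test_that("as_sync zero-fills sites missing from a sample", {
  ref <- poolmapeval:::new_chassis("toy", strrep("A", 60))
  a <- pileup_counts(toy_aln(list(list(name = "r", pos = 1L, cigar = "4M",
                                       seq = "ACGT"))), ref)
  b <- pileup_counts(toy_aln(list(list(name = "r", pos = 3L, cigar = "4M",
                                       seq = "GGGG"))), ref)
  sync <- as_sync(list(a, b))
  expect_equal(sync$pos, 1:6)
  expect_equal(unname(sync$counts[[1]][5:6, "G"]), c(0L, 0L))
  expect_equal(unname(sync$counts[[2]][1:2, "A"]), c(0L, 0L))
  expect_equal(unname(sync$counts[[2]][3, "G"]), 1L)
})

test_that("coverage histogram conserves the site count", {
  ts <- tiny_templates(len = 1050, indels = FALSE, seed = 111)
  cfg <- sim_config(read_length = 25, inner_distance_mean = 0,
                    n_pairs = 202, seed = 112)
  counts <- pileup_counts(filter_alignments(oracle_align(
    simulate_pairs(ts, cfg), ts)), ts$reference)
  h <- coverage_histogram(counts)
  expect_equal(sum(h$histogram$n_sites), nrow(counts))
  # interior sites form a single spike at the uniform-layout coverage
  interior <- counts[counts$pos >= 50 & counts$pos <= 1001, ]
  hi <- coverage_histogram(interior)
  expect_equal(nrow(hi$histogram), 1L)
  expect_equal(hi$histogram$coverage, 10L)
  # empty input
  h0 <- coverage_histogram(counts[0, ])
  expect_equal(nrow(h0$histogram), 0L)
})
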
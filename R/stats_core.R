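#' SNP calling and per-site differentiation statistics
#'
#' SNP calling follows PoPoolation2 semantics: allele counts are summed
#' across samples for the minimum-count test (a site is a SNP iff at least
#' two alleles reach `min_count` in the summed counts), while every sample
#' must individually satisfy the coverage bounds. Per-site differentiation
#' between two samples is measured by the classical pi-based FST,
#' `(pi_total - mean(pi_within)) / pi_total` with `pi = 1 - sum(p_i^2)`,
#' by the two-sided Fisher exact test on the major/minor 2x2 table
#' (reported as -log10 p), and across replicate pairs by the
#' Cochran-Mantel-Haenszel chi-square on the stratified 2x2 tables.
#'
#' @name stats_core
NULL

#' Call SNPs from a sync set
#'
#' @param sync A `sync` object.
#' @param min_count Minimum allele count, applied to counts summed across
#'   samples (default 2).
#' @param min_coverage,max_coverage Per-sample coverage bounds (A+T+C+G);
#'   every sample must satisfy them at a called site.
#' @return A `snp_calls` data.frame: `chrom`, `pos`, `ref`, `major`,
#'   `minor`, `multiallelic` (3rd allele also reaches `min_count`), pooled
#'   `cov`, `f_major` and `f_ref` (pooled major / reference allele
#'   frequencies). Per-sample count matrices and forward-strand counts ride
#'   along as attributes `counts` and `fwd`; sites with ref not in A/C/G/T
#'   are excluded.
#' @export
call_snps <- function(sync, min_count = 2L, min_coverage = 10L,
                      max_coverage = 500L) {
  stopifnot(inherits(sync, "sync"), min_count >= 1,
            min_coverage <= max_coverage)
  S <- length(sync$counts)
  acgt <- lapply(sync$counts, function(m) m[, 1:4, drop = FALSE])
  pooled <- Reduce(`+`, acgt)
  covs <- vapply(acgt, rowSums, numeric(length(sync$pos)))
  if (is.null(dim(covs))) covs <- matrix(covs, nrow = 1L)
  cov_ok <- rowSums(covs >= min_coverage & covs <= max_coverage) == S
  n_alleles <- rowSums(pooled >= min_count)
  ref_ok <- sync$ref %in% c("A", "T", "C", "G")
  keep <- which(cov_ok & n_alleles >= 2L & ref_ok)

  p <- pooled[keep, , drop = FALSE]
  covp <- rowSums(p)
  major_i <- max.col(p, ties.method = "first")
  tmp <- p; tmp[cbind(seq_along(keep), major_i)] <- -1L
  minor_i <- max.col(tmp, ties.method = "first")
  nuc <- c("A", "T", "C", "G")
  ref_i <- match(sync$ref[keep], nuc)
  calls <- data.frame(
    chrom = rep(sync$chrom, length(keep)),
    pos = sync$pos[keep], ref = sync$ref[keep],
    major = nuc[major_i], minor = nuc[minor_i],
    multiallelic = n_alleles[keep] >= 3L,
    cov = covp,
    f_major = p[cbind(seq_along(keep), major_i)] / covp,
    f_ref = p[cbind(seq_along(keep), ref_i)] / covp,
    stringsAsFactors = FALSE)
  attr(calls, "counts") <- lapply(sync$counts,
                                  function(m) m[keep, , drop = FALSE])
  attr(calls, "fwd") <- sync$fwd[keep, , drop = FALSE]
  attr(calls, "params") <- list(min_count = min_count,
                                min_coverage = min_coverage,
                                max_coverage = max_coverage)
  class(calls) <- c("snp_calls", "data.frame")
  calls
}

#' Rebuild a sync set from called SNPs
#'
#' Inverse of [call_snps()] on the called subset; re-calling on the result
#' with the same thresholds reproduces the same call set (idempotence).
#'
#' @param calls A `snp_calls` data.frame.
#' @return A `sync` object restricted to the called sites.
#' @export
calls_as_sync <- function(calls) {
  structure(list(chrom = calls$chrom[1L], pos = calls$pos, ref = calls$ref,
                 counts = attr(calls, "counts"), fwd = attr(calls, "fwd")),
            class = "sync")
}

#' Allele frequency of a designated allele
#'
#' @param calls A `snp_calls` data.frame.
#' @param allele One of "reference", "major", "minor", or a fixed base.
#' @param sample Sample index, or `NULL` for pooled counts.
#' @return Numeric vector of frequencies (one per called site). Zero
#'   coverage in the requested sample yields `NaN` with a warning.
#' @export
allele_frequency <- function(calls, allele = c("reference", "major", "minor"),
                             sample = NULL) {
  if (!allele[1L] %in% c("A", "C", "G", "T")) allele <- match.arg(allele)
  cm <- attr(calls, "counts")
  mats <- if (is.null(sample)) list(Reduce(`+`, cm)) else cm[sample]
  m <- Reduce(`+`, mats)[, 1:4, drop = FALSE]
  cov <- rowSums(m)
  if (any(cov == 0)) warning("zero coverage at ", sum(cov == 0), " site(s)")
  target <- switch(allele,
                   reference = calls$ref, major = calls$major,
                   minor = calls$minor, allele)
  m[cbind(seq_len(nrow(m)), match(target, c("A", "T", "C", "G")))] / cov
}

#' Per-site FST between two samples
#'
#' Classical pi-based estimator: with allele frequency vectors `p_a`, `p_b`
#' and their unweighted mean `p_t`, `pi = 1 - sum(p^2)` and
#' `FST = (pi_total - mean(pi_within)) / pi_total`, clamped to \[0, 1\].
#' A site monomorphic in the pooled sample (`pi_total = 0`) is undefined
#' and returns `NA`.
#'
#' @param a,b Numeric vectors of allele counts (same allele order).
#' @return FST in \[0, 1\], or `NA` where undefined.
#' @examples
#' fst_site(c(A = 200, T = 0), c(A = 0, T = 200))   # 1
#' fst_site(c(A = 100, T = 100), c(A = 100, T = 100)) # 0
#' @export
fst_site <- function(a, b) {
  stopifnot(length(a) == length(b), sum(a) > 0, sum(b) > 0)
  pa <- a / sum(a); pb <- b / sum(b)
  pt <- (pa + pb) / 2
  pi_t <- 1 - sum(pt^2)
  if (pi_t == 0) return(NA_real_)
  pi_w <- ((1 - sum(pa^2)) + (1 - sum(pb^2))) / 2
  min(1, max(0, (pi_t - pi_w) / pi_t))
}

#' Per-site Fisher exact score between two samples
#'
#' Two-sided Fisher exact test on the major/minor 2x2 count table (the
#' standard rule: the p-value sums the probabilities of all tables at most
#' as probable as the observed one). Returned as `-log10(p)`. A degenerate
#' table with an empty margin scores 0 (p = 1).
#'
#' @param a,b Length-2 allele counts (major, minor) for each sample.
#' @return `-log10(p)`, >= 0.
#' @export
fisher_site <- function(a, b) {
  stopifnot(length(a) == 2L, length(b) == 2L)
  m <- cbind(a, b)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(0)
  # fisher.test can return p marginally above 1 in floating point
  -log10(min(1, fisher.test(m)$p.value))
}

#' Cochran-Mantel-Haenszel test across replicate 2x2 tables
#'
#' Standard CMH chi-square on a 2x2xK table:
#' `(|sum(a_k - E_k)| - cc)^2 / sum(V_k)` with hypergeometric mean `E_k` and
#' variance `V_k` per stratum, referred to chi-square with 1 df. The
#' continuity correction `cc = 0.5` is off by default. Degenerate strata
#' (an empty margin) contribute nothing; if all strata are degenerate the
#' p-value is 1.
#'
#' @param tables A list of 2x2 matrices (columns = samples, rows = alleles)
#'   or a 2x2xK array, one stratum per replicate pair.
#' @param correct Apply the continuity correction?
#' @return The p-value.
#' @examples
#' cmh_site(list(matrix(c(90, 110, 110, 90), 2)))  # single stratum
#' @export
cmh_site <- function(tables, correct = FALSE) {
  if (is.array(tables) && length(dim(tables)) == 3L)
    tables <- lapply(seq_len(dim(tables)[3L]), function(k) tables[, , k])
  stopifnot(length(tables) >= 1L)
  num <- 0; var <- 0
  for (tb in tables) {
    stopifnot(all(dim(tb) == 2L))
    n <- sum(tb)
    r1 <- sum(tb[1L, ]); r2 <- sum(tb[2L, ])
    c1 <- sum(tb[, 1L]); c2 <- sum(tb[, 2L])
    if (n < 2 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) next
    num <- num + (tb[1L, 1L] - r1 * c1 / n)
    var <- var + r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  }
  if (var == 0) return(1)
  cc <- if (correct) 0.5 else 0
  stat <- (max(0, abs(num) - cc))^2 / var
  pchisq(stat, df = 1L, lower.tail = FALSE)
}

#' Lowest value inside a top tail
#'
#' Order statistic without interpolation: sort descending and return the
#' value at rank `ceiling(q * N)` — the least extreme value still inside
#' the top-`q` tail (e.g. the paper-style "0.1% outlier quantile").
#'
#' @param values Numeric vector (NAs dropped).
#' @param q Tail fraction in (0, 1).
#' @return The threshold value.
#' @examples
#' tail_quantile(1:1000, 0.01)   # 991
#' @export
tail_quantile <- function(values, q) {
  values <- values[!is.na(values)]
  stopifnot(q > 0, q < 1, length(values) > 0)
  sort(values, decreasing = TRUE)[ceiling(q * length(values))]
}

# per-sample major/minor count columns for called sites
maj_min_counts <- function(calls, sample) {
  m <- attr(calls, "counts")[[sample]][, 1:4, drop = FALSE]
  i <- seq_len(nrow(m))
  nuc <- c("A", "T", "C", "G")
  cbind(maj = m[cbind(i, match(calls$major, nuc))],
        min = m[cbind(i, match(calls$minor, nuc))])
}

#' Per-site FST table for a sample pair
#'
#' Vectorized [fst_site()] over all called, biallelic sites. Multiallelic
#' sites and sites monomorphic in the pooled pair are excluded.
#'
#' @param calls A `snp_calls` data.frame.
#' @param s1,s2 Sample indices to compare.
#' @return data.frame `chrom`, `pos`, `fst` (a `site_stat` table).
#' @export
fst_pairwise <- function(calls, s1 = 1L, s2 = 2L) {
  keep <- !calls$multiallelic
  a <- attr(calls, "counts")[[s1]][keep, 1:4, drop = FALSE]
  b <- attr(calls, "counts")[[s2]][keep, 1:4, drop = FALSE]
  pa <- a / rowSums(a); pb <- b / rowSums(b)
  pt <- (pa + pb) / 2
  pi_t <- 1 - rowSums(pt^2)
  pi_w <- (2 - rowSums(pa^2) - rowSums(pb^2)) / 2
  fst <- ifelse(pi_t == 0, NA_real_, pmin(1, pmax(0, (pi_t - pi_w) / pi_t)))
  out <- data.frame(chrom = calls$chrom[keep], pos = calls$pos[keep],
                    stat = fst, stringsAsFactors = FALSE)
  out <- out[!is.na(out$stat), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "statistic") <- "fst"
  out
}

#' Per-site Fisher exact score table for a sample pair
#'
#' @inheritParams fst_pairwise
#' @return data.frame `chrom`, `pos`, `stat` with `stat = -log10(p)`.
#' @export
fisher_pairwise <- function(calls, s1 = 1L, s2 = 2L) {
  keep <- which(!calls$multiallelic)
  a <- maj_min_counts(calls, s1)[keep, , drop = FALSE]
  b <- maj_min_counts(calls, s2)[keep, , drop = FALSE]
  stat <- vapply(seq_along(keep), function(i)
    fisher_site(a[i, ], b[i, ]), numeric(1))
  out <- data.frame(chrom = calls$chrom[keep], pos = calls$pos[keep],
                    stat = stat, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "statistic") <- "neg_log10_p"
  out
}

#' Per-site CMH p-values across replicate sample pairs
#'
#' One 2x2 stratum per replicate pair (major/minor counts of the two
#' samples), combined with the Mantel-Haenszel chi-square; vectorized over
#' sites.
#'
#' @param calls A `snp_calls` data.frame.
#' @param pairs List of length-2 sample-index vectors, one per replicate.
#' @param correct Continuity correction (default off).
#' @return data.frame `chrom`, `pos`, `stat` with `stat` = CMH p-value.
#' @export
cmh_pairwise <- function(calls, pairs, correct = FALSE) {
  stopifnot(length(pairs) >= 1L)
  keep <- which(!calls$multiallelic)
  num <- numeric(length(keep)); var <- numeric(length(keep))
  for (pr in pairs) {
    a <- maj_min_counts(calls, pr[1L])[keep, , drop = FALSE]
    b <- maj_min_counts(calls, pr[2L])[keep, , drop = FALSE]
    n <- a[, 1L] + a[, 2L] + b[, 1L] + b[, 2L]
    r1 <- a[, 1L] + b[, 1L]; r2 <- a[, 2L] + b[, 2L]
    c1 <- a[, 1L] + a[, 2L]; c2 <- b[, 1L] + b[, 2L]
    ok <- n >= 2 & r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
    num[ok] <- num[ok] + (a[ok, 1L] - r1[ok] * c1[ok] / n[ok])
    var[ok] <- var[ok] + r1[ok] * r2[ok] * c1[ok] * c2[ok] /
      (n[ok]^2 * (n[ok] - 1))
  }
  cc <- if (correct) 0.5 else 0
  p <- ifelse(var == 0, 1,
              pchisq(pmax(0, abs(num) - cc)^2 / var, df = 1L,
                     lower.tail = FALSE))
  out <- data.frame(chrom = calls$chrom[keep], pos = calls$pos[keep],
                    stat = p, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "statistic") <- "cmh_p"
  out
}
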
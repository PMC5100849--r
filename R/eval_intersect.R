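#' Truth-based evaluation, comparison filters, and mapper intersection
#'
#' A pipeline run is scored against the simulation truth: called SNPs at
#' truth positions are true positives, calls elsewhere are false positives
#' (with error-free reads, false positives are pure alignment artifacts),
#' and a true positive whose estimated allele frequency deviates from the
#' known frequency by more than `outlier_delta` (0.4: f > 0.9 or f < 0.1
#' against a truth of 0.5) is an extreme outlier. The mapper-intersection
#' strategy keeps, for every SNP shared between two runs, only the least
#' significant statistic (minimum FST, minimum -log10 p), which removes
#' artifact peaks specific to a single mapper.
#'
#' @name eval_intersect
NULL

# subset a snp_calls frame, keeping its count/strand attributes in step
subset_calls <- function(calls, keep) {
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- lapply(attr(calls, "counts"),
                                function(m) m[keep, , drop = FALSE])
  attr(out, "fwd") <- attr(calls, "fwd")[keep, , drop = FALSE]
  attr(out, "params") <- attr(calls, "params")
  class(out) <- class(calls)
  out
}

#' Score called SNPs against the simulation truth
#'
#' @param calls A `snp_calls` data.frame.
#' @param truth SNP truth table (`pos`, `ref`, `alt`, `true_freq`), e.g.
#'   `templates$snps`.
#' @param outlier_delta A true positive is an extreme outlier iff
#'   `|f - true_freq| > outlier_delta` (strict inequality; default 0.4).
#' @param region Optional `c(lo, hi)` restricting both calls and truth to a
#'   position window (e.g. the interior of the template, away from the
#'   coverage ramp at the edges).
#' @return An `eval_summary` list: `n_truth`, `n_true_positive`,
#'   `n_false_positive`, `n_extreme_outliers`, `mean_ref_freq` (reference
#'   allele, true positives only) and the position sets.
#' @export
evaluate_run <- function(calls, truth, outlier_delta = 0.4, region = NULL) {
  stopifnot(nrow(truth) > 0, outlier_delta > 0)
  if (!is.null(region)) {
    truth <- truth[truth$pos >= region[1L] & truth$pos <= region[2L], ,
                   drop = FALSE]
    calls <- subset_calls(calls, calls$pos >= region[1L] &
                                 calls$pos <= region[2L])
  }
  is_tp <- calls$pos %in% truth$pos
  f_ref <- calls$f_ref[is_tp]
  tf <- truth$true_freq[match(calls$pos[is_tp], truth$pos)]
  outl <- abs(f_ref - tf) > outlier_delta
  structure(list(n_truth = nrow(truth),
                 n_true_positive = sum(is_tp),
                 n_false_positive = sum(!is_tp),
                 n_extreme_outliers = sum(outl),
                 mean_ref_freq = if (any(is_tp)) mean(f_ref) else NaN,
                 tp_pos = calls$pos[is_tp],
                 fp_pos = calls$pos[!is_tp]),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf(
    "<eval_summary> truth %d | TP %d | FP %d | extreme outliers %d | mean ref freq %.4f\n",
    x$n_truth, x$n_true_positive, x$n_false_positive,
    x$n_extreme_outliers, x$mean_ref_freq))
  invisible(x)
}

#' Intersect two per-site statistic tables
#'
#' Output contains exactly the sites present in both inputs; at each shared
#' site the statistic is the minimum of the two — the least significant
#' result found by either run (minimum FST, minimum -log10 p).
#'
#' @param a,b `site_stat` data.frames (`chrom`, `pos`, `stat`) from
#'   [fst_pairwise()], [fisher_pairwise()] or [cmh_pairwise()].
#' @return A `site_stat` data.frame of the shared sites.
#' @export
intersect_results <- function(a, b) {
  m <- merge(a, b, by = c("chrom", "pos"), suffixes = c(".a", ".b"))
  out <- data.frame(chrom = m$chrom, pos = m$pos,
                    stat = pmin(m$stat.a, m$stat.b),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "statistic") <- attr(a, "statistic")
  out
}

#' Remove the most strand-biased SNPs
#'
#' Strand bias per SNP is `SB = |f_fwd - 0.5|`, where `f_fwd` is the
#' fraction of site-covering reads (A/C/G/T bases, pooled over samples)
#' mapping to the forward strand, irrespective of allele. Exactly
#' `floor(remove_fraction * N)` SNPs with the largest SB are removed; ties
#' are broken by genomic order, so the removal count is deterministic.
#'
#' @param calls A `snp_calls` data.frame with strand information.
#' @param remove_fraction Fraction of SNPs to remove (default 0.10).
#' @return The filtered `snp_calls`.
#' @export
strand_bias_filter <- function(calls, remove_fraction = 0.10) {
  stopifnot(remove_fraction >= 0, remove_fraction < 1)
  fwd <- attr(calls, "fwd")
  if (is.null(fwd)) stop("calls carry no strand information")
  total <- Reduce(`+`, lapply(attr(calls, "counts"),
                              function(m) rowSums(m[, 1:4, drop = FALSE])))
  sb <- abs(rowSums(fwd) / total - 0.5)
  k <- floor(remove_fraction * nrow(calls))
  if (k == 0L) return(calls)
  drop_idx <- order(-sb, calls$pos)[seq_len(k)]
  subset_calls(calls, setdiff(seq_len(nrow(calls)), drop_idx))
}

#' Keep only SNPs on an external site list
#'
#' The site list is typically the positions called by an external variant
#' caller (e.g. a FreeBayes VCF reduced to chrom/pos).
#'
#' @param calls A `snp_calls` data.frame.
#' @param allowed_pos Integer vector of allowed positions (single
#'   chromosome), or a data.frame with columns `chrom` and `pos`.
#' @return The filtered `snp_calls` (subset of the input).
#' @export
site_list_filter <- function(calls, allowed_pos) {
  if (is.data.frame(allowed_pos)) {
    keep <- paste(calls$chrom, calls$pos) %in%
      paste(allowed_pos$chrom, allowed_pos$pos)
  } else {
    keep <- calls$pos %in% allowed_pos
  }
  subset_calls(calls, keep)
}

#' Rank runs across criteria and sum the ranks
#'
#' Each criterion is ranked with 1 = best in its stated direction; ties get
#' average ranks (so rank-sums may be non-integer on small sets). Runs are
#' returned sorted by ascending rank-sum (best first).
#'
#' @param scores data.frame or matrix, one row per run (rownames = run
#'   names), one column per criterion.
#' @param directions Character vector, per criterion: `"max"` if larger is
#'   better, `"min"` if smaller is better.
#' @return data.frame of per-criterion ranks plus `rank_sum`.
#' @examples
#' rank_sum(data.frame(tp = c(10, 30), fp = c(5, 2),
#'                     row.names = c("m1", "m2")),
#'          directions = c("max", "min"))
#' @export
rank_sum <- function(scores, directions) {
  scores <- as.data.frame(scores)
  stopifnot(ncol(scores) >= 2L, length(directions) == ncol(scores),
            all(directions %in% c("min", "max")))
  if (anyNA(scores))
    stop("missing score: run '",
         rownames(scores)[which(rowSums(is.na(scores)) > 0)[1L]], "'")
  ranks <- as.data.frame(lapply(seq_len(ncol(scores)), function(j) {
    x <- scores[[j]]
    rank(if (directions[j] == "max") -x else x, ties.method = "average")
  }))
  names(ranks) <- names(scores)
  rownames(ranks) <- rownames(scores)
  ranks$rank_sum <- rowSums(ranks)
  ranks[order(ranks$rank_sum), , drop = FALSE]
}
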
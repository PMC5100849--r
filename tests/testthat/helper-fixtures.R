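# Shared fixtures and independent oracles, built in code at test time.

# small template set for unit tests
tiny_templates <- function(len = 3000, indels = TRUE, seed = 101) {
  build_templates(random_chassis(len, seed = seed), indels = indels,
                  seed = seed)
}

# build a sync object directly from per-sample count matrices
# (rows = sites, columns A/T/C/G/N/del), for constructed-count tests
make_sync <- function(pos, ref, counts_list, fwd = NULL, chrom = "sim") {
  counts_list <- lapply(counts_list, function(m) {
    m <- as.matrix(m)
    if (ncol(m) == 4L) m <- cbind(m, N = 0L, del = 0L)
    colnames(m) <- c("A", "T", "C", "G", "N", "del")
    storage.mode(m) <- "integer"
    m
  })
  names(counts_list) <- paste0("s", seq_along(counts_list))
  if (is.null(fwd))
    fwd <- matrix(0L, length(pos), length(counts_list))
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref,
                 counts = counts_list, fwd = as.matrix(fwd)),
            class = "sync")
}

# Independent two-sided Fisher oracle: exhaustive enumeration over the
# hypergeometric support, summing the probabilities of all tables at most
# as probable as the observed one.
fisher_enum_neglog10 <- function(tb) {
  r1 <- sum(tb[1L, ]); r2 <- sum(tb[2L, ]); c1 <- sum(tb[, 1L])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tb[, 2L]) == 0) return(0)
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  pobs <- dhyper(tb[1L, 1L], r1, r2, c1)
  p <- sum(probs[probs <= pobs * (1 + 1e-7)])
  -log10(min(1, p))
}

# Single-stratum Mantel-Haenszel chi-square in its determinant form,
# algebraically distinct from the packaged E/V accumulation.
cmh_single_det <- function(tb) {
  n <- sum(tb)
  num <- (tb[1, 1] * tb[2, 2] - tb[1, 2] * tb[2, 1])^2 * (n - 1)
  den <- sum(tb[1, ]) * sum(tb[2, ]) * sum(tb[, 1]) * sum(tb[, 2])
  pchisq(num / den, df = 1, lower.tail = FALSE)
}

# zero-truncated Poisson pmf (for the indel length distribution test)
dztpois <- function(k, lambda) {
  ifelse(k >= 1, dpois(k, lambda) / (1 - exp(-lambda)), 0)
}
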
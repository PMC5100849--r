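#' Paired-end read simulation with truth-bearing names
#'
#' Reads are laid uniformly over each template (equal 5' distance between
#' consecutive fragment starts), both templates contributing the same number
#' of pairs, so that every planted SNP segregates at exactly the known
#' frequency. The true origin of each pair (template, fragment start in
#' template coordinates, fragment length, pair index) is encoded in the read
#' name, so any aligner's output remains evaluable against the truth.
#'
#' Terminology: the *inner distance* d is the gap in bp between the inner
#' ends of the two reads of a pair; fragment length = 2 * read_length + d.
#' The start-to-start distance used by some mapper configurations is
#' read_length + d + read_length, i.e. the full fragment length.
#'
#' @name read_sim
NULL

#' Pair count needed for a target coverage
#'
#' @param template_length Template length in bp.
#' @param coverage Target fold coverage.
#' @param read_length Read length in bp.
#' @return `round(template_length * coverage / (2 * read_length))`, the total
#'   number of pairs (to be split evenly across the two templates).
#' @examples
#' pairs_for_coverage(2e6, 200, 100)  # 2,000,000
#' pairs_for_coverage(2e6, 200, 50)   # 4,000,000
#' @export
pairs_for_coverage <- function(template_length, coverage, read_length) {
  stopifnot(template_length > 0, coverage > 0, read_length > 0)
  round(template_length * coverage / (2 * read_length))
}

#' Simulation configuration
#'
#' @param read_length Read length in bp (both mates).
#' @param inner_distance_mean Mean inner distance d in bp (gap between the
#'   inner ends of the two reads; fragment = 2 * read_length + d).
#' @param inner_distance_sd SD of the inner distance; per-fragment draws are
#'   Normal(mean, sd) rounded to integers and floored at 0.
#' @param error_rate Per-base substitution probability.
#' @param n_pairs Total pair count (exactly one of `n_pairs` /
#'   `target_coverage`).
#' @param target_coverage Fold coverage from which the pair count is derived
#'   via [pairs_for_coverage()].
#' @param base_quality Uniform Phred base quality (default 40).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(read_length = 100L, inner_distance_mean = 100L,
                       inner_distance_sd = 0L, error_rate = 0,
                       n_pairs = NULL, target_coverage = NULL,
                       base_quality = 40L, seed = NULL) {
  stopifnot(read_length >= 1, inner_distance_sd >= 0,
            error_rate >= 0, error_rate < 1,
            base_quality >= 0, base_quality <= 93)
  if (is.null(n_pairs) == is.null(target_coverage))
    stop("exactly one of n_pairs / target_coverage must be given")
  structure(list(read_length = as.integer(read_length),
                 inner_distance_mean = as.integer(inner_distance_mean),
                 inner_distance_sd = inner_distance_sd,
                 error_rate = error_rate,
                 n_pairs = if (!is.null(n_pairs)) as.integer(n_pairs),
                 target_coverage = target_coverage,
                 base_quality = as.integer(base_quality),
                 seed = seed),
            class = "sim_config")
}

# Read-name codec: pme:<template>:<tstart>:<flen>:<idx>
# tstart is the fragment start in the *template's own* coordinates; reference
# coordinates are obtained through the template's coord_map.
encode_read_names <- function(template, tstart, flen, idx) {
  sprintf("pme:%s:%d:%d:%d", template, tstart, flen, idx)
}

#' Decode simulated read names
#'
#' @param names Character vector of read names produced by [simulate_pairs()].
#' @return data.frame with `template` ("ref"/"var"), `tstart` (fragment start,
#'   template coordinates), `flen` (fragment length) and `idx` (pair index).
#' @export
decode_read_names <- function(names) {
  parts <- strsplit(names, ":", fixed = TRUE)
  bad <- lengths(parts) != 5L | vapply(parts, `[`, "", 1L) != "pme"
  if (any(bad))
    stop("undecodable read name(s), e.g. ", names[which(bad)[1L]])
  m <- matrix(unlist(parts), ncol = 5L, byrow = TRUE)
  data.frame(template = m[, 2L], tstart = as.integer(m[, 3L]),
             flen = as.integer(m[, 4L]), idx = as.integer(m[, 5L]),
             stringsAsFactors = FALSE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Simulate pairs from a single template sequence. Fragment starts are laid
# with equal spacing on 1 .. L - nominal_fragment + 1 (truncated layout, no
# wrap-around; coverage ramps down at the template edges).
sim_pairs_one <- function(seq, template_id, n, config) {
  rl <- config$read_length
  d0 <- config$inner_distance_mean
  L <- nchar(seq)
  flen0 <- 2L * rl + d0
  if (flen0 > L) stop("nominal fragment length exceeds template length")
  max_start <- L - flen0 + 1L
  starts <- if (n == 1L) 1L else as.integer(round(seq(1, max_start, length.out = n)))
  d <- rep.int(d0, n)
  if (config$inner_distance_sd > 0) {
    d <- pmax(0L, as.integer(round(rnorm(n, d0, config$inner_distance_sd))))
    # clamp fragments that would run off the template end
    over <- starts + 2L * rl + d - 1L > L
    d[over] <- L - starts[over] + 1L - 2L * rl
  }
  flen <- 2L * rl + d
  seq1 <- substring(seq, starts, starts + rl - 1L)
  seq2 <- revcomp(substring(seq, starts + flen - rl, starts + flen - 1L))
  data.frame(name = encode_read_names(template_id, starts, flen, seq_len(n)),
             seq1 = seq1, seq2 = seq2, stringsAsFactors = FALSE)
}

#' Simulate uniformly distributed paired-end reads from a template set
#'
#' Each template contributes `n_pairs / 2` pairs (an odd total is rounded
#' down to even so the templates stay in exact 1:1 proportion). Read 1 is the
#' forward strand of the fragment's left end; read 2 is the reverse
#' complement of its right end (FR orientation). Substitution errors are
#' applied at `error_rate` via [apply_errors()].
#'
#' @param templates A `template_set` from [build_templates()].
#' @param config A [sim_config()].
#' @return A `read_pairs` data.frame (`name`, `seq1`, `seq2`, `qual1`,
#'   `qual2`) with the config attached as attribute `config`.
#' @export
simulate_pairs <- function(templates, config) {
  stopifnot(inherits(templates, "template_set"), inherits(config, "sim_config"))
  n_pairs <- config$n_pairs %||%
    pairs_for_coverage(templates$reference$length, config$target_coverage,
                       config$read_length)
  n_t <- n_pairs %/% 2L
  if (n_t < 1L) stop("fewer than 2 pairs requested")
  pairs <- with_seed(config$seed, {
    a <- sim_pairs_one(templates$reference$seq, "ref", n_t, config)
    b <- sim_pairs_one(templates$variant$seq, "var", n_t, config)
    # deterministic interleave: ref_1, var_1, ref_2, var_2, ...
    ord <- order(rep(seq_len(n_t), 2L), rep(1:2, each = n_t))
    out <- rbind(a, b)[ord, , drop = FALSE]
    rownames(out) <- NULL
    if (config$error_rate > 0) {
      out$seq1 <- substitute_bases(out$seq1, config$error_rate)
      out$seq2 <- substitute_bases(out$seq2, config$error_rate)
    }
    out
  })
  qchar <- rawToChar(as.raw(33L + config$base_quality))
  pairs$qual1 <- strrep(qchar, nchar(pairs$seq1))
  pairs$qual2 <- strrep(qchar, nchar(pairs$seq2))
  attr(pairs, "config") <- config
  class(pairs) <- c("read_pairs", "data.frame")
  pairs
}

# Per-base substitution at rate e: each base independently replaced by a
# uniform draw from the three other bases. Vectorized over all reads via a
# character matrix (requires equal read lengths, which the simulator
# guarantees).
substitute_bases <- function(seqs, error_rate) {
  if (error_rate <= 0 || length(seqs) == 0L) return(seqs)
  w <- unique(nchar(seqs))
  stopifnot(length(w) == 1L)
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = w, byrow = TRUE)
  hit <- which(runif(length(m)) < error_rate)
  if (length(hit)) {
    alt_tab <- t(vapply(BASES, function(b) setdiff(BASES, b), character(3)))
    orig <- m[hit]
    m[hit] <- alt_tab[cbind(match(orig, BASES),
                            sample.int(3L, length(hit), replace = TRUE))]
  }
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Apply substitution errors to simulated pairs
#'
#' Each base of each read is independently substituted with probability
#' `error_rate` by a uniform draw from the three other bases; base qualities
#' are unchanged. With `error_rate = 0` this is the identity.
#'
#' @param pairs A `read_pairs` data.frame.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return The mutated `read_pairs`.
#' @export
apply_errors <- function(pairs, error_rate, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate < 1)
  if (error_rate == 0) return(pairs)
  with_seed(seed, {
    pairs$seq1 <- substitute_bases(pairs$seq1, error_rate)
    pairs$seq2 <- substitute_bases(pairs$seq2, error_rate)
  })
  pairs
}

#' Write paired FASTQ files
#'
#' Sanger (offset 33) quality encoding; mate order is preserved between the
#' two files.
#'
#' @param pairs A `read_pairs` data.frame.
#' @param out1,out2 Output paths for mate 1 and mate 2.
#' @return Invisibly, `c(out1, out2)`.
#' @export
write_fastq <- function(pairs, out1, out2) {
  write_one <- function(seqs, quals, path) {
    ds <- Biostrings::DNAStringSet(seqs)
    names(ds) <- pairs$name
    Biostrings::writeXStringSet(ds, path, format = "fastq",
                                qualities = Biostrings::BStringSet(quals))
  }
  write_one(pairs$seq1, pairs$qual1, out1)
  write_one(pairs$seq2, pairs$qual2, out2)
  invisible(c(out1, out2))
}

#' Read paired FASTQ files written by [write_fastq()]
#'
#' @param in1,in2 FASTQ paths for mate 1 and mate 2.
#' @return A `read_pairs` data.frame.
#' @export
read_fastq <- function(in1, in2) {
  # Biostrings warns about dropped metadata columns on the FASTQ description
  # lines; the sequence/quality content itself is read losslessly
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(in1))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(in2))
  if (length(r1) != length(r2))
    stop("mate files differ in record count")
  as_chr <- function(x) suppressWarnings(as.character(x))
  pairs <- data.frame(name = names(r1),
                      seq1 = as_chr(r1), seq2 = as_chr(r2),
                      qual1 = as.character(Biostrings::quality(r1)),
                      qual2 = as.character(Biostrings::quality(r2)),
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  class(pairs) <- c("read_pairs", "data.frame")
  pairs
}
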
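#' Alignment ingest, oracle aligner and quality filters
#'
#' The pipeline consumes alignments from any external mapper (SAM/BAM), but
#' also ships an *oracle aligner* that places every simulated pair at its
#' true reference coordinates (projecting variant-template reads through the
#' template coordinate map, with CIGARs carrying the planted indels), plus a
#' controllable mismapping model. This makes the full pipeline testable by
#' construction: filtering at a mapping-quality threshold removes exactly
#' the mismapped pairs, and the best-case run recovers the truth perfectly.
#'
#' Alignments are held as a plain data.frame with columns `qname`, `flag`,
#' `rname`, `pos`, `mapq`, `cigar`, `mpos`, `tlen`, `seq`, `qual` (and, for
#' oracle output, the truth label `mismapped`), with the reference name and
#' length in attribute `sq`.
#'
#' @name align_layer
NULL

# Build CIGAR (and leftmost mapped position) from the reference-coordinate
# projection of one read: rp[i] is the reference position of query base i,
# NA for bases inside planted insertions. Leading/trailing insertions are
# soft-clipped; gaps between consecutive mapped bases become deletions.
cigar_from_refpos <- function(rp) {
  n <- length(rp)
  mapped <- which(!is.na(rp))
  if (!length(mapped)) stop("read lies entirely inside an insertion")
  lead <- mapped[1L] - 1L
  trail <- n - mapped[length(mapped)]
  core <- rp[(lead + 1L):(n - trail)]
  m <- length(core)
  isI <- is.na(core)
  cond <- rep(FALSE, m); cond[1L] <- TRUE
  if (m > 1L) {
    a <- isI[-m]; b <- isI[-1L]
    dd <- core[-1L] - core[-m]
    cond[-1L] <- (b != a) | (!a & !b & dd != 1L)
  }
  starts <- which(cond)
  lens <- diff(c(starts, m + 1L))
  ops <- character(0); olens <- integer(0)
  last_ref <- NA_integer_
  for (k in seq_along(starts)) {
    s <- starts[k]
    if (isI[s]) {
      ops <- c(ops, "I"); olens <- c(olens, lens[k])
    } else {
      if (!is.na(last_ref) && core[s] > last_ref + 1L) {
        ops <- c(ops, "D"); olens <- c(olens, core[s] - last_ref - 1L)
      }
      ops <- c(ops, "M"); olens <- c(olens, lens[k])
      last_ref <- core[s + lens[k] - 1L]
    }
  }
  if (lead) { ops <- c("S", ops); olens <- c(lead, olens) }
  if (trail) { ops <- c(ops, "S"); olens <- c(olens, trail) }
  list(pos = core[which(!isI)[1L]],
       cigar = paste0(olens, ops, collapse = ""))
}

# Project a batch of template-coordinate read starts to reference positions
# and CIGARs. cmap is the variant->reference coordinate map; nna is
# cumsum(is.na(cmap)), used to detect insertion-free, contiguous slices that
# can take the all-M fast path.
project_segments <- function(a, rl, cmap, nna) {
  b <- a + rl - 1L
  pos <- cmap[a]
  cigar <- rep(paste0(rl, "M"), length(a))
  nna_prev <- ifelse(a > 1L, nna[pmax(a - 1L, 1L)], 0L)
  simple <- !is.na(pos) & !is.na(cmap[b]) &
    (nna[b] - nna_prev == 0L) & (cmap[b] - pos == rl - 1L)
  for (i in which(!simple)) {
    cg <- cigar_from_refpos(cmap[a[i]:b[i]])
    pos[i] <- cg$pos
    cigar[i] <- cg$cigar
  }
  list(pos = pos, cigar = cigar)
}

#' Oracle alignment of simulated pairs
#'
#' Places each pair at its true reference coordinates (MAPQ 60, proper-pair
#' flag set). Variant-template reads are projected through the template
#' coordinate map; reads spanning a planted indel carry it in the CIGAR,
#' and read bases inside insertions are soft-clipped at read edges. With
#' probability `mismap_rate` a pair is instead placed uniformly at random
#' with MAPQ `mismap_mapq` and the proper-pair flag cleared, emulating an
#' ambiguously mapped pair. If `mismap_targets` is given (a vector of
#' reference positions, e.g. planted indel positions), only pairs whose true
#' fragment overlaps a target are eligible for mismapping, which concentrates
#' artifacts near those sites.
#'
#' @param pairs A `read_pairs` data.frame from [simulate_pairs()].
#' @param templates The `template_set` the pairs were simulated from.
#' @param mismap_rate Probability that an eligible pair is mismapped.
#' @param mismap_mapq MAPQ assigned to mismapped pairs (default 5).
#' @param mismap_targets Optional reference positions near which mismapping
#'   is concentrated; `NULL` makes every pair eligible.
#' @param mismap_proper Keep the proper-pair flag (and mate flags) on
#'   mismapped pairs. The default `FALSE` emulates a mapper that signals its
#'   own uncertainty (such pairs are removable by the standard filters);
#'   `TRUE` emulates a confidently wrong mapper, the source of the artifact
#'   peaks the intersection strategy targets.
#' @param mismap_template Which template's pairs are eligible: `"both"`,
#'   `"var"` or `"ref"`. Restricting to `"var"` emulates the real failure
#'   mode where reads carrying an indel are the ones misplaced, which skews
#'   the local allele frequency instead of just thinning coverage.
#' @param seed Integer seed for mismap draws.
#' @return An alignment data.frame (two rows per pair, mates adjacent) with
#'   truth column `mismapped` and attribute `sq`.
#' @export
oracle_align <- function(pairs, templates, mismap_rate = 0,
                         mismap_mapq = 5L, mismap_targets = NULL,
                         mismap_proper = FALSE,
                         mismap_template = c("both", "var", "ref"),
                         seed = NULL) {
  mismap_template <- match.arg(mismap_template)
  stopifnot(inherits(templates, "template_set"),
            mismap_rate >= 0, mismap_rate < 1)
  meta <- decode_read_names(pairs$name)
  rl <- nchar(pairs$seq1[1L])
  n <- nrow(pairs)
  L <- templates$reference$length
  chrom <- templates$reference$name

  a1 <- meta$tstart
  a2 <- meta$tstart + meta$flen - rl
  pos1 <- integer(n); pos2 <- integer(n)
  cig1 <- character(n); cig2 <- character(n)

  is_ref <- meta$template == "ref"
  pos1[is_ref] <- a1[is_ref]; cig1[is_ref] <- paste0(rl, "M")
  pos2[is_ref] <- a2[is_ref]; cig2[is_ref] <- paste0(rl, "M")
  if (any(!is_ref)) {
    cmap <- templates$coord_map
    nna <- cumsum(is.na(cmap))
    v <- which(!is_ref)
    p1 <- project_segments(a1[v], rl, cmap, nna)
    p2 <- project_segments(a2[v], rl, cmap, nna)
    pos1[v] <- p1$pos; cig1[v] <- p1$cigar
    pos2[v] <- p2$pos; cig2[v] <- p2$cigar
  }

  # fragment span on the reference, for mismap eligibility
  mismapped <- rep(FALSE, n)
  if (mismap_rate > 0) {
    mismapped <- with_seed(seed, {
      elig <- rep(TRUE, n)
      if (mismap_template != "both") elig <- meta$template == mismap_template
      if (!is.null(mismap_targets) && length(mismap_targets)) {
        tg <- sort(as.integer(mismap_targets))
        rs <- pos1; re <- pos2 + rl - 1L
        elig <- elig & (findInterval(re, tg) - findInterval(rs - 1L, tg)) > 0L
      }
      hit <- elig & runif(n) < mismap_rate
      if (any(hit)) {
        nh <- sum(hit)
        flen <- pmin(meta$flen[hit], L - 1L)
        u <- 1L + as.integer(floor(runif(nh) * pmax(1L, L - flen + 1L)))
        pos1[hit] <- u
        pos2[hit] <- u + flen - rl
        cig1[hit] <- paste0(rl, "M")
        cig2[hit] <- paste0(rl, "M")
      }
      hit
    })
  }

  mapq <- ifelse(mismapped, as.integer(mismap_mapq), 60L)
  # 99/147: paired, proper, mate-reverse / reverse, first/second in pair.
  # Mismapped pairs lose the proper-pair bit (97/145) unless mismap_proper.
  flag1 <- ifelse(mismapped & !mismap_proper, 97L, 99L)
  flag2 <- ifelse(mismapped & !mismap_proper, 145L, 147L)
  tlen <- pos2 + rl - pos1

  idx <- rep(seq_len(n), each = 2L)
  mate1 <- rep(c(TRUE, FALSE), n)
  aln <- data.frame(
    qname = pairs$name[idx],
    flag = ifelse(mate1, flag1[idx], flag2[idx]),
    rname = chrom,
    pos = ifelse(mate1, pos1[idx], pos2[idx]),
    mapq = mapq[idx],
    cigar = ifelse(mate1, cig1[idx], cig2[idx]),
    mpos = ifelse(mate1, pos2[idx], pos1[idx]),
    tlen = ifelse(mate1, tlen[idx], -tlen[idx]),
    seq = ifelse(mate1, pairs$seq1[idx], revcomp(pairs$seq2)[idx]),
    qual = ifelse(mate1, pairs$qual1[idx],
                  vapply(pairs$qual2, function(q)
                    paste(rev(strsplit(q, "")[[1L]]), collapse = ""), "",
                    USE.NAMES = FALSE)[idx]),
    mismapped = mismapped[idx],
    stringsAsFactors = FALSE)
  attr(aln, "sq") <- c(name = chrom, length = L)
  aln
}

#' Filter alignments by mapping quality and pair flags
#'
#' The default reproduces the standard Pool-Seq filter: mapping quality
#' >= 20 and proper pairs with both mates mapped (samtools
#' `-q 20 -f 0x002 -F 0x004 -F 0x008`). For single-end data set
#' `require_proper = FALSE` and `require_mapped_pair = FALSE`.
#'
#' @param aln An alignment data.frame.
#' @param min_mapq Minimum mapping quality kept.
#' @param require_proper Require the proper-pair flag (0x2).
#' @param require_mapped_pair Require both the read (0x4) and its mate (0x8)
#'   to be mapped.
#' @param verbose Emit a message with kept/dropped counts.
#' @return The filtered alignment data.frame (attributes preserved).
#' @export
filter_alignments <- function(aln, min_mapq = 20L, require_proper = TRUE,
                              require_mapped_pair = TRUE, verbose = FALSE) {
  keep <- aln$mapq >= min_mapq
  if (require_proper) keep <- keep & bitwAnd(aln$flag, 0x2L) > 0L
  if (require_mapped_pair)
    keep <- keep & bitwAnd(aln$flag, 0x4L) == 0L & bitwAnd(aln$flag, 0x8L) == 0L
  if (verbose)
    message(sprintf("filter_alignments: kept %d / %d records",
                    sum(keep), length(keep)))
  out <- aln[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sq") <- attr(aln, "sq")
  out
}

#' Write alignments to a SAM file
#'
#' @param aln An alignment data.frame with attribute `sq`.
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(aln, path) {
  sq <- attr(aln, "sq")
  if (is.null(sq)) stop("alignment frame lacks an 'sq' attribute")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", sq[["name"]], as.integer(sq[["length"]])))
  body <- paste(aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq, aln$cigar,
                "=", aln$mpos, aln$tlen, aln$seq, aln$qual, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignments from SAM or BAM
#'
#' SAM input is converted through [Rsamtools::asBam()]; the returned frame
#' matches the oracle-aligner layout (without the `mismapped` truth column).
#'
#' @param path SAM or BAM file with a header.
#' @return Alignment data.frame with attribute `sq`.
#' @export
read_alignments <- function(path) {
  bam <- if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  b <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                             "mapq", "cigar", "mpos", "isize",
                                             "seq", "qual")))[[1L]]
  aln <- data.frame(qname = b$qname, flag = b$flag,
                    rname = as.character(b$rname), pos = b$pos,
                    mapq = b$mapq, cigar = b$cigar, mpos = b$mpos,
                    tlen = b$isize, seq = as.character(b$seq),
                    qual = as.character(b$qual), stringsAsFactors = FALSE)
  hd <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (length(hd))
    attr(aln, "sq") <- c(name = names(hd)[1L], length = unname(hd[1L]))
  aln
}
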
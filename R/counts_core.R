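#' Per-site allele counts and the sync format
#'
#' Filtered alignments are reduced to per-site nucleotide counts
#' (A/T/C/G/N/del, plus the forward-strand read count used by the
#' strand-bias filter). Counting is CIGAR-aware and delegates to the
#' `Rsamtools` pileup engine with settings matching `samtools mpileup -B`
#' semantics: no base-alignment-quality recalibration, M/=/X bases counted
#' at their reference positions, deleted reference positions tallied in the
#' `del` column, inserted bases counted nowhere, and bases below the quality
#' threshold excluded. Multi-sample count sets round-trip through the
#' PoPoolation2 sync format (TAB-separated `chrom pos ref` then one
#' `A:T:C:G:N:del` block per sample). Coverage, wherever the package applies
#' minimum/maximum-coverage rules, is A+T+C+G only; N and del tallies are
#' carried but excluded.
#'
#' @name counts_core
NULL

NUC6 <- c("A", "T", "C", "G", "N", "del")

#' Pile up alignments into per-site allele counts
#'
#' @param aln An alignment data.frame (oracle or [read_alignments()] output),
#'   or a path to a SAM/BAM file.
#' @param reference The reference `chassis` (supplies the `ref` column).
#' @param min_base_quality Minimum base quality counted (0 for simulated
#'   reads with uniform quality; 20-30 typical for real data).
#' @param max_depth Pileup depth cap; keep above the expected coverage.
#' @return A `site_counts` data.frame: `chrom`, `pos`, `ref`, counts `A`,
#'   `T`, `C`, `G`, `N`, `del`, and `fwd` (forward-strand A/C/G/T reads at
#'   the site, irrespective of allele). Only covered sites are emitted.
#' @export
pileup_counts <- function(aln, reference, min_base_quality = 0L,
                          max_depth = 100000L) {
  stopifnot(inherits(reference, "chassis"))
  bam <- if (is.character(aln)) {
    if (grepl("\\.sam$", aln, ignore.case = TRUE))
      Rsamtools::asBam(aln, tempfile(), overwrite = TRUE,
                       indexDestination = TRUE)
    else {
      sorted <- Rsamtools::sortBam(aln, tempfile())
      Rsamtools::indexBam(sorted)
      sorted
    }
  } else {
    if (nrow(aln) == 0L) stop("no alignments to pile up")
    sam <- tempfile(fileext = ".sam")
    on.exit(unlink(c(sam, bam_out, paste0(bam_out, ".bai"))), add = TRUE)
    write_sam(aln, sam)
    bam_out <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                                indexDestination = TRUE)
    bam_out
  }
  pp <- Rsamtools::PileupParam(
    max_depth = as.integer(max_depth),
    min_base_quality = as.integer(min_base_quality),
    min_mapq = 0L, min_nucleotide_depth = 1L,
    distinguish_strands = TRUE, distinguish_nucleotides = TRUE,
    ignore_query_Ns = FALSE,
    include_deletions = TRUE, include_insertions = FALSE)
  p <- Rsamtools::pileup(bam, pileupParam = pp)
  upos <- sort(unique(p$pos))
  n <- length(upos)
  pi_ <- match(p$pos, upos)
  nuc <- as.character(p$nucleotide)
  nuc[nuc == "-"] <- "del"
  j <- match(nuc, NUC6)
  keep <- !is.na(j)
  m <- matrix(0L, n, 6L, dimnames = list(NULL, NUC6))
  # column-major linear index into m
  key <- (j[keep] - 1L) * n + pi_[keep]
  agg <- rowsum(p$count[keep], group = key)
  m[as.integer(rownames(agg))] <- as.integer(agg)
  fwd <- integer(n)
  fk <- keep & p$strand == "+" & j <= 4L
  if (any(fk)) {
    fa <- rowsum(p$count[fk], group = pi_[fk])
    fwd[as.integer(rownames(fa))] <- as.integer(fa)
  }
  out <- data.frame(chrom = reference$name, pos = upos,
                    ref = substring(reference$seq, upos, upos),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(m), fwd = fwd)
  class(out) <- c("site_counts", "data.frame")
  out
}

#' Coverage histogram of a site-counts table
#'
#' Coverage is A+T+C+G per site (N and deletion tallies excluded).
#'
#' @param sites A `site_counts` data.frame.
#' @return A list: `histogram` (data.frame `coverage`, `n_sites`), `mean`,
#'   `median`.
#' @export
coverage_histogram <- function(sites) {
  cov <- site_coverage(sites)
  if (length(cov) == 0L)
    return(list(histogram = data.frame(coverage = integer(),
                                       n_sites = integer()),
                mean = NaN, median = NA_integer_))
  tab <- table(cov)
  list(histogram = data.frame(coverage = as.integer(names(tab)),
                              n_sites = as.integer(tab)),
       mean = mean(cov), median = stats::median(cov))
}

site_coverage <- function(sites) {
  if (nrow(sites) == 0L) return(integer(0))
  sites$A + sites$T + sites$C + sites$G
}

#' Combine single-sample count tables into a sync set
#'
#' Sites are the union of the samples' covered positions; a sample without
#' reads at a site contributes zero counts there.
#'
#' @param counts_list List of `site_counts` data.frames (one per sample).
#' @param sample_names Optional sample labels.
#' @return A `sync` object: `chrom`, `pos`, `ref`, `counts` (list of
#'   site-by-6 matrices, columns A/T/C/G/N/del) and `fwd` (site-by-sample
#'   forward-strand read counts).
#' @export
as_sync <- function(counts_list, sample_names = NULL) {
  stopifnot(length(counts_list) >= 1L)
  chrom <- counts_list[[1L]]$chrom[1L]
  pos <- sort(unique(unlist(lapply(counts_list, `[[`, "pos"))))
  n <- length(pos)
  ref <- rep(NA_character_, n)
  counts <- vector("list", length(counts_list))
  fwd <- matrix(0L, n, length(counts_list))
  for (s in seq_along(counts_list)) {
    sc <- counts_list[[s]]
    m <- matrix(0L, n, 6L, dimnames = list(NULL, NUC6))
    i <- match(sc$pos, pos)
    m[i, ] <- as.matrix(sc[, NUC6])
    counts[[s]] <- m
    fwd[i, s] <- sc$fwd
    ref[i[is.na(ref[i])]] <- sc$ref[is.na(ref[i])]
  }
  names(counts) <- sample_names %||% paste0("s", seq_along(counts_list))
  structure(list(chrom = chrom, pos = pos, ref = toupper(ref),
                 counts = counts, fwd = fwd),
            class = "sync")
}

#' @export
print.sync <- function(x, ...) {
  cat(sprintf("<sync> %s: %d sites, %d sample(s)\n",
              x$chrom, length(x$pos), length(x$counts)))
  invisible(x)
}

#' Write a sync set in PoPoolation2 dialect
#'
#' One line per site: `chrom TAB pos TAB ref` then one `A:T:C:G:N:del`
#' count block per sample; no header line. The sync format carries no
#' strand information, so forward-strand totals are written to a parallel
#' `<path>.strand` TSV (keyed by chrom and pos) unless `strand_file =
#' FALSE`; [read_sync()] picks the side file up automatically.
#'
#' @param sync A `sync` object.
#' @param path Output path.
#' @param strand_file Also write the `.strand` side file?
#' @return Invisibly, `path`.
#' @export
write_sync <- function(sync, path, strand_file = TRUE) {
  stopifnot(inherits(sync, "sync"))
  blocks <- vapply(sync$counts, function(m)
    paste(m[, 1L], m[, 2L], m[, 3L], m[, 4L], m[, 5L], m[, 6L], sep = ":"),
    character(length(sync$pos)))
  if (is.null(dim(blocks))) blocks <- matrix(blocks, nrow = 1L)
  lines <- do.call(paste, c(list(sync$chrom, sync$pos, sync$ref),
                            lapply(seq_len(ncol(blocks)),
                                   function(j) blocks[, j]),
                            sep = "\t"))
  writeLines(lines, path)
  if (strand_file) {
    sf <- data.frame(chrom = sync$chrom, pos = sync$pos, sync$fwd)
    names(sf)[-(1:2)] <- names(sync$counts) %||%
      paste0("s", seq_along(sync$counts))
    writeLines(paste0("#", paste(names(sf), collapse = "\t")),
               paste0(path, ".strand"))
    write.table(sf, paste0(path, ".strand"), append = TRUE, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a sync file
#'
#' @param path Path to a PoPoolation2-style sync file. A `<path>.strand`
#'   side file written by [write_sync()] is read back into `fwd` when
#'   present.
#' @return A `sync` object (with `fwd` all-zero if no side file exists).
#' @export
read_sync <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty sync file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- unique(lengths(fields))
  if (length(nf) != 1L || nf < 4L) {
    bad <- which(lengths(fields) != lengths(fields)[1L])
    stop("malformed sync row at line ", if (length(bad)) bad[1L] else 1L,
         " of ", path)
  }
  tab <- matrix(unlist(fields), ncol = nf, byrow = TRUE)
  n_samples <- nf - 3L
  pos <- as.integer(tab[, 2L])
  counts <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    block <- strsplit(tab[, 3L + s], ":", fixed = TRUE)
    bad <- which(lengths(block) != 6L)
    if (length(bad))
      stop("malformed count column at line ", bad[1L], " of ", path)
    m <- matrix(as.integer(unlist(block)), ncol = 6L, byrow = TRUE,
                dimnames = list(NULL, NUC6))
    counts[[s]] <- m
  }
  names(counts) <- paste0("s", seq_len(n_samples))
  fwd <- matrix(0L, length(pos), n_samples)
  spath <- paste0(path, ".strand")
  if (file.exists(spath)) {
    sf <- read.table(spath, sep = "\t", comment.char = "#",
                     stringsAsFactors = FALSE)
    i <- match(sf[[2L]], pos)
    fwd[i, ] <- as.matrix(sf[, -(1:2), drop = FALSE])
  }
  structure(list(chrom = tab[1L, 1L], pos = pos, ref = toupper(tab[, 3L]),
                 counts = counts, fwd = fwd),
            class = "sync")
}
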
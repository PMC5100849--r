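#' Simulation templates: chassis, planted SNPs, planted indels
#'
#' The simulation substrate is a pair of haploid template sequences: a
#' *reference chassis* (any stretch of A/C/G/T sequence) and a *variant
#' chassis* derived from it by planting a SNP at every fixed-spacing position
#' and, optionally, one short indel between each pair of adjacent SNPs.
#' Reads simulated in equal proportion from the two templates then carry
#' every planted SNP at a known population frequency (0.5), so downstream
#' allele-frequency estimates can be scored against an exact truth.
#'
#' @name template_forge
NULL

new_chassis <- function(name, seq) {
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("chassis sequence is empty")
  if (grepl("[^ACGT]", seq)) stop("chassis sequence contains non-ACGT characters")
  structure(list(name = name, seq = seq, length = nchar(seq)), class = "chassis")
}

#' @export
print.chassis <- function(x, ...) {
  cat(sprintf("<chassis> %s: %d bp\n", x$name, x$length))
  invisible(x)
}

#' Build a chassis sequence from a FASTA file
#'
#' Reads the first sequence of a FASTA file, removes every character other
#' than A, C, G or T (case-insensitively), and keeps the first `take_bp`
#' remaining bases. Deterministic.
#'
#' @param fasta_path Path to a FASTA file (first record is used).
#' @param take_bp Number of cleaned bases to keep.
#' @param name Chassis label; defaults to the FASTA record name.
#' @return A `chassis` object (`name`, `seq`, `length`).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">toy", "ACGTNNNACGT"), fa)
#' build_chassis(fa, 8)$seq   # "ACGTACGT"
#' @export
build_chassis <- function(fasta_path, take_bp, name = NULL) {
  stopifnot(take_bp >= 1)
  ss <- Biostrings::readBStringSet(fasta_path)
  if (length(ss) == 0L) stop("no sequences in ", fasta_path)
  raw <- toupper(as.character(ss[[1L]]))
  clean <- gsub("[^ACGT]", "", raw)
  if (nchar(clean) < take_bp)
    stop(sprintf("only %d clean bases available, %d requested",
                 nchar(clean), as.integer(take_bp)))
  new_chassis(name %||% names(ss)[1L], substr(clean, 1L, take_bp))
}

#' Generate a random chassis
#'
#' Uniform i.i.d. A/C/G/T sequence. Any chassis works as a simulation
#' substrate because all variation is planted on top of it; a random chassis
#' is the default for tests and scaled-down runs.
#'
#' @param length Chassis length in bp.
#' @param seed Integer seed; the chassis is reproducible given the seed.
#' @param name Chassis label.
#' @return A `chassis` object.
#' @export
random_chassis <- function(length, seed = NULL, name = "sim") {
  stopifnot(length >= 1)
  seq <- with_seed(seed, paste(sample(BASES, length, replace = TRUE), collapse = ""))
  new_chassis(name, seq)
}

# SNP positions for a chassis of length L: multiples of `spacing` up to L - 1
# (the final position of the chassis never carries a SNP). For L = 2e6 and
# spacing = 100 this yields exactly 19,999 positions.
snp_positions <- function(length, spacing) {
  stopifnot(spacing >= 1)
  n <- floor((length - 1) / spacing)
  if (n < 1L) return(integer(0))
  as.integer(seq.int(spacing, by = spacing, length.out = n))
}

#' Plant SNPs at fixed spacing
#'
#' Introduces a SNP with a random non-reference allele at every `spacing`-th
#' position of the chassis (1-based positions `spacing, 2*spacing, ...` up to
#' `length - 1`). The alternative allele is drawn uniformly from the three
#' non-reference bases.
#'
#' @param chassis A `chassis` object.
#' @param spacing SNP spacing in bp (default 100).
#' @param true_freq Known population frequency recorded for every SNP
#'   (0.5 when the two templates contribute reads in equal proportion).
#' @param seed Integer seed for allele draws.
#' @return A list with `chassis` (the SNP-bearing variant of the input) and
#'   `snps`, a data.frame with columns `pos`, `ref`, `alt`, `true_freq`.
#' @export
plant_snps <- function(chassis, spacing = 100L, true_freq = 0.5, seed = NULL) {
  stopifnot(inherits(chassis, "chassis"), spacing >= 1)
  pos <- snp_positions(chassis$length, spacing)
  chars <- strsplit(chassis$seq, "", fixed = TRUE)[[1L]]
  ref <- chars[pos]
  # three alternatives per reference base, indexed by base
  alt_tab <- t(vapply(BASES, function(b) setdiff(BASES, b), character(3)))
  alt <- with_seed(seed, {
    pick <- sample.int(3L, length(pos), replace = TRUE)
    alt_tab[cbind(match(ref, BASES), pick)]
  })
  chars[pos] <- alt
  snps <- data.frame(pos = pos, ref = ref, alt = alt, true_freq = true_freq,
                     stringsAsFactors = FALSE)
  list(chassis = new_chassis(paste0(chassis$name, "_snp"),
                             paste(chars, collapse = "")),
       snps = snps)
}

# Zero-truncated Poisson draws: resample zero draws until all are positive.
rztpois <- function(n, lambda) {
  x <- rpois(n, lambda)
  while (any(zero <- x == 0L)) x[zero] <- rpois(sum(zero), lambda)
  x
}

# Apply a sorted set of indel events to a sequence, returning the mutated
# sequence and the coordinate map from mutated (variant) coordinates back to
# input (reference) coordinates; inserted bases map to NA.
apply_indels <- function(seq, indels) {
  if (is.null(indels) || nrow(indels) == 0L)
    return(list(seq = seq, coord_map = seq_len(nchar(seq))))
  stopifnot(!is.unsorted(indels$pos))
  pieces <- vector("list", 2L * nrow(indels) + 1L)
  maps <- vector("list", 2L * nrow(indels) + 1L)
  at <- 1L   # next unconsumed input position
  k <- 0L
  for (i in seq_len(nrow(indels))) {
    p <- indels$pos[i]
    k <- k + 1L
    pieces[[k]] <- substr(seq, at, p)
    maps[[k]] <- at:p
    if (indels$kind[i] == "insertion") {
      k <- k + 1L
      pieces[[k]] <- indels$inserted_seq[i]
      maps[[k]] <- rep(NA_integer_, indels$length[i])
      at <- p + 1L
    } else {
      at <- p + indels$length[i] + 1L
    }
  }
  k <- k + 1L
  pieces[[k]] <- substr(seq, at, nchar(seq))
  maps[[k]] <- at:nchar(seq)
  list(seq = paste(unlist(pieces[seq_len(k)]), collapse = ""),
       coord_map = as.integer(unlist(maps[seq_len(k)])))
}

#' Plant one indel between each pair of adjacent SNPs
#'
#' Between every pair of adjacent SNP positions one indel is planted at a
#' uniform random position, with a zero-truncated Poisson(lambda) length
#' (zero-length draws are rejected and redrawn). The event kind is insertion
#' or deletion with probability 0.5 each; insertions carry a uniform random
#' sequence. A deletion must fit strictly inside the inter-SNP interval so
#' that it never touches a flanking SNP; infeasibly long draws are redrawn.
#'
#' @param snp_chassis The SNP-bearing chassis from [plant_snps()].
#' @param snps The SNP truth table from [plant_snps()].
#' @param lambda Poisson rate for indel lengths (default 1; the resulting
#'   zero-truncated mean is lambda / (1 - exp(-lambda)), about 1.58 at 1).
#' @param seed Integer seed.
#' @param max_retries Redraw budget per interval before erroring.
#' @return A list with `chassis` (SNPs + indels), `indels` (data.frame
#'   `pos`, `kind`, `length`, `inserted_seq`; `pos` is the reference position
#'   immediately left of the event) and `coord_map` (variant coordinate ->
#'   reference coordinate, NA for inserted bases).
#' @export
plant_indels <- function(snp_chassis, snps, lambda = 1, seed = NULL,
                         max_retries = 100L) {
  stopifnot(inherits(snp_chassis, "chassis"), nrow(snps) >= 2L, lambda > 0)
  n <- nrow(snps) - 1L
  indels <- with_seed(seed, {
    kind <- ifelse(runif(n) < 0.5, "insertion", "deletion")
    len <- rztpois(n, lambda)
    pos <- integer(n)
    ins <- character(n)
    for (i in seq_len(n)) {
      p1 <- snps$pos[i]; p2 <- snps$pos[i + 1L]
      if (kind[i] == "deletion") {
        tries <- 0L
        # deletion removes pos+1 .. pos+len, all inside (p1, p2)
        while (p2 - 1L - len[i] < p1) {
          tries <- tries + 1L
          if (tries > max_retries)
            stop(sprintf("interval %d-%d too short for a deletion", p1, p2))
          len[i] <- rztpois(1L, lambda)
        }
        pos[i] <- as.integer(p1 + floor(runif(1) * (p2 - len[i] - p1)))
      } else {
        pos[i] <- as.integer(p1 + floor(runif(1) * (p2 - p1)))
        ins[i] <- paste(sample(BASES, len[i], replace = TRUE), collapse = "")
      }
    }
    data.frame(pos = pos, kind = kind, length = len, inserted_seq = ins,
               stringsAsFactors = FALSE)
  })
  built <- apply_indels(snp_chassis$seq, indels)
  list(chassis = new_chassis(sub("_snp$", "_snp_indel", snp_chassis$name),
                             built$seq),
       indels = indels,
       coord_map = built$coord_map)
}

#' Build a full template set
#'
#' Convenience constructor running [plant_snps()] and optionally
#' [plant_indels()] on a chassis, returning the two-template substrate used
#' by the read simulator and the oracle aligner.
#'
#' @param chassis A `chassis` object (see [build_chassis()], [random_chassis()]).
#' @param spacing SNP spacing in bp.
#' @param indels Plant indels between adjacent SNPs?
#' @param lambda Indel length rate (zero-truncated Poisson).
#' @param true_freq Known SNP frequency (0.5 for equal template proportions).
#' @param seed Integer seed; SNP and indel draws use derived child seeds.
#' @return A `template_set`: `reference` and `variant` chassis, `snps` and
#'   `indels` truth tables, `coord_map` (variant -> reference coordinates),
#'   and the construction parameters.
#' @examples
#' ts <- build_templates(random_chassis(5000, seed = 1), seed = 1)
#' nrow(ts$snps)   # 49 SNPs on 5 kb at 100 bp spacing
#' @export
build_templates <- function(chassis, spacing = 100L, indels = TRUE,
                            lambda = 1, true_freq = 0.5, seed = NULL) {
  ps <- plant_snps(chassis, spacing, true_freq, seed = child_seed(seed, 1L))
  if (indels) {
    pi_ <- plant_indels(ps$chassis, ps$snps, lambda, seed = child_seed(seed, 2L))
    variant <- pi_$chassis; indel_tab <- pi_$indels; cmap <- pi_$coord_map
  } else {
    variant <- ps$chassis
    indel_tab <- data.frame(pos = integer(), kind = character(),
                            length = integer(), inserted_seq = character(),
                            stringsAsFactors = FALSE)
    cmap <- seq_len(variant$length)
  }
  structure(list(reference = chassis, variant = variant,
                 snps = ps$snps, indels = indel_tab, coord_map = cmap,
                 params = list(spacing = as.integer(spacing),
                               indels = indels, lambda = lambda,
                               true_freq = true_freq, seed = seed)),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> ref %s (%d bp), variant %d bp, %d SNPs, %d indels\n",
              x$reference$name, x$reference$length, x$variant$length,
              nrow(x$snps), nrow(x$indels)))
  invisible(x)
}

# Rebuild the variant sequence from reference + truth tables; used for
# round-trip verification and by read_truth().
reconstruct_variant <- function(reference, snps, indels) {
  chars <- strsplit(reference$seq, "", fixed = TRUE)[[1L]]
  chars[snps$pos] <- snps$alt
  apply_indels(paste(chars, collapse = ""), indels)
}

#' Write a template set to FASTA + TSV truth files
#'
#' Writes `<prefix>_ref.fasta`, `<prefix>_var.fasta`, `<prefix>_snps.tsv` and
#' `<prefix>_indels.tsv`. The TSV truth tables carry `#`-prefixed header
#' lines recording the construction parameters and seed, so a run is
#' self-describing. [read_truth()] round-trips losslessly.
#'
#' @param templates A `template_set`.
#' @param out_prefix Output path prefix.
#' @return Invisibly, the named vector of paths written.
#' @export
write_truth <- function(templates, out_prefix) {
  stopifnot(inherits(templates, "template_set"))
  paths <- c(ref = paste0(out_prefix, "_ref.fasta"),
             var = paste0(out_prefix, "_var.fasta"),
             snps = paste0(out_prefix, "_snps.tsv"),
             indels = paste0(out_prefix, "_indels.tsv"))
  ref <- Biostrings::DNAStringSet(templates$reference$seq)
  names(ref) <- templates$reference$name
  Biostrings::writeXStringSet(ref, paths[["ref"]])
  var <- Biostrings::DNAStringSet(templates$variant$seq)
  names(var) <- templates$variant$name
  Biostrings::writeXStringSet(var, paths[["var"]])
  p <- templates$params
  hdr <- sprintf("#poolmapeval truth spacing=%d indels=%s lambda=%g true_freq=%g seed=%s",
                 p$spacing, p$indels, p$lambda, p$true_freq,
                 p$seed %||% "NA")
  writeLines(c(hdr, "#pos\tref\talt\ttrue_freq"), paths[["snps"]])
  write.table(templates$snps, paths[["snps"]], append = TRUE, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(c(hdr, "#pos\tkind\tlength\tinserted_seq"), paths[["indels"]])
  if (nrow(templates$indels))
    write.table(templates$indels, paths[["indels"]], append = TRUE, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Read a template set written by [write_truth()]
#'
#' @param prefix The prefix passed to [write_truth()].
#' @return A `template_set`; the coordinate map is rebuilt by replaying the
#'   indel truth table and verified against the stored variant sequence.
#' @export
read_truth <- function(prefix) {
  ref_ss <- Biostrings::readDNAStringSet(paste0(prefix, "_ref.fasta"))
  var_ss <- Biostrings::readDNAStringSet(paste0(prefix, "_var.fasta"))
  reference <- new_chassis(names(ref_ss)[1L], as.character(ref_ss[[1L]]))
  variant <- new_chassis(names(var_ss)[1L], as.character(var_ss[[1L]]))
  hdr <- readLines(paste0(prefix, "_snps.tsv"), n = 1L)
  getp <- function(key) sub(sprintf(".*%s=([^ ]+).*", key), "\\1", hdr)
  snps <- read.table(paste0(prefix, "_snps.tsv"), sep = "\t",
                     comment.char = "#", stringsAsFactors = FALSE,
                     col.names = c("pos", "ref", "alt", "true_freq"))
  ipath <- paste0(prefix, "_indels.tsv")
  ilines <- readLines(ipath)
  if (sum(!startsWith(ilines, "#")) > 0L) {
    indels <- read.table(ipath, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE, na.strings = NULL,
                         col.names = c("pos", "kind", "length", "inserted_seq"),
                         colClasses = c("integer", "character", "integer",
                                        "character"))
    indels$inserted_seq[is.na(indels$inserted_seq)] <- ""
  } else {
    indels <- data.frame(pos = integer(), kind = character(),
                         length = integer(), inserted_seq = character(),
                         stringsAsFactors = FALSE)
  }
  rebuilt <- reconstruct_variant(reference, snps, indels)
  if (rebuilt$seq != variant$seq)
    stop("truth tables do not reproduce the stored variant sequence")
  seed_chr <- getp("seed")
  structure(list(reference = reference, variant = variant, snps = snps,
                 indels = indels, coord_map = rebuilt$coord_map,
                 params = list(spacing = as.integer(getp("spacing")),
                               indels = as.logical(getp("indels")),
                               lambda = as.numeric(getp("lambda")),
                               true_freq = as.numeric(getp("true_freq")),
                               seed = if (seed_chr == "NA") NULL
                                      else as.integer(seed_chr))),
            class = "template_set")
}
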
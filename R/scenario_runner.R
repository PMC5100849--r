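#' Named end-to-end scenarios
#'
#' Each scenario reproduces one of the study designs at a configurable
#' scale: the scale multiplies the chassis length (and, through the fixed
#' 200x target coverage, the read count) while the 100 bp SNP spacing keeps
#' truth density constant, so a scale-0.02 run is a 40 kb miniature of the
#' full 2 Mbp design.
#'
#' Single-sample designs (scored against truth):
#' * `best_case` — 2x100 bp, inner distance 100+/-0, error 0, no indels.
#' * `indel_insert` — 2x100 bp, inner distance 100+/-40, error 0, indels.
#' * `indel_error` — 2x100 bp, inner distance 100+/-0, error 5%, indels.
#'
#' Two-sample designs (FST / Fisher between samples simulated from the same
#' indel-bearing templates, so any differentiation is technical):
#' * `fst_id` — inner distance 100+/-20 vs 300+/-60, error 1%.
#' * `fst_rl` — read length 100 vs 50, inner distance 100+/-20, error 1%.
#' * `fst_error` — error 1% vs 5%, inner distance 100+/-20.
#'
#' `intersection_demo` runs the `fst_id` design through two "mappers": a
#' clean oracle and an oracle that confidently mismaps a fraction of the
#' pairs near planted indels, then intersects the two Fisher tables. The
#' artifact peaks present in the contaminated run shrink after intersection.
#'
#' @name scenario_runner
NULL

scenario_names <- c("best_case", "indel_insert", "indel_error",
                    "fst_id", "fst_rl", "fst_error", "intersection_demo")

# per-scenario design: indels on the variant template + per-sample read
# configs (read length, inner distance mean/sd, error rate)
scenario_design <- function(name) {
  sc <- function(rl, id, sd, e) list(rl = rl, id = id, sd = sd, e = e)
  switch(name,
    best_case    = list(indels = FALSE, samples = list(sc(100, 100, 0, 0))),
    indel_insert = list(indels = TRUE,  samples = list(sc(100, 100, 40, 0))),
    indel_error  = list(indels = TRUE,  samples = list(sc(100, 100, 0, 0.05))),
    fst_id       = list(indels = TRUE,  samples = list(sc(100, 100, 20, 0.01),
                                                       sc(100, 300, 60, 0.01))),
    fst_rl       = list(indels = TRUE,  samples = list(sc(100, 100, 20, 0.01),
                                                       sc(50, 100, 20, 0.01))),
    fst_error    = list(indels = TRUE,  samples = list(sc(100, 100, 20, 0.01),
                                                       sc(100, 100, 20, 0.05))),
    intersection_demo =
                   list(indels = TRUE,  samples = list(sc(100, 100, 20, 0),
                                                       sc(100, 300, 60, 0)),
                        two_mappers = TRUE),
    stop("unknown scenario: ", name))
}

#' Run a named scenario end-to-end
#'
#' Simulates templates and reads, aligns with the oracle, applies the
#' standard filters (mapping quality >= 20, proper pairs), piles up, calls
#' SNPs (min count 2, coverage 10-500) and computes the scenario's scores.
#' Fully deterministic given `seed`.
#'
#' @param name One of `best_case`, `indel_insert`, `indel_error`, `fst_id`,
#'   `fst_rl`, `fst_error`, `intersection_demo`.
#' @param scale Fraction of the full 2 Mbp design (0.02 = 40 kb).
#' @param seed Integer master seed; all stages derive child seeds from it.
#' @param chassis Optional `chassis` to build on; default is a random
#'   chassis of length `round(2e6 * scale)`.
#' @param coverage Target fold coverage per sample (default 200).
#' @param spacing SNP spacing in bp (default 100; fixed across scales so
#'   truth density is preserved).
#' @param min_mapq,min_count,min_coverage,max_coverage Analysis parameters.
#' @param single_end Drop mate 2 and the pair-related filters (the
#'   single-end variant of the designs).
#' @param mismap_rate,mismap_targets_indels For `intersection_demo`: the
#'   second mapper confidently mismaps this fraction of pairs, restricted to
#'   pairs overlapping planted indels when `mismap_targets_indels` is TRUE.
#' @return A `scenario_run` list: `templates`, per-sample `calls`/`sync`,
#'   `summary` (truth scores, single-sample designs), `stats` (site-stat
#'   tables) and `quantiles` (tail-quantile table, two-sample designs),
#'   plus `intersection` for the demo.
#' @export
run_scenario <- function(name, scale = 0.02, seed = 1L, chassis = NULL,
                         coverage = 200, spacing = 100L,
                         min_mapq = 20L, min_count = 2L,
                         min_coverage = 10L, max_coverage = 500L,
                         single_end = FALSE,
                         mismap_rate = 0.5, mismap_targets_indels = TRUE) {
  stopifnot(scale > 0, scale <= 1)
  design <- scenario_design(name)
  if (is.null(chassis))
    chassis <- random_chassis(round(2e6 * scale), seed = child_seed(seed, 10L))
  templates <- build_templates(chassis, spacing = spacing,
                               indels = design$indels,
                               seed = child_seed(seed, 20L))
  two_mappers <- isTRUE(design$two_mappers)

  run_sample <- function(i, mapper = "clean") {
    p <- design$samples[[i]]
    cfg <- sim_config(read_length = p$rl, inner_distance_mean = p$id,
                      inner_distance_sd = p$sd, error_rate = p$e,
                      target_coverage = coverage,
                      seed = child_seed(seed, 30L + i))
    pairs <- simulate_pairs(templates, cfg)
    # The "mismap" mapper fails on indel-carrying (variant-template) pairs
    # of the last sample near a sparse subset of the planted indels (every
    # 10th): such pairs get MAPQ 5 and lose the proper-pair flag, so the
    # standard filter removes them. The surviving counts lose alternative
    # alleles at the flanking SNPs of those indels — a focal, one-library
    # allele-frequency artifact, the failure mode real mappers show at
    # indel-dense regions.
    noisy <- mapper == "mismap" && i == length(design$samples)
    aln <- if (!noisy) {
      oracle_align(pairs, templates)
    } else {
      targets <- if (mismap_targets_indels && nrow(templates$indels))
        templates$indels$pos[seq(1L, nrow(templates$indels), by = 10L)]
        else NULL
      oracle_align(pairs, templates, mismap_rate = mismap_rate,
                   mismap_targets = targets, mismap_template = "var",
                   seed = child_seed(seed, 50L + i))
    }
    if (single_end) {
      aln <- aln[bitwAnd(aln$flag, 0x40L) > 0L, , drop = FALSE]
      aln$flag <- 0L
      attr(aln, "sq") <- c(name = templates$reference$name,
                           length = templates$reference$length)
      aln <- filter_alignments(aln, min_mapq = min_mapq,
                               require_proper = FALSE,
                               require_mapped_pair = FALSE)
    } else {
      aln <- filter_alignments(aln, min_mapq = min_mapq)
    }
    list(config = cfg,
         counts = pileup_counts(aln, templates$reference,
                                max_depth = max(1e5, 10 * coverage)))
  }

  pipeline <- function(mapper) {
    per_sample <- lapply(seq_along(design$samples), run_sample, mapper = mapper)
    sync <- as_sync(lapply(per_sample, `[[`, "counts"))
    calls <- call_snps(sync, min_count = min_count,
                       min_coverage = min_coverage,
                       max_coverage = max_coverage)
    list(configs = lapply(per_sample, `[[`, "config"),
         sync = sync, calls = calls)
  }

  main <- pipeline("clean")
  out <- list(name = name, scale = scale, seed = seed,
              templates = templates, configs = main$configs,
              sync = main$sync, calls = main$calls)

  if (length(design$samples) == 1L) {
    out$summary <- evaluate_run(main$calls, templates$snps)
  } else {
    fst <- fst_pairwise(main$calls)
    fisher <- fisher_pairwise(main$calls)
    out$stats <- list(fst = fst, fisher = fisher)
    qs <- c(0.001, 0.01)
    out$quantiles <- data.frame(
      q = qs,
      fst = vapply(qs, function(q) tail_quantile(fst$stat, q), 0),
      neg_log10_p = vapply(qs, function(q) tail_quantile(fisher$stat, q), 0))
    out$summary <- list(n_compared = nrow(fst),
                        n_true_positive = sum(fst$pos %in% templates$snps$pos))
  }

  if (two_mappers) {
    noisy <- pipeline("mismap")
    fisher_noisy <- fisher_pairwise(noisy$calls)
    out$mapper_b <- list(sync = noisy$sync, calls = noisy$calls,
                         fisher = fisher_noisy)
    out$intersection <- intersect_results(out$stats$fisher, fisher_noisy)
  }
  class(out) <- "scenario_run"
  out
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("<scenario_run> %s @ scale %g (seed %s): %d bp chassis, %d truth SNPs\n",
              x$name, x$scale, x$seed, x$templates$reference$length,
              nrow(x$templates$snps)))
  if (inherits(x$summary, "eval_summary")) print(x$summary)
  invisible(x)
}

#' Run a manifest of scenarios
#'
#' The manifest is a TSV with a header and columns `run`, `scenario`,
#' `seed`, `scale` (lines starting with `#` are comments). Each run writes
#' its own sub-directory (sync file, calls table, summary table, and a
#' `params.tsv` provenance record); a cross-run `summary.tsv` suitable for
#' [rank_sum()] is written at the top level.
#'
#' @param config_path Path to the manifest TSV.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the cross-run summary data.frame.
#' @export
run_manifest <- function(config_path, out_dir) {
  man <- read.table(config_path, sep = "\t", header = TRUE,
                    comment.char = "#", stringsAsFactors = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (i in seq_len(nrow(man))) {
    r <- man[i, ]
    if (!r$scenario %in% scenario_names)
      stop("unknown scenario name: ", r$scenario)
    run <- run_scenario(r$scenario, scale = r$scale, seed = r$seed)
    rd <- file.path(out_dir, r$run)
    dir.create(rd, showWarnings = FALSE)
    write_sync(run$sync, file.path(rd, "sites.sync"))
    write.table(as.data.frame(run$calls), file.path(rd, "calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(key = c("scenario", "seed", "scale"),
                           value = c(r$scenario, r$seed, r$scale)),
                file.path(rd, "params.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    s <- run$summary
    rows[[i]] <- data.frame(
      run = r$run, scenario = r$scenario, seed = r$seed, scale = r$scale,
      n_true_positive = s$n_true_positive %||% NA_integer_,
      n_false_positive = if (inherits(s, "eval_summary"))
        s$n_false_positive else NA_integer_,
      n_extreme_outliers = if (inherits(s, "eval_summary"))
        s$n_extreme_outliers else NA_integer_,
      mean_ref_freq = if (inherits(s, "eval_summary"))
        s$mean_ref_freq else NA_real_,
      fst_q001 = if (!is.null(run$quantiles))
        run$quantiles$fst[run$quantiles$q == 0.001] else NA_real_,
      stringsAsFactors = FALSE)
    if (inherits(s, "eval_summary")) {
      write.table(data.frame(metric = c("n_truth", "n_true_positive",
                                        "n_false_positive",
                                        "n_extreme_outliers",
                                        "mean_ref_freq"),
                             value = c(s$n_truth, s$n_true_positive,
                                       s$n_false_positive,
                                       s$n_extreme_outliers,
                                       s$mean_ref_freq)),
                  file.path(rd, "summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(run = character(), scenario = character(),
               seed = integer(), scale = numeric(),
               n_true_positive = integer(), n_false_positive = integer(),
               n_extreme_outliers = integer(), mean_ref_freq = numeric(),
               fst_q001 = numeric(), stringsAsFactors = FALSE)
  write.table(summary, file.path(out_dir, "summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(summary)
}

#' Interior truth SNPs of a scenario run
#'
#' Truth SNP positions at least one nominal fragment length away from both
#' template edges, where the uniform read layout gives full coverage.
#'
#' @param run A `scenario_run`.
#' @return Integer vector of interior truth positions.
#' @export
interior_truth <- function(run) {
  cfg <- run$configs[[1L]]
  flen <- 2L * cfg$read_length + cfg$inner_distance_mean
  L <- run$templates$reference$length
  snps <- run$templates$snps$pos
  snps[snps > flen & snps <= L - flen]
}
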
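---
title: "Evaluating read mapping for Pool-Seq scans with truth-bearing simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating read mapping for Pool-Seq scans with truth-bearing simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolmapeval)
```

## Motivation and model

Pool-Seq infers population allele frequencies from the per-site composition
of reads sequenced from a pooled DNA sample. A site covered by $n$ reads of
which $k$ carry the alternative allele estimates $f = k/n$; genome-wide
scans then flag sites where $f$ differs between samples more than sampling
noise permits. Any process that systematically misplaces reads — alignment
near indels, ambiguous placements, differences between libraries in read
length or insert size — distorts $k/n$ locally and creates spurious
differentiation outliers that are indistinguishable, statistically, from
biological signal.

`poolmapeval` makes this failure mode measurable by construction. The
simulation substrate is a pair of haploid templates:

* the **reference chassis**, any A/C/G/T sequence (a slice of a real
  chromosome via `build_chassis()`, or a random sequence via
  `random_chassis()` — the variation is planted, so the chassis identity is
  immaterial to the design);
* the **variant chassis**, derived from it by substituting a random
  non-reference allele at every `spacing`-th position (default 100 bp,
  positions $100, 200, \dots \le L - 1$) and, optionally, inserting one
  indel between each pair of adjacent SNPs.

Reads are drawn from the two templates in exact 1:1 proportion, so every
planted SNP has a known population frequency of 0.5 and every planted indel
is in complete linkage disequilibrium with the surrounding SNPs — which is
precisely what makes indel-driven allele-frequency distortion visible: a
mapper (or a filter) that treats indel-carrying reads differently from
reference-matching reads shifts $f$ away from 0.5 at the flanking SNPs.

A pipeline run is then scored against this truth: *true positives* (called
SNPs at planted positions), *false positives* (calls anywhere else; with
error-free reads these can only be alignment artifacts), *extreme outliers*
(true positives with $|f - 0.5| > 0.4$), and the mean estimated
reference-allele frequency.

## Parameters and defaults

| parameter | default | unit | rationale |
|---|---|---|---|
| SNP spacing | 100 | bp | truth density: one SNP per typical read |
| indel length rate λ | 1 | — | zero-truncated Poisson; mean λ/(1−e^{−λ}) ≈ 1.58 |
| read length | 100 | bp | standard short-read length |
| inner distance | 100 ± 0 | bp | gap between the *inner* ends of a pair |
| per-base error rate | 0–0.05 | — | 0 isolates alignment effects; 5% stresses them |
| base quality | 40 | Phred | uniform; real quality profiles are out of scope |
| target coverage | 200 | fold | enough that binomial noise in $f$ is small |
| MAPQ filter | ≥ 20 | — | standard ambiguity cutoff (strict variant: 40) |
| SNP min count | 2 | reads | summed across samples |
| coverage bounds | 10–500 | fold | per sample, A+T+C+G only |
| outlier rule | \|f−0.5\| > 0.4 | — | strict inequality (f = 0.9 is not an outlier) |

A note on conventions: the *inner distance* $d$ is the gap between the
inner ends of the two reads, so the fragment length is $2 \cdot rl + d$ and
the start-to-start distance (the convention some mapper configurations use)
is $rl + d + rl$. This is stated prominently because the two conventions
are easy to confuse when configuring external mappers.

## The scenarios

`run_scenario()` packages the named experimental designs. `scale`
multiplies the chassis length (default full design: 2 Mbp, 200×; scale 0.02
= 40 kb) while the SNP spacing stays fixed, so truth density is preserved:
a 2 Mbp chassis carries exactly 19,999 truth SNPs, a 40 kb chassis 399.

Single-sample designs, scored against truth: `best_case` (2×100 bp,
100±0 bp, error 0, no indels), `indel_insert` (100±40 bp, indels),
`indel_error` (100±0 bp, 5% errors, indels). Two-sample designs, where both
samples come from the *same* templates so any differentiation is technical:
`fst_id` (inner distance 100±20 vs 300±60, 1% errors), `fst_rl` (read
length 100 vs 50), `fst_error` (1% vs 5% errors); these report per-site
FST and Fisher tables and their tail quantiles (the "lowest value inside
the top-q tail" order statistic, without interpolation).

`intersection_demo` stages the artifact-removal strategy end to end: two
libraries with different insert-size configurations, mapped once by a clean
oracle and once by an oracle that fails on indel-spanning variant-template
pairs of one library near a sparse subset (every 10th) of the planted
indels. The failing pairs receive MAPQ 5 and lose the proper-pair flag, so
the standard filter removes them — the surviving counts lose alternative
alleles at the flanking SNPs of those indels, a focal, one-library
allele-frequency artifact. Intersecting the two mappers' Fisher tables
(keeping the minimum −log10 *p* per shared site) removes these peaks, which
the test suite asserts as a strict decrease of the count of sites above a
fixed threshold.

## What the oracle aligner does and does not emulate

The oracle places every pair at its true reference coordinates: MAPQ 60,
proper-pair flag set, variant-template reads projected through the
template coordinate map so that CIGARs carry the planted indels (read bases
inside insertions at read edges are soft-clipped). Its mismapping model is
deliberately simple — with probability `mismap_rate`, an eligible pair is
relocated uniformly at random with a configurable MAPQ, optionally
restricted to pairs overlapping given positions and/or to variant-template
pairs. Two regimes are useful: low-MAPQ/improper mismapping emulates a
mapper that signals its own uncertainty (the filters then remove exactly
those pairs, which the tests assert), while confident mismapping
(`mismap_proper = TRUE`, high MAPQ) emulates the dangerous case that
survives filtering.

Real mappers differ in ways the oracle does not model: MAPQ scales are
tool-specific, misplacement is not uniform but concentrated at repeats and
paralogs, and local aligners soft-clip rather than relocate. Passing the
package's tests therefore demonstrates correctness of the *pipeline
machinery* and the direction of the artifact/intersection effects, not the
ranking of any real mapper.

## Numerical and design choices

* **Coordinates** are 1-based and fully closed throughout, matching
  mpileup/sync conventions.
* **SNP placement** uses multiples of the spacing up to $L - 1$ (the final
  chassis position is excluded); this is the only placement consistent with
  19,999 SNPs on 2 Mbp at 100 bp spacing.
* **Indels**: kind is insertion or deletion with probability 0.5 each (the
  design brief does not fix a ratio); insertion sequences are uniform
  random; positions are uniform in the open inter-SNP interval, and a
  deletion must fit strictly inside it (redrawn otherwise, bounded retries).
* **Read layout**: fragment starts are equally spaced on
  $1 \dots L - \text{fragment} + 1$ — truncated at the template end, not
  wrapped — accepting a coverage ramp at the edges; evaluation can restrict
  to interior sites (`interior_truth()`). Inner-distance draws are
  Normal(mean, sd) rounded to integers and floored at 0 (no
  overlapping-read simulation).
* **Counting** delegates to the `Rsamtools` pileup engine configured to
  match `samtools mpileup -B` semantics (no BAQ realignment): M/=/X bases
  count at their reference positions, deleted reference positions are
  tallied in a separate `del` column, inserted bases count nowhere.
  **Coverage means A+T+C+G only**; N and del tallies are carried but never
  enter coverage bounds. Deletion-spanning reads thus reduce effective
  coverage at deleted positions, which is what makes indel-adjacent
  distortion observable.
* **Sync format**: PoPoolation2 dialect, no header; forward-strand totals
  (which the sync format cannot carry) travel in a `.strand` side file.
* **FST** is the classical π-based estimator with the unweighted mean of
  the two sample frequency vectors as the pooled frequency, clamped to
  [0, 1], undefined (dropped) at pooled-monomorphic sites. No pool-size
  bias correction is applied; the estimator is the plain formula stated
  here, and numeric parity with any external implementation's corrected
  variants is explicitly not claimed.
* **Fisher** uses the standard two-sided exact rule (sum of probabilities
  of all tables at most as probable as observed); degenerate tables score
  0. **Multi-allelic sites** (a third allele reaching the min count) are
  flagged and excluded from FST/Fisher/CMH, whose 2×2 machinery is
  undefined there.
* **CMH** accumulates the hypergeometric mean and variance per stratum;
  degenerate strata contribute nothing, all-degenerate gives $p = 1$; the
  continuity correction is off by default (a flag enables it) since
  correction conventions differ between implementations. The single-stratum
  case reduces to the score chi-square, which the tests verify against an
  algebraically distinct closed form, and multi-stratum results are checked
  against `stats::mantelhaen.test`.
* **Ties**: the strand-bias filter removes exactly
  $\lfloor \text{fraction} \cdot N \rfloor$ sites, breaking SB ties by
  genomic order; rank-sum tables use average ranks for ties (so rank-sums
  may be non-integer on small sets); tail quantiles are order statistics
  shared by tied values.
* **Intersection** is position-level: a site must be present in both
  inputs, and the minimum statistic is kept. Requiring agreement on allele
  identity as well would be a stricter variant; position-level matching is
  the implemented definition.

## Problem sizes and determinism

Desk-scale runs use 0.5–5% of the full design (10–100 kb, 200×), keeping a
full pipeline run in seconds to tens of seconds; the full 2 Mbp truth
construction itself takes well under a minute. The test suite runs the
best-case pipeline at scales 0.005–0.02, the null-comparison FST bound at
scale 0.05, and the intersection demonstration at scale 0.01. Every
stochastic stage draws from a child seed derived from one master seed, so
any run — including the acceptance script — is exactly reproducible, and
truth tables record their parameters in `#` header lines.

## Limitations

The simulator omits position- and cycle-dependent error profiles, quality
simulation, adapter contamination, PCR duplicates, variable post-trimming
read lengths, multi-chromosome references, and structural variants beyond
short indels. Low-frequency alleles are deliberately not simulated: planted
SNPs segregate at 0.5, where mapping errors have the strongest effect on
frequency estimates and where differentiation tests are most sensitive.
Results on real data additionally depend on mapper-specific MAPQ scales and
library-preparation effects that no simulation here captures.
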
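---
title: "Calling crosslink sites and integrating RNA-binding-protein targets with clipxl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling crosslink sites and integrating RNA-binding-protein targets with clipxl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipxl)
```

## Scope and model

`clipxl` analyses iCLIP experiments in which an RNA-binding protein is
immunoprecipitated from UV-crosslinked tissue and the truncation points of
the sequenced cDNAs mark the protein–RNA contact sites. The package covers
the path from demultiplexed reads (or aligned read tables) to a
control-subtracted set of target transcripts, the sequence context of the
binding sites, and the integration of those targets with RIP-seq,
differential-expression and splicing evidence.

The statistical model is deliberately simple and nonparametric. Within one
transcript region, crosslink events at position $x$ are summed over a
$\pm$`flank` window to give a height $h(x)$; the observed tail probability
$P(h) = \sum_{i \ge h} n_i / N$ (with $n_h$ the number of crosslinked
positions of height $h$ and $N$ their total) is compared against the same
number of events thrown uniformly over the region. Writing $\mu_h$ and
$\sigma_h$ for the mean and standard deviation, across background draws,
of the random tail statistic at height $h$, the per-height false discovery
rate is
$$\mathrm{FDR}(h) = \frac{\mu_h + \sigma_h}{P(h)},$$
and a position is significant when $\mathrm{FDR}(h(x)) < \alpha$. The
uniform background is the null model: it asserts only that, absent
binding, truncations scatter evenly within a region. Working per region
(5′ UTR, concatenated coding exons, introns, 3′ UTR) keeps regions with
very different coverage from contaminating each other's background.

Two quantities are deliberately kept distinct. $N$, the number of distinct
crosslinked positions, normalises the tail probability so that
$\sum_h n_h = N$ and $P$ is a proper tail probability; the number of
*events* (reads after deduplication) is what the background redistributes.
The prose description of $\mu_h, \sigma_h$ admits two readings — moments
of the random tail *probability* or of the random tail *count*. The
package defaults to the probability reading, which keeps the FDR a
unit-free ratio of exceedance probabilities; `background_stat = "count"`
selects the count reading, rescaled by $N$ so both modes share units.
In practice the two orderings of sites agree; the choice matters only in
regions where background draws occupy many fewer positions than the
observed track.

## Stability, consensus and controls

Because the background is itself random, the entire significance
assignment is rerun (default 1000 times, each with 100 fresh draws), and
only positions significant in at least 95% of reruns survive. This
suppresses positions whose significance depends on lucky background
draws, which matters most in long regions with few crosslinks.

Biological reproducibility is enforced at nucleotide resolution: a
consensus site must be called at the identical coordinate in at least
$R - 1$ of $R$ replicates (both, when $R = 2$). Requiring all $R$ was
found too strict in practice because crosslinks scatter over a few
nucleotides around a contact; "all but one" is the compromise the
package encodes as the default, and `min_support` exposes it.

Control libraries (GFP-only, RNA-binding-dead protein variants) are
processed by the identical pipeline per control group, with a group-level
consensus threshold that defaults to 2 supporting replicates. Any gene
owning a control consensus site is removed *entirely* from the treatment
targets — site-level subtraction would leave sibling sites of a sticky
transcript in place. Control subtraction operates on group consensus
rather than any single replicate's calls; that is the stricter and more
reproducible of the two possible readings.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `flank` (calling) | 15 | nt | height window half-width |
| `n_draws` | 100 | draws | background simulations per rerun |
| `n_reruns` | 1000 | reruns | stability resampling |
| `alpha` | 0.05 | – | FDR threshold, strict `<` |
| `stability` | 0.95 | fraction | minimum share of significant reruns |
| `min_support` | R−1 (2 if R=2) | replicates | consensus threshold |
| `control_min_support` | 2 | replicates | control-group consensus |
| `flank` (motifs) | 10 | nt | 21-nt windows around sites |
| `n_background` | 100 | draws | pentamer background |
| RIP gates | TPM ≥ 5, log2FC ≥ 0.5, q < 0.001 | – | enrichment filter |
| DEG gates | q < 0.05, TPM > 1 | – | differential expression |
| PSI gates | \|ΔPSI\| > 0.1, p < 0.01 | – | splicing filter |

The RIP fold-change gate is `>= 0.5` by default with a `strict = TRUE`
mode using `> 0.5`; published descriptions use both phrasings and the
boundary case is rare, but the package exposes both so either convention
can be reproduced exactly. Percentages in overlap reports are rounded
half-away-from-zero at the requested precision, matching how such values
are printed, rather than R's round-half-even.

## Coordinate and sequence conventions

All internal coordinates are 0-based half-open; GFF3 (1-based inclusive)
is converted on read and BED output stays 0-based. The representative
model per gene is the mRNA with the greatest summed exonic length, ties
broken by the lexicographically smallest transcript id — annotation
sources name a representative model but not a selection rule, so the rule
here is deterministic and documented. "Exon" in the region partition
means *coding sequence*; UTR exonic intervals are never double-counted.
Introns located inside UTR genomic spans are assigned to the intron
region: the partition is by splicing status first, which keeps intron
windows from absorbing UTR-specific signal. Truncation sites are
`start − 1` for plus-strand reads and the half-open `end` for minus-strand
reads — in both cases the genomic base immediately 5′ of the read in
transcript orientation. Windows at chromosome ends are clipped and
flagged, not discarded, so motif steps can decide their own policy.

PCR deduplication keys on the *full read sequence plus the random barcode*
(UMI), not on mapping position: two reads are duplicates only if both
agree, which is the conservative reading of barcode-based deduplication
and avoids collapsing genuinely distinct molecules that merely share a
truncation point. The "quality score of 20" filter is interpreted as mean
Phred ≥ 20 (configurable to a min-base rule).

## The synthetic-data generator

Every stage is testable without downloads because the `synthetic_data`
functions generate inputs with the statistical structure the analysis
assumes, plus the planted truth:

* a random genome and GFF3 with genes on both strands (5′ UTR, coding
  exons with introns, 3′ UTR; UTR-internal introns are not generated —
  that corner is covered by hand-written fixtures in the tests);
* per-replicate truncation events: uniform Poisson background
  (default 60 events per region per replicate over regions of a few
  hundred nucleotides, i.e. an expected window height of 4–5, the sparse
  regime the FDR procedure assumes) with planted point signal at 10× the
  expected background window height, matching the recovery condition the
  pipeline is designed for; five treatment replicates, a three-replicate
  GFP-like control group and a two-replicate binding-dead-like group,
  mirroring the experimental design;
* FASTQ molecules with experimental barcodes, UMIs and geometric PCR
  duplication for the demultiplexing path;
* negative-binomial RIP/poly(A)/RNA-seq count tables (dispersion 0.05,
  three replicates) with planted log2 enrichment and DEG effects, plus a
  convenience wrapper around edgeR to turn them into the log2FC/p/q
  tables the filters consume — the filters themselves never run a
  differential test, they consume statistics, as in the real pipeline
  where edgeR/SUPPA provide them;
* two-isoform TPM tables with binomially sampled inclusion at depth 1000
  and planted ΔPSI shifts of 0.3.

What passing tests on these data do *not* show: robustness to
non-uniform within-region background (expression gradients, mappability),
crosslink-induced mutations/deletions, overlapping gene models, or
alignment artefacts — real libraries contain all of these, and the
uniform-background null is the model's known simplification.

## Numerical choices and degenerate inputs

Tail probabilities are ratios of small integers and exact in double
precision; all threshold comparisons are strict (`FDR < alpha`,
`q < 0.001`, `TPM > 1`, `|ΔPSI| > 0.1`) so boundary fixtures behave
deterministically. Heights never reached by the background give
$\mu = \sigma = 0$ and hence FDR 0 — a height the background cannot
produce is evidence, not a division-by-zero. Empty tracks yield empty
(not failing) results; an empty region with events to place is an error.
Zero-variance pentamers with observed excess are reported as `Inf` with a
flag and rank top rather than being given an arbitrary large number. The
exact 3-vs-3 replicate permutation test for ΔPSI has a smallest
achievable p of $1/\binom{6}{3} = 0.05$; with the default `p < 0.01` gate
this means permutation p-values alone can never declare significance at
three replicates — externally supplied p-values (as from a dedicated
splicing tool) or more replicates are required, and the package keeps
both routes open.

## Problem sizes used in the tests

The test-suite and acceptance computations run the procedure at reduced
resampling depth — 50 reruns of 25 draws, regions of a few hundred to
2000 nt, 200 background events, 20 seeds for calibration runs, two full
pipeline seeds for recovery — chosen as the smallest sizes at which the
calibration and recovery properties are statistically meaningful. The
defaults (1000 reruns × 100 draws) remain those of the procedure itself.

## Known limitations

* One representative model per gene: no multi-isoform region partitions.
* Alignment, adapter trimming beyond exact matching, negative-binomial
  dispersion estimation, motif discovery itself (MEME) and splicing-event
  classification are consumed as inputs or prepared for, not performed.
* A position overlapped by two same-strand genes is assigned to both;
  antisense events are binned separately and excluded from motif windows.
* The uniform background makes no attempt to model 3′ coverage bias or
  crosslinking sequence preference; enrichment near U-rich sequence
  should be interpreted with the UV crosslinking U-bias in mind.
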
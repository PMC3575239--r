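---
title: "Estimating constrained sequence with the Neutral Indel Model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating constrained sequence with the Neutral Indel Model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nimtools)
```

## The question and the model

Most functional sequence in vertebrate genomes is noncoding, so counting
protein-coding bases badly underestimates how much of a genome selection
actually cares about. The Neutral Indel Model (NIM) sidesteps annotation
entirely: it asks where insertions and deletions have *failed* to accumulate
between two genomes. If neutral indels strike uniformly at random at rate
$p$ per base, the length $l$ of an inter-gap segment (IGS) — a maximal
ungapped run of aligned columns between gap delimiters — is geometric, and
the expected count of segments of length $l$ falls on a straight line in
log space:

$$\ln E(l) = a + l\,\ln(1 - p).$$

Functional elements purge indels, so they sit inside unusually long IGSs.
The observed counts $O(l)$ therefore exceed the neutral line at large $l$,
and that excess measures shared constrained sequence directly.

The estimator proceeds per G+C bin (indel rates covary with base
composition, so the genome is cut into equally populated GC bins first):

1. fit $a$ and $b = \ln(1-p)$ by count-weighted least squares of
   $\ln O(l)$ on $l$ over a short-length window; $\hat p = 1 - e^{b}$ and
   $K = 1/\hat p$ is the mean neutral spacing between indels;
2. choose a threshold $l^\*$ beyond the fit window where the fitted tail
   probability drops below 1%;
3. accumulate the excess, with the fitted tail summed in closed form:
   $S = \sum_{l \ge l^\*} (O - E)$ segments and
   $B = \sum_{l \ge l^\*} l\,(O - E)$ bases;
4. correct for the neutral bases that every excess segment still carries.
   An indel-purified segment contains between $K$ and $2K$ neutral bases
   depending on how functional elements cluster inside it, giving

$$\text{lower} = B - 2K\,S, \qquad \text{upper} = B - K\,S,$$

clamped at zero per bin and summed across bins.

A deliberate design choice: $S$ and $B$ sum the *signed* difference
$O - E$ over the tail rather than the per-length positive part
$\max(0, O - E)$. At tail lengths the expected count per individual length
is far below one, so a positive-part sum would convert every observed
neutral segment into nearly a full unit of "excess" and acquire a large
positive bias — under a purely neutral simulation it reports hundreds of
kilobases of phantom constraint. The signed sum is unbiased under the null
(its fluctuations are clamped at zero per bin) and identical to the
positive-part sum in the regime that matters, where observed counts
dominate a negligible expectation.

## What the simulator emulates

`simulate_alignment()` realises exactly the null the NIM assumes, plus the
signal it is meant to detect:

* an ancestral sequence with a per-window (default 10 kb) target GC
  profile;
* non-overlapping constrained elements covering `constrained_fraction` of
  the ancestor, placed uniformly or (optionally) biased toward high-GC
  windows;
* on each of two branches, indel events at `indel_rate` per neutral base —
  insertion or deletion with equal probability, geometric lengths (mean 3
  by default; the length law is a free parameter because nothing in the
  estimator depends on it) — with events whose footprint would touch a
  constrained element redrawn elsewhere, so elements are *exactly*
  indel-free;
* substitutions applied everywhere, constrained or not.

Because both branches are evolved from the ancestor with full event
bookkeeping, the emitted pairwise alignment is the true alignment, not a
re-inferred one, and the truth ledger (element intervals, event tables,
per-window constrained bases) supports exact recovery tests. Rejection
rather than rate-suppression of indels in elements matches the model's
idealisation of constraint as complete indel purging.

What the simulator does *not* emulate — and therefore what passing tests do
not establish about real data: alignment error (real gap placement is
inferred, not known), context-dependent or clustered indel processes,
partial constraint (elements that merely slow indels), lineage-specific
element turnover, and realistic substitution models. On real alignments the
estimates inherit all of those as systematic uncertainties; the K-versus-2K
spread is a model-internal bracket, not a confidence interval.

## Parameters that matter

* **`indel_rate`** (default 0.005/base/branch): sets the neutral spacing
  $K \approx 100$ bases for a two-branch comparison, a density comparable
  to moderately diverged bird genome pairs.
* **GC windows and bins** (defaults 10 kb, 20 bins): bins are *equally
  populated in aligned bases* — windows are ranked by GC and the
  cumulative aligned-base weight is cut into equal shares — so every bin's
  fit rests on similar amounts of data.
* **Fit window** (default 2–50 bp): length-1 segments are excluded as
  alignment-artifact-prone. The window must balance two pressures: its
  upper end has to stay below the lengths that functional elements
  generate, but the slope's relative error scales inversely with the
  window's span times the root of its segment count, and the error is
  amplified by $e^{\hat p\,l^\*}$ when the line is extrapolated to the
  excess threshold. At whole-genome scale (hundreds of thousands of
  segments per bin) 2–50 bp is comfortably stable. For the 10 Mb
  simulations used throughout the tests and the acceptance script we use
  `fit_window = c(2, 300)`: the simulations contain no functional lengths
  below 500 bp, so lengths up to 3 K are guaranteed neutral there, and the
  wider window is needed for per-bin slope errors of a few percent at that
  problem size. Both choices are reported in the fit objects.
* **`l_star`**: by default the smallest length past the fit window where
  the fitted tail probability is below 1% (preferring the first such
  length with an observed excess). The published method never states where
  "long" begins; this rule keeps the expected neutral tail beyond $l^\*$
  around 1% of segments, small against any real signal.
* **`min_segments`** (default 1000): bins with fewer segments in the fit
  window are flagged low-confidence and dropped from the aggregate.
* **Sex chromosomes and unplaced scaffolds** (default pattern
  `chrZ|chrW|chrUn|random`) are excluded: their indel dynamics differ from
  autosomes, and the neutral expectation is an autosomal one.

Numerical details: zero-count lengths inside the fit window are dropped
from the regression (their log is undefined) but the fitted expectation is
evaluated everywhere; fits whose counts fail to decay raise an error and
the bin is reported unusable rather than contributing nonsense; block-edge
segments are length-censored and excluded from histograms by default;
consecutive gap columns collapse to a single delimiter (one indel event),
including mixed-row gap runs.

## Problem sizes used in the tests

The statistical guarantees are exercised at 10 Mb with
$\theta = 0.005$/base/branch: three neutral-only runs must show an
aggregate upper bound at or below 1% of aligned bases (observed:
0.02–0.04%), and ten seeded runs at each constrained fraction of 5%, 10%
and 20% (500 bp elements) must bracket the planted truth within
$[0.75\,\text{lower},\ 1.25\,\text{upper}]$ in at least nine of ten runs.
Unit-level checks run at 0.05–1.2 Mb. Genome-scale published quantities
(tens of megabases of constrained sequence between real bird genomes)
require the real whole-genome alignments and are out of scope for the
test suite.

## The companion toolsets

**Assembly QC.** `genome_size_from_coverage()` divides total sequenced
bases by the modal per-base depth ("peak" read as the mode of the integer
coverage histogram). `euchromatic_completeness()` triangulates: sequence
aligned between two outgroups but absent from the target is counted as
missed. `splice_site_substitution_rate()` audits the four GT..AG
dinucleotide nucleotides of every canonical reference intron in the aligned
target — these positions are so conserved that apparent substitutions there
estimate the assembly's base-call error rate; unaligned sites leave the
denominator, non-canonical reference introns are skipped and counted.
`indel_error_upper_bound()` counts three-way alignment gap events private
to the target (disagreeing with outgroup *and* sister); assuming no true
target-lineage indels makes this an upper bound on assembly indel error.
Percentages are reported to the integer and rates to two significant
figures, matching conventional reporting.

**Filter cascade.** The codon-alignment filters run in a fixed order —
external masks, gap columns, phred ≤ 30 codons (inclusive boundary), the
sliding 15-nt/>5-substitution window between the focal species pair
(sliding is the stricter reading of an ambiguous prescription; tiled mode
is available), single-pass 7-codon flanks, then the discard rule
(< 100 codons or < 10% of predicted). The window filter counts mismatches
on the columns that survive the earlier rules, the order in which the
rules are stated; gaps and Ns never count as substitutions (other rules own
them). Flanks deliberately do not cascade: only pre-existing removals seed
them. Every removal is ledgered, the kept set only shrinks, and replaying
the ledger reproduces the filtered alignment byte for byte.

**Site enrichment.** The test universe is *sites*, not genes: all filtered
codon sites of all tested genes, of which the positively selected sites are
the marked subset. Annotations are first closed over `is_a` parents
(`part_of` optional — "parental" is underspecified in common usage), each
term with at least one annotated site receives an upper-tail hypergeometric
p, and Bonferroni multiplies by the number of tested terms (counting only
testable terms by default, since untestable ones would inflate the
correction arbitrarily; a flag switches to all terms).

## Known limitations

* The NIM measures *shared* constraint: sequence functional in only one
  lineage contributes gaps like neutral sequence and is invisible.
* The geometric fit assumes a single indel rate per bin; residual rate
  heterogeneity within bins fattens the observed tail and inflates the
  bounds. Equal-population GC binning mitigates but cannot remove this.
* Elements shorter than about one $K$ sit inside segments the neutral tail
  also produces and are partially absorbed into the fit; recovery tests
  use 500 bp elements ($5K$) where detection is essentially complete.
* The splice audit attributes every splice-dinucleotide difference to
  assembly error; true lineage-specific splice-site turnover exists at a
  low rate, so the estimate is conservative (an upper bound).
* The hypergeometric enrichment treats sites within a gene as
  exchangeable; clustering of selected sites within genes makes the test
  anti-conservative, which the Bonferroni correction does not repair.
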
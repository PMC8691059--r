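---
title: "Estimating structural-variation-causing mutation rates from MA lines"
author: "svcmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating structural-variation-causing mutation rates from MA lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svcmr)
```

## The measurement problem

A mutation-accumulation (MA) experiment propagates many lines from a
small set of ancestral genotypes by single-progeny descent, so that
selection is nearly powerless and spontaneous mutations accumulate at
their intrinsic rate. After `g` generations each line is whole-genome
sequenced and compared with its ancestor. For structural variants the
observable unit is an *event* — an insertion, deletion, tandem
duplication, or copy-number change — and the estimand is the
structural-variation-causing mutation rate (svcMR): events per base
pair (or per gene) per generation.

svcmr implements the analysis layer of such an experiment for a
multi-genotype, multi-population design: nine ancestral genotypes from
three populations, 66 MA lines, 819 line-generations in total, and
53–71 Mb of callable genome per genotype are the default study
dimensions of the synthetic generator. The package deliberately starts
*after* variant calling: its inputs are per-line event tables,
per-line metadata, gene annotations, and (for the validation loop)
reference contigs. Read mapping and SV calling are out of scope.

## Event categories and why the channel decides

Six categories are used throughout: short insertions and deletions
(< 50 bp), long deletions and tandem duplications (≥ 50 bp), and
deletions and duplications at copy-number-variable (CNV) sites
(≥ 2,000 bp). Short and long events are detected from split/discordant
reads; CNV events from read depth. The long-deletion and CNV-deletion
length ranges overlap, so length alone cannot classify an event.
`classify_events()` therefore treats the *detection channel* as the
category authority: a read-depth event is a CNV (and must be at least
the CNV minimum length); a split-read event is short or long by the
50 bp threshold. All three boundaries (49/50/2,000 bp) live in
`category_spec()` and are configurable. We do not deduplicate across
channels: a split-read deletion above 2 kb and a read-depth deletion at
the same locus would both be counted, because the upstream pipelines
that produce the two tables are independent; users who merge calls
should do so before import.

A split-read tandem duplication under 50 bp is recorded as a short
insertion — its detectable signature is inserted sequence — and a
split-read insertion of 50 bp or more is rejected as contradictory,
since the long categories contain only deletions and tandem
duplications.

CNV semantics: deletions at CNV sites carry a copy-number change
between −1.0 (homozygous loss) and −0.5 (loss of one of two copies);
duplications always +0.5 (one extra copy over the diploid pair).

## Rate estimators

For category \(i\) in one MA line with \(x_i\) events of lengths
\(l_{i,j}\), \(g\) generations, \(n\) callable sites, and \(m\)
annotated genes:

\[
u_i = \frac{x_i}{2gn}, \qquad
v_i = \frac{\sum_j l_{i,j}}{2gn}, \qquad
w_i = \frac{y_i}{2gm},
\]

with the factor 2 for diploidy; \(y_i\) counts genes overlapped by
events of category \(i\). The total-length and net-length rates are
\(\sum_i v_i\) and \(\sum_i c_i v_i\), where \(c_i = +1\) for
insertions and duplications and \(-1\) for deletions; the net rate
measures genome-size drift and is expected to hover near zero when
insertion and deletion processes balance.

Within one line, \(v_i = u_i \times \bar{l}_i\). That identity does
**not** survive averaging across lines with unequal exposures, which is
why a length-adjusted column in a summary table is not the product of
its neighbours; a regression test keeps this property visible.

### Aggregation and confidence intervals

Genotype, population and species-wide point estimates are unweighted
means of per-line rates, *including* lines with zero events — a
species-wide CNV rate is diluted by the populations in which no CNV was
observed, by design. Per-line denominators are each line's own
\(2gn\); lines never share denominators. A pooled estimator
(\(\sum x / \sum 2gn\)) is available behind the `pooled` flag of
`rate_table()` for comparison; it down-weights low-exposure lines and
differs from the line mean whenever exposures are unequal.

No distributional form for the CIs is imposed: we use a seeded
nonparametric percentile bootstrap over MA lines, 10,000 replicates by
default. With mostly-zero per-line rates this reproduces the
characteristic zero-truncated lower bounds of sparse categories
naturally. Simulation shows the interval is honest but slightly
anticonservative at very low expected counts: coverage of a true rate
is about 89% when a category expects ~25 events study-wide and
93–96% at ≥ 60 expected events (the regime the package's own
acceptance checks run in, using 100 replicate experiments at a 10 Mb
callable genome and ~65 expected events per category, with 2,000
bootstrap replicates inside the loop purely to keep the suite fast).

`coefficient_of_variation()` summarizes across-genotype dispersion as
sample-sd/mean, the package's measure of intraspecific rate variation;
it is flagged `NA` when the mean is zero.

## The synthetic experiment generator

`simulate_experiment()` draws, for each line and category, a Poisson
event count with mean \(r_i \cdot 2gn\) — a constant per-generation
mutation process with independent events is the natural null for an MA
design — then places events uniformly on the genome, rejection-sampling
until a line's events are pairwise disjoint (so they can later be
spiked into a sequence). Defaults encode the emulated study: 66 lines
as 7/7/8 per genotype within each of three populations; a fixed
12-or-13-generation pedigree summing to 819 (mean 12.4); 60 Mb of
callable genome; and species-wide per-category rates (in units of
10⁻¹⁰ per bp per generation: insertions 2.72, deletions 10.68, long
deletions 0.98, tandem duplications 0.06, CNV deletions 3.05, CNV
duplications 3.48) applied homogeneously across populations. The
observed study was heterogeneous — CNVs appeared only in one
population — and tests that need such structure configure per-population
rates explicitly.

Event lengths are artifact choices, since forward-simulation length
models are not part of the emulated study's published description:
short indels are geometric on 1..49 with mean ≈ 3.7 bp; long events
log-uniform on [50, 6000] bp; CNV lengths are 1,000 bp multiples on
[2000, 10000], reflecting the quantized resolution of read-depth
calling. All are configurable. A configuration whose expected total
event footprint exceeds 10% of the genome is rejected: the
disjoint-event model (and the biology it mimics) breaks down there.

What the generator does *not* emulate: sequencing error, read-level
artifacts, mapping bias, heterozygosity, and calling-pipeline false
negatives. Tests passing on synthetic data therefore validate the
*estimators and their calibration*, not any particular caller's
sensitivity; the spike-in loop below exists precisely to separate those
concerns.

## Gene overlap and the resampling null

An event overlaps a gene when their half-open intervals share at least
1 bp; a gene is completely deleted/duplicated when the union of one
line-and-category's events covers more than 95% of its length. Each
gene counts once per line per category even when hit twice. Overlap
uses interval trees (GenomicRanges); a brute-force all-pairs scan is
kept in the test suite as an independent oracle.

`resample_null()` asks whether events hit genes more or less often than
chance: each observed event is re-placed uniformly at random *on its
original contig with its original length* — preserving the per-contig
event density and length spectrum while randomizing position — 1,000
times, and the observed gene-overlapping event count is compared with
the empirical 5th/95th percentile band (nearest-rank; ties count as
"within"). Placement is clamped so events never run off a contig,
keeping replicate event counts equal to the observed count. When the
null is true this verdict lands "within" about 90% of the time — the
band is a 90% interval plus a small discreteness excess — which the
acceptance suite verifies over 500 seeded trials at the observed event
spectrum (121 events across five 200 kb contigs, 150 genes of 2 kb).
The null can be run pooled per category (default) or per line.

## Statistical layer

Omnibus population effects on per-line rates use Kruskal–Wallis (base
R, tie-corrected) with a hand-implemented Dunn post hoc on mean ranks
(tie-corrected variance, Holm adjustment) — no Dunn implementation
ships in the dependency set, so the package authors its own and checks
it against manual rank arithmetic. Insertion-vs-deletion comparisons
use paired t (per-line rates; df = lines − 1) and Welch t (event
lengths). Cross-category Pearson correlations report per-pair t tests
on genotype-level rates (df = genotypes − 2), raw p by default with
Holm alongside, since with nine genotypes and many zeros the power is
limited either way.

For population effects on *counts*, a full binomial GLMM with a
per-line random effect is deliberately not re-fitted: with one
observation per line the random effect acts as an overdispersion
device, poorly identified at this size. Instead
`population_effect_binomial()` fits a binomial GLM of counts on the
\(2gn\) exposure with population as fixed effect and tests the
likelihood-ratio statistic two ways — asymptotic \(\chi^2_{k-1}\), and a
seeded parametric bootstrap from the fitted common-rate null (199
replicates by default; 99 inside the calibration loops). Simulated
type-I error at \(\alpha = 0.05\) is 3–7% for both omnibus tests under
null Poisson count data at study-scale exposures.

## Spike-in validation loop

`spike_events()` writes classified events into reference contigs:
deletions remove their interval, insertions add seeded random bases,
tandem and CNV duplications insert one extra copy immediately after the
duplicated segment (a +50% CNV on a diploid is represented as one
haplotype edit; diploidy re-enters only through the \(2gn\)
denominator). Edits are applied right-to-left so coordinates compose,
and a per-line liftover table maps reference to mutated positions.

`oracle_caller()` closes the loop without external tools: it recovers
events by anchored diff — scan the common prefix, then find the
smallest reference-skip (deletion) or mutated-skip (insertion) that
re-synchronizes a 30 bp anchor. An inserted segment of ≥ 50 bp equal to
its adjacent reference window is reported as a tandem duplication.
This is exact whenever events are separated by at least one unmutated
base and breakpoints are not anchor-length periodic; the test suite
holds it to zero false discoveries and zero false negatives over 100
seeded configurations with ≥ 50 bp separation.

`match_calls()` scores any call set against truth: same contig and
category family (insertion/deletion/duplication), breakpoints within a
10 bp tolerance for sub-50 bp events, reciprocal overlap ≥ 0.5 for long
and CNV events, greedy one-to-one matching by breakpoint distance.
Both knobs are exposed; they are evaluation conventions, not published
constants, so FDR/FNR values quoted for any real pipeline depend on
them and on the read simulator and caller used — which is why the
package validates the *evaluator* (exactness, and FNR tracking an
imposed call-drop rate) rather than asserting any particular caller's
published FNR.

## Numerical and degenerate-input conventions

- Coordinates are 0-based half-open everywhere internally; GFF3 is
  converted on read, BED passes through. Strand is ignored.
- All randomized functions take a seed and restore the caller's RNG
  state; identical config + seed gives byte-identical output.
- Degenerate statistics are flagged, not errored: all-tied
  Kruskal–Wallis reports H = 0, p = 1; a zero-variance paired t is
  t = 0, p = 1; an all-zero count table gives p = 1; CV of a zero-mean
  vector, FDR of an empty call set, and the ratio to zero deletions are
  `NA`.
- Percentile ties in the resampling null count as "within";
  percentiles use the nearest-rank convention.
- Bootstrap sub-seeds for the many CIs inside one table are derived
  from the user seed by a fixed affine map, so a single seed
  reproduces the entire report.

## Known limitations

Rates below roughly one expected event per study cannot be
distinguished from zero, and their bootstrap lower bounds collapse to
the point mass at 0. The binomial-GLM surrogate does not model
between-genotype overdispersion beyond what the parametric bootstrap
captures. The generator's length models are conventions, and the
spike-in loop validates software, not wet-lab sensitivity. Inversions
and translocations are not modeled at all.
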
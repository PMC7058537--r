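---
title: "Models and methods: TAD boundary disruption by structural variants"
author: "tadsv"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Models and methods: TAD boundary disruption by structural variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadsv)
```

This vignette documents the statistical machinery of `tadsv`: the
insulation-based TAD boundary caller, the shuffle null models behind every
enrichment statistic, the domain classification, the expression
fold-change procedure, the TAD-fusion statistics, and the synthetic-data
model the tests are built on. It also records the numerical and design
choices that were genuinely open, and what the passing test suite does —
and does not — demonstrate about real Hi-C data.

## Contact matrices and normalization

The unit of analysis is an intra-chromosomal contact matrix at a fixed
bin size (25 kb by default), held in a `ContactMatrix` object. Unmappable
or zero-coverage bins are masked: their rows and columns carry `NA`,
never a silent zero, and every statistic in the package averages over
unmasked entries only. A square insulation window with fewer than 25% of
its entries unmasked yields a missing value rather than a noisy one.

Two normalizations are provided. `applyKR()` divides each contact by the
product of the two bins' Knight–Ruiz balancing scores, masking bins whose
score is missing or non-positive. `iceNormalize()` performs iterative
correction — alternating row/column balancing until the coefficient of
variation of unmasked row sums drops below a tolerance (default `1e-5`)
— and returns the bias vector `b` with
`out[i,j] = raw[i,j] / (b[i] b[j])`. Both leave all downstream log-ratio
statistics invariant to a global scale factor, a property the test suite
checks directly.

## Insulation score and boundary calling

The raw insulation of bin *i* is the mean contact over the off-diagonal
square `(i-s..i-1) x (i+1..i+s)` with `s = 40` bins (1 Mb). Scores are
log2-normalized against the chromosome mean — per chromosome, not
genome-wide, so chromosomes with different coverage are comparable — and
bins within one square of a chromosome end are undefined.

The delta track is the mean normalized score over the 8 bins (200 kb)
downstream minus the 8 bins upstream. At an insulation minimum the score
descends then rises, so delta crosses zero from below; candidate
boundaries sit at those upward crossings, on whichever of the two
crossing bins has the lower score. A candidate's strength is the delta at
the nearest following local maximum minus the delta at the nearest
preceding local minimum — the total rise of delta through the trough.
Candidates weaker than the noise threshold (0.1) are dropped; candidates
within one bin of each other merge, the stronger surviving and ties going
to the smaller coordinate. Each call is emitted as a 3-bin (75-kb)
interval centered on the minimum bin, the width the merge margin implies.

One internal convention deserves note: with delta defined as downstream
minus upstream, the extremum *preceding* an upward crossing is a local
minimum of delta and the one *following* it is a local maximum. The
strength is therefore `delta(following max) - delta(preceding min)`,
which is positive at real boundaries and reduces to the familiar
insulation-caller strength under the opposite sign convention.

The `tadSignal()` track is a companion diagnostic: the log2 ratio of a
bin's banded contact sum (partners within 2 Mb, diagonal excluded) to the
mean of that sum over the surrounding 2-Mb window. Of the two readings
the defining sentence admits, the banded-row-sum reading is implemented;
a per-entry log-ratio variant was considered and not adopted because it
has no single per-bin value to profile around boundaries.

## Consensus boundaries

Boundary sets from several cell types are pooled and grouped greedily
left to right: a boundary joins the current group when its center lies
within 50 kb (two bins) of the previous member's center. Chain grouping,
rather than strict mutual distance, is used deliberately: a group of
centers at −25 kb, 0, 0, +25 kb and +50 kb around a shared position
should be — and is — one consensus, even though its extremes are 75 kb
apart. Only groups containing at least one member from *every* input set
survive; the consensus position is the bin-rounded median of member
centers, re-emitted as a 3-bin interval. The representative-position
choice (median) was open; the median is robust to one stray member and
keeps the consensus on the bin grid.

## Shuffle null models

Every enrichment statistic is referred to the same null: boundaries are
re-placed uniformly at random on the bin grid of their own chromosome,
preserving the per-chromosome count and each boundary's width, with no
two shuffled boundaries overlapping. The placement is sampled exactly
uniformly over all non-overlapping configurations through a combinatorial
bijection, not by rejection, so dense chromosomes do not bias the null.
When a mappability mask is supplied, shuffled boundaries avoid masked
start bins (rejection sampling); by default there is no mask.

`boundaryOverlapTest()` discretizes the genome to bins, counts bins
covered by both sets (a logical AND), and shuffles one set 10,000 times
by default. Two p-values are reported side by side: a two-sided
normal-approximation p from `z = (obs - mean)/sd`, and the upper-tail
empirical p `(1 + #{null >= obs}) / (n + 1)`, which can never drop below
`1/(n+1)`. Reporting both is intentional — applying a t-test to a
bootstrap null distribution is not a well-defined recipe, so the package
shows the normal approximation *and* the assumption-free empirical
answer, which agree whenever the null is near-Gaussian.

`baEnrichment()` applies the same machinery to boundary-affecting SV
counts per SV type among short-range (< 2 Mb) events, reporting
fold = observed / null mean alongside z and both p-values.

Calibration is checked, not assumed: under a null in which the observed
boundary set is itself a draw from the placement distribution and SVs are
placed uniformly, the empirical p rejects at 5% close to 5% of the time,
and overlap z-scores fall within ±2 in ≥ 93% of replicates. Note the
subtlety that an *evenly spaced* boundary set is not a draw from this
null — regular spacing prevents the clumping that wastes shuffled
boundaries, inflating containment probability by tens of percent — so
calibration experiments must draw their "observed" boundaries from the
null itself.

## Boundary-affecting SVs

An SV affects a boundary when its footprint contains the whole boundary
interval, inclusive at both ends (an SV exactly equal to the interval
qualifies; any partial overlap does not). The implementation is
interval-tree containment via `GenomicRanges::findOverlaps(type =
"within")`, verified against a quadratic brute-force oracle on 10,000
random configurations; the shuffle loops use an equivalent sorted
`findInterval` fast path, itself tested against the slow path.

Supporting analyses follow the same containment rule: germline-vs-somatic
deletion rates on the closed 75–250-kb length window; binary
sample-by-boundary recurrence matrices with a strict >10% recurrence
fraction; loop disruption as overlap with exactly one of an insulated
neighborhood's two CTCF anchors; and the distribution of
spanned-boundary counts per BA-SV by type and minimum length.

## Domain classes

Domains are the gaps between adjacent consensus boundaries (boundary
intervals and chromosome-terminal segments excluded). Each domain's
15-state chromatin coverage vector — the fraction of its length in each
state — is clustered with `stats::kmeans` (k = 5, 50 restarts, best
inertia, fixed seed). Clusters are then *named*, making the labeling
invariant to k-means index permutation: centroids are ranked by active
mass minus quiescent mass under a state dictionary (states tagged
active / quiescent / neutral; the Roadmap-style default ships as a
config file in `inst/extdata/`, not hard-coded) and assigned, in rank
order, heterochromatin, low, repressed, low-active and active, with
activity ranks 0–4. The hierarchical clustering of state rows used in
presentations of such heatmaps is display-only and omitted.

Flanking-domain pairs of BA-SVs take, for each breakend, the class of the
containing domain (or the nearest by center, ties to the left — the
left/right choice for a breakend inside a boundary interval was open and
fixed this way) and count unordered class pairs in a symmetric 5×5
matrix. The shuffle null for the same-class diagonal re-derives domains
from shuffled boundaries and assigns them to the *observed* centroids
rather than re-running k-means: re-clustering each shuffle would
re-define the classes under the null (and suffer label switching),
whereas the quantity of interest is how often the *fixed* class
definitions produce same-class flanks by chance.

LAD overlap tests categorize each SV by its two breakend labels (both in
constitutive LADs, both in inter-LADs, or crossing) and re-place each
event uniformly on its own chromosome, length preserved, 10,000 times.

Gene-to-domain assignment uses the gene's start position (a TSS-based
alternative would differ only for genes straddling a boundary); per-class
median log2 expression is compared to the active class with one-tailed
Mann–Whitney tests.

## Expression fold changes

For each BA-SV, the nearest genes lying wholly outside the footprint on
each side (genes overlapping a breakend are excluded from candidacy;
equidistant ties go to the smaller coordinate) are scored as
`fc = expression(gene, carrier sample) / mean(expression over the rest of
the cohort)`. Three independent filters follow, each strict so that
records exactly at a threshold are kept: cohort-mean expression below
0.1 FPKM (the cohort mean, not the per-sample value, so the denominator
of fc is stable — the per-sample reading was the open alternative); copy
number above 4 in that sample for either flank gene of the SV (a missing
entry is treated as diploid, with a warning); and breakend-to-gene
distance above 1 Mb. Because the filters are independent predicates,
their order cannot change the retained set.

Each record's flank relation compares its own side's domain class to the
opposite side's: to-more-active, to-less-active or same-class. Group
comparisons are one-tailed Mann–Whitney tests (exact when both groups
have ≤ 20 records and no ties, tie-corrected normal approximation
otherwise). The more-than-twofold fraction is strict in both directions
(fc > 2 or fc < 0.5) and counted per SV — an SV qualifies when any of its
flank records exceeds twofold — with a per-record mode available.

## TAD fusions in rearranged maps

The expected model is the empirical mean contact at each bin separation,
per chromosome and genome-wide (weighted by pair counts); distances with
fewer than 10 unmasked pairs are pooled with neighbors rather than
smoothed with a spline. The per-SV scaling factor is the mean observed
contact over all unmasked pairs in the SV's window — the footprint
extended symmetrically to a 2-Mb total span, truncated on either side at
the nearest other-SV breakend — divided by the mean distance-matched
expectation over the same pairs. It is exactly 1 when the matrix equals
its own expected model, estimates the copy ratio of a
contact-doubled region, and values below 0.1 flag SV calls unsupported
by the contact data. Windows collapsing below 4 bins are excluded with a
reason.

Cross-SV bin pairs are classified against the nearest boundary beyond
each breakend: pairs confined between breakends and their nearest
boundaries are intra-TAD/SV (the putative fused domain), pairs reaching
past a nearest boundary are inter-TAD/SV. Both classes are summarized as
observed/expected ratios (the distance normalization is applied to both
classes, resolving an ambiguity in how such decay comparisons are
usually drawn) and the statistic is the intra/inter mean ratio. A
geometric constraint worth knowing: with TAD spacing `T` and a 2-Mb
window, a centered deletion leaves room for inter-TAD/SV pairs only when
`T < 1 Mb`; fusion analyses therefore need sub-megabase domain spacing
or a wider window.

Breakend aggregate enrichment extracts the `(2h+1)^2` observed/expected
submatrix centered on each SV's (start-bin, end-bin) pixel — for
bin-aligned deletions, the informative pixels flanking the junction —
and averages over SVs; SVs whose breakend bin is masked are skipped and
counted.

## Synthetic data model

Contact maps follow `E[count(i,j)] = depth * d^(-alpha) * (1 + tau *
[same TAD])` with Poisson noise, `alpha = 1`, within-TAD enrichment
`tau = 1`, and `depth = 50` (≥ 50 expected near-diagonal counts) as the
default study conditions; the diagonal, which the power law leaves
undefined, carries the d = 1 expectation and is excluded from every
downstream statistic. Planted boundaries are evenly spaced 3-bin
intervals, nine per 20-Mb chromosome by default (2-Mb domains); fusion
scenarios use 500-kb spacing for the geometric reason above.

Rearranged maps are simulated on the *derived* chromosome: the bin map
implied by non-overlapping deletions (bins removed), tandem duplications
(bins repeated) and inversions (bins reversed) is built, TADs are
re-derived from the surviving boundary bins, contacts are simulated with
the same model, and every derived contact is projected back to reference
bins, summing over duplicated copies. Nested or overlapping events are
rejected; complex rearrangements are emulated as many disjoint events.
For scaling-factor tests the package instead uses a copy-ratio contact
boost (`boostRegion`/`boostFactor` in `simulateHiC`): a full
tandem-duplication projection adds cross-copy contacts at shifted
distances and measures *above* the copy ratio, whereas the boost model
realizes the "contacts uniformly doubled" situation the scaling factor
estimates.

SV catalogs draw per-sample event counts from a Poisson, types from a
mixture, lengths log-uniformly, and placements uniformly; an enrichment
knob forces a fraction of events to span (or avoid) boundaries, and a
calibrated mode derives the per-event forcing probability from the
closed-form chance `baChanceProbability()` — the union length of
per-boundary valid-start intervals over all starts — so that the planted
BA rate is an exact multiple of the geometric expectation. State tracks
tile each domain with segments drawn from Dirichlet-perturbed class
archetypes; expression is log-normal (CV 0.3) around class-dependent
baselines ordered heterochromatin < low < repressed < low-active <
active, with planted per-(gene, sample) fold effects; copy number is
diploid outside a small aberrant fraction. Every generator is a pure
function of its parameters and seed.

What the passing tests do show: the caller recovers planted block-TAD
boundaries (recall ≥ 90% within ±1 bin, ≤ 1 false call per 20 Mb at the
stated depth); the containment annotation is exactly correct; the nulls
are calibrated; planted enrichments, clusters, expression effects and
fusion signals are recovered at their planted magnitudes. What they do
not show: robustness to the things real Hi-C has and the generator lacks
— distance-decay that deviates from a single power law, compartment
structure, nested/hierarchical TADs, mappability artifacts beyond simple
masking, overdispersed counts, and SV calls with coordinate uncertainty.
Conclusions about real data should lean on the masked-bin policy, the
empirical p-values, and the scaling-factor exclusion, all of which were
designed for those failure modes but are exercised here only in their
clean-room forms.

## Reproducibility and problem sizes

All randomness flows from explicit integer seeds; stage seeds in the
pipeline derive from one root seed, and two runs with identical inputs,
configuration and seed produce byte-identical outputs. The test suite
and the acceptance script run on deliberately modest problem sizes —
20-Mb chromosomes at 25-kb resolution, cohorts of tens of samples,
nulls of 200 replicates with 500–1,000 shuffles (scaled down from the
10,000-shuffle default used for single analyses) — chosen so the whole
battery completes in minutes on one CPU while keeping every Monte-Carlo
tolerance at ≥ 3 standard errors except where a stated acceptance band
is intentionally tighter.
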
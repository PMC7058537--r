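# tadsv

Quantifying how somatic structural variants (SVs) disrupt topologically
associating domains (TADs) in cancer genomes.

Mammalian chromosomes fold into TADs — regions whose interior chromatin
contacts are enriched relative to their surroundings — separated by
boundaries roughly 75 kb (three 25-kb Hi-C bins) wide. Deletions,
duplications, inversions and complex rearrangements can remove or bypass a
boundary, fusing adjacent domains and rewiring enhancer–promoter contacts.
`tadsv` is a Bioconductor-style toolkit for the full analysis chain a
pan-cancer study of this phenomenon needs:

- **Boundary calling.** Insulation scores I(i) — the mean contact frequency
  in a square window (default 1 Mb = 40 bins) sliding along the matrix
  diagonal — are log2-normalized per chromosome; boundaries sit where the
  delta track Δ(i) (downstream minus upstream mean of the score over
  200 kb) crosses zero upward, with a strength threshold of 0.1 and 1-bin
  merging. KR and ICE matrix normalization are included.
- **Consensus boundaries** across cell types: groups of calls whose centers
  chain within 50 kb, with one member from every cell type.
- **Boundary-affecting SVs (BA-SVs).** An SV is boundary-affecting when its
  footprint fully contains a boundary interval. Enrichment is measured
  against a null that re-places boundaries uniformly on the bin grid
  (10,000 shuffles by default), reporting fold = observed/null mean, z,
  and both normal-approximation and empirical p-values. Germline/somatic
  rate comparison (75–250-kb deletions), cohort recurrence (boundaries hit
  in >10% of samples), and insulated-neighborhood anchor disruption are
  included.
- **Domain classes.** Inter-boundary domains are annotated with their
  15-state chromatin-state coverage and k-means-clustered (k = 5) into
  heterochromatin / low / repressed / low-active / active classes, named
  by centroid composition under a configurable state dictionary; per-class
  expression summaries and BA-SV flanking-class pair matrices follow.
- **Expression fold changes.** For each BA-SV, the nearest non-overlapping
  genes up- and downstream; fc = expression in the carrier sample divided
  by the mean of the rest of the cohort, with <0.1-FPKM, copy-number >4
  and >1-Mb distance filters; one-tailed Mann–Whitney group tests and the
  fraction of events with a more-than-twofold change.
- **TAD fusions in rearranged maps.** Distance-decay expected model;
  per-SV scaling factor (mean observed/expected over a 2-Mb window,
  <0.1 flags unsupported calls); intra- vs inter-TAD/SV classification of
  cross-SV bin pairs and their decay comparison; aggregate
  observed/expected enrichment at SV breakend pixels.
- **Synthetic data.** Generators for every input — distance-decay block-TAD
  contact maps (optionally rearranged through a derived-chromosome bin
  map), cohort SV catalogs with a calibrated boundary-enrichment knob,
  state/LAD/gene tracks and expression/copy-number tables — all pure
  functions of a seed, so the whole pipeline is testable end to end with
  no downloads.

## Worked example

Simulate a 20-Mb chromosome with nine planted TAD boundaries, call
boundaries back, and test a planted duplication catalog for boundary
enrichment:

```r
library(tadsv)

cs  <- c(chr1 = 2e7)
tru <- plantedBoundaries(cs, 9)
mat <- simulateHiC(cs, tru, tau = 1, depth = 50, seed = 42)$chr1
mat
#> ContactMatrix: chr1, 800 bins @ 25000 bp (0 masked)

calls <- callBoundaries(insulationProfile(mat))
length(calls)
#> [1] 9

svs <- simulateSVCatalog(cs, tru, nSamples = 8, meanPerSample = 8,
                         typeMix = c(DUP = 1), lenRange = c(2e5, 1e6),
                         enrichmentKnob = 1, seed = 7)
enr <- baEnrichment(svs, tru, cs, nShuffles = 1000, seed = 1)
enr$DUP$null
#> ShuffleNull: observed 74 vs null 14.54 +/- 6.53 (n=1000)
#>   z = 9.105, p_normal = 8.61e-20, p_empirical = 0.000999
```

All nine planted boundaries are recovered, and a catalog in which every
duplication is forced to span a boundary shows a ~5-fold excess of
boundary-affecting events over the shuffle null, with the empirical p at
its floor of 1/(n+1).

The full pipeline runs over a generated input bundle:

```r
simulateBundle("bundle", seed = 11)
runPipeline("bundle", "out", pipelineConfig(nShuffles = 1000), seed = 5)
```

writing per-cell-type boundary calls, consensus boundaries, BA
annotations, enrichment/recurrence tables, classified domains, expression
fold changes and TAD-fusion statistics as BED/TSV files.

## Vignette

`vignettes/tad-disruption-analysis.Rmd` documents the statistical model,
parameter choices, null-model design, and the limits of what the
synthetic generators can demonstrate about real Hi-C data.
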
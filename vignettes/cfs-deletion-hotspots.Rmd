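---
title: "Methods: deletion hotspots at fragile sites and the RSF score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deletion hotspots at fragile sites and the RSF score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, procedures and numerical choices
behind `cfsdel`, in the spirit of a statistical-methods supplement: what
each stage computes, which parameters matter, what the synthetic cohort
does and does not emulate, and where the design was genuinely open.

## Scientific model

Common fragile sites (CFSs) are late-replicating, AT-rich regions that
often host very large genes. Under replication stress, transcription of
such a gene can persist into S-phase and suppress the firing of the
dormant origins that would normally rescue stalled replication forks.
When two converging forks both stall with no origin left between them
(a double-fork failure), the unreplicated interval is resolved by
deletion of the intervening DNA, with occasional re-replication near the
flanking origins producing duplications. This transcription-dependent
double-fork failure (TrDoFF) mechanism makes four testable predictions
on cohort structural-variant data, and the package implements one
analysis stage per prediction:

1. deletions recur at a limited set of genomic regions (hotspots);
2. their breakpoints lie *between consecutive replication origins*, and
   the local inter-origin distance bounds the deletion size;
3. within the affected genes, deletions center on the gene midpoint
   while duplications sit at the flanks, independent of strand;
4. the affected genes are transcribed — they show higher expression than
   matched untranscribed large genes, and split RNA-seq reads span the
   deletion junctions.

A clinical corollary: cells able to resolve stalled forks should also
cope better with platinum-induced fork stalling, so a high hotspot
deletion burden (the *resolved stalled fork*, RSF, score) should predict
shorter progression-free survival (PFS) on platinum-containing therapy.

## Coordinate conventions

All in-memory coordinates are 0-based half-open. VCF input (1-based
`POS`, `END`) is converted at the reading boundary; BED and the package
TSV dialects are already half-open. Origin peaks may be points or
intervals; every distance and containment computation uses the peak
midpoint `floor((start + end)/2)`, because the analysis treats peaks as
positions bounding origin-free regions and no convention for peak width
exists. Chromosome names are taken verbatim, with an optional
strip/add-`chr` normalization for mixed-source inputs.

## Hotspot calling

Deletions are first restricted to 10 kb–1 Mb, the size band in which the
fragile-site signal lives; bounds are inclusive at both ends (the least
surprising reading of a printed range). Per chromosome, deletions are
clustered by **single linkage**: two deletions join one cluster when
their intervals overlap or lie within `merge_gap` (default 100 kb).
Clusters with at least `min_events` = 150 deletion *records* — not
distinct samples; recurrently hit samples typically carry several
overlapping deletions — become hotspot regions spanning the first
deletion start to the last deletion end. Cluster-extent reporting is the
natural companion of a first-DEL/last-DEL region definition; the merge
gap is exposed because reasonable alternatives (e.g. merging sub-clusters
within a cytoband) differ only through it. Clustering is
order-independent and spans are pairwise disjoint after merging; raising
`min_events` can only remove regions.

Breakpoint base composition pools both breakpoints of every deletion and
tabulates per-offset A/C/G/T frequencies in ±20 bp windows; windows
truncated by a chromosome end are skipped with a logged count. Motif
*discovery* is deliberately out of scope — the expected signal is plain
AT-richness.

## Origin containment and enrichment

For each chromosome the `k` origin-peak midpoints define `k − 1`
consecutive inter-peak intervals. A deletion is *between peaks* when one
interval satisfies `left < start` and `end < right` — **strict**
inequalities, so a breakpoint exactly on an origin midpoint counts as
not-between. Strictness follows from the meaning of "between two
consecutive origins"; boundary coincidences are measure-zero on real
coordinates, so the choice is inert in practice but keeps the predicate
unambiguous. Duplicate peak midpoints are dropped with a warning (a
zero-width interval is uninformative).

The 2×2 table of hotspot membership × containment is summarized by the
odds ratio `ad/bc` with a Wald CI on the log scale (Haldane–Anscombe
+0.5 when a cell is zero, flagged), Pearson's χ² without continuity
correction (df = 1), and proportions rounded half-away-from-zero to
whole percent. A multivariable logistic regression (`in_hotspot ~
between_peaks + between_tads`, IRLS, convergence 1e−8, ≤ 100
iterations) separates the origin effect from the TAD effect; complete
separation is flagged with an infinite-OR marker instead of an error.

"Between TADs" is not operationally defined by the biology alone, so two
readings are implemented: intervals joining consecutive TAD-annotation
midpoints (default, the same machinery as origin peaks) and the gaps
between annotation blocks (`tad_mode = "gap"`). Neither is asserted to
be canonical.

Inter-peak distances are summarized by the median with a
**distribution-free order-statistic CI** (the largest rank `l` with
`P(Bin(n, ½) ≤ l − 1) ≤ 0.025` and its mirror `n − l + 1`), chosen over
a bootstrap because it is deterministic and exact, and the 95th
percentile by linear interpolation.

## Positions within genes

Each structural variant is assigned to the gene containing its
*midpoint* — the only single-point summary compatible with asking
whether events are "centered" — so every event maps to at most one gene;
where two genes share one origin-free window each event goes to the gene
holding its midpoint, and events between the two midpoints map to none.
The relative position `r = (midpoint − start)/length` is flipped to
`1 − r` on minus-strand genes, so 0 is always the transcription start.
Histograms use equal-width bins on [0, 1] with a right-closed last bin
and densities integrating to one. Positions are computed relative to the
gene body (the object the centering claim is about); positions relative
to the inter-peak interval are available through the containment table's
`rel_position` column. The concentration contrast (deletions closer to
0.5 than duplications, or hotspot deletions closer than background ones)
is a one-sided Mann–Whitney test on `|r − 0.5|`.

## Expression comparison

Candidate genes are those longer than 500 kb (strict) whose entire body
lies strictly between one consecutive origin-peak pair, partitioned by
overlap with any hotspot region — genes and regions are treated
interchangeably here because hotspot regions are defined by the genes
they damage. Expression is aggregated to a per-gene median across
samples before the two-group Mann–Whitney test, giving one value per
gene. The U statistic uses exact enumeration when both groups have ≤ 8
tie-free values and the tie-corrected normal approximation (no
continuity correction) otherwise; two constant equal groups return
p = 1 by convention.

## Junction support

Split reads arrive as pre-tabulated aligned segments. Segments sharing a
read and sample are paired by read offset (reads with ≥ 3 segments use
the outermost two, since one deletion splits a read once); a pair
supports a deletion of the same sample when segment A's end is within
`tolerance` of the deletion start and segment B's start within
`tolerance` of the deletion end. The default tolerance of 5 bp absorbs
aligner soft-clip jitter — exact abutment (tolerance 0) is available and
is what the synthetic tests assert. Each read pair supports at most one
deletion: smallest combined gap, ties to the smaller deletion start.
Matches can never cross samples by construction, and raising the
tolerance can only add matches. An optional minimum-mapping-quality
filter is applied when the segment table carries a `mapq` column;
no particular cutoff is asserted.

## The RSF score and survival

Per-sample counts include every 10 kb–1 Mb deletion **fully contained**
in a hotspot region — consistent with regions being defined by their
outermost deletions; an any-overlap mode exists for sensitivity
analysis, as does a flag collapsing overlapping same-sample deletions.
The threshold comes from a continuous three-segment piecewise-linear
least-squares fit of the sorted counts against rank, with the
changepoint pair found by exhaustive grid search at data-point
resolution (each segment ≥ 3 points). The deterministic grid search
replaces a Bayesian changepoint sampler because the only consumed output
is the threshold and exact reproducibility is worth more than posterior
uncertainty here. The threshold is the fitted count at the rank midway
between the two changepoints; interpreting "midpoint between the
changepoints" on the count axis instead is available via
`threshold_on = "count"`. A fit that does not improve on a single
regression line (within 1e−6 relative) is flagged degenerate; constant
counts fall back to a threshold of 20, the value reported for the
motivating cohort. Classification is strict: a sample is RSF+ only when
its count exceeds the threshold.

Survival uses the standard machinery: Kaplan–Meier product-limit curves
(events before censorings at ties), the two-group log-rank test with
hypergeometric variance, and a Cox proportional-hazards model with
Breslow tie handling (RSF status, prior platinum exposure, number of
prior treatment lines), restricted to patients treated with platinum
after biopsy. The test-suite cross-checks all three against independent
hand-written implementations (product-limit recursion, O−E/V summation,
Newton iteration on the partial likelihood).

## The synthetic cohort

The generator plants exactly the structure the pipeline claims to
recover, on a desk-scale genome of 3 × 60 Mb — large enough to host 13
fragile-site regions plus 40 large control genes with realistic spacing,
small enough for seconds-scale runs. Defaults encode the emulated study
conditions:

* **Origins**: each CFS gene is bracketed by two peaks 1.6 Mb apart with
  no origin between them; elsewhere peaks follow exponential spacing
  with a 25 kb median. Large non-CFS genes are likewise placed in
  origin-free windows so they qualify for the expression comparison.
* **Deletions**: per sample and expressed CFS gene, Poisson(1) deletions
  (×4 for the latent RSF+ fraction, 15% of samples) with midpoints
  normal around the gene midpoint (SD = 0.08 × gene length, truncated so
  the deletion stays strictly between its peaks) and sizes uniform on
  10 kb–1 Mb. Multiple overlapping deletions per gene and sample are
  expected — clonal heterogeneity, not an artifact. Duplications
  concentrate at relative gene positions 0.05/0.95 with smaller sizes.
* **Background deletions**: 3 per sample, uniform over the genome,
  log-uniform sizes 1 kb–2 Mb. This preserves the per-megabase
  background deletion density of a ~3 Gb cohort carrying ~20 background
  deletions per sample: scaling by genome length rather than copying the
  per-sample count keeps background cluster sizes — the thing the
  150-event threshold is calibrated against — realistic on the small
  genome, where the unscaled rate would blanket every chromosome in
  overlapping deletions.
* **Expression**: log-normal, higher location for CFS genes; 30% of
  non-CFS large genes are fully silent, emulating untranscribed large
  genes that accumulate no deletions.
* **Junction reads**: 5% of CFS deletions receive 1–3 read pairs whose
  segments abut the breakpoints exactly, plus decoy pairs whose internal
  gap (37 bp) is smaller than any simulated deletion, so no decoy can
  match at any reasonable tolerance.
* **Clinical**: PFS is exponential with hazard `h₀ · HR^RSF`
  (`h₀ = ln 2 / 250` days, HR = 3), independent censoring at an expected
  20%, small-Poisson prior treatment lines with platinum exposure
  consistent with them. The simulated cohort represents the
  platinum-after-biopsy subset, so all records carry that flag.
* **Sequence**: A+T fraction 0.65 inside CFS gene bodies, 0.5 elsewhere.
  Sequence generation is optional (`include_sequence = FALSE`) since
  most analyses only need coordinates.

The RSF designation is planted as a **latent label**, not derived from
the generated counts, so threshold recovery is a supervised
classification check. All generators draw from named substreams of one
seed; identical configurations are byte-identical.

What the generator does *not* emulate: mechanistic fork dynamics,
read-level sequence and base quality, inversions/translocations,
copy-number context, inter-gene correlation of expression, or real
hg19 annotation. Passing tests therefore demonstrate that the
*procedures* recover planted structure at realistic signal-to-noise —
not that any particular biological cohort will show the same effect
sizes. Quantities that depend on the real genome and cohort (the
specific Table-style region coordinates, a 1647 kb hotspot inter-peak
median, exact gene counts and read totals) are out of reach at desk
scale and are covered instead by direction- and recovery-style checks.

## Problem sizes and runtime

The shipped tests and the acceptance script run the full pipeline on the
default 200-sample cohort (~5,000 structural variants, ~7,000 origin
peaks; a few seconds per cohort without sequence), 20-seed replications
for direction-of-effect checks, a 400-sample × 20-seed hazard-ratio
recovery, and a 200-seed log-rank null calibration — sizes chosen so the
whole suite completes in well under half an hour on one core while
keeping Monte-Carlo acceptance margins comfortable.

## Known limitations

* Hotspot spans can chain into adjacent background deletions through the
  100 kb merge gap, stretching a region past its bracketing origins;
  region definitions inherit this property of single linkage.
* The changepoint grid is O(n²) in the number of samples; fine to a few
  thousand samples, inappropriate beyond.
* `read_sv_calls` parses a deliberately small VCF subset (`SVTYPE`,
  `END`); full breakend semantics, homology tags and BAM traversal
  belong to upstream callers.
* With very few RSF+ samples the Cox model's Wald intervals become
  unstable before the flag triggers; the log-rank test is the more
  robust primary read-out in small cohorts.
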
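# cfsdel

Deletion hotspots at common fragile sites and the resolved stalled fork
(RSF) score.

## The problem

Metastatic colorectal cancer genomes carry an excess of deletions (DELs)
of a characteristic 10 kb–1 Mb size, clustered at common fragile sites
(CFSs) — late-replicating, AT-rich regions that host very large genes.
Under the transcription-dependent double-fork failure (TrDoFF) model,
transcription of a large gene during S-phase suppresses the firing of
dormant replication origins, so two converging stalled forks leave an
unreplicated gap that is resolved as a central deletion with duplications
(DUPs) at the flanks. The same fork-rescue capacity that resolves these
lesions plausibly also resolves platinum-induced stalled forks, making a
high hotspot-deletion burden a candidate marker of reduced benefit from
platinum-containing therapy.

`cfsdel` implements the full analysis chain for cohort structural-variant
calls, for genomicists and translational researchers who want to score
their own cohorts or probe the model on simulated ones:

1. **Hotspot calling** — single-linkage clustering of 10 kb–1 Mb DELs
   (linked when within a 100 kb gap); clusters with ≥ 150 events become
   hotspot regions, annotated with their nearest gene and the number of
   samples carrying more than one DEL.
2. **Replication-origin containment** — is a DEL bracketed by two
   *consecutive* Ini-seq peaks (no origin midpoint inside it)? Enrichment
   inside versus outside hotspots is quantified by the 2×2 odds ratio
   `OR = ad/bc` with a Wald CI, Pearson's χ², and a multivariable
   logistic regression of hotspot membership on peak- and TAD-containment.
   Inter-peak distances are summarized by the median with a
   distribution-free order-statistic CI and the 95th percentile.
3. **Gene positioning** — transcription-orientation-corrected relative
   positions `r = (m − g_start)/L` (flipped to `1 − r` on minus-strand
   genes) of DELs and DUPs within hotspot genes; DELs pile up near
   `r = 0.5`, DUPs near the flanks.
4. **Expression comparison** — Mann–Whitney U test of per-gene median
   expression for large (> 500 kb) genes lying between consecutive origin
   peaks, inside versus outside hotspots.
5. **Junction support** — split RNA-seq reads whose two aligned segments
   abut a DEL's breakpoints (segment A ends at the 5′ breakpoint, segment
   B starts at the 3′ breakpoint) prove the deleted locus is still
   transcribed.
6. **RSF score** — per-sample counts of DELs fully contained in hotspot
   regions; a continuous three-segment piecewise-linear fit of the sorted
   counts against rank locates two changepoints, and the fitted count at
   their midpoint is the RSF threshold (strictly greater ⇒ RSF+).
   Association with progression-free survival uses Kaplan–Meier curves,
   the log-rank test, and a Cox proportional-hazards model
   `h(t) = h₀(t)·exp(β₁·RSF + β₂·priorPt + β₃·lines)`.

Because the motivating patient-level data are access-restricted, the
package ships a seeded synthetic-cohort generator
(`simulate_cohort()`) that reproduces the statistical structure the
analysis assumes — sparse origins across CFS regions, midpoint-centered
DELs, flank DUPs, elevated CFS expression, junction reads, and
exponential survival with a configurable hazard ratio — so every stage is
testable end to end.

## Worked example

```r
library(cfsdel)

cfg    <- sim_config(seed = 7)                       # 200-sample synthetic cohort
cohort <- simulate_cohort(cfg, include_sequence = FALSE)

dels <- filter_dels_by_size(cohort$sv)               # 10 kb - 1 Mb DELs
hs   <- call_hotspots(dels, genes = cohort$annotation$genes)
head(as.data.frame(hs), 3)
#>   chrom    start      end n_events n_samples_multi nearest_gene gene_distance
#> 1  chr1 41653810 42943018      316              79        CFS01             0
#> 2  chr2 30349396 32653899      280              64        CFS02             0
#> 3  chr2 40680724 42305379      288              71        CFS03             0

rsf_analysis(dels, hs, clinical = cohort$clinical, samples = cohort$samples)
#> RSF analysis: 200 samples, threshold 30.85 (changepoint fit)
#> RSF- RSF+
#>  170   30
#> log-rank: chi-sq 39.85, p = 2.738e-10
#> Cox proportional hazards:
#>             term    hr ci_low ci_high        p flagged
#> 1            rsf 3.762  2.421    5.85 3.85e-09   FALSE
#> 2 prior_platinum 0.928  0.624    1.38 7.10e-01   FALSE
#> 3    prior_lines 0.927  0.744    1.15 4.95e-01   FALSE
```

All 13 planted fragile-site regions are recovered (each overlapping its
gene, `gene_distance = 0`), the changepoint fit separates the latent
high-burden samples, and the Cox hazard ratio for RSF+ (3.76, CI
2.4–5.9) recovers the simulated hazard ratio of 3; the prior-treatment
covariates, simulated as noise, sit at HR ≈ 1. On published 2×2
containment counts the package reports the expected enrichment:

```r
odds_ratio(c(4836, 401, 6488, 3065))$or
#> [1] 5.697153
```

A full run over files (`simulate` writes the cohort, `all` chains the
seven analysis stages, each leaving TSV outputs and a checksummed
manifest):

```r
run_pipeline("simulate", outdir = "demo")
run_pipeline("all",      outdir = "demo")
```

or from a shell, `Rscript inst/scripts/run_pipeline.R all --outdir demo`.

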
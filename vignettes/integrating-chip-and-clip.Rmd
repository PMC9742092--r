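---
title: "Integrating ChIP and CLIP evidence with differential expression and splicing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating ChIP and CLIP evidence with differential expression and splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipclipr)
```

## The question the pipeline answers

Some RNA-binding proteins are detectable on chromatin, which raises the
possibility that one factor regulates a gene twice: at transcription, by
binding promoters or enhancers of genes whose expression shifts when the
factor is depleted, and after transcription, by binding nascent transcripts
near alternative exons whose inclusion shifts. chipclipr integrates the
five kinds of evidence such a study produces — a gene annotation, ChIP-seq
peaks, input-normalised eCLIP peaks, DESeq2-style differential-expression
tables and rMATS-style differential-splicing tables for two contrasts (a
factor knockdown and a differentiation time course) — into gene
classifications, direct-target sets and finally the genes supported on both
routes.

Every user-facing function takes a data frame and returns a tibble, so the
pipeline composes with the usual dplyr verbs; `run_integration()` wires the
whole cascade together over a bundle directory.

## Significance filters

The three evidence layers are filtered by fixed rules, all inequalities
strict:

* expression: `pvalue < .05` and `|log2FC| > log2(1)`. Note that
  `log2(1) = 0`, so the rule as stated imposes **no** fold-change cutoff
  beyond excluding exactly-zero estimates; it is implemented literally and
  the threshold is a `filter_thresholds()` parameter for users who want a
  real cutoff. The raw p-value, not the BH-adjusted one, is tested; `padj`
  is carried for reporting.
* splicing: `|dPSI| > .05`, `pvalue < .05`, `FDR < .1`. dPSI follows the
  convention Psi(condition) − Psi(control); the rMATS reader documents that
  the caller must have run the upstream tool with the condition as sample 1.
* eCLIP peaks: `p < 1e-3` and IP/input fold enrichment `> 4`. A peak at
  exactly 4-fold is excluded — boundary rows fall out of every filter, which
  keeps the rules reproducible at the cost of charity of interpretation.

Rows with missing statistics are excluded from the kept set, counted in the
totals, and reported via a message.

## Region classification

Every genomic position receives exactly one label through a deterministic
priority: promoter > TTS > 5′-UTR proxy > 3′-UTR proxy > exon > intron >
intergenic, with ties between genes at equal priority going to the
lexicographically smaller `gene_id`. Windows are configurable through
`region_config()`; the defaults (−1000..+100 bp around the TSS,
−100..+1000 bp around the TES) are the conventional promoter/TTS windows of
peak-annotation tools. The toy annotation carries no UTR features, so
fixed-width proxies (200 bp at each transcript end, within the gene body)
stand in for the UTR classes; set `utr_proxy = 0` to disable them. Peaks
are classified by their midpoint, `floor((start + end) / 2)`, so a peak has
one label and region percentages over a peak set sum to 100%.

A gene counts as *bound* by a peak when the peak midpoint falls in the gene
body or its promoter/TTS windows (`nearest_gene()` distance 0). Distal
enhancer-to-gene linking is out of scope — there is no defensible linking
rule without extra data — but `bound_genes(regions = ...)` exposes a region
whitelist so binding evidence can be restricted to, say, promoters only.

## Enrichment against the genome background

`genome_region_composition()` accounts for every base exactly (interval
arithmetic under the same priority scheme; the seven fractions sum to 1).
The enrichment ratio of a peak set in a region is the fraction of peaks
there divided by the fraction of genome bp there. For the one-tailed
Fisher test both margins must be counts, so the background is discretised
into tiles of width equal to the median peak width (rounded up, minimum
1 bp), each tile classified by its midpoint; the 2×2 table is
[[peaks in region, peaks elsewhere], [tiles in region, tiles elsewhere]]
and the p-value is the exact hypergeometric upper tail. Whether such a
test should be computed on bp, tiles or peaks is a genuinely open choice;
the tile construction keeps the two margins in comparable units and is
isolated in one function so it can be swapped.

Metagene profiles (`metaprofile()`) average a bedGraph track in 50-bp bins
over ±3000 bp around each anchor peak. Anchors are peak midpoints by
default (the narrowPeak summit column is optional in real data; a switch
uses it when present). Profiles are peak-centric and strand-agnostic — no
orientation flipping — and use the per-bin *mean* so profiles are
comparable across anchor sets of different sizes. Tracks are assumed
pre-normalised; positions off the covered extent contribute depth 0.

## Integration

Genes partition into DEG-only, AS-only, Both and none; Both genes whose
events agree in inclusion direction get one of four subgroups
(down+inclusion-up, down+inclusion-down, up+inclusion-up,
up+inclusion-down), and genes with events of both signs are `mixed` with no
subgroup. Transcriptional targets are significant DEGs that are ChIP-bound;
splicing targets are genes with a significant event whose alternative
segment shares at least 1 bp (half-open arithmetic, configurable extension
window, default 0 — the most specific reading of "event in an enriched
region") with a surviving CLIP peak. Matching uses the alternative segment
only, not whole flanking introns.

The differentiation contrast restricts both sets: transcriptional targets
must be significant, sign-concordant DEGs in both contrasts ("commonly
repressed/activated" means identical log2FC sign), and splicing targets
must have their matched event re-identified exactly — same gene, type and
segment interval — in the differentiation contrast. The co-regulated set is
the intersection of the two restricted sets, emitted with its supporting
evidence rows.

Co-occupancy is summarised per gene group by the Jaccard index of
ChIP-bound versus CLIP-bound genes, and spatially by the distance profile:
for each ChIP peak, the edge-to-edge gap to the nearest CLIP peak on the
same chromosome, binned as overlap (≥1 shared bp), ≤5 kb, 5–10 kb and
>10 kb. Two conventions are worth noting: half-open adjacency (gap 0, no
shared base) counts as ≤5 kb, not overlap; and a ChIP peak whose chromosome
carries no CLIP peak lands in the >10 kb bin. All five splicing event types
are read and reported; users can exclude types by restricting the `types`
argument of `read_rmats_bundle()`.

## The synthetic study

`simulate_bundle()` writes a complete, self-consistent bundle whose
statistical structure mirrors the study design: promoter ChIP peaks planted
on differentially expressed genes, intronic/exonic CLIP peaks planted
inside the alternative segments of significant splicing events, and a
co-regulated subset present in both pools and shared concordantly with the
differentiation contrast. Defaults: 2 chromosomes × 2 Mb, 500
non-overlapping single-transcript genes with 3–8 exons, 40 transcriptional
and 30 splicing targets of which 10 are co-regulated, 60% of each pool
shared with the differentiation contrast (plus 30/20
differentiation-only targets so the overlap is a proper subset both ways),
planted |log2FC| = 2, |dPSI| = 0.3, true CLIP peaks at 8-fold enrichment
with decoys at 2-fold, and 300 decoy peaks per assay.

Null rows follow the stated null: uniform p-values, near-zero effects
(|dPSI| < .05 for null events, so no null event can pass the splicing
filter), and decoy CLIP peaks at or below the fold cutoff, so the CLIP
filter removes every decoy. Null expression rows *can* clear the
expression filter by chance — that is what a uniform null means — so the
truth manifest records two things: the planted pools, and under
`$expected` the downstream sets implied by the written files, recomputed by
the generator's own independent bookkeeping (plain scans of the emitted
tables, no pipeline calls). Recovery is asserted two ways: the pipeline's
sets equal `$expected` exactly, and every planted target is recovered.

`noise_sd` is the coefficient of variation of the planted effect sizes; a
target's p-value is coupled to its realised relative magnitude r as
`10^(-u*r)` with `u ~ U(4, 8)`, so at `noise_sd = 0` target p-values are at
most 1e-4 and, as noise grows, targets increasingly shrink below the
effect-size cutoffs and lose significance together — which is how real
effect attenuation behaves, and what makes recovery degrade smoothly and
monotonically in expectation.

What the generator does **not** emulate: read-level sampling noise (p-values
are planted, because the upstream statistical engines are out of scope, so
their output contract is emulated rather than their internals), isoform
complexity (one transcript per gene), realistic genome composition or GC
structure, correlated nulls, and batch structure. Passing the recovery
tests therefore shows that the integration logic is faithful to its
definitions — not that the pipeline is robust to upstream
misspecification on real data.

## Numerical choices and test design

* All classification, filtering and set operations are pure functions;
  `simulate_bundle()` is byte-identical for a fixed seed and restores the
  caller's RNG state.
* Ties everywhere break lexicographically on `gene_id`; degenerate inputs
  (empty annotation, empty layers, missing optional files) return empty or
  `NULL` sections rather than failing, except where a result is undefined
  (distance profile of an empty ChIP set).
* The exact Fisher tail is computed with `phyper`; the test suite checks it
  against direct `choose()` enumeration (exhaustively for small tables,
  randomised up to margins of 30) and against `fisher.test`.
* The uniform-null calibration check (10,000 uniformly placed peaks must
  show every region ratio within 1 ± 0.1) runs on a deterministic grid
  annotation built so every occupied region class covers at least 10% of
  the genome. That makes the band a ≥3σ bound (relative sampling error
  `sqrt((1-f)/(nf)) ≈ 0.03` at f = 0.1); under the default simulated
  annotation the effective 5′-proxy class is ~1% of the genome, where the
  same band is only ~1σ and would fail by chance alone about one run in
  four — a property of binomial sampling, not of the estimator.
* Test problem sizes are chosen to exercise every code path at desk scale:
  the shared recovery bundle uses the full default configuration; replicate
  checks (partition identities over 25 simulations, noise degradation over
  3 noise levels × 10 seeds) use reduced configurations (120–200 genes,
  0.6–1 Mb chromosomes) with target pools scaled proportionally.

## Known limitations

Headline numbers from any real study of this design depend on
genome-scale annotation, real peak calling and the upstream statistical
engines, none of which are in scope; this package reproduces the
integration arithmetic on their outputs. Enhancer-to-gene assignment is
deliberately absent. The Fisher background discretisation is one defensible
choice among several; rerun `region_enrichment()` with a replacement
background function to probe sensitivity. The splicing-side matching keys
events by exact segment coordinates across contrasts, which is correct for
identically-annotated runs but brittle across annotation versions.
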
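---
title: "Simulating and evaluating multiplexed reduced-representation bisulfite sequencing"
author: "mrrbsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating multiplexed RRBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrrbsim)
```

## Why reduced representation, and what this package models

Reduced-representation bisulfite sequencing (RRBS) measures DNA methylation
at single-CpG resolution for a fraction of the sequencing cost of a whole
methylome. The trick is the restriction enzyme MspI, which cuts `C^CGG`
regardless of CpG methylation: because the recognition site contains a CpG,
every internal digestion fragment carries methylation information for at
least one CpG, and because CpG-dense regions (CpG islands) contain more
MspI sites, a size-selected digest concentrates reads exactly where
methylation is most dynamic. The classical protocol size-selects fragments
with a preparative gel (a manual 40–220 bp cut); the multiplexed, gel-free
variant (mRRBS) replaces the gel with SPRI bead clean-up (which removes
fragments below ~40 bp) plus the implicit bias of bisulfite fragmentation
and PCR against long fragments, and pools many six-base-barcoded libraries
per lane.

`mrrbsim` implements that entire measurement process as a simulation with
recorded ground truth, plus the analytics used to evaluate such protocols:
per-CpG coverage summaries, fragment-length coverage profiles,
feature-level CpG accounting, bisulfite-conversion estimation,
replicate-correlation checks, and a pooled-amplification chimera
experiment. Everything runs on synthetic genomes, so the full pipeline is
testable without downloads; `digest_genome()` and the downstream analytics
accept any FASTA genome as well.

## The synthetic genome and methylome

`generate_genome()` builds chromosomes as an i.i.d. background at a stated
GC fraction from which all chance CG dinucleotides are removed, and then
plants CpGs at a controlled per-base rate: `background_cpg_rate` everywhere
and `island_cpg_rate` inside non-overlapping planted intervals. Planting
rather than letting CpGs arise by chance means the CpG rate is an exact,
testable parameter; the cost is a slight distortion of the background base
composition (a few percent of G's are redrawn), which none of the analyses
are sensitive to.

The defaults are study conditions chosen once to mimic a human-like
contrast at desk scale: background GC 0.45 with 0.01 CpG/bp (observed/
expected ≈ 0.2, like bulk human sequence), and 800–1500 bp islands at 0.10
CpG/bp, giving island GC ≈ 0.56 and O/E ≈ 1.3 — i.e. planted islands
satisfy the detection criteria below and the background does not.
MspI-site density scales with CpG density, so islands digest into the
short, well-retained fragments that make RRBS work; this emergent
enrichment is the core of what the simulation reproduces.

`generate_methylome()` assigns each genomic CpG a truth methylation
probability: bimodal by default (islands near 0.1, background near 0.9,
Gaussian noise SD 0.05 clamped to [0, 1]). CpGs are keyed by the
plus-strand C position throughout; the paired minus-strand G is the same
CpG unit (symmetric methylation), so both strands' evidence accumulates
under one key.

What the generator does **not** emulate: repeat elements, assembly gaps,
sequence-context-dependent methylation, CNVs, or non-CpG methylation.
Passing tests therefore demonstrate correctness of the machinery under a
clean generative model, not performance on real libraries.

## From fragments to reads

`digest_genome()` enumerates fragments exactly (a cut at offset 1 of every
`CCGG`; `N` never matches; fragments tile each chromosome). Fragment
coordinates are 0-based half-open everywhere, as in BED.

The sequenced molecule for a fragment `[s, e)` is `[s, e + 2)`: end repair
fills in the two-base `CG` overhang left by the downstream cut. Reads take
`read_length` (default 29) bases inward from one of the two cut ends — the
plus strand from the 5' end, or the reverse complement from the filled-in
3' end. Both therefore begin `[C/T]GG`, and the first base reports the
methylation state of the MspI-site CpG itself (the plus-strand C at `s`
for 5' reads, at `e` for 3' reads — the junction CpG travels with both
neighbouring fragments, as in the real chemistry). Only fragments with
MspI cuts at *both* ends enter a library, since adapter ligation requires
two repaired ends; chromosome-terminal fragments are flagged and excluded.

Size selection is a retention probability per fragment length:

* **gel** — indicator on the inclusive 40–220 bp window;
* **gel_free** — `logistic((L - 45)/5) * exp(-max(0, L - 250)/50)`, hard
  zero below 40 bp. The logistic ramp models incomplete SPRI recovery just
  above the cutoff; the exponential tail models bisulfite fragmentation
  and amplification bias against long fragments. The protocol literature
  describes these mechanisms only qualitatively, so the midpoint (45 bp),
  steepness (5 bp), onset (250 bp) and decay constant (50 bp) are tunable
  stand-ins, chosen so that 60–300 bp fragments are well covered while
  coverage declines steeply beyond ~300 bp.

Bisulfite conversion is parameterised by `conversion_rate` (unmethylated C
reads T; default 0.99), `failure_rate` (methylated C reads T; default 0)
and a uniform per-base substitution `sequencing_error_rate`. Per-read CpG
states are Bernoulli draws from the truth methylome, recorded in a truth
sidecar, so every downstream estimate can be checked against its
generating value.

PCR template switching (`chimera_model`) splices another pooled molecule's
post-conversion suffix at a uniform internal position while keeping the
first molecule's barcode — chimeras act on converted templates because PCR
follows conversion.

## Mapping and methylation calling

Because RRBS reads begin at MspI cut sites by construction, the mapper is
deliberately anchored rather than general: for every fragment up to 300 bp
(longer fragments are excluded from the alignment target) it indexes the
C→T-collapsed read-length prefix of both ends/strands, and a read maps iff
it has a unique best hit within a mismatch budget (default 2, counted on
the collapsed alphabet so conversion never counts as mismatch). Ties and
collapsed-key collisions are unmapped as ambiguous, since the
informative-read definition — mapped uniquely *and* covering at least one
CpG — requires uniqueness. This anchored design is not equivalent to a
production short-read aligner; published coverage numbers from real
libraries are context for the analytics here, not reproduction targets.

Methylation is called from the bisulfite transformation observed in the
read, never from the genome: read C at a genomic CpG → methylated call,
read T → unmethylated, anything else (a sequencing error) → no call.
Conversion efficiency is estimated per sample as T/(T+C) over covered
non-CpG cytosines, which are assumed unmethylated. One practical
consequence of the collapsed alphabet is that a substitution error landing
on a C/T position is invisible one third of the time, so the fraction of
mapped reads with ≥ 1 mismatch lies between `1-(1-2e/3)^L` and
`1-(1-e)^L` for per-base error `e` — the property the test suite checks.

## Coverage, feature and chimera analytics

* `summarize_coverage()` counts distinct CpGs covered at ≥ 1×/5×/10×
  (coverage = number of calls, not overlapping reads); the counts are
  monotone in the threshold by construction.
* `fragment_profile()` reports, per fragment length, the percentage of
  fragments covered by ≥ 1 read and the mean per-fragment depth with
  zero-covered fragments included — deliberately understating depth, but
  making `sum(n_fragments * mean_depth)` exactly the mapped read count.
* `filter_high_quality()` applies a total-read cutoff (5 million by
  default, the production-scale value; desk-scale simulations pass
  `min_total_reads` explicitly).
* `replicate_correlation()` correlates per-CpG methylation fractions
  between two runs of one sample over CpGs covered at a threshold in both.
  Pearson by default (Spearman available); deeper thresholds trade CpG
  count for better-estimated fractions, which is why agreement improves
  with coverage in a regime where per-CpG depth actually varies.

### CpG islands and friends

`find_cpg_islands()` uses the classical composition criteria: GC ≥ 0.5,
CpG observed/expected `(N_CpG * L)/(N_C * N_G)` ≥ 0.6 (undefined — hence
failing — when a window lacks C or G; a CpG is counted when both bases lie
in the window), and length ≥ 700 bp. Published island callers implement
different search strategies over these criteria; the definition adopted
here is: every candidate start is paired with its longest qualifying end,
overlapping-or-adjacent qualifying intervals are clustered, and each
cluster contributes its single longest qualifying interval (leftmost on
ties). The scan is exact and bounded by `max_length` (default 10 kb, well
above biological island scale); it runs in C++ and is validated against a
brute-force R oracle in the test suite. Note that with permissive
composition thresholds a maximal qualifying interval can extend well
beyond a planted island's edges — island *recovery* is therefore measured
as planted bases covered, not boundary agreement.

Shores are the 2 kb flanks of islands minus any island overlap, merged;
promoters are symmetric TSS windows (1 kb up/down, so strand only matters
for asymmetric windows); tiles partition chromosomes into 5 kb bins with
the final partial tile retained. `score_feature_cpgs()` implements the
80%-of-samples rule with an inclusive comparison on the exact fraction
(4 of 5 samples qualifies), scores classes independently, and
deduplicates CpGs within a class.

### The pooled-amplification chimera experiment

`pooled_amplification_experiment()` rebuilds the classic two-library
design in silico: sample A fully CpG-methylated; sample B with
region-level methylation (2 kb blocks all-0 or all-1, 45% unmethylated by
default) so that roughly 45% of its reads are completely unmethylated.
Each library is simulated amplified separately (chimera rate 0) and as a
pool, reads are classified (completely methylated / completely
unmethylated / partial, over CpG-bearing reads only), and per-class
proportions are compared with two-proportion z statistics. Statistical
nullity is operationalised as |z| < 3 rather than an equivalence bound.
Reads are classified at the CpG offsets of their barcode-labeled origin
fragment end rather than re-mapped: the scientific question is about reads
*assigned to a barcode*, and a mismatch-budgeted mapper would discard
exactly the heavily chimeric reads the experiment needs to see.
Methylation blocks are region-level rather than per-fragment so that the
junction CpG shared by neighbouring fragments almost never straddles two
methylation states.

## Numerical and design choices

* Coordinates: 0-based half-open internally and in BED output; 1-based
  only at Biostrings/IRanges boundaries and in SAM.
* All randomness flows through R's RNG; every generator takes an optional
  seed scoped with `withr::with_seed`, and `run_pipeline()` is a pure
  function of its config (whose seed is mandatory) — report bundles are
  byte-identical across reruns.
* Probabilities from noisy draws are clamped to [0, 1]; island placement
  uses rejection sampling with an explicit failure (an error, not a
  silent retry forever) when the plan cannot fit.
* Ties: island clusters pick the leftmost longest interval;
  ambiguous mapping is never broken arbitrarily — ties are unmapped.
* Degenerate inputs: CpG-free genomes give empty methylomes; empty call
  tables give zero counts; a size selection retaining nothing raises an
  explicit empty-library error; conversion estimation with no covered
  non-CpG C reports `NA`.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
genomes of 20–200 kb with 2–12 samples and 10³–10⁵ reads per library —
sizes chosen so the whole suite completes in minutes while every
statistical check retains power (e.g. ≥ 10⁵ non-CpG cytosine observations
for conversion recovery, 10⁵ reads per condition for the chimera null).
The same code paths scale to real genomes: digestion and island detection
are linear and bounded-quadratic scans, and the mapper is hash-based.

## Known limitations

* The anchored mapper requires reads to start exactly at cut sites; it is
  unsuitable for trimmed or shifted real-world reads.
* No indels, no quality-aware calling, no PCR duplicate model, no
  adapter-dimer or index-hopping simulation.
* The gel-free retention tail and the chimera mechanism are qualitative
  stand-ins with tunable parameters, not fitted curves.
* Island detection reports one maximal interval per qualifying cluster;
  recursive sub-island structure inside a long cluster is not resolved.
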
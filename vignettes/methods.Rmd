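---
title: "Ranking-and-recovery enrichment of cis-regulatory regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking-and-recovery enrichment of cis-regulatory regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisrank)
```

## The model

`cisrank` treats regulatory-feature discovery as a ranking-and-recovery
problem, in the spirit of gene-set enrichment analysis but over genomic
intervals. The scored universe is a fixed database of candidate
regulatory regions (CRRs). Each feature — a binding-motif model or an
experimental track — induces one *total ordering* of that universe, from
the region with the strongest signal to the weakest. A user's input set,
once mapped onto the universe, becomes a *foreground* of region
identifiers, and the question "is feature f active in my regions?"
becomes "does the foreground concentrate at the top of f's ranking?".

This framing has two assumptions worth keeping in mind. First, only the
*order* of scores matters: any monotone transformation of a feature's
scores leaves the analysis unchanged, which makes motif log-odds scores
and arbitrary-unit track signals commensurable. Second, the null model is
implicit and empirical: a feature's AUC is judged against the AUC
distribution of *all other features in the same database*, so the
normalised score (NES) is a relative statement. A database should
therefore contain many features of comparable character — that is why
motifs, open-chromatin tracks, histone tracks and TF ChIP tracks are
normalised as separate databases, and why very small databases are
uninformative (with n features, no NES can exceed √(n−1)).

## CRR database construction

Feature intervals from all source sets are merged, with book-ended
(touching) intervals coalescing — a contiguous stretch of regulatory
evidence becomes one candidate region. Two element classes then carve the
merged regions:

* a region with ≥ `insulator_fraction` (default 0.2) of its length under
  insulator elements, or ≥ `exon_fraction` (default 0.8) under coding
  exons, is removed outright;
* a region below those fractions that still touches such an element is
  *split* at the element boundaries, and only fragments containing no
  excluded base survive;
* fragments shorter than `min_size` (30 bp) are dropped;
* surviving regions shorter than `target_size` (1000 bp) are grown toward
  it — symmetrically when both flanks are free, one-sided when the other
  flank is blocked by an excluded element or a chromosome end, and each
  side up to its own limit when both are constrained. An odd deficit puts
  its extra base on the left flank. Grown regions may overlap; they are
  never re-merged, so the region count is stable through extension.

The exon clause is read in parallel with the insulator clause: the
*region's* covered fraction is compared against 0.8 (not the exon's). The
whole construction is checked, in the test suite, against an independent
per-base mask-and-segment brute force (with 1-bp alternating growth for
the extension), exactly, on randomized toy genomes.

## Scoring

**CRM scorer.** For a motif of length L with position probabilities
p<sub>j</sub>(b) and background q(b), a placement at window w scores
Σ<sub>j</sub> log₂(p<sub>j</sub>(b<sub>j</sub>)/q(b<sub>j</sub>)). The
region score is the maximum, over all sets of mutually non-overlapping
placements on either strand, of the summed placement scores, counting
only placements with positive score. The optimum is exact by dynamic
programming over window starts. `N` bases contribute log-odds 0
(background-equal), so masked sequence neither helps nor hurts. The
scorer deliberately has a one-function surface (`crm_score`) so an
external cluster scorer can be substituted without touching the rest of
the pipeline.

**Cross-genome aggregation.** When orthologous coordinates in additional
genomes are available, each genome yields its own ranking; a region's
per-genome ranks become rank ratios r ∈ (0,1], and the combined statistic
is the joint cumulative probability Q that N independent uniform order
statistics lie componentwise below the sorted ratios, computed by the
standard recursion Q = N!·V<sub>N</sub>,
V<sub>k</sub> = Σ<sub>i=1..k</sub> (−1)^(i−1) V<sub>k−i</sub> r<sub>N−k+1</sub><sup>i</sup>/i!.
A region with no ortholog in some genome is imputed at ratio 1.0
(uninformative) rather than dropped, keeping N constant across regions so
Q values remain comparable. The recursion is validated against Monte-Carlo
estimates (10⁶ draws, agreement within 3 standard errors) in the tests.

**Tracks.** A peak track scores each region by the maximum signalValue of
any peak intersecting it by ≥ 1 bp (no peak → 0); a coverage track by the
max (or mean) per-base value.

**Ties.** Score ties — pervasive for short motifs and sparse tracks — are
broken by a pseudo-random shuffle seeded deterministically from
`(run seed, feature id)`. This makes every ranking a reproducible full
permutation, which the NES determinism guarantee requires; the seed is
recorded in the database metadata.

## Recovery analysis

With foreground size F and a rank cutoff T = `threshold_rank(total,
fraction)` — rounding half-away-from-zero, the rule that reproduces the
published cutoffs 6115/4692/1364 at the published database sizes — the
recovery curve rc(x) counts foreground members at rank ≤ x and

AUC = (1/T) Σ<sub>x=1..T</sub> rc(x)/F.

This unit-width step integral keeps AUC in [0,1] with 1 meaning "entire
foreground at the very top". The default `auc_fraction` is 0.005 (0.5%),
the genome-scale default; on toy universes of a few hundred regions that
window would be 1–2 ranks, so the bundled fixtures analyse at 0.1. NES =
(AUC − μ)/σ uses the *population* σ (divide by n) over all features of
one database — the choice is documented precisely so NES values are
bit-reproducible; σ = 0 yields NES = 0 for all features. The leading edge
maximises rc(x) − (mean(x) + 2·sd(x)) over x ≤ T_le, taking the first
argmax on ties and reporting whether the maximum is positive.

T_le defaults to T, and is exposed as a parameter. The fixture analyses
set T_le = 2T: on a ~170-region universe T ≈ 17 while a realistic
foreground is 30 regions, so a T-sized search window would clip the
target list below the foreground itself; doubling the window removes the
clip without touching the enrichment statistics (AUC and NES do not
depend on T_le).

Combining features re-uses the order-statistic machinery: the selected
features' rank ratios are aggregated region-wise and regions re-ranked by
ascending Q, yielding a new ranking that can itself be analysed.

## Input mapping

Region input: a CRR joins the foreground when ≥ `min_fraction` (default
0.4) of *the CRR's length* is covered by the union of input peaks. The
denominator choice (CRR, not peak) matters when sizes differ; covering by
the union makes the mapping invariant to splitting a peak into abutting
pieces. Gene input: "20 kb around the TSS" is implemented as ±10 kb
(total-width reading, configurable in both total and split); on the minus
strand the window is the exact mirror image about the TSS base. The
fly-style space is the strand-aware upstream window plus all introns. For
gene input a single overlapping base suffices — the fraction threshold
applies to peak input only, where peak geometry is meaningful.

## Annotation layer

Motif similarity is the minimum over ungapped offsets and both
orientations of the mean per-column sum of squared probability
differences, with columns covered by only one motif compared against the
other motif's background (penalising length mismatch proportionally, and
keeping the distance symmetric). Enriched motifs are clustered by
average-linkage on this distance; the cluster count maximises the
Calinski–Harabasz index over k = 2..min(10, n−1, distinct motifs), falling
back to one cluster when nothing finite beats it. Clusters are ranked by
best member NES, members within clusters by NES, giving the
"cluster rank (member rank)" report labels. Motif→TF candidates come from
an evidence-typed table ordered direct > orthology > similarity,
deduplicated keeping the best evidence. Closest-gene assignment uses
target-midpoint-to-TSS distance with lexicographic tie-breaking — the
simplest deterministic rule.

## Synthetic fixtures

`make_case()` emulates, at desk scale, the study conditions the pipeline
targets: an i.i.d. background genome (uniform composition by default, so
log-odds calibration against the scoring background is exact), ~190 CRRs
built *by the real builder* from peak-like features on a 500-bp grid of a
2 × 50 kb genome (target size 400 bp at this scale), 20 motifs of which
one is planted at near-consensus strength (2 sites per region) into 24 of
30 foreground CRRs, and 20 peak tracks of which one carries elevated
signal (10 vs 1, sd 1) on the foreground. Twenty tracks rather than a
handful because the NES of a single outlier among n features is bounded
by √(n−1); a track database must be comfortably larger than 10 for a
NES > 3 call to be reachable at all. TSSs of the fixture's genes sit at
foreground CRR midpoints with ±300 bp windows, so gene-mode and
region-mode foregrounds are nearly identical by construction.

What passing fixture tests does *not* show: the generator has no Markov
sequence structure, no conservation (single genome; the aggregation path
is exercised with N = 1 and separately with constructed orthology
tables), no realistic peak shapes, and no chromatin-domain structure.
Results on the fixtures demonstrate correctness of the machinery and
sensitivity under idealised planting, not performance on real chromatin.

## Numerical choices and degenerate inputs

* Coordinates are uniformly 0-based half-open; 1-based dialects (GTF) are
  converted at the reader boundary. Chromosome names are opaque strings.
* `threshold_rank` clamps to ≥ 1; fractions outside (0,1] are errors.
* Empty foregrounds, foreground ids outside the universe, mismatched
  database/CRR checksums, ratios outside (0,1], and <2 features for NES
  are errors, not silent defaults.
* Absent motif scores (missing orthologs) are NA end-to-end and rank
  after all present scores; they are never conflated with 0.
* PWM counts get a 0.001 pseudocount; rows must sum to 1 within 1e-9.
* The recovery engine is tested to 1e-12 against a from-scratch
  recomputation; interval arithmetic and the CRR builder are tested
  exactly against per-base brute force.

## Limitations

The scorer is a deliberate stand-in for richer CRM models (no HMM state
structure, no inter-site spacing model); NES is a z-score, not a
calibrated p-value; liftOver itself is out of scope (orthology tables are
inputs); and the published genome-scale databases (10⁶ regions, ~10⁴
motifs) are not shipped — the package builds databases from whatever
features the user provides.
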
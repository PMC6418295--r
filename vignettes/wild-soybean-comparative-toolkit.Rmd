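---
title: "Methods: synteny-based variation calling, optical maps, and RIL binmap/QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny-based variation calling, optical maps, and RIL binmap/QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

soykit reimplements, as tested and reusable R functions, the computational
stages that turn a reference-grade wild soybean (*Glycine soja*) assembly
into comparative results: whole-genome synteny blocks, insertion and
transposable-element (TE) insertion calls, large structural variant (SV)
detection, assembly quality metrics, optical genome map (OM) operations,
evidence-merged superscaffolding, and recombinant-inbred-line (RIL) binmap
construction with QTL mapping. Every stage is exercised on synthetic inputs
with planted ground truth, so the package needs no external data.

This vignette records the models, the parameters that matter, and the
design decisions taken where the underlying procedures were originally
manual, tool-internal, or unstated.

## Synthetic data: what it emulates and what it does not

`generate_reference()` draws i.i.d. bases at a target GC fraction (default
0.35, typical of legume genomes), writes TE library copies into the
chromosomes, and lays down non-overlapping gene intervals.
`derive_variant_genome()` applies a validated event plan in a fixed order —
translocations, inversions, insertions, then background SNPs — so that
every event's ancestor coordinates remain well defined, and emits an exact
liftover for every planted breakpoint. Conventions worth knowing:

* TE insertions copy library elements verbatim (tandem-tiled if the
  element is shorter than the requested TE span) plus random filler, so the
  planted TE occupancy of each insertion is controlled to the base.
* Background SNPs are never placed within 200 bp of a planted breakpoint;
  this keeps anchor alignment unambiguous immediately next to events and
  makes breakpoint recovery a property of the caller, not of SNP luck.
* Event application order (translocation → inversion → insertion → SNP) is
  fixed by design so truth coordinates are deterministic.

What the generator does **not** emulate: TE nesting and decay, indel
polymorphism, segmental duplication, sequencing reads, or assembly errors.
Passing the planted-truth tests therefore demonstrates correctness of the
calling rules at anchor resolution, not robustness to misassembly or to
repeat families that defeat unique anchoring.

The RIL generator plants crossovers per line as a Poisson process with
mean `genetic_length_cM / 50` — one crossover per Morgan per F1 meiosis,
doubled for the classical map expansion of selfed RILs. This avoids
simulating six selfing generations while matching the expected RIL
recombination fraction to first order; the cost is a slight (<10%) upward
bias of long-range map length relative to the exact Haldane–Waddington
expectation, which is irrelevant at the 50 Kb bin scale used downstream.
Lines are fully homozygous (residual heterozygosity enters only through
genotyping error). Phenotypes are `sum(effect_i * x_i) + N(0, sigma^2)`
with `sigma` chosen so realized heritability converges to the requested
`h2`. The generation number of real RIL populations is usually unknown;
the 2x expansion is this package's recorded choice, not a claim about any
particular population.

Optical molecules are subintervals of a source map with Gaussian label
sizing error, Bernoulli label drop-out, Poisson false labels per 100 Kb,
and an opaque per-molecule intensity; this mirrors the attributes the
molecule QC rules consume, not the imaging physics behind them.

## Whole-genome alignment: unique-anchor blocks

`anchor_align()` is a deliberately minimal aligner in the
maximal-unique-match tradition: k-mers (default k = 21) occurring exactly
once in each genome (counting both strands) are matched between genomes,
collapsed into same-diagonal runs, merged across gaps ≤ `join_gap`
(default 500 bp; substitution scars inside a collinear segment are only
~k wide), and chained per (reference chromosome, query chromosome, strand)
by iterated weighted longest-increasing-subsequence extraction, so that
displaced (translocated) runs survive as their own chains. There is no
extension beyond exact anchors, and blocks shorter than `min_chain`
(default 1 Kb) are discarded.

Numerical choices: k ≤ 26 keeps 4^k exactly representable in a double, so
k-mer codes are hashed exactly in vectorized arithmetic. Anchors can
extend a few bases across an event edge whenever the first inserted base
happens to equal the reference continuation; consecutive blocks may then
overlap by 1–2 bp on the reference. Such sub-k overlaps are trimmed from
the right-hand block (the convention delta-filter users will recognize),
restoring strict adjacency. All block edges are therefore resolved to
within one anchor length, and all recovery tests use ±k bp tolerances.

`pair_adjacent()` forms pairs only between consecutive blocks sharing
chromosome pair and strand with strand-consistent query order, reporting
signed gaps (`ref_gap = right.ref_start − left.ref_end − 1`; the query gap
measured between query-proximal ends).

## Variation calling rules

The calling thresholds are deliberately literal:

* insertion: query gap strictly > 1000 bp AND reference gap in [0, 100);
  overlapping blocks (negative reference gap) never call an insertion — an
  overlap is not a gap.
* TE insertion: strictly > 80% of the inserted query interval covered by
  the union of TE annotation intervals. Coverage is measured on query
  coordinates ("inserted regions in the query genome"); equality at
  exactly 0.8 is a non-call, and because the ratio of two integers and the
  literal 0.8 round to the same double, the strict comparison is exact.
* TE-affected gene: the reference insertion site intersects the gene
  extended by 500 bp on each side, closed intervals — a site exactly
  500 bp away counts, 501 bp does not.
* Large SVs: maximal block runs — strand-minority runs (inversions), runs
  mapping to a different query chromosome than their flanks
  (inter-chromosomal translocations), and runs whose query order is
  displaced off the heaviest collinear chain (intra-chromosomal
  translocations) — reported only above a strict 100 Kb reference span.
  Where the original procedure checked SV boundaries manually, soykit
  reports the bounding coordinates of the flanking collinear blocks; this
  deterministic rule is auditable and reproducible, at the cost of
  breakpoint precision limited to anchor resolution. Runs are grouped at
  the run level (not per block) before the size threshold; the paper-scale
  alternative (per-block) would fragment large events into sub-threshold
  pieces.

## Assembly statistics

`nxx()` is the standard Nxx family (N50: the largest length L such that
pieces ≥ L cover ≥ 50% of the assembly). Occupancy tracks default to 1 Mb
windows with 500 Kb steps and the GC track to non-overlapping 200 Kb
windows with N bases excluded from the denominator; partial terminal
windows are emitted and flagged rather than dropped. Telomeres are tandem
arrays of CCCTAAA (TTTAGGG on the other strand) with ≤1 mismatch per copy;
an end is telomeric when an array of ≥10 copies lies within 10 Kb of the
end. Those three parameters are this package's defaults — the original
analyses do not state them — and are configurable. Centromeric monomers
(e.g. the soybean 91/92 bp families) are user inputs; matching is
substitution-only at ≥80% identity with hits merged within one monomer
length, a controlled stand-in for BLAST local alignment that behaves
identically on tandem arrays. In silico PCR consolidates the three tools
traditionally combined (isPCR, e-PCR, BLAST) into one matcher: ≤2
substitutions per primer with an exact 3′ trinucleotide, opposite strands,
facing 3′ ends, product strictly < 1000 bp, and "multiple best hits"
interpreted as more than one valid product at the best total-mismatch
tier.

## Optical maps

Labels sit at the forward-strand start of every recognition-motif
occurrence on either strand; the constant within-motif nick offset cancels
in comparisons and is ignored. Label merging clusters neighbours < 1 Kb
apart greedily left-to-right and replaces each cluster with the rounded
midpoint of its extremes — the output is idempotent and pairwise ≥ 1 Kb
separated. Molecule QC removes molecules with length < 150 Kb, intensity
> 0.6, or < 9 labels (any rule suffices; all triggered reasons are
recorded). The repetitive-map filter removes maps in which ≥ 90% of
inter-label gaps lie within ±10% of the modal gap — an explicit, testable
stand-in for the unpublished "lowden" heuristic of OM preprocessing tools.
`align_maps()` is a fitted dynamic program over label pairs: cumulative
spacing must agree within `sizing_tolerance` per spanned interval
(default 1.5 Kb), interior skips are penalized on both maps, unaligned
margins of the reference map are free, and both orientations are tried
with ties broken toward fewer skips then forward orientation. Regions
supported by fewer than 30 spanning molecules are excluded from
comparative analysis.

## Superscaffold merging and gap closing

Two contig orderings (Hi-C-derived and optical-hybrid-derived) are merged
on an orientation-aware adjacency graph in which an adjacency equals its
mirror image ((A+,B+) ≡ (B−,A−)). Shared adjacencies carry evidence
"both"; source-exclusive adjacencies keep evidence "hic" or "map" unless
the other source puts a different neighbour on one of the same contig
ends. The sources are not ranked: contradictions join neither side and are
reported, which is the conservative, auditable choice when no arbitration
evidence is available. Gap closing searches for head-to-tail identical
flank copies (longest suffix/prefix overlap ≥ 500 bp at ≥ 98% identity,
seeded by exact 20-mers so mismatched overlaps are still found) and closes
a gap only when long-range one-copy evidence strictly exceeds two-copy
evidence and reaches a minimum count (default 5; ties keep the gap —
sequence is never destroyed on ambiguous evidence). Evidence is abstracted
to counts so the decision rule is testable without read mapping.

## RIL binmap and QTL scan

SNP filters: locus quality strictly > 30; no 10 bp window may hold 3 or
more loci; calls not matching a parental allele become missing and
all-heterozygous loci are dropped; ≥ 20 genotyped lines per locus.

Window genotyping uses 15-SNP windows advancing 1 SNP. The majority rule
inside the window is applied proportionally: a window is called homozygous
when ≥ ceil(11/15 × informative) of its non-missing calls agree, is H
otherwise, and is missing below 5 informative calls. The proportional form
keeps the intended 11-of-15 stringency when calls are missing; the exact
rule in the original "modified sliding window" is not published, so this
is a recorded, configurable decision. Breakpoints are emitted between the
last window of one homozygous state and the first of the other, with the
transition region (including intervening H/missing windows) as the
uncertainty interval and its midpoint as the point estimate.

A window-based caller cannot see crossovers closer than one window span
to a chromosome end or to each other (the flanking homozygous states are
never both observed). Recovery statements in the tests and the acceptance
script therefore quantify recovery over *detectable* crossovers — those at
least one 15-SNP window span from ends and neighbours; on clean data
recovery of detectable crossovers is complete.

Bins: breakpoint point estimates are snapped to the nearest 50 Kb grid
boundary (half-up, so exact cell midpoints resolve deterministically) and
adjacent grid cells with identical genotype columns across lines are
merged. A chromosome without breakpoints is one bin; a breakpoint at
1.23 Mb produces exactly one bin boundary, at 1.25 Mb.

Genetic distances derive from adjacent-bin discordance R (H/missing
excluded). Because selfed-RIL discordance is map-expanded, R is converted
to the meiotic recombination fraction r = R / (2(1−R)) before the map
function — the same treatment standard RIL map software applies — with
Kosambi as default (standard in soybean maps) and Haldane selectable;
fractions ≥ 0.5 are capped at 0.4999 with a warning. The raw closed forms
are exported as `kosambi_cM()` / `haldane_cM()`.

The LOD scan is Haley–Knott style single-QTL interval mapping on a 0.5 cM
grid: the phenotype is regressed on the expected genotype given flanking
bins and `LOD = (n/2) log10(RSS0/RSS1)`; with one predictor this is
computed from squared correlations, which makes the 1000-permutation
null (genome-wide max LOD per permuted phenotype, threshold at the
empirical 1−α quantile, α = 0.05) a single matrix product. A composite
mode with forward-selected cofactors excluded within the 10 cM scan
window is available but plain interval mapping is the default and the
calibrated mode; full composite-interval-mapping internals of legacy QTL
software are out of scope. QTL are maximal super-threshold runs with a
1.5-LOD support interval.

## Problem sizes used in the tests and acceptance script

The standard benchmark (`sv_benchmark()`) is a 10 Mb, 3-chromosome pair
with five insertions (1.5–8 Kb, TE occupancies 0.95/0.88/0.82/0.80/0.65),
150 Kb and 90 Kb inversions, a reciprocal 1 Mb-tail translocation, and
2×10⁻³ background SNPs — divergence in the range separating wild and
cultivated soybean assemblies. Oracle-equivalence checks run the aligner
against a per-base diff oracle on 30 Kb insertion-only pairs and the Nxx
statistic against brute-force enumeration on random length multisets. QTL
calibration uses 96 lines, one 100 cM chromosome, 1000 SNPs, 200
permutations per replicate, 200 null and 100 power replicates in the test
suite (smaller replicate counts in the acceptance script); these sizes
were chosen once as the smallest populations on which the binomial bands
of the calibration criteria are meaningful.

## Known limitations

* Anchor-resolution breakpoints: all coordinates carry a ±k uncertainty;
  no base-level breakpoint refinement is attempted.
* Unique-anchor alignment is blind inside long perfect repeats (by
  construction); insertions inside freshly duplicated sequence will not be
  called.
* The centromere matcher and in silico PCR are substitution-only; indel
  divergence in monomers or primer sites is not modelled.
* The OM aligner is pairwise and fitted; multiple alignment of many maps
  and split (chimeric) molecule handling are out of scope.
* `detect_large_svs()` classifies one event per run; nested or adjacent
  SVs closer than one block are reported as their dominant class only.
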
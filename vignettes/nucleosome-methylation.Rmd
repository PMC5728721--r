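---
title: "Methods: nucleosome positioning and DNA methylation analysis"
author: "nucmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleosome positioning and DNA methylation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
procedures it implements, the parameters that matter, the design choices
made where the method left them open, and the limits of what the synthetic
tests demonstrate.

## Scope

`nucmeth` analyses the relationship between nucleosome positions (from
MNase-seq fragments) and cytosine methylation (from per-cytosine bisulfite
counts in the CG/CHG/CHH contexts). It covers: replicate-based nucleosome
positioning-reliability classification with dyad anchoring; anchored
methylation metaprofiles and difference profiles; windowed,
mutant-exclusive DMR calling with a one-sided exact test; FFT quantification
of the ~10 bp rotational methylation periodicity; and self-organizing-map
clustering of dyad-centred methylation matrices. A seeded synthetic-data
generator provides all inputs, so every stage is testable end to end
without sequencing data. Read alignment, external peak callers, and RNA
quantification are out of scope; externally produced peak BEDs and
expression-decile tables are consumed as inputs.

## Nucleosome positioning

**Fragment selection.** Paired-end MNase fragments are restricted to
mononucleosomal sizes, `120 < length < 180` bp with both bounds exclusive.

**Peak calling.** The built-in caller is a deliberately simple stand-in
for dedicated nucleosome-position software: fragment midpoints are
smoothed with a Gaussian kernel (default bandwidth 15 bp, a little under a
quarter of the 147 bp core, wide enough to merge stochastic midpoint
scatter without merging adjacent nucleosomes at a ~177 bp repeat); local
maxima of the smoothed density become summits, and each bound is placed
walking outward from the summit at the half-maximum crossing or the first
flanking minimum, whichever comes first. The density domain extends one
kernel half-width beyond the outermost midpoints so edge peaks keep their
full footprint. Summits below a support threshold
(`min_fragments * dnorm(0, sd = bandwidth) / 2`, default 3 fragments) are
discarded. Peaks from external callers can be supplied as BED via
`read_bed()` wherever a peak set is consumed.

**Width filter.** Peaks wider than 140 bp are removed (a 140 bp peak is
kept): wide peaks indicate fuzzy positioning rather than a single
well-placed particle.

**Reliability classification.** For each replicate-1 peak, the reciprocal
overlap with a replicate-2 peak is the *minimum* of the two fractional
overlaps — both directions must pass, which is what "reciprocal" overlap
requires. Each peak is classified by its best reciprocal overlap across
replicate 2 in 25% increments: group 1 for fractions in (0.75, 1], then
(0.50, 0.75], (0.25, 0.50], (0, 0.25], and "other" for peaks with no
overlap. Boundaries go to the lower group (a fraction of exactly 0.75 is
group 2), reading "more than 75%" strictly; since the fractions are
continuous, "less than 76%" and "≤ 75%" describe the same set. The groups
partition the input exhaustively. Classification is anchored on
replicate 1; a symmetrised variant (also classifying replicate 2 against
replicate 1) is not applied, as the anchored form is the simpler reading
and the choice only affects which replicate's coordinates are reported.

**Dyads.** The presumptive dyad of a call is the arithmetic mean of the
combined 5'- and 3'-most ends of the member peaks — the midpoint of their
union span — rounded half-up to a base. A replicate-1 peak overlapping
several replicate-2 peaks contributes all of them to the union span
(multiple overlaps allowed) while being classified by its best overlap.
The alternative reading, the mean of *all* member endpoints (which differs
for asymmetric overlaps), is available as
`compute_dyad(..., method = "endpoint_mean")`.

**Shared nucleosomes.** Calls from two genotypes are matched when their
dyads lie within 20 bp, inclusive. Matching is greedy by increasing
distance with ties to the leftmost dyad, and each call matches at most
once.

**Annotation filters.** Genic nucleosomes (147 bp spans around dyads) are
"exonic" on any ≥ 1 bp exon overlap and "intronic" only when entirely
inside a single intron; nucleosomes matching neither rule stay unlabelled.
Heterochromatic TEs are those with > 5% CG methylation, H3K9me2 enrichment
in the upper two quintiles (rank-based quintiles of the supplied scores),
and length > 30 bp.

## Methylation metaprofiles

Anchored profiles pool methylated and total read counts of one context
into offset bins relative to each anchor and report the pooled fraction
`sum(meth) / sum(total)` per bin. Pooled (coverage-weighted) averaging is
the default because it is stable at low per-cytosine coverage; averaging
per-cytosine fractions instead is available via
`weighting = "per_cytosine"`. Strands are pooled as filed; symmetric-CG
collapsing is not performed, since pooling makes it unnecessary. Dyad
anchors are unoriented; TSS/gene anchors can be oriented so minus-strand
offsets are mirrored into the feature's 5'→3' frame. Bin width defaults to
1 bp for dyad-scale profiles; 10 bp bins suit anchor sets such as CTCF
sites. MNase coverage tracks are normalised to reads per million
(`count × 1e6 / total_mapped`) with zero-count bins inside the covered
span reported as 0.

## DMR calling

Chromosomes are tiled with non-overlapping 50 bp windows anchored at
position 0 (the grid phase is not identifiable from the method's
definition; 0 is the natural fixed choice). Per window and genotype,
methylated/total CHH counts are pooled. A window is a candidate DMR for
the focal mutant iff:

1. WT methylation ≥ 10% (`min_wt = 0.10`);
2. relative loss `(f_WT − f_mut) / f_WT > 0.30`;
3. a one-sided Fisher exact test for a *decrease* gives p < 0.01.

The 30% criterion is read as *relative* loss: an absolute 30-point reading
would make windows near the 10% WT floor mathematically uncallable, which
the definition's own floor admits. The test is one-sided because the
definition targets losses; a mutant gain can never be significant. The
p-values are raw (no multiple-testing correction), matching the original
procedure; Benjamini–Hochberg adjustment is available (`p_adjust = "BH"`)
but off by default. Windows that also satisfy all three criteria against
the *other* mutant are discarded, keeping only genotype-exclusive regions;
a significance-only exclusivity variant is provided
(`exclusivity = "significance"`). Surviving windows that are book-ended
(gap exactly 0) merge into DMRs; windows separated by a failing window do
not merge. DMRs can further be required to overlap ≥ 1 bp of annotated TE.

The exact test itself is the hypergeometric tail
`P(X ≤ meth_mut)` with margins fixed, computed through the log-gamma
hypergeometric CDF (`stats::phyper`), which is numerically stable far
beyond the 10^4-read scale of pooled windows. The test suite checks it
against brute-force enumeration of the hypergeometric pmf from binomial
coefficients for every 2×2 table with grand total ≤ 30.

For nucleosome-aware DMR profiles, two anchor sets are derived: dyads of
group-1 nucleosomes whose 147 bp span overlaps a DMR by ≥ 1 bp, and
centres (floor of the interval midpoint) of DMRs disjoint from all
group 1–4 nucleosome spans.

## Rotational periodicity

Fragments of length exactly 147 bp — one full nucleosome core — are
anchors; an optional mask (e.g. heterochromatic TEs) restricts them to a
compartment, requiring full containment. For offsets 1..147 from each
fragment's 5'-most end, counts are pooled across anchors into a per-base
methylation vector. The 5' end defines offset 1 with no
reverse-orientation averaging by default (an option symmetrises the vector
with its reverse; for the cosine modulation centred on the dyad the two
conventions agree in expectation).

The periodogram is raw: missing offsets are imputed with the vector mean
(keeping `n` fixed and adding no spectral component), the vector is
mean-centred, and `power(k) = |DFT_k|² / n` for `k = 1..⌊n/2⌋` is reported
against period `n/k` bp, truncated to ≤ 30 bp for reporting. No taper or
detrending beyond mean removal is applied. Under this normalisation
Parseval's identity reads `2 Σ power(k) = Σ (x − mean(x))²` for odd `n`
(the Nyquist term counts once for even `n`); the tests verify it to 1e-9,
and a unit cosine at period 21 over `n = 147` concentrates all its power
(`n/4`) in the single bin `k = 7`. The period grid is restricted to
Fourier periods `n/k` without interpolation; "a peak at 10 bp" means the
maximising Fourier period rounds to 10 (147/15 = 9.8 or 147/14 = 10.5).
`peak_period()` breaks exact power ties toward the smaller period.

One caveat discovered in validation: for a *stochastic* vector the
spectral ordinates of pure noise are approximately iid exponential, so the
ratio of the maximum to the median over 25–73 Fourier bins exceeds 3
almost surely — a "no bin above 3× the median" flatness check is
unattainable for any noisy input and is not used. Absence of rotational
signal is instead assessed by where the maximum falls and by the collapse
of power in the 10 bp band relative to a modulated counterpart (the
amplitude-zero genotype retains band power more than tenfold below the
wild-type-like one under default conditions).

## SOM clustering

The locus matrix has one row per anchor and one pooled-fraction column per
offset bin; pooling its rows count-wise reproduces the anchored profile
exactly, which the tests assert. A 1×k Kohonen map is trained online:
best-matching unit by Euclidean distance, Gaussian neighbourhood, learning
rate decaying linearly from 0.5 to 0.01 and neighbourhood width from k/2
to 0.3 over 100 epochs (defaults). Missing cells are imputed by column
means for training only. Training is deterministic given the seed
(codebook initialised from sampled rows; row order reshuffled per epoch
from the same stream). These hyperparameters are package defaults; the
settings of the heatmap tool originally used for such clustering are not
recoverable, so a sensitivity check over epochs/rate is the user's
responsibility when comparing against published cluster counts.

Cluster labels are arbitrary. The "phased" cluster is identified post hoc
as the unit whose mean-centred codebook has the largest squared
cosine/sine amplitude at the nucleosome repeat length (default 177 bp =
147 bp core + 30 bp mean linker).

A property of 1-D SOMs worth knowing: with more units than distinct data
modes, the map tiles each mode with several near-identical units
(magnification), so a single unit cannot capture ≥ 90% of a homogeneous
planted class at k = 5 over two classes — neighbouring units split it
roughly evenly, with empty "gap" units in between. The planted-recovery
test therefore matches k to the number of planted classes (k = 2), where
one unit captures the phased class essentially completely; the k = 5
behaviour on simulated heterochromatin is exercised separately through the
phased-cluster score and cluster-restricted profiles.

## The synthetic-data generator

The generator is first-class, tested code. Its defaults are the study
conditions for all property tests, chosen once:

* **Genome**: one 1 Mb chromosome tiled with heterochromatic TE blocks
  (2–8 kb, ~35% of the genome), euchromatic TE blocks (0.2–1 kb, ~10%),
  genes (1–4 kb, ~30%, with alternating exon/intron segments that tile the
  gene exactly), and intergenic gaps. Sizes are scaled-down but
  proportioned like a plant heterochromatin-rich region; 1 Mb yields
  ~5,650 nucleosomes, enough for spectral and recovery statistics while
  keeping any single test in seconds.
* **Nucleosomes**: 147 bp cores, linkers Normal(30, 5) bp rounded and
  clamped at 0, so consecutive dyads are ≥ 147 bp apart (repeat length
  ~177 bp, a typical heterochromatic spacing).
* **Fragments**: per nucleosome, Poisson(20) fragments per replicate;
  midpoints jitter Normally around the true dyad with a per-class sd
  (2 bp in heterochromatic TEs — well-positioned arrays — up to 20 bp
  intergenic); lengths follow a triangular distribution on 137–157 bp
  peaked at 147. Replicates draw from independent substreams of the master
  seed.
* **Methylomes**: cytosine sites are placed at density 0.18 per strand per
  bp and labelled CG/CHG/CHH with probabilities 0.17/0.20/0.63
  (approximating the context mix of a plant genome); sites are shared
  across genotypes so genotype comparisons happen at identical positions.
  Within ±73 bp of a true dyad the methylation probability is
  `core_rate + amplitude · cos(2π·(pos − dyad)/10)` — cosine maximum at
  the dyad, a fixed phase convention that makes tests exact — and
  `linker_rate` otherwise. Read totals are Poisson(10), methylated counts
  Binomial. Per-genotype rates emulate the qualitative genotype structure:
  wild type methylates cores and linkers efficiently with a mild core dip;
  `h1` slightly above wild type; `ddm1` strongly reduced everywhere with
  rotational amplitude 0 (remodeler loss abolishes the rotational
  signal); `h1ddm1` with linker methylation near wild type but
  `ddm1`-like cores. All distributional choices (Normal jitter, Poisson
  coverage, Binomial methylation) are the simplest models carrying the
  structure the analyses consume.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: nucleotide sequence and MNase sequence bias;
context-dependent site clustering (e.g. CG density varying with TE
family); chromatin heterogeneity within a compartment; array phase
decoherence over long distances (linker-length noise accumulates only
±5 bp per linker here, so simulated arrays are more regular than most real
heterochromatin); biological replicate effects beyond resampling noise.
Positive results on synthetic data demonstrate that the *computations*
recover planted structure at realistic coverage, not that any particular
biological claim holds.

A second, purpose-built generator (`simulate_dmr_methylomes()`) plants 100
mutant-exclusive hypomethylated regions (CHH 0.25 → 0.05 at 20× coverage)
and 100 shared-loss decoys lost in both mutants; a correct exclusivity
filter must recover the former (sensitivity ≥ 0.95 observed) and call zero
of the latter.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; BED/CX conversions happen
  only at file boundaries (CX positions are 1-based on disk).
* Dyad rounding is half-up (`floor(x + 0.5)`), deterministic and
  direction-free at `.5`.
* Empty inputs flow through as empty outputs for filters; operations that
  are undefined on empty input (dyads of no peaks, vectors with no
  anchors, periodograms of all-missing vectors) raise errors naming the
  problem.
* Zero-coverage bins/windows are reported as missing (`NA`), never as 0%
  methylation; zero-coverage *count* bins in RPM tracks are genuine zeros.
* Exact-test inputs with a zero grand total are errors; zero margins give
  p = 1 naturally.
* The SOM errors when k exceeds the row count; k = 1 assigns everything to
  one cluster.

## Problem sizes

Unit tests run on 50–300 kb genomes; the spectral and recovery properties
use the 1 Mb default (~5,650 nucleosomes, ~6,500 heterochromatic 147 bp
anchors, ~360k cytosine records per genotype). The full suite completes in
about a minute on one core; the acceptance script in under 30 seconds.

## Known limitations

* The peak caller is a stand-in: it has no peak-shape classification and a
  single bandwidth; for publication-grade positioning use a dedicated
  caller and import its peaks.
* Reliability groups depend on exactly two replicates, anchored on
  replicate 1.
* The periodogram offers no significance machinery beyond the
  amplitude-zero contrast; no multitaper or smoothed estimators.
* SOM results depend on hyperparameters that published heatmap tools do
  not document; only the seed-fixed defaults are tested.
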
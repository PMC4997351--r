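---
title: "Models and methods behind mucinEvol"
author: "mucinEvol authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mucinEvol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucinEvol)
```

# Scope

mucinEvol studies the evolution of copy-number variable subexonic tandem
repeats in mucin-type coding sequences — in-frame repeat units (69 nt, 23
codons by default) encoding proline/threonine/serine-rich (PTS) domains
whose T and S residues are candidate O-glycosylation sites. The package
covers five analysis layers: repeat detection and divergence
partitioning; a dated-tree random-walk neutrality test for cross-species
copy numbers; a multispecies-coalescent stepwise-mutation simulator with
truncation selection; a gene-window scan for clusters of tissue-specific
expression; and Jensen–Shannon conservation profiling with per-segment
nonsynonymous/synonymous summaries. Synthetic-data generators with
machine-readable ground truth make every layer testable without external
downloads.

# Repeat detection

`detectRepeats()` is a frame-constrained seed-and-extend detector for
fixed-length, in-frame units. Candidate starts are scanned
codon-by-codon. Because two units that each sit within `1 - minIdentity`
of their common consensus can differ from *each other* by up to twice
that, seeding and extension use the relaxed pairwise bound
`2*minIdentity - 1`; each collected run is then re-verified unit-by-unit
against the final majority-rule consensus at `minIdentity`, keeping the
maximal contiguous verified stretch.

A tandem array matches itself at every codon-shifted phase with identity
`(U - s)/U` for shift `s`, so several overlapping candidate runs usually
describe the same array. Selection is by unit count, then by a
boundary-penalised match score, then by leftmost start. The boundary
term counts how well the single codon adjacent to each end of a run
continues the consensus: a phase-shifted annotation leaves true repeat
sequence just outside its span (high continuation), while a correctly
phased maximal run is flanked by non-repeat sequence. The term is scaled
by 1/7 — strictly below 1/6, the reciprocal of its maximal range — so it
can break exact match-count ties but can never overturn a strict
one-match advantage. Consensus ties are resolved toward the earliest
unit's base, making results deterministic in the input.

Defaults: `unitLength = 69`, `minIdentity = 0.8`, `minUnits = 2`. These
are declared defaults for a reproducible stand-in for what is usually
manual curation, not a reconstruction of any manual protocol. A trailing
copy shorter than one unit that matches the consensus prefix is flagged
separately and never counted. Coordinates follow the IRanges convention
(1-based closed) inside the package; BED export is 0-based half-open.

# Divergence partitioning

`pairwiseDivergence()` compares equal-length, in-frame units position by
position (no alignment — the repeats it is designed for stay in frame at
constant length). Nucleotide differences are partitioned into synonymous
and nonsynonymous fractional counts by Nei–Gojobori pathway averaging:
all orderings of the differing codon positions are enumerated, each
single-base step is classified by whether the encoded amino acid
changes, and pathway counts are averaged. Pathways through stop codons
are excluded from the average; in the rare degenerate case where every
pathway crosses a stop, all pathways are used with stop-crossing steps
classified by amino-acid change. By construction
`syn + nonsyn == nt` exactly — the partition-closure invariant the test
suite asserts on random codon pairs.

Codon pairs that themselves contain a stop codon are skipped from *all*
counts (nucleotide, synonymous, nonsynonymous, amino-acid) with a
warning. Skipping them only from the synonymous/nonsynonymous partition
would silently break partition closure, which downstream code relies on.

`recurrenceScore()` summarises species-private clustering: for each
species, the fraction of its units whose nearest neighbour in the
divergence matrix is a same-species unit. Ties at the minimum distance
are broken toward a different-species neighbour, which makes the score
conservative: 1.0 requires every unit of a species to be *strictly*
closer to a sibling than to any cross-species unit, the signature of a
lineage-specific duplication burst. Orthologous arrays (unit *i* of each
species closest to unit *i* of the others) score 0.

Ordinary least squares for the three divergence regressions is delegated
to `stats::lm`. A zero-variance response yields an undefined (`NA`)
R-squared rather than 0; a zero-variance predictor is an error.

# Random-walk neutrality test

`simulateWalk()` implements a discrete-time neutral model on an
ultrametric species tree with branch lengths in million years: from the
ancestral state at the root age, every `step` Myr each extant lineage
gains or loses `rate` copies with probability 1/2, independently across
lineages and steps; lineages share their trajectory until their
divergence age. States are clipped at `floor` (default 0 — copy numbers
cannot go negative; `-Inf` disables clipping for diagnostics). The
literal step semantics (fixed magnitude, random sign) admit fractional
states at rates 0.5 and 1.5; that is accepted as-is.

The default configuration is the great-ape analysis: tree
`(((Human:5,Chimpanzee:5):3,Gorilla:8):3,Orangutan:11)`, ancestral state
5 at 11 Mya, rates 0.5/1.0/1.5/2.0 per Myr, 1,000 replicates per rate.
"Variation" is read as the sample variance (n−1 denominator) of the four
terminal states; the comparison below is rank-based, so any monotone
transform (standard deviation, population variance) yields the same
p-value. Observed states are small allele sets per species (Human {5,6},
Chimpanzee {5}, Gorilla {4,5}, Orangutan {6,7}); `observedVariationSet()`
enumerates the Cartesian product (8 combinations) and computes one
variance per combination. Enumeration is the default representation of
observed variation; a single representative variance is equally possible
by passing single-valued sets.

`rankSumTest()` is the package's Wilcoxon–Mann–Whitney implementation:
an exact null by complete enumeration of group assignments whenever
`choose(n+m, min(n,m)) <= 1e6` (ties handled through midranks), and a
normal approximation with tie and continuity corrections otherwise. The
exact path is cross-checked in the test suite against
`stats::wilcox.test` and against an independent enumeration oracle.

One numerical subtlety is documented rather than hidden: at the lowest
rate (0.5 copies/Myr) the neutrality p-value estimated from a single
1,000-replicate draw has a Monte Carlo sampling distribution straddling
0.01 (median ≈ 0.009, spread ≈ ±0.004). `neutralityTest(mcRepeats = k)`
therefore reports, per rate, the *median* p-value over `k` independent
repetitions of the full prescribed test. Each repetition is exactly the
1,000-replicate procedure; the median only reduces estimator variance.
With `mcRepeats = 101` the estimate is stable at ≈ 0.0095 across seeds —
below 0.01 at every rate, but genuinely marginal at rate 0.5.

# Coalescent copy-number simulator

`simulateGenealogy()` samples a neutral Wright–Fisher multispecies
coalescent. Time is measured in units of `4·Ne_ref` generations
(`Ne_ref` = the human effective size, default 10⁴; generation time 25
years). Within a population of relative size `x = Ne_pop/Ne_ref` holding
`j` lineages, the next coalescence is exponential with rate
`choose(j,2)/x`; populations merge at species divergence times converted
by `t_coal = t_years/(genTime · 4·Ne_ref)`. Under these conventions two
samples in a reference-size population have `E[TMRCA] = 1` and carry an
expected `θ` pairwise mutations when mutations fall as Poisson with mean
`θ/2` per unit branch length — the closed-form anchors the acceptance
suite verifies at 10,000 replicates. Chimpanzee `Ne` defaults to twice
the human value; ancestral populations take the reference size; there is
no migration or recombination (a single repeat locus is being modelled).
`thetaFromK()` maps a rate of `k` copy-number events per Myr to
`θ = 4·Ne·(k·genTime/10⁶)`, which equals `k` under the defaults; the
conventional grid spans 0.2–5.5.

`stepwiseCopyNumber()` applies the stepwise (microsatellite-style)
mutation model: each mutation is ±1 copy with probability 1/2; a tip's
copy number is the root state plus the signed sum along its root-to-tip
path, clipped at 0. Truncation selection against maladaptively high copy
numbers (> 12, the highest copy number observed among primates) is
implemented as replicate-level rejection sampling in
`simulateCopyNumbers()`: any replicate with a tip above `maxCN` is
redrawn in full, the acceptance rate is recorded, and an acceptance rate
below 10⁻⁴ aborts with a diagnostic. Rejection is the simplest scheme
consistent with a hard truncation bound; when nothing is rejected the
accepted stream is identical to the unselected stream under the same
seed.

Between-species "variation" is the sample variance of species mean copy
numbers (a pooled-haplotype variance is available behind the `pooled`
flag); within-species variation is the per-species haplotype variance,
scored for species with at least 6 haplotypes (more than 3 diploid
individuals). The ancestral copy number for coalescent runs defaults to
5, matching the random-walk analysis.

`obsVsNullGrid()` compares an observed genotype table to the simulated
null across the θ grid. By design, the null is
simulated on the *shallow great-ape reference tree* while observed
contrasts may span deeper families: each comparison group can name its
observed species and its simulated-null species separately. One honest
caveat, visible in the package's own property tests: with a
deep-divergence neutral null, the between-family excess
(observed/expected > 1) holds only at low θ, because at high mutation
rates the truncated neutral model by itself generates any observed
spread. What is robust across the whole grid is the *row contrast* —
between-family ratios exceed every within-species ratio — together with
within-species ratios falling below 1 for θ ≥ 1.

# Expression window scan

`specificityPvalues()` tests each gene for higher expression in a target
tissue (per *sample*, not per tissue mean, since RPKM-like matrices are
per sample) with the package's one-sided rank-sum test; when the exact
path is infeasible a vectorized normal approximation with identical
corrections is used. All-zero genes get p = 1 with a warning.

`callSpecific()` flags the most significant `quantile` fraction of genes
(default 1%). "Upper 1% of all the p-values" is read as the
most-significant tail — the literal opposite reading would flag the
*least* tissue-specific genes, contradicting the stated intent of
finding significantly higher expression. The type-1 empirical quantile
is used, with ties at the cutoff all included; the quantile is applied
per chromosome (the generator emits one chromosome), with genome-wide
application a matter of passing the whole vector.

`windowScan()` slides a 15-gene window in steps of one gene along the
chromosomal gene order and counts flagged genes per window.
`scanReport()` reports the maximal window, the best window covering a
focal gene, a histogram of window counts, and an enrichment p-value
comparing the focal window's gene p-values against all other genes
(one-sided rank-sum; 1 by convention when no window contains any flagged
gene). When several windows tie at the maximal count — common when an
edge gene of a cluster narrowly misses the cutoff — any of them is a
legitimate argmax; the package's recovery criterion is therefore
tie-inclusive.

# Conservation profiling

`jsdColumnScore()` scores an alignment column by the Jensen–Shannon
divergence (base-2 logarithms, equal mixture weights) between the
column's residue distribution and a background distribution, bounded in
[0, 1]. Defaults follow the established JSD-conservation formulation:
BLOSUM62-implied background frequencies (uniform behind a flag),
pseudocount `1/n` for `n` sequences, and columns with more than 30% gaps
reported as missing. No window smoothing is applied.

`segmentNsRatio()` summarises, per functional segment of a codon
alignment, the ratio `(nonsyn diffs / nonsyn sites) / (syn diffs / syn
sites)` accumulated over all sequence pairs and codon columns
(concatenated counts by default; per-pair averaging behind `perPair`).
Site counts are Nei–Gojobori fractional sites with mutations to stop
codons discounted. Columns with gaps, ambiguity codes or stops in either
member of a pair are skipped. A segment with no synonymous differences
has an undefined ratio, reported missing. "Normalized" is implemented as
division by the ratio over all retained segments (`whole`, the default),
with `max` and `none` available, since no single normalization is
canonical. Segments whose name matches `PTS` are excluded by default:
copy-number change makes alignment columns in repeat regions
unreliable.

# Synthetic data and what passing tests mean

The generators emulate the shapes of the analysis inputs — mucin-like CDS
with planted 69-nt in-frame repeats, diploid copy-number genotype panels
with stated allele ranges, and a GTEx-like gene-by-sample RPKM matrix
with tissue labels — with ground truth recorded in sidecars that the
recovery tests consume.

- `makeRepeatCds()` / `makeCdsFamily()` draw repeat units from a
  T/S/P-biased codon pool (T+S codons weighted so units are
  O-glycosylation-rich, `tsFraction` ≥ ~0.3) and flanks from a disjoint
  low-T/S codon pool. `makeCdsFamily()` evolves an array along the
  species tree under infinite-sites bookkeeping — every substitution
  event takes a fresh unit position and a base different from the one it
  replaces — so the pairwise nucleotide distance between any two unit
  lineages equals the number of events separating them, and the sidecar
  event-distance matrix is an exact oracle for the divergence matrix.
  Substitutions avoid each unit's first and last codon. This is an
  identifiability guarantee, not a convenience: when a substitution hits
  an edge unit's boundary codon *and* the flank locally continues the
  consensus, a phase-shifted annotation of the same array becomes
  content-equivalent to the planted one and no detector can distinguish
  them. A fixture generator must produce recoverable ground truth, so
  the degenerate construction is excluded by design. Species-private
  duplication bursts rewrite one tip's array as near-identical copies of
  a source unit, producing the recurrent-expansion signature.
- `makeGenotypeTable()` samples diploid rows uniformly from per-species
  allele sets (defaults mirror the observed great-ape ranges), with an
  all-heterozygous option for small panels.
- `makeExpressionMatrix()` uses a log-normal model: per-gene levels
  `Lognormal(meanlog = 1, sdlog = 1)` with per-sample scatter
  `sdlog = 1`, 5 target-tissue samples and 52 single-sample other
  tissues (the ambiguity of whether "52 others" counts tissues or
  samples is parameterized), and a contiguous cluster (default 10 genes)
  multiplied by the fold-change (default 5) in target samples only.

Passing tests on these fixtures show that the algorithms recover planted
signal under clean generative assumptions: uniform substitution
placement without transition/transversion bias, no alignment error, no
sequencing noise, log-normal expression without batch structure, and
neutral demography without migration. They do not show robustness to
misassembled reference repeats, alignment artifacts in repeat regions,
GC-biased mutation, or expression normalization artifacts — the known
failure modes of the corresponding real-data analyses.

# Problem sizes and numerical choices

The test suite runs at the analysis's full scale where that is cheap (1,000
random-walk replicates per rate; 1,000 detection fixtures; 2,000-gene
expression matrices; 100 seeded recovery runs; 10,000-replicate
closed-form anchors) and at reduced replicate counts for the coalescent
grid (150–200 replicates per θ), sizes chosen so the whole suite
completes in a few minutes on one CPU. Monte Carlo assertions use
3-standard-error bands around closed forms. All randomness flows from
explicit integer seeds; identical seed and configuration reproduce every
output bit for bit, including rejection histories.

# Limitations

- The repeat detector assumes a known, fixed unit length and in-frame
  units; it does not handle unit-length polymorphism or frameshifts.
- Pathway averaging treats all pathways as equally likely and applies no
  multiple-hit correction; distances are difference counts, not
  substitution-rate estimates.
- The coalescent model is single-locus, panmictic per species, constant
  `Ne`, and without migration; selection is a hard truncation, not a
  fitness gradient.
- The expression scan performs no normalization and no multiple-testing
  correction beyond the quantile rule; it assumes the input matrix is
  already RPKM-like.
- Tree inference, multiple alignment construction, ortholog discovery
  and branch-site likelihood tests are out of scope; alignments and
  dated trees are inputs.
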
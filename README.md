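# mucinEvol

Evolutionary analysis of copy-number variable subexonic tandem repeats
in mucin-type coding sequences.

Mucins owe their function to densely O-glycosylated PTS
(proline/threonine/serine-rich) domains encoded by tandem repeats that
sit *inside* a coding exon — so gaining or losing a repeat copy changes
protein length in frame. These repeats mutate fast, vary in copy number
within and between primate species, and can expand recurrently in
single lineages. mucinEvol is for evolutionary genomicists who want to
ask, with reproducible code instead of one-off scripts:

- where are the in-frame repeat units in a CDS, and how many copies are
  there (`detectRepeats`)?
- how much of the divergence between repeat units is synonymous vs
  nonsynonymous, and does T+S content stay constant while sequences
  diverge (`pairwiseDivergence`, `divergenceRegressions`)?
- do a species' repeats cluster with each other (recurrent,
  lineage-private duplication) or with their orthologs
  (`clusterRepeats`, `recurrenceScore`)?
- is the observed cross-species copy-number variation *lower* than
  neutral drift predicts (`neutralityTest`,
  `simulateCopyNumbers`/`obsVsNullGrid`)?
- do tissue-specific genes cluster around a focal gene on the
  chromosome (`specificityPvalues`, `windowScan`, `scanReport`)?
- which protein segments are conserved, by Jensen–Shannon divergence and
  by nonsynonymous/synonymous contrast (`conservationProfile`,
  `segmentNsRatio`)?

## The two neutral models at the core

**Random walk on a dated tree.** Copy number starts at 5 in the
great-ape ancestor 11 Mya and, every million years on every extant
lineage, gains or loses a fixed amount *r* ∈ {0.5, 1.0, 1.5, 2.0} with
probability ½, lineages sharing their trajectory until their divergence
(8 Mya for gorilla, 5 Mya for human–chimpanzee). Per replicate the
variance of the four terminal states is computed; the observed allele
sets (Human {5,6}, Chimpanzee {5}, Gorilla {4,5}, Orangutan {6,7})
expand into 8 combination variances; a one-sided Wilcoxon rank-sum test
asks whether observed variation is smaller than the 1,000 simulated
variances.

**Multispecies coalescent with stepwise mutation.** Genealogies are
drawn under a Wright–Fisher coalescent (time in units of 4·Ne
generations, Ne = 10⁴, generation time 25 y, chimpanzee Ne doubled);
mutations fall as Poisson(θ/2 × branch length) with
θ = 4·Ne·(k·25/10⁶) = k for k copy-number events per Myr (grid
0.2–5.5); each mutation steps the copy number ±1; replicates with any
copy number above 12 are rejected (truncation selection). Observed
within- and between-species variation is compared to the simulated null
per θ.

## Worked example

Generate a synthetic orthologous CDS family with a planted duplication
burst in orangutan, detect the repeats, and score recurrence:

```r
library(mucinEvol)

fam <- makeCdsFamily(burst = list(species = "Orangutan", copies = 5,
                                  subs = 1), seed = 7)
detectRepeats(as.character(fam$cds[["Orangutan"]]), species = "Orangutan")
#> RepeatAnnotation for cds (Orangutan)
#>    5 full unit(s) of 69 nt
#>    spans 61 - 405

div <- divergenceMatrix(fam$units)
div
#> RepeatDivergence over 20 units from 4 species
#>   mean pairwise nt differences: 8.879
round(recurrenceScore(div), 2)
#>      Human Chimpanzee    Gorilla  Orangutan
#>          0          0          0          1
```

Every orangutan unit's nearest neighbour is another orangutan unit
(score 1): the planted lineage-private expansion is recovered, while the
orthologous arrays of the other species score 0.

The copy-number neutrality test under the default great-ape
configuration:

```r
nt <- neutralityTest(seed = 1, mcRepeats = 101)
nt[, c("rate", "p_value", "mean_sim_var", "mean_obs_var")]
#>   rate  p_value mean_sim_var mean_obs_var
#> 1  0.5 9.72e-03         2.25        0.917
#> 2  1.0 5.32e-06         7.91        0.917
#> 3  1.5 1.57e-06        14.52        0.917
#> 4  2.0 1.29e-06        22.37        0.917
```

At every gain/loss rate the observed variance of great-ape copy numbers
(mean 0.92) sits far below the neutral expectation (2.3–22), and the
one-sided rank-sum p-value is below 0.01: the observed copy-number range
is narrower than drift predicts, the signature of adaptive constraint.

`runPipeline(outDir, seed)` chains all stages on synthetic data and
writes TSV/JSON results plus a manifest from which the run is exactly
reproducible.

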
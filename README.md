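# ltrclone

Genotyping LTR-retrotransposon insertion polymorphism from short reads of
single individuals, and testing whether those insertions are inherited
clonally or shuffled by sex.

## The problem

Long-terminal-repeat (LTR) retrotransposons insert at essentially random
genomic positions, so a shared insertion site is strong evidence of shared
descent. In organisms whose reproductive mode is in question — bdelloid
rotifers being the canonical case, since males have never been observed —
polymorphic insertion sites double as inheritance markers. Under strict
clonality, presence/absence patterns across insertion loci must be *nested*
(each new insertion arises once, inside one lineage); under outcrossing sex,
variation is shuffled among loci. `ltrclone` implements that whole chain of
inference:

1. **Tag library.** Full-length elements (annotated 5' and 3' LTRs) are
   filtered — removed if a predicted gene overlaps either LTR, if an `N`
   base sits within 150 bp of the element (possible mis-assembly), or if a
   separate repeat annotation gives no homology support. Each retained
   element yields two 100 bp *LTR-tags* spanning its insertion boundaries,
   50 bp genomic flank + 50 bp element terminus each. Tags within pairwise
   divergence 0.1 are collapsed as orthologous.
2. **Scoring.** Each sample's reads are locally aligned to the tags
   (`minid` 0.5). Per tag the single best read (most alignment matches
   M, penalised by mismatches X) gives the presence score

   S_i = ((M_Li − X_Li) + (M_Ri − X_Ri)) / 200,

   1 for a perfectly covered insertion, ≈ 0.5 for the empty site (only the
   genomic half of each tag matches). Scores strictly above 0.875 are coded
   present.
3. **Clonality statistics.** The binarized matrix is tested for nestedness:
   parsimony consistency index (CI = 1 means no homoplasy) over an
   exhaustive or seeded-heuristic most-parsimonious tree search with Fitch
   lengths, four-gamete compatibility, and the standardized index of
   association r̄\_d with a permutation null (each locus shuffled
   independently).
4. **Frequency of sex.** A forward-time Wright–Fisher model with
   facultative sex (probability σ of sexual reproduction per offspring,
   Poisson(θ) new insertions per genome per generation at unique sites,
   per-copy loss μ) generates reference tables over a log10-uniform prior
   σ ∈ [10⁻⁷, 1]; rejection ABC accepts draws whose (CI, r̄\_d) lie within
   Euclidean distance 0.05 of the observed statistics.

A synthetic-data module generates genomes with planted elements, clonally
derived individuals with known presence/absence, and error-bearing reads, so
the full pipeline runs and is tested without any external data.

## Worked example

The `analysis/` scripts run the whole study in four stages:

```sh
Rscript analysis/01_simulate.R        # synthetic population + reads
Rscript analysis/02_tags_and_scores.R # tag library, scoring, binarization
Rscript analysis/03_clonality.R       # CI, compatibility, r_bar_d
Rscript analysis/04_abc.R             # rejection ABC on sigma
```

Stage 2 prints the score matrix for five clonally derived individuals and
eight planted elements (rows truncated here):

```
     ltr01 ltr02 ltr03 ltr04 ltr05 ltr06 ltr07 ltr08
ind1 0.970 0.945 0.945 0.980 0.985  0.96 0.950 0.990
ind2 0.955 0.990 0.975 0.970 0.955  0.93 0.500 0.530
ind4 0.980 0.980 0.510 0.505 0.500  0.52 0.505 0.530
Binary matrix reproduces the planted truth in 100% of cells.
```

Carried insertions score ≈ 0.93–0.99 (the best read rarely covers all 100
tag bases exactly), empty sites ≈ 0.5, and binarization at 0.875 recovers
the planted truth exactly. Stage 3 then reports

```
Consistency index: 1.000 (mp length 8)
Laminar (nested/disjoint carrier sets): TRUE
I_A = 1.083, r_bar_d = 0.155, permutation p = 0.022
```

— perfect nesting and significant multilocus association, the clonal
signature. Stage 4 accepts simulations down to σ ≈ 10⁻⁷:

```
Posterior quantiles of sigma:
    2.5%      25%      50%      75%    97.5%
1.44e-07 1.94e-06 8.71e-05 5.94e-03 2.47e-01
Sigma values below 1e-3 are accepted: strictly clonal evolution is not rejected.
```

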
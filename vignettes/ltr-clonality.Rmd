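---
title: "Insertion-site genotyping and clonality inference with ltrclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insertion-site genotyping and clonality inference with ltrclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrclone)
```

## The method in one paragraph

LTR retrotransposons insert at effectively unique genomic sites, so each
insertion is a heritable binary marker: an individual either carries the
element at that site or carries the ancestral empty site. `ltrclone`
genotypes such markers in short-read data from single individuals using
100 bp boundary tags, assembles a samples × loci presence/absence matrix,
and asks whether the pattern of variation is tree-like (clonal) or shuffled
(sexual) — first with descriptive statistics (parsimony consistency index,
character compatibility, standardized index of association), then by
estimating the frequency of sex σ with rejection ABC against a
facultative-sex Wright–Fisher simulator.

## Boundary tags and the presence score

A usable marker needs a trustworthy insertion boundary. Candidate
full-length elements are dropped when

* a predicted gene overlaps the 5' or 3' LTR itself (any overlap ≥ 1 base):
  gene-overlapping "LTRs" are frequently mis-annotation;
* an `N` base occurs within 150 bases upstream or downstream of the element
  span, a sign of local mis-assembly;
* no interval of an independent repeat annotation overlaps the element span
  (missing homology support); or
* less than 50 bases of scaffold remain on either side (no room for a tag).

Each retained element contributes a *left* tag (genome positions
`[start − 50, start + 50)`, crossing the upstream boundary) and a *right*
tag (`[end − 50, end + 50)`). For minus-strand elements both tags are
reverse-complemented and swapped so "left" is always the element-5'
junction in element orientation — a convention, invisible to the score,
that keeps tag headers interpretable. Tags marking the same insertion found
from different assemblies are merged by single-linkage clustering at
uncorrected p-distance < 0.1 over the concatenated 200 positions; distance
is computed ungapped on the joint left+right sequence because the two tags
of a pair describe one insertion event and should be collapsed jointly.
The cluster representative is the lexicographically smallest element id, a
deterministic tie-break.

Scoring aligns every read locally against every tag (Smith–Waterman with
match +1, mismatch −1, gap open −2, gap extend −1, both orientations);
alignments with identity below 0.5 over the aligned span are discarded. A
shared-12-mer prefilter skips read/tag pairs that cannot align usefully; it
is a pure performance device and can be disabled. Per tag, the single best
read — most matches M, ties broken by fewer mismatches X, then read id —
defines the side statistics, and

$$S_i = \frac{(M_{Li} - X_{Li}) + (M_{Ri} - X_{Ri})}{200}$$

is the presence score, floored at 0 (the raw value can go negative past 50%
mismatches; the floor keeps S in [0, 1]). "Best read" is selected per side
independently: two 100 bp tags sit kilobases apart, so no single short read
can cover both. A side with no aligned reads contributes 0, the formula's
literal reading. An empty site yields S ≈ 0.5 — each tag's genomic half
matches perfectly and its element half not at all — so the strict presence
threshold S > 0.875 (no more than half a tag's context missing across both
tags) separates the two cases with a wide margin; 0.8 or 0.9 give the same
binarization on the synthetic fixtures, and the boundary value 0.875 itself
codes absent. External alignments (SAM/BAM against the tag FASTA) can
replace the built-in aligner; mismatches are taken from extended CIGAR
`=`/`X` operations when present, else the MD tag, else NM minus indel
bases.

## Clonality statistics

Monomorphic loci carry no signal and are excluded throughout. The
*consistency index* is CI = (number of polymorphic loci) / (length of the
most-parsimonious tree), since a binary character needs at least one change.
Tree search is exhaustive over all unrooted topologies up to 8 individuals
((2n−5)!! ≤ 10,395) and otherwise a seeded nearest-neighbour-interchange
hill-climb from 10 random starts, flagged `heuristic` in the output. The
Fitch pass propagates state sets leaf-to-root; the basal multifurcation of
an unrooted tree is combined child-by-child, which equals rooting along an
edge and is exact. By default `consistency_index()` first runs the pairwise
four-gamete test: for binary characters pairwise compatibility implies a
perfect phylogeny, so CI = 1 can be returned without any search
(`method = "search"` forces the full path; the tests use it so the CI ↔
compatibility cross-check stays independent).

The *index of association* compares the variance of pairwise multilocus
distances V_O with its no-association expectation V_E = Σ_j Var(d_j):
I_A = V_O/V_E − 1, and the loci-count-corrected
r̄_d = (V_O − V_E) / (2 Σ_{j<k} √(Var d_j · Var d_k)), which is 1 for
perfectly correlated loci. Population variances (divide by the number of
pairs) are used consistently; the ratio-form statistics do not depend on
that denominator choice. Individuals are treated as haploid binary
genotypes: for presence/absence data the statistics are invariant to
recoding each locus as a codominant diploid genotype, so the haploid coding
is a presentation choice, not a modelling one. The permutation null
shuffles each locus column independently (the free-recombination
expectation) and reports p = (1 + #{r̄_d,perm ≥ r̄_d,obs}) / (n_perm + 1)
with n_perm = 999 by default; an exhaustive mode enumerates the exact null
through weight-preserving column patterns (shuffling a column uniformly is
uniform over the patterns with the same number of carriers, each equally
likely), feasible for small matrices.

## The facultative-sex simulator

The simulator is a forward-time Wright–Fisher model, written as an explicit
re-implementation of the facultative-sex coalescent target: constant
population size N, discrete non-overlapping generations. Each offspring
clones a uniform parent with probability 1 − σ; with probability σ it draws
two parents and inherits each locus independently from either with
probability ½ — free recombination, appropriate for TE loci dispersed
across the genome. New insertions arise Poisson(θ) per genome per
generation at globally unique sites (infinite sites); every carried copy is
excised with probability μ per generation. After 10·N burn-in plus 10·N
further generations, `sample_n` individuals are drawn without replacement,
loci monomorphic in the sample are dropped, and columns are uniformly
subsampled to `n_loci` (reruns with fresh seeds, up to 100, if too few; the
error suggests raising θ).

Defaults are N = 50, θ = 0.1, μ = 0.01, sample size 10, 20 loci. These were
chosen once as a desk-scale regime that reliably yields 20–40 polymorphic
loci in a 10-individual sample — enough polymorphism for the statistics to
discriminate — with an equilibrium copy number (θ/μ = 10 per genome) in a
biologically plausible range, and they are not tuned per analysis. Note
that μ > 0 permits homoplasy even under σ = 0 (the same insertion lost
twice), so CI = 1 is guaranteed only in the loss-free clonal regime; the
simulator's loss process is exactly what the descriptive statistics must be
robust against.

## Rejection ABC

σ is drawn from a log10-uniform prior on [10⁻⁷, 1] (a grid mode is
available); each draw is simulated at the observed matrix shape and
summarized as (CI, r̄_d) — the same two statistics computed on the observed
matrix, by the same code. The summary vector is deliberately small and
pluggable; CI and r̄_d are the two statistics the clonality analysis is
built on. Draws within Euclidean distance 0.05 of the observed vector are
accepted. Distances are computed on the raw statistics by default — both
components live on comparable O(1) scales — with optional per-statistic MAD
normalization; results with and without normalization can be compared via
the `normalize` flag. Reported output is the accepted σ sample, the
acceptance rate and σ quantiles (2.5/25/50/75/97.5%). Zero acceptances
produce a warning carrying the minimum distance rather than an empty
silence. Shrinking the tolerance provably shrinks (or preserves) the
accepted set.

## What the synthetic data does and does not emulate

The generator plants LTR–internal–LTR elements with identical terminal
repeats (a newly inserted element) into i.i.d.-base genomes, derives
individuals by clean excision of absent elements, and simulates single-end
reads with uniform starts, both strands, and i.i.d. substitution errors at
fixed base quality. Deliberately *not* modelled: target-site duplications
(so junction arithmetic stays exact), solo-LTR recombination remnants,
indel sequencing errors, paired-end structure, amplification bias, and
diploid/tetraploid genome structure — real bdelloid samples are degenerate
tetraploids, and a hemizygous insertion could in principle halve the
effective read support without changing the best-read score's logic.
Passing tests therefore demonstrate the correctness of the machinery on
clean haploid ground truth, not robustness to assembly artefacts or ploidy
effects in real data.

## Numerical and design notes

* Internal coordinates are 0-based half-open everywhere; GFF3 (1-based
  inclusive) is converted at the I/O boundary, BED consumed natively.
* All generators and stochastic analyses are bit-reproducible from a single
  integer seed; child seeds are derived with a seeded draw so stages are
  independent of each other's consumption of the RNG stream.
* Collapse threshold comparisons are strict (`< 0.1`); binarization is
  strict (`> 0.875`); identity filtering keeps alignments at exactly the
  minimum identity.
* Reads aligning equally well to two collapsed tags count for both: scores
  are per-tag maxima, not read assignments.
* The exhaustive/heuristic switch for tree search sits at 8 taxa; the
  heuristic equals the exhaustive length on every 5-taxon case in the test
  suite, but co-optimal topology enumeration under the heuristic is
  restart-limited.
* Desk-scale problem sizes are used throughout the scripts and tests
  (5–10 individuals, 8–20 loci, 2,000 ABC simulations vs. the 50,000 a
  production analysis would run); they were chosen so the full analysis
  reruns in minutes while leaving every qualitative conclusion intact.
* Configuration files are YAML rather than TOML: the R ecosystem this
  package sits in has a standard YAML reader and no equally standard TOML
  one, and the config surface is flat enough that the format carries no
  semantics.

## Known limitations

The aligner is exact Smith–Waterman per candidate pair and scales as
reads × tags; for genome-scale tag sets an external mapper via the SAM
route is the intended path. The heuristic tree search does not certify
optimality beyond 8 taxa. ABC posteriors inherit the usual rejection-ABC
caveats: with two summary statistics and a wide prior, flat likelihood
regions (e.g. very small σ in small samples) yield posteriors that mirror
the prior below the scale the data can resolve — which is precisely why
"clonality cannot be rejected" is the strongest supported phrasing.
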
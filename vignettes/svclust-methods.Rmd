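---
title: "Merging structural variants under breakpoint uncertainty: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging structural variants under breakpoint uncertainty: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svclust)
```

## The problem

Structural variants (SVs) called from short-read sequencing carry
*breakpoint uncertainty*: the caller reports a most-probable position, but
the same underlying variant is routinely placed at slightly different
coordinates in different samples. When per-sample call sets are combined
into a population table, one true SV then appears as several distinct
records, inflating apparent variant counts and corrupting downstream
population statistics. The standard remedy is to cluster nearby records of
the same type and replace each cluster by a single merged variant. svclust
implements this merging framework, three clustering strategies of
increasing sophistication, and the quality measures needed to choose among
them.

## Data model

The central object is a genotype matrix with one row per SV record and one
column per sample, entries coded 0 (reference homozygote), 1
(heterozygote), 2 (alternative homozygote). Each row also carries an
interval record: chromosome, 1-based inclusive `[start, end]`, and type
(DEL, DUP, INV, INS). Insertions are given the pseudo-interval
`[POS, POS + |SVLEN| - 1]` so that overlap is defined for every record
pair.

*Merging* a set of rows is elementwise summation of their genotype
vectors. Summation is only meaningful when no sample carries a
non-reference genotype in two of the rows; such a pair is
**merging-incompatible** — in that sample the two records are evidently two
different variants (on the same or opposite haplotypes), not one variant
observed twice. Pairwise compatibility guarantees the merged vector stays
in {0, 1, 2} and per-sample allele counts are conserved; both properties
are enforced and tested.

## Dissimilarity measures and the threshold graph

Two measures are implemented for same-chromosome, same-type pairs with
intervals $g_1, g_2$:

* overlap-based: $D_1 = 1 - |g_1 \cap g_2| / \max(|g_1|, |g_2|)$, in
  $[0, 1]$, with 1 meaning disjoint — so useful thresholds satisfy
  $D_{max} < 1$ and disjoint pairs can never cluster;
* breakpoint-based:
  $D_2 = \max(|start_1 - start_2|,\ |end_1 - end_2|)$ in bp, a metric that
  can remain small for disjoint but adjacent intervals.

Clusters at a threshold $D_{max}$ are the connected components of the
graph with an edge for every pair at dissimilarity $\le D_{max}$.
Candidate edges are generated by a sorted sweep per (chromosome, type)
stratum: for $D_2$ a partner's start must lie within $D_{max}$ of the
record's start; for $D_1$ the partner must overlap, so its start cannot
exceed the running maximum of earlier ends. The sweep provably misses no
edge and is tested for equality against a brute-force all-pairs graph.

## Clustering strategies

**Trivial.** A component containing any merging-incompatible pair is left
entirely unmerged; all other components are merged. This wastes the
compatible sub-structure of mixed components, and as the threshold grows,
components that merged cleanly at smaller thresholds are progressively
poisoned by newly absorbed incompatible records.

**Corrected.** An incompatible component is re-split at the largest
threshold $D < D_{max}$ whose sub-components are all incompatibility-free,
and the sub-components are merged. Only the realized pairwise
dissimilarities within the component (plus a value below the minimum,
giving singletons) can change the sub-component structure, so scanning
that finite set downward finds the exact maximum with finite work; a valid
threshold always exists because singletons are always compatible. No
recursion is needed — all sub-components at the chosen threshold are
simultaneously incompatibility-free by construction.

**Constrained.** The novel strategy uses parent–child trios. A trio
genotype configuration (child, parent1, parent2) is *Mendelian-consistent*
when the child's alleles can be drawn one from each parent; a violation is
a Mendelian inheritance error (MIE). A single true variant whose record is
split across nearby positions leaves a characteristic signature: 2–3
records, non-trivial in the trio, pairwise compatible, whose genotype sum
is Mendelian-consistent (e.g. a child 2/parents 1,1 variant observed as
(2,1,0) — an MIE — plus (0,0,1)). Exhaustive enumeration over $\{0,1,2\}^3$
shows exactly 26 such unordered pairs and 7 triplets exist, and that no
fourth non-trivial vector can ever join a triplet — which is what makes the
combinatorial search tractable. The algorithm:

1. **Group search**: in every trio, find all record pairs/triplets matching
   a mergeable pattern that are (a) pairwise compatible over *all* samples
   and (b) pairwise within $D_{max}$.
2. **Reduction**: groups sharing a record are mutually exclusive. On each
   connected component of the group-intersection graph, greedily accept the
   group detected in the most trios (ties broken at random under the run
   seed), provided it stays compatible with the groups already accepted
   there and the running merged vector remains Mendelian-consistent (or
   all-reference) in every trio.
3. **Constrained agglomeration**: accepted reductions are must-link seeds;
   merging-incompatible pairs are cannot-link. Candidate pairs are
   processed in ascending dissimilarity (ties in genomic order), uniting
   two clusters only if the union contains no cannot-link pair, until no
   cross-cluster pair at $\le D_{max}$ remains. Because every cluster stays
   internally compatible, the union test reduces to disjointness of the
   two clusters' carrier supports.

The stopping rule mirrors the unconstrained strategies' threshold so all
three strategies are comparable at equal $D_{max}$.

## Quality measures

* `f_mei`: per trio, the fraction of *informative* SVs (non-trivial in the
  trio) whose configuration is an MIE. Using informative SVs as the
  denominator is a definitional choice of this package: all-reference
  trios carry no inheritance signal. Per-family values are trio means.
* `mendelian_merge_counts`: per trio, `n_ic` counts merged clusters that
  contained an MIE member and merged into a non-trivial consistent
  configuration (decompositions repaired), `n_cc` counts clusters with no
  MIE member whose merge *created* an MIE. Singletons cannot "result from
  merging" and are excluded.
* kinship separation: with pairwise relatedness estimates (the
  proportion-of-shared-alleles estimator `sxy_kinship` is built in; any
  external estimator can be plugged into `kinship_separation()`), pairs are
  grouped into relationship-coefficient categories; a pair is correctly
  placed when its estimate falls strictly between the neighboring
  categories' extremes, and `s = 1 - L/n_pairs` per category, averaged into
  $\langle s \rangle$. The denominator is the number of pairs in the
  category (the only reading that keeps `s` in $[0,1]$); categories with
  fewer than two pairs are skipped with a warning.
* `hwe_fraction`: per polymorphic SV among unrelated samples, a 1-df
  Pearson chi-square against $p^2, 2pq, q^2$ expectations (no continuity
  correction), Bonferroni-corrected over tested SVs; the reported fraction
  is of SVs *not* rejected at `alpha = 0.05`.

## The null model

`randomize_genotypes()` shuffles genotype rows uniformly within each
SV-type stratum, leaving coordinates untouched: any clustering of the
coordinates keeps its size distribution while the genotype–position
association is destroyed. An ensemble (default 10 replicates, replicate
$k$ seeded `seed + k`) re-scored with the corrected strategy gives the
chance level of every metric; decomposed-SV structure in the data shows up
as the real `n_ic` exceeding the ensemble maximum across the whole grid.
Rows are shuffled genome-wide within type; the shuffle is applied to the
pre-correction matrix.

## The synthetic cohort generator

`simulate_sv_cohort()` produces the ground-truth test bed: true SV loci
with log-uniform lengths (51 bp–100 kb) and uniform allele frequencies
(0.05–0.5) on a 250 Mb chromosome; founder genotypes drawn under
Hardy–Weinberg proportions; descendant genotypes by gene dropping (one
allele transmitted per parent), so the true matrix is Mendelian-clean by
construction. Three error processes emulate real call sets:

* **decomposition** (`p_decompose = 0.2`): a true SV's carriers are split
  into 2 or 3 non-empty subsets (2 parts with odds 2:1, echoing the
  pairs-dominant 26:7 combinatorics) and one record is emitted per subset
  at geometrically shifted breakpoints — the pattern the constrained
  strategy is designed to repair;
* **jitter** (`p_jitter = 0.1`, mean offset 30 bp): breakpoint noise on
  single records;
* **hotspots** (`p_nearby = 0.15`, range 300 bp): some distinct SVs of the
  same type are placed within one another's merge window. Real call sets
  contain clustered distinct variants; without them no
  merging-incompatible cluster ever arises and the three strategies
  coincide, so this term is what makes the comparison non-degenerate.

What the generator does **not** emulate: linkage disequilibrium between
loci, genotyping error in the 0/1/2 calls themselves, sex chromosomes
(all samples are treated as diploid everywhere), chromosome-specific SV
density, and caller-specific breakpoint error distributions. Passing tests
therefore demonstrate correctness of the algorithms under a controlled
error model, not calibrated performance on any particular caller's output.

## Numerical and design choices

* Coordinates are VCF-native 1-based inclusive; overlap length is
  `max(0, min(end) - max(start) + 1)`.
* Missing genotypes (`./.`) are read as reference with a logged count —
  the conservative choice, since it can never create a spurious
  incompatibility; the converse (treating missing as carrier) could.
* Merged representatives span min-start to max-end of their members and
  take the lexicographically smallest member ID; components are processed
  in (chromosome, start, ID) order, so outputs are bit-reproducible.
* All randomness (reduction tie-breaks, null-model shuffles, simulation)
  flows from explicit integer seeds.
* A sample can be a child in one trio and a parent in another; every
  (child, father, mother) triple is evaluated independently.
* Relationship coefficients come from the standard recursive coancestry
  computation on the pedigree, reported for the classes
  {0, 0.0625, 0.125, 0.25, 0.5}.

## Problem sizes used by the test suite

The suite validates the strategies against brute-force references on 100+
random instances of up to ~30 SVs, and the end-to-end claims on simulated
cohorts of 500 true SVs with 30 samples (two trios) — large enough for
stable orderings of the strategies, small enough to run routinely. The
null-model check uses the default 10-replicate ensemble over a six-point
$D_2$ grid.

## Known limitations

* The Loiselle kinship estimator is not implemented (only the
  proportion-of-shared-alleles estimator); `kinship_separation()` accepts
  external estimates.
* Breakend (BND) records are skipped on input; inter-chromosomal events
  are out of scope.
* The greedy reduction step is order-dependent on ties by design (seeded);
  a rejected group is never retried.
* Hemizygous calls on sex chromosomes are treated as diploid genotypes.

## A worked example

```{r example}
ped <- simulate_pedigree(n_families = 1, n_gen2 = 2, n_gen3 = 2,
                         n_unrelated = 24)
sim <- simulate_sv_cohort(n_svs = 500, pedigree = ped, seed = 1)

results <- lapply(c("trivial", "corrected", "constrained"), function(s) {
  cl <- cluster_svs(sim$callset, s, measure = "d2", d_max = 150,
                    pedigree = ped, seed = 1)
  cbind(glance(cl)[, c("strategy", "n_input", "n_output")],
        score_recovery(cl, sim$truth)[, c("recall", "precision")],
        f_mei = mean(f_mei(cl$callset, ped)$f_mei))
})
do.call(rbind, results)
```

The constrained strategy reassembles at least as many decomposed variants
(recall) and leaves at most as many Mendelian errors (`f_mei`) as the
corrected strategy, which in turn dominates the trivial one.
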
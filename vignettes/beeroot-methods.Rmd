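---
title: "Rooting a honeybee SNP panel: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rooting a honeybee SNP panel: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeroot)
```

## The problem

Subspecies of the Western honeybee *Apis mellifera* fall into four
morphometric-genetic lineage groups: A (Africa), M (western and northern
Europe), C (eastern Europe) and O (Middle East). Where the root of the
subspecies tree falls — within Africa, between the A+M and C+O clusters, or
elsewhere — discriminates between competing hypotheses for the species'
geographic origin. The question is usually attacked with a panel of
biallelic SNPs typed across subspecies samples plus outgroup species
(*A. cerana*, *A. florea*, *A. dorsata*) used to locate the root.

Two properties of such panels make the answer fragile. First, most SNP
variation is shared across subspecies and groups, so internal branches are
short relative to sampling noise. Second, individual taxa of mixed ancestry
(in the original panel, *A. m. intermissa*, which carries both A and M
ancestry) can relocate the apparent root. `beeroot` implements the full
analysis chain needed to quantify that fragility — diversity and
differentiation estimators, distance-based trees with locus bootstrap,
consensus and compatibility filtering, categorical outgroup-placement
tallies under taxon exclusion, and split networks — together with a
synthetic panel generator that provides ground truth for every stage.

## Data model

A `genotype_matrix` is samples x loci with calls in {0, 1, 2, NA}: the count
of the alternate allele in a diploid genotype. Every locus is biallelic by
construction of the coding. Haploid samples (honeybee drones) can be marked
in the `sample_sheet` ploidy column and are coded {0, 2}, one allele counted
once where chromosome counts matter. The `sample_sheet` maps each sample to
a subspecies and a lineage group in {M, C, O, A, OUTGROUP}. Supported
formats: a TSV dialect (`read_genotypes(format = "tabular")`) and VCF v4.x
through `vcfR` (GT field; `./.` is missing; phasing ignored; multi-allelic
records rejected in strict mode).

## Polymorphism sharing

Within a unit (subspecies or group), a locus is *polymorphic* when both
alleles are observed among non-missing calls; *private* when additionally
every other unit is monomorphic; *fixed private* when the unit is
monomorphic for an allele observed in no other unit (so a fixed-private
locus is never polymorphic in that unit — the two classes are disjoint).
Outgroup species are excluded both as units and from the "elsewhere"
comparison, because the tabulation describes *A. mellifera* variation.
Loci with no non-missing call in a unit are excluded from that unit's
counts; there is no imputation. Monomorphic-in-panel loci stay in the
matrix (they still inform outgroup distances) but belong to no polymorphism
class. `group_sharing_spectrum()` assigns each locus to the exact subset of
the four groups in which it is polymorphic; bucket counts sum to the locus
count.

## Diversity: Watterson's theta

For a unit with S segregating loci and n sampled chromosomes,

theta = S / a_n, with a_n = sum_{i=1}^{n-1} 1/i.

Missing data make n vary by locus while the classical correction is a
single number per unit. The default uses the modal per-locus chromosome
count (ties broken toward the larger n); `correction = "per_locus"` instead
sums 1/a_{n_l} over segregating loci. Both are defensible; the default
matches the convention of reporting one sample-size-corrected figure per
subspecies. The panel has no sequence length, so theta is reported raw and
per assayed locus, never per base pair; only relative comparisons across
units are meaningful.

## Differentiation: Weir–Cockerham F_ST

`wc_fst()` implements the two-population Weir–Cockerham (1984) moment
estimator for biallelic loci with the full within-individual term: per
locus, variance components a (among populations), b (among individuals
within populations) and c (within individuals, from observed
heterozygosity), combined as the multi-locus ratio of sums
sum(a) / sum(a + b + c). Loci lacking data in either population, lacking
within-population degrees of freedom (mean sample size of one diploid), or
monomorphic across the pooled sample are non-informative and contribute
nothing. The raw estimate may be negative; `fst_matrix()` floors negatives
at zero only when embedding estimates into a distance matrix (neighbor
joining requires a dissimilarity), records every flooring event, and leaves
reported F_ST tables untouched. F_ST is used directly as the distance, with
no -ln(1 - F_ST) transform. Outgroup species enter `fst_matrix()` as
ordinary populations, or pooled into one `OUTGROUP` unit via
`pool_outgroups = TRUE`; because the original analysis is ambiguous about
which convention its group-level tree used, both are exposed and neither is
guessed.

## Distances between individuals

The allele-sharing distance between two diploid samples, over loci where
both calls are non-missing, averages the identity-by-state share
(2 - |c_i - c_j|) / 2 and subtracts it from one (plink `--distance 1-ibs`
semantics, matching the original pipeline). A pair with no shared
non-missing locus is an error naming the pair, not a silent NA.

## Trees, bootstrap, consensus, placement

`neighbor_joining()` is the Saitou–Nei agglomeration with the
Studier–Keppler criterion Q(i, j) = (m - 2) d(i, j) - r_i - r_j. Two
numerical policies matter for non-additive inputs such as F_ST matrices:
ties in Q break deterministically toward the minimal pair in label-sorted
order, and negative branch-length estimates are clamped to zero with the
deficit moved to the adjacent branch of the same join (Kuhner–Felsenstein),
preserving path lengths.

`bootstrap_trees()` resamples loci (columns) with replacement to the
original locus count, rebuilds the distance matrix of the requested kind
and reruns NJ; a replicate whose resampled panel is degenerate (a sample
pair with no shared loci, or no informative loci for some population pair)
is redrawn and counted. Runs are reproducible given the seed. Bootstrap is
available for both distance kinds, since the original description of which
matrices were bootstrapped is generic.

`majority_rule_consensus()` retains exactly the non-trivial bipartitions
present in strictly more than the threshold fraction of trees (default
0.5); supports are occurrence percentages, carried at full precision in the
`supports` attribute and integer-rounded in Newick output.
`filter_compatible()` declares a tree compatible with the reference when
every reference split is compatible with every tree split (two splits are
compatible iff one of the four side-intersections is empty), then computes
a second consensus from the remainder — the competing signal. The original
pipeline performed this filtering step in PAUP* without documenting its
exact predicate; split-wise compatibility is this package's documented
interpretation.

`classify_outgroup_placement()` requires the outgroup leaves to form one
connected subtree (otherwise `"other"`), removes it, and reads the
bipartition its attachment edge induces on the ingroup: `sister_to_X` when
one side is all-and-only group X, `within_X` when a proper subset of a
single group is split off, `between_AM_and_CO` when the bipartition is
exactly {A u M} | {C u O}, else `"other"`. When the attachment point is a
polytomy (possible in consensus trees, never in binary NJ replicates) the
induced bipartition is not unique and the tree is classified `"other"`.
The classification depends only on topology, so it is invariant to leaf
order and branch-length rescaling.

`run_exclusion_analysis()` chains the whole pipeline — drop excluded
subspecies, bootstrap, consensus, compatibility filter, placement tallies
over all replicates and over the post-filter remainder (both are reported,
since it is unknowable from the original description which set the
published percentages used) — deterministically from one seed. The same
base seed is reused across baseline and exclusion runs so locus resampling
is comparable (common random numbers).

## Split networks

`neighbor_net()` builds a circular split system: the NeighborNet
agglomeration provides a circular ordering of taxa (delegated to
`phangorn::neighborNet`; on degenerate inputs whose agglomeration leaves no
defined cycle, such as an all-equal matrix, the input order is used — any
order is then circular), after which the weights of all n(n-1)/2 interval
splits are fit in this package by non-negative least squares
(`pracma::lsqnonneg`) against the observed distances. Splits with weight
below `epsilon` (default 1e-9) are dropped. On additive inputs the
surviving splits are exactly the generating tree's splits with weights
equal to branch lengths; on conflicting inputs incompatible splits coexist,
which is the point of drawing networks. The method choice itself is an
assumption: the original figure does not name which SplitsTree method was
used, and NeighborNet is the standard distance-based default. The dense
NNLS fit is quadratic in taxa in columns, so population-level matrices (a
few dozen taxa) are the intended use; sample-level networks with hundreds
of leaves are out of this implementation's comfortable range.

## The synthetic panel generator

`simulate_panel()` draws a Balding–Nichols frequency hierarchy: ancestral
frequency p per locus, drifted into two super-groups according to the
planted topology ((A,M),(C,O)), then into groups, then into subspecies,
each step Beta(p(1-F)/F, (1-p)(1-F)/F); genotypes are Binomial(2, f). An
admixed subspecies draws each locus's frequency from source group one with
probability alpha, else from source two — admixture at the locus-frequency
level, not ancestry tracts, which matches an unlinked SNP panel. Outgroup
species are fixed per locus: for the rare panel allele with a shared
probability (plus a smaller per-species one), else the common allele.
Fixed loci stay fixed under drift (the Beta is degenerate there), and the
F = 0 and F = 1 boundaries are handled as exact copy and as fixation draws.

Defaults emulate the reference panel's design and behavior, and are the
package's standing definition of "study conditions":

* sample design: the panel's 14 subspecies in 4 groups (with the
  North-African taxon as the A/M-admixed subspecies, alpha = 0.5, assigned
  to group A) plus 3 outgroup species — `study_design()`, with a
  proportional `scale` argument for desk-scale runs (floor of two samples,
  keeping every unit usable for pairwise F_ST);
* L = 1029 loci; ancestral frequencies 0.01 + 0.98 Beta(0.35, 0.35), a
  U-shaped spectrum;
* drift: F_super = 0.01 (the between-group relationships in such panels
  are weakly supported, so the central edges must be short);
  F_group = (A 0.08, M 0.45, C 0.12, O 0.12) and
  F_sub = (A 0.03, M 0.10, C 0.04, O 0.04). The asymmetry encodes the
  population history the panel reflects: African populations with large
  effective sizes (short branches, high within-group polymorphism), a
  strongly bottlenecked western-European M lineage (the long-branch group,
  with by far the lowest per-subspecies polymorphism counts), C and O
  intermediate;
* outgroup fixed-difference probabilities 0.35 (shared) and 0.05
  (per species).

These values were chosen once, during generator design, by matching the
panel's published sharing structure — with them, a simulated panel has
roughly 47% of loci polymorphic in an average subspecies, 58% in an average
group, 31% polymorphic in all four groups, and about five private loci per
subspecies — and the qualitative exclusion behavior (below). They are
deliberately not per-analysis knobs.

Under these conditions the pipeline reproduces the headline robustness
phenomenon as a sign effect: with the admixed taxon present the outgroup's
modal attachment is diverted (typically into or next to the A cluster, or
unresolvable), while with it excluded the modal attachment is
sister-to-the-M-group in the large majority of seeds — the long-branch
attachment the drift asymmetry implies. The acceptance suite runs this
experiment at `study_design(0.25)` (about 51 samples), 100 bootstrap
replicates, 20 seeds; the acceptance script re-runs it at 10 seeds.

`apply_ascertainment()` emulates SNP discovery restricted to a subset of
subspecies by a minor-allele-count threshold within that panel, which is
how a European discovery panel inflates apparent European polymorphism.

What the generator does *not* emulate: linkage and LD (loci are
independent), mutation processes, migration after divergence (admixture is
a single taxon), real ascertainment's two-source structure, or genotyping
error. Passing tests therefore demonstrate the pipeline's internal
correctness and the qualitative reproducibility of the exclusion effect
under the emulated conditions — not that the original panel's published
percentages are recovered, which would require the original genotypes.

## Numerical choices and problem sizes

Branch lengths are serialized at 15 significant digits, so additive-matrix
round trips hold to well below 1e-9. Splits are canonicalized as the side
not containing the first label in sorted order, making split keys
comparable across trees. The consensus builder assembles the laminar family
of retained splits directly into a (possibly multifurcating) tree. The test
suite sizes simulations to run on one CPU in a few minutes: NJ recovery on
1,000 random 6–10-taxon trees, F_ST calibration at 100 seeds x 1,000 loci,
and the exclusion experiment at quarter scale; the full-scale design is
exercised by the acceptance script's panel summary.

## Known limitations

* Weir–Cockerham components treat all samples as diploid; the ploidy
  column affects genotype coding and theta's chromosome counts only.
* `fst_matrix()` at subspecies level requires every unit to contribute
  within-population degrees of freedom somewhere (two single-diploid units
  have no informative loci between them).
* The compatibility filter is the split-wise interpretation described
  above; other predicates ("tree is a refinement of the reference") would
  partition tree sets differently.
* NeighborNet weights come from a dense constrained fit without the
  active-set economies of dedicated implementations; use population-level
  matrices.
* Consensus trees carry no branch lengths, only supports.
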
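---
title: "Phylogenetic fate mapping from polyG somatic mutations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic fate mapping from polyG somatic mutations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polygfate)
```

## The problem

During mammalian development, cell divisions leave a permanent record:
replication slippage at polyguanine (polyG) mononucleotide tracts changes
tract length at a roughly constant per-division rate, and each cell carries
the accumulated changes of its entire mitotic history. Genotyping a panel of
polyG loci in single-cell clones — cells dissected from tissues and expanded
ex vivo so the founding cell's genotype can be read as the clone's modal
allele — therefore allows lineage relationships to be inferred
retrospectively: cells with similar mutation profiles shared a recent
ancestor. This package implements that inference chain for diploid polyG
genotypes: genotype calling from fragment-analysis peaks, a
missing-data-aware genetic distance, molecular-clock conversion of distance
into divisions, eBURST-style clustering into clonal complexes, a
permutation-calibrated similarity network, and tree-imbalance statistics
against a randomized-genotype null. A ground-truth lineage simulator makes
every stage testable without access to animal data.

The combinatorial stakes are what make somatic-mutation markers necessary:
the number of rooted lineage histories for $n$ cells is
$(2n-3)!/(2^{n-2}(n-2)!)$ — 15 for four cells, 135,135 for eight, beyond
$10^{15}$ for sixteen (`count_lineage_histories()`, evaluated with exact
digit-vector arithmetic because no big-integer dependency is assumed).

## Genotype calling

Each clone x locus genotype is measured as triplicate PCR fragment
profiles. Writing $I_{1H} \ge I_{2H} \ge I_{3H}$ for the three strongest
peak intensities in one replicate, the call rules are:

* homozygous if $|I_{2H} - I_{3H}| \le 10^4\,\mathrm{U}$ (the second and
  third peaks are both background),
* heterozygous if $|I_{2H} - I_{3H}| \ge 10^4\,\mathrm{U}$ and
  $I_{2H} > 0.8\, I_{1H}$ (two comparably strong allele peaks),
* ambiguous otherwise, written `106/X`.

The final call requires all three replicates to agree exactly; otherwise the
call is ambiguous, retaining the top allele only when every replicate ranks
the same fragment first. Both thresholds are exposed in
`call_thresholds()`; the defaults are the values above. PCR stutter — an
artifact peak one repeat below each true allele — is what the triplicate
design defends against; `simulate_peak_profiles()` generates synthetic
triplicates with configurable stutter so the caller can be validated by
round trip.

Alleles are then assigned to parental (founder) origins
(`assign_parental_alleles()`). The founders of a locus are taken as its two
most frequent allele lengths (one founder if the locus is homozygous
throughout), and each clone's alleles are routed to the founder slot that
minimizes the implied mutational deviation; this minimizes the total number
of mutations needed to explain the matrix, clone by clone, because clones
contribute independently to the objective. Consensus genotypes
(`consensus_genotype()`) — the zygote estimate over all clones, or a tissue
consensus over a subset — take the per-slot modal allele, with frequency
ties broken toward the smaller length so outputs are reproducible.

## Genetic distance

For two diploid genotypes the per-locus contribution is the smaller of the
two allele pairings of summed absolute length differences,

$$ d_\ell = \min\left(|a_1 - b_1| + |a_2 - b_2|,\;
                      |a_1 - b_2| + |a_2 - b_1|\right), $$

and the pair's distance is $\sum_\ell d_\ell$ divided by the number of loci
examined for that pair. Missing data are handled conservatively: a locus
with more than one missing allele across the pair is excluded; with exactly
one missing allele the known allele of the incomplete call is compared to
the closer of the counterpart's two alleles, with no rescaling. Because
different pairs can be normalized over different locus sets, the distance is
a symmetric premetric — the triangle inequality is not guaranteed and is not
asserted anywhere.

Under a constant mutation rate $\mu$ per locus per division, the expected
per-locus distance between two cells separated by $s$ divisions (path length
through their most recent common ancestor) is $\mu s$
(`clock_model()`, `divisions_from_distance()`). The clock is linear only
while multiple hits are rare: with $\pm 1$-bp slippage steps, opposite
mutations on one allele cancel, and mutations on opposite slots of a locus
whose founders are homozygous cancel through the pairing minimum. In
simulation the mean distance stays within 5% of $\mu s$ for
$\mu s \lesssim 0.1$ and undershoots by roughly 10% at $\mu s \approx 0.2$,
the regime of the clustering threshold below; the package's property tests
assert the linear regime and the direction of the saturation rather than
pretending the clock is exact.

## Clonal complexes and the similarity network

`build_clonal_complexes()` adapts eBURST to diploid distance data: clones
whose distance does not exceed a threshold are linked, complexes are the
connected components of the link graph (single linkage, the classical
eBURST semantics), and each complex's founder is the member with the most
within-threshold links — ties broken by smallest mean distance to the other
members, then by clone id, so output is deterministic. The default
threshold 0.2 equals the expected distance of cells separated by 15
divisions at $\mu = 0.013$ ($0.013 \times 15 = 0.195 \approx 0.2$);
`threshold_in_divisions()` reports this equivalence for any configuration.
Undefined distances (no shared usable loci) are treated as above-threshold.
Links that join clones from different tissues or opposite body sides
(`cross_tissue_links()`) are the migration-candidate readout.

`build_similarity_network()` calls a clone pair an edge when its distance is
significantly smaller than expected under the null in which lineage
information is destroyed but allele frequencies are preserved: each locus's
calls are independently permuted across clones (`randomize_genotypes()`).
Two calibration choices matter:

* **Pooled null.** Per-locus-normalized distances are exchangeable across
  pairs under this null, so null distances are pooled across pairs and
  permutations. This gives p-value resolution $1/(\text{pairs} \times
  \text{permutations})$; with per-pair nulls a matrix with $m$ pairs and $B$
  permutations could never reach a Benjamini–Hochberg-adjusted p below
  $m/(B+1)$, making small networks structurally edge-free.
* **BH correction** across all pairs at level `alpha` controls the false
  discovery rate of edges.

Node weights carry the mean intra-tissue distance (the circle-diameter
convention of population-snapshot renderings); layout is deliberately left
to the renderer. `compare_networks()` aggregates clone-pair edges to tissue
pairs and intersects two individuals' networks to report conserved
relationships.

A caution that the package documents rather than hides: pair-level distance
values are not independent (pairs share clones), so a naive t-test comparing
intra- versus inter-tissue pair values is anticonservative — its true SE is
about three times the nominal one in our simulations.
`tissue_distance_summary()` reports the conventional one-sample t-test of
group pair values against the global mean because that is the field's
reporting convention, but calibration checks in the test suite use
label-permutation tests, which are exact by construction.

## Tree shape

Two imbalance statistics summarize how a rooted tree grew
(`nbar()`, `colless()`):

* $\bar N$: the mean over tips of the number of internal nodes between tip
  and root, counting the root. The complete balanced tree on $2^k$ tips has
  $\bar N = k$ (4 for 16 tips); the $n$-tip caterpillar attains the maximum
  $(n-1)(n+2)/(2n)$ (7.43 for 14 tips). $\bar N$ handles multifurcations
  directly.
* Colless' $I_c$: the sum over internal nodes of $|L - R|$ tip-count
  differences, 0 for maximally balanced trees and $(n-1)(n-2)/2$ for
  caterpillars; it requires a bifurcating tree, so polytomies are either
  rejected or randomly resolved under a seed.

`shape_null_comparison()` contrasts observed trees with trees rebuilt from
randomized genotypes. Bayesian tree inference itself is delegated:
`recode_for_phylogenetics()` converts each parental allele slot into a
0–9 character column (digits by descending allele frequency, rarest merged
into 9 beyond ten alleles, missing as `?`) and `write_nexus()` emits a
standard-datatype NEXUS file with a MrBayes command block recording gamma
rate variation with a uniform(0.05, 50) shape prior; externally sampled
trees can be read back with `ape::read.tree`/`read.nexus`. For end-to-end
runs without an external sampler, `build_distance_tree()` provides a
deterministic UPGMA tree. Equal division rates across lineages produce
symmetric trees, so a downward shift of observed $\bar N$ against the null
is the signature of unbiased lineage commitment.

## The lineage simulator

`simulate_lineage()` generates the study design the analysis targets, as a
ground-truth object: synchronous divisions from the zygote; per division
and locus, a mutation with probability $\mu$ hits one of the two alleles
uniformly and steps its length by $\pm 1$ bp (the step spectrum is
configurable; the field has not published a polyG step-size spectrum, so
the symmetric single-step default is the conservative choice); at scheduled
generations, tissue/side progenitor pools of configurable size are drawn
from the cells then alive; sampled clones, split-clone duplicates and
per-allele missing calls complete the output. Defaults mirror the targeted
study: 110 loci, $\mu = 0.011$ (within the measured 0.010–0.013 range),
40 generations, six tissue/side pools — muscle fibroblasts and
preadipocytes committed early (generation 7) from broad pools of 20,
brain vascular endothelium late (generation 13) from pools of 4 — and 16
cells sampled per pool, about 100 clones in total. Founder (zygote) alleles
are 70% heterozygous with 3–10 bp separation, typical of inherited tract
polymorphisms.

Only sampled lineages are instantiated: each sampled cell is a random
root-to-tip path in the implicit complete division tree, the genealogy is
the trie of those paths, and mutations are dropped per edge as
Binomial(divisions, $\mu$) events. This makes 40 generations tractable
while keeping the genealogy, per-pair mitotic separations, per-tip mutation
events and the pre-masking genotypes all available as ground truth.
`simulate_subclone_experiment()` reproduces the in-vitro rate assay: 12
single cells from a parental clone, each passaged 20 doublings, genotyped
at 110 loci.

What the simulator does not emulate: cell death and asynchronous division
(pools are drawn from a synchronous full tree), spatial structure and
migration (a "migrating" lineage can only be mimicked by labelling), PCR
artifacts beyond stutter, and ex-vivo culture mutations (split-clone pairs
are exact duplicates before masking). Passing tests therefore validate the
analysis chain's correctness and calibration, not the biological realism of
any particular mouse.

## Estimating the mutation rate

`estimate_mutation_rate()` pools new mutations across subclones and loci:
$\hat\mu = M / (n_{\text{sub}} \times \text{doublings} \times
n_{\text{loci}})$, with the SE taken from the spread of per-subclone rates.
$M$ counts, per allele slot, the absolute bp difference from the parent —
the minimal number of single-bp slippage events — rather than the number of
differing slots. Under the stepwise model the two counts differ when a slot
is hit more than once: counting differing slots once underestimates the
rate by about 7% at $\mu = 0.012$ over 20 doublings, while the step count
is nearly unbiased (a residual ~4% from exact in-slot cancellation). With
no multiple hits the two definitions coincide, e.g. 264 single-step changes
over 12 subclones, 20 doublings and 110 loci give
$264/26400 = 0.010$.

## Numerical and testing choices

Deterministic tie-breaks are used everywhere a choice is arbitrary:
consensus ties toward the smaller allele, founder ties toward the more
frequent founder, eBURST founder ties by mean distance then clone id, UPGMA
via average-linkage `hclust` (deterministic given label order). All
stochastic operations take explicit integer seeds and draw from one stream,
so identical configurations yield bit-identical outputs, including the
pipeline manifest hash of `fatemap()`.

The test suite regenerates all fixtures in code. Problem sizes were chosen
so the full suite exercises realistic regimes while remaining quick:
distance oracles sweep $10^4$ random diploid pairs; eBURST is checked
against a union-find oracle on 100 random matrices; the rate assay is
replicated 100 times; null calibration uses 200 randomized replicates with
99 label permutations each; tree-shape nulls use 40 randomizations of a
110-locus, 32-clone balanced lineage. The data-dependent reproduction of
the original per-mouse statistics requires the published supplementary
genotype workbooks, which have no machine-readable public accession; the
corresponding test states exactly which files to place under
`inst/extdata/` and fails (rather than silently skipping) while they are
absent.

## Known limitations

* The distance is a premetric; downstream methods use it only through
  thresholds, means and ranks, never through triangle-inequality
  arguments.
* The molecular clock saturates: division estimates from distances near or
  above 0.3 per locus are lower bounds.
* Undefined distances (pairs with no shared usable loci) propagate as
  unlinked/excluded, which can disconnect otherwise related clones in
  sparse matrices.
* The permutation null preserves per-locus allele frequencies but not
  linkage between loci induced by technical artifacts; batch effects would
  require a stratified permutation, which is not implemented.
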
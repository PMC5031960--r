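---
title: "Methods: gene-family reconciliation and genome rearrangement in genetrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family reconciliation and genome rearrangement in genetrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genetrace)
```

genetrace studies two complementary signals of genome evolution across a
fixed species phylogeny: the expansion and contraction of gene families
(duplications and losses read off gene-tree/species-tree reconciliations)
and the rearrangement of gene order (double-cut-and-join distances,
sorting scenarios and median ancestors). Both tracks are driven by fully
seeded simulators with known ground truth, so every stage of the pipeline
is testable without any external data.

## The species frame

The default frame is a rooted binary tree over six eudicots: *Theobroma
cacao* (`the`, rosid outgroup), *Solanum lycopersicum* (`tom`, asterid
outgroup), *Coffea canephora* (`cof`, Rubiaceae) and three Apocynaceae —
*Rhazya stricta* (`rha`), *Catharanthus roseus* (`cra`) and *Rauvolfia
serpentina* (`rsa`). The branching order within the Apocynaceae trio is
not firmly established; the shipped fixture places `cra` and `rsa` as
sisters. This is an explicit assumption, and the fixture
(`inst/extdata/species_tree.nwk`) can be replaced by any rooted binary
Newick tree — all operations take the species tree as an argument.
Branch lengths are expected amino-acid substitutions per site; the
defaults (0.03–0.35) put congeneric taxa a few percent diverged and the
rosid outgroup at roughly 35% expected change, which is the regime where
both the homolog screen and distance-based tree building are
informative.

## Synthetic data: what it emulates and what it does not

`simulate_gene_family()` runs a continuous-time birth–death process per
gene lineage along the species tree, with branch length as exposure:
duplications arise at `birth_rate` and losses at `death_rate` per
lineage per branch-length unit, and every lineage splits at each
speciation. Defaults are `birth_rate = 0.3` and (in the pipeline's
low-noise fixture) `death_rate = 0`, giving families of roughly 6–15
genes over the six taxa — the size range of the alkaloid-pathway
families that motivate this kind of analysis. Extinct lineages are
pruned from the emitted tree; `true_dup_count` counts the duplication
nodes that survive pruning (the quantity a reconciliation of the true
tree can recover) while `true_loss_count` counts every death event. The
complete event log is returned, and `replay_family_events()` rebuilds
both counts from the log alone — a replayability invariant the tests
assert.

`evolve_sequences()` simulates gap-free protein evolution by a
reversible Markov chain under the Le–Gascuel exchangeabilities (a
Poisson/uniform matrix is available as `"Poisson"`), with optional
discrete-Gamma(4) site-rate heterogeneity. The transition matrix is the
matrix exponential of the normalized rate matrix, computed by spectral
decomposition of its symmetrized form.

`simulate_genome_evolution()` diverges a signed gene-order genome by a
known number of uniformly random DCJ operations per branch, logging
every operation. Gene content is preserved by construction.

What the simulators deliberately do **not** model: insertions/deletions
(alignments are gap-free, so the screen's trimming and the distance
machinery face no alignment error), incomplete lineage sorting,
horizontal transfer, codon-level selection, and gene-content change
along genomes (the rearrangement track operates on the single-copy
ortholog set, as the classification step enforces). Consequently a green
test suite demonstrates algorithmic correctness and internal
consistency — not robustness to alignment error or model violation on
real data.

## Homolog screening

The screen reimplements the database search as exact Smith–Waterman
local alignment (via Biostrings) because at desk scale the seeded
heuristic and its database-size-dependent E-value add nothing: the
operative filters are percent identity ≥ 35 and query coverage ≥ 0.5,
the two thresholds the analysis actually turns on. Percent identity is
defined as identical columns over aligned columns *including gap
columns* (the stricter convention; the threshold's source does not
define it), and coverage is measured on the query, the reference
homolog. Subject sequence outside the aligned span is trimmed. Gap
costs follow the `open + L·extend` convention, defaulting to the
protein-BLAST 11/1; a linear penalty is `gap_open = 0`. One isoform is
retained per locus (`dedup_isoforms()`): highest score, then longest
trimmed sequence, then lexicographic id — a fully deterministic rule.

## Tree building

Gene trees are built by neighbor joining on Poisson-corrected
p-distances (`d = −log(1 − p)`, gapped columns excluded pairwise).
The correction diverges as p → 1, so observed proportions are capped at
p = 0.93 (d ≈ 2.66) with a warning; the cap only matters for
near-random pairs that the screen would discard anyway. Nonparametric
bootstrap supports (default 100 replicates) are the percentage of
replicate NJ trees containing each internal bipartition.

Candidate trees are compared by likelihood, not re-optimized: the
pruning algorithm evaluates per-site log-likelihoods under LG +
discrete-Gamma(4). The Gamma shape is fixed (default 1) or picked from
the coarse grid {0.25, 0.5, 1, 2, 4} by total likelihood
(`gamma_alpha = "grid"`); branch lengths for each candidate topology
are re-estimated from the distance matrix by non-negative least squares
on the unrooted topology. This is deliberate: likelihood serves only to
*rank and filter* candidate refinements of the same data, so shared,
distance-fitted branch lengths are the fair comparison, and full ML
optimization would buy nothing but runtime. Likelihoods are therefore
not comparable to any external ML program's values — only the ranking
is used.

## Reconciliation

`lca_reconcile()` implements standard duplication–loss parsimony: each
leaf maps to its species, each internal node to the LCA of its
children's images; a node is a duplication exactly when a child maps to
the same species node. Losses on an edge are the species-tree branches
skipped between the two images, minus one when the parent is a
speciation. Duplications and losses have unit cost; the analyses this
supports count "duplication and loss operations" without weights, and
any other weighting would need a justification the data do not provide.
The test suite verifies the minimality claim directly: the LCA cost
equals an exhaustive minimum over all ancestry-respecting mappings.

The candidate machine follows the established recipe for turning one
uncertain gene tree into a population of plausible reconciled trees:

1. contract internal branches below a bootstrap threshold, for each
   threshold in {20, 30, ..., 90};
2. root the resulting non-binary tree on every branch (branch rooting
   subsumes node rooting for reconciliation purposes — rooting "at a
   node" of an unrooted tree is realized on one of its incident
   branches);
3. resolve every polytomy at minimum duplication+loss cost.

Polytomy resolution uses dynamic programming over the species tree:
for species node *s* and *k* gene lineages entering it,
`c_s(k) = min over k'' of |k'' − k| + c_s1(l) + c_s2(l)` with
`l = k'' − n(s)`, where `n(s)` children of the polytomy map exactly to
*s*; leaves force `k'' = n(s)`, and `k = 0` is feasible only where no
genes occur below. The polytomy's optimum is `c_r(1)` at the LCA of its
children's images. Because a refinement never changes its root's image,
polytomies resolve independently and the per-polytomy optima sum to the
global optimum — a property the tests check against exhaustive
enumeration of all binary refinements up to degree 6. When several
resolutions tie, up to `max_solutions` distinct ones are constructed by
systematically varying the join order; joins are ordered by an NJ-style
Q-criterion on the family's distance matrix (average linkage between
the joined subtrees' leaf sets), so tie-breaking is deterministic given
the data.

Candidates are deduplicated by rooted topology with multiplicity
retained: support frequencies are over replicate *outcomes* weighted by
how many (threshold × rooting × refinement) combinations produced them.
Selection applies the SH test (RELL resampling with centering, 1000
replicates by default) against the best candidate at `alpha = 0.05`,
then keeps the minimum reconciliation cost among the survivors. The
combination rule — SH first, then cost — operationalizes "best by both
likelihood and cost" in the conservative direction: likelihood can only
veto, never promote, a costly tree. The alpha is a documented default,
not an externally fixed value. The final tree is the selected candidate
closest (clade symmetric difference) to the extended majority-rule
consensus of the selected set, ties broken by likelihood; each node
then carries an event support — the weighted fraction of all candidates
containing the same clade with the same event — and clade bootstraps
recomputed on the final topology. Losses are grafted as labelled
pseudo-leaves (`LOST_<branch>`) for the NHX output.

## The rearrangement track

Genomes are signed gene orders over linear and circular chromosomes
(GRIMM text conventions: `$` linear, `@` circular). The adjacency graph
of two genomes with equal content yields the DCJ distance
`d = N − (C + I/2)` with *C* cycles and *I* odd paths. Sorting is the
greedy optimal scenario: install each target adjacency with one
operation, then split excess adjacencies at target telomeres; the tests
assert both optimality (length = distance) and validity (applying the
scenario transforms source into target, every prefix decreasing the
distance).

The median of three genomes — the parsimony ancestor — is NP-hard in
general. The exact mode searches the complete space of genomes on the
shared gene set (all pairings of extremities into adjacencies and
telomeres), terminating early when the pairwise lower bound
`⌈(d(a,b) + d(a,c) + d(b,c))/2⌉` is attained; it is capped at 6 genes,
above which it raises a capability error pointing at the heuristic
mode (steepest-descent hill climbing over single-DCJ neighbours from
each input genome). On the simulated study conditions — 30-gene
genomes, two rearrangements per branch — the heuristic recovers the
true ancestor in the majority of runs, and its score never beats the
lower bound, which brackets how far it can be from optimal.

Duplicate-pair ages are measured by Nei–Gojobori Ks: synonymous sites
counted per codon (changes to stop codons count as nonsynonymous, so
S + N equals the nucleotide length), differences averaged over all
mutational pathways, and the Jukes–Cantor correction
`Ks = −(3/4)·log(1 − (4/3)·pS)`, undefined (flagged saturated) at
pS ≥ 3/4. Ortholog versus out-paralog classification is a joint
threshold on Ks and percent similarity. No published threshold values
exist for this split, so both default to unset: they must be supplied,
or fitted from the data by `ks_threshold_split()`, a deterministic
one-dimensional 2-means (quantile-initialized) whose midpoint separates
the recent (speciation-age) from the ancient (paleopolyploidy-age)
component. Saturated pairs are classified out-paralogs, matching their
role as the old, weak signal to be discarded.

## Numerical and engineering choices

- All randomness is seeded; every simulator and resampling function
  takes an explicit `seed`, restores the caller's RNG state, and the
  pipelines derive per-stage seeds from the one config seed, so reruns
  are bit-identical (asserted in the tests on the written files).
- Likelihood pruning scales per-node column maxima into a log
  accumulator, keeping 1000-site alignments on large trees away from
  underflow; rate categories are combined by log-sum-exp.
- NJ branch lengths clamped at zero; nnls-fitted candidate branch
  lengths likewise.
- SH-test ties: under a reversible model every rooting of one unrooted
  topology has the same total likelihood up to floating-point noise, so
  candidates within `1e-8·|best|` of the best likelihood are never
  rejected — strict RELL comparisons between numerically identical
  vectors would be coin flips.
- The p-distance cap (0.93) and the BLOSUM `X`-scored-0 convention are
  the only places the distance machinery departs from textbook
  formulas, both to keep degenerate inputs finite.
- Problem sizes in the test suite (e.g. 200 BFS-verified genome pairs
  of ≤ 5 genes, 50 exhaustively enumerated polytomies of degree ≤ 6,
  100 reconciliation instances against the brute-force oracle,
  3–5-family pipeline fixtures at 300 residues) are chosen so each
  oracle comparison is exact yet the whole suite runs in minutes on one
  core; the statistical conclusions do not depend on these sizes.

## Known limitations

- Gene trees come from distance/NJ plus bootstrap, not ML topology
  search; the threshold-contraction machinery is designed exactly to
  absorb that uncertainty, but very short internal branches may be
  contracted at every threshold and then resolved purely by parsimony.
- The SH filter inherits RELL's assumptions (sites i.i.d., large-ish
  alignments); below ~50 sites its p-values are rough.
- The exact DCJ median is limited to toy sizes by design; the
  heuristic's optimality gap is reported against the lower bound rather
  than guaranteed.
- Reconciliation considers duplications and losses only — no transfers,
  no ILS-aware models — and assumes the species tree is correct.
- The multiplicity convention for event supports (dedup by topology,
  weight by origin count) is one of two defensible choices; the other
  (dedup without multiplicity) is available by setting the `n` column
  to 1 before `final_tree_and_support()`.
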
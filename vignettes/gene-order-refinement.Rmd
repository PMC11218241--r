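---
title: "Gene-order-aware refinement of bacterial pangenome clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-order-aware refinement of bacterial pangenome clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pangraft)
```

## The problem

Pangenome tools cluster genes into homologous families by sequence
similarity. At species level that works well; across a genus, true
orthologs may share only 60–90% similarity and high-stringency clustering
fragments a single family into several clusters, so the core genome — the
genes present in (essentially) all members — is underestimated. Gene
*order*, however, is often conserved even when sequences have diverged: if
a questionable pair of genes sits between two confidently matched
neighbors in both genomes, synteny is evidence of orthology that sequence
similarity alone cannot provide.

pangraft combines both signals. A high-stringency (95%) scaffold
partition keeps precise clusters, and pairwise gene-order-aware homology
assignments — computed by an integer linear program over a family-free
rearrangement model — merge scaffold clusters that belong to the same
family, resolve paralogs into subgroups, and extract the core genome.

## The distance model

For a genome pair $A$ (with $n$ genes) and $B$ (with $m$ genes) we build
the bipartite *gene similarity graph* $GS_\sigma(A,B)$: one vertex per
gene, and an edge $(a,b)$ for every cross-genome gene pair whose
normalized similarity $\sigma(a,b) \in (0,1]$ reaches the evidence floor
(0.6 by default). Raw alignment bitscores are normalized by the larger of
the two self-alignment bitscores, which keeps weights in $[0,1]$ even for
asymmetric local alignments; reciprocal hits are collapsed to one
undirected edge by maximum bitscore because the matching model needs one
edge per pair (the choice between directed and collapsed scores is a
design decision of this package; collapsed-max is symmetric and
conservative).

A *matching* $M$ of this graph pairs each gene with at most one partner.
Unmatched genes are *singletons*; removing them yields the reduced
genomes $A^M, B^M$. Every gene has two extremities (tail and head,
swapped in genome coordinates for minus-strand genes); consecutive genes
on a circular replicon define an *adjacency* of two extremities. The
*adjacency graph* connects adjacencies of $A^M$ and $B^M$ that share a
matched extremity; with circular contigs every vertex has degree two, so
the graph decomposes into cycles. Two identical gene neighborhoods form a
2-cycle ("fixed component" — no rearrangement needed); every additional
cycle saved corresponds to one double-cut-and-join (DCJ) rearrangement
avoided.

The family-free DCJ-indel distance minimized here is

$$ d(A,B) \;=\; \alpha\,\bigl(|M| - c + I + S\bigr) \;+\; (1-\alpha)\,\bigl(|M| - \omega(M)\bigr), $$

where $c$ counts adjacency-graph cycles, $S$ counts singletons, $I$
counts *blocks* of consecutive singletons (a long deleted segment is one
event), and $\omega(M)$ is the summed edge weight of the matching.
$\alpha \in [0,1]$ (default 0.5) trades gene order against sequence
similarity: $\alpha = 1$ ignores similarities (classical DCJ on the
matched genes), $\alpha = 0$ reduces to maximum-weight matching. Indels
are deliberately penalized twice — once per singleton (via a self-edge
cost) and once per block — because with only the per-singleton term the
optimizer overestimates indels, and with only the block term it can
write off one genome as a single deletion and the other as a single
insertion. $M$ is constrained to maximum cardinality, so an indel is only
ever declared for genes that cannot be matched at all.

## The ILP and its solver

`formulate()` builds an explicit integer program per similarity-graph
component: binary matching indicators $x_e$, self-edge indicators
$s_g = 1 - \sum_{e \ni g} x_e$, block-end indicators
$b_g \ge s_g - s_{\mathrm{next}(g)}$ on each circular gene order, binary
adjacency indicators marking extremity pairs that become adjacent after
contraction of singletons, and cycle counting by the label scheme of
Shao and colleagues: each extremity carries a bounded integer label,
labels are equalized along active matching/adjacency edges, and a binary
representative per vertex — feasible only when the vertex attains its own
index as label — contributes $-\alpha$ to the objective, so the optimal
representative sum is exactly the cycle count. One subtlety is ours: the
transition-based block count is zero when an entire circular contig is
singleton (a closed run has no end), so a per-contig indicator forces one
block in that case; this makes a fully isolated gene cost exactly
$2\alpha$.

No mixed-integer solver is linked; `solve_ilp()` is an exact specialized
branch-and-bound written for this formulation. It branches on the
matching indicators in stable sorted-edge order; once a
maximum-cardinality matching is fixed, the rest of the program is solved
exactly (singleton and block variables take their minimal feasible
values, and the label subproblem's optimum is the cycle count, obtained
by merging the equalization classes). Admissible bounds — the singleton
count is fixed by maximum cardinality, cycles are at most $|M|$, and the
remaining matching weight is bounded by the best undecided edges — prune
the search. Two independent verifications guard every reported optimum:
the decoded matching is re-evaluated on the adjacency graph built by a
separate traversal implementation, and a full variable assignment is
checked row by row against the formulated constraint matrix and the
objective (tolerance $10^{-6}$). The brute-force oracle
(`brute_force_ffdcj_indel()`), which simply enumerates all maximum
matchings, is kept as a third, fully independent reference and is the
backbone of the test suite.

Solutions are deterministic: ties between optima are broken by larger
$\omega(M)$, then by the lexicographically smallest pair set. The time
limit (240 s per component by default) returns the best incumbent when
exceeded; since the search is deterministic and anytime, a longer limit
can only improve the reported distance. If a component times out before
any incumbent exists, a greedy maximum-weight matching is substituted and
flagged `timeout-fallback`.

### Decomposition

The pairwise problem is split along connected components of the
similarity graph. Components that are a single edge (one gene of each
genome, degree one) are accepted directly as homolog pairs — the trivial
case, which dominates real datasets and is never formulated as an ILP.
For a nontrivial component, the circular gene orders are restricted to
the component's genes: genes outside the component are contracted away,
freezing the surrounding matched context. This is an approximation —
cycles that would thread through several components are not visible to
any single sub-program — so `pairwise_refine(decompose = FALSE)` and
`ffdcj_indel_distance()` solve the full instance exactly for small
inputs, and all oracle-equivalence tests run in that mode.

## From pairwise homologs to groups

The scaffold partition is single-linkage clustering (connected
components over edges at or above the threshold) at 0.95 stringency; an
external Roary-style `clustered_proteins` file can be substituted
verbatim. Clusterings at 0.60/0.70/0.80/0.90 are computed only to
annotate the outputs — single linkage makes the ladder nested, and
downstream computation consumes only the 0.95 partition. Single linkage
stands in for the CD-HIT/MCL pipeline of the original scaffold tools: the
contract here is "a deterministic high-stringency partition", not a
re-implementation of any specific tool.

Merging is union-find over scaffold clusters: every homology pair whose
genes sit in different clusters merges them; unclustered genes join
through their pairs or become singleton groups. Group IDs are assigned by
sorted smallest member gene ID, which makes them invariant to genome and
file ordering.

If a genome contributes $n \ge 2$ genes to a group, a representative is
chosen by a ladder: (1) most homology-pair connections into the rest of
the group; (2) largest originating scaffold cluster; (3) annotated name
matching the group's majority gene name, where "hypothetical protein"
placeholders are ignored because they carry no evidence; (4)
lexicographically smallest gene ID — the published ladder can still tie,
and determinism requires a final rule. The remaining $n-1$ genes each
seed a subgroup (`group7.1`, `group7.2`, ...); other members follow the
paralog they are directly paired with, and the procedure recurses while
any genome still has paralogs (nested splits extend the suffix). A
subgroup's presence does not count toward its parent's genome coverage:
after resolution the parent holds at most one gene per genome, and
coverage bookkeeping stays per-group.

A group is core when it covers at least
$\lceil \mathrm{core\_perc}/100 \times n_{\mathrm{genomes}} \rceil$
genomes (default 100%: all of them). The ceiling implements "at least"
semantics — in small datasets a 99% threshold must not admit an absence.

## The synthetic data generator

`simulate_genome_pair()` and `simulate_pangenome()` generate the study
conditions used throughout the tests: single circular replicons (the
bacterial case; a multi-contig option exists for plasmid-like edge
cases), oriented genes, and known truth. Genome B derives from A by
seeded inversions, transpositions, deletions, insertions and
duplications; pangenome datasets draw an ancestral family pool with a
core fraction and per-genome accessory presence. Similarity is emitted at
two fidelity levels: normalized weights drawn from per-family divergence
tiers (fast, exact control of where similarity lands relative to the
0.6/0.95 thresholds), or mutated DNA sequences calibrated so the internal
Smith–Waterman aligner reproduces the tier (with match $+2$/mismatch
$-3$ scoring, identity $q$ gives a normalized score near $(5q-3)/2$, so
the mutation rate is solved from the target weight). Decoy edges fall
below 0.6.

What the generator does *not* emulate: realistic sequence evolution
(codon structure, indels within genes, rate heterogeneity), horizontal
transfer, annotation errors, or fragmented assemblies. Passing tests
therefore demonstrate the correctness of the optimization and merging
machinery under controlled conditions, not end-to-end accuracy on real
genus-level datasets, which additionally depends on the external
annotation and search tools that produce the inputs.

Problem sizes in the tests and acceptance script — up to 5 genes per
genome for enumeration-verified instances (the oracle is guarded at 8), 7
genes for rearrangement recovery, 5 genomes x 8 families for the
pipeline scenarios — were chosen so the brute-force oracle remains an
exact reference and the whole suite re-runs in a couple of minutes on one
CPU.

## Numerical and design choices

* **Tolerances.** Distances are compared at $10^{-6}$; all arithmetic is
  exact apart from summing edge weights.
* **Degenerate inputs.** A one-gene circular contig contributes the
  self-adjacency of its gene (head–tail), keeping every vertex at degree
  two. Empty reduced genomes have zero cycles. Strand-"." features are
  accepted as "+" with a warning — the model needs oriented genes and
  unoriented annotations are rare artifacts.
* **Tie-breaks.** Gene order within a contig is `(start, end, gene_id)`;
  overlapping annotations are ordered deterministically even though
  upstream annotation tools do not specify an order.
* **POCP.** Conservation filters are strict inequalities (e-value
  $< 10^{-5}$, identity $> 40\%$, alignable fraction $> 0.5$); around 50%
  is the proposed genus boundary. The internal aligner estimates no
  e-values (its e-value field is a sentinel 0), so POCP on internally
  aligned data should set `use_evalue = FALSE`.
* **Both objective variants** are exposed: `indel_model = FALSE` drops
  the $I + S$ term, recovering the plain family-free DCJ objective.
  The indel-aware variant is the default.

## Known limitations

* Linear chromosomes are modeled as circular; DCJ path/telomere
  accounting is out of scope.
* Component decomposition freezes cross-component context (see above).
* The specialized branch-and-bound is exact but exponential in the worst
  case; dense components beyond ~8 genes per side rely on the time limit
  and the anytime incumbent.
* Chained merging can, in principle, link unrelated clusters through
  spurious intermediate pairs; the package logs group provenance
  (originating cluster IDs) so such chains can be audited, but no guard
  is applied.

## A worked example

```{r example}
cfg <- sim_config(n_genomes = 5, genes_per_genome = 8, core_fraction = 1,
                  inversions = 1, family_tiers = list("3" = c(0.60, 0.895)),
                  seed = 7)
sim <- simulate_pangenome(cfg)
res <- run_pipeline(sim$genomes, hits = sim$hits, seed = 11)
res

# family 3 is split by the 0.95 scaffold but united by gene order:
fam <- sim$truth$families[["3"]]$gene_id
sum(vapply(res$scaffold$clusters, function(cl) any(cl %in% fam), logical(1)))
res$group_table
```
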
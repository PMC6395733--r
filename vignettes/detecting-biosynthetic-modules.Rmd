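---
title: "Detecting and ranking biosynthetic modules: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and ranking biosynthetic modules: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcmodules)
```

This vignette explains the statistical model behind `bgcmodules`, the
choices made where the design was genuinely open, and what the synthetic
benchmark does and does not establish.

## The model

The unit of analysis is a collection of gene clusters, each an ordered
list of gene positions. Genes carry an orthogroup label (smCOG) or an
`UNASSIGNED` placeholder; only order matters, so strand and genomic
coordinates are dropped at load time. A *module* is a set of at least
three smCOGs that recur together across clusters more often than chance
allows.

Testing all smCOG sets directly is hopeless: with 12,842 orthogroups the
number of size-3-to-10 candidate sets is

```{r search-space}
module_search_space(12842)$exact
```

about $3.35 \times 10^{34}$ (the package computes this with exact integer
arithmetic; see *Numerical choices*). The method therefore works at the
level of **pairs** and reassembles modules afterwards.

### Pairwise null model

For an ordered pair (fixed COG A, moving COG B) the A genes stay where
they are, and the null hypothesis is that the $B_{tot}$ B genes fall
uniformly at random, as an unordered set, on the $N_{tot}$ positions not
occupied by A — pooled across the entire collection, because the null is
random distribution over the whole dataset, not within one cluster.
Positions are partitioned into classes by their exposure to A:

* **adjacency**: adjacent to 0, 1 or 2 A genes (capacities $N_a, N_b,
  N_c$); a B gene in class $b$ contributes one interaction, in class $c$
  two, so $i_{orig} = B_b + 2B_c$;
* **colocalization**: outside/inside an A-containing cluster; $i_{orig} =
  B_b$.

The probability of a class occupancy is multivariate hypergeometric, and
the p-value is the exact upper tail at $i_{orig}$. Both directions of a
pair are tested and the **larger** p-value is kept — the conservative
choice, since the two directions answer slightly different questions and
we only trust an interaction both support.

Unassigned genes are counted as available positions. This is deliberate:
they are real genes whose orthogroup is merely unknown, so they dilute
the search space exactly as an unrelated orthogroup would.

### The duplicate collapse

Colocalization classes are defined per cluster, so an smCOG occurring
$k \ge 2$ times in one cluster would multiply the class count and make
the exact tail expensive. Before colocalization counting (only), every
such occurrence set is emptied in place and re-attached at the end of its
cluster behind one empty separator position. The transform lengthens the
cluster; the added empty positions remain *available* to the null model,
inflating $N_{tot}$ and therefore making the p-value conservative —
significance can only be lost, never gained. Adjacency always uses the
original clusters. The collapsed dataset is flagged in its provenance and
the transform refuses to run twice, so it is idempotent by construction
and cannot be applied accidentally on top of itself.

One consequence worth knowing: with duplicated smCOGs the colocalization
count is direction-dependent (two B copies beside one A gives
$i_{orig}=2$ with A fixed but 1 with B fixed). The conservative max over
directions absorbs the asymmetry.

### FDR control

The pairwise tests share genes, clusters and positions, and are strongly
dependent. The Benjamini–Yekutieli step-up procedure is therefore used,
which controls FDR under arbitrary dependency at the cost of an extra
$\sum_{k\le m} 1/k$ factor. Adjacency and colocalization tests are pooled
into a **single family** before correction — the correction is applied to
all p-values of both kinds at once, the stricter of the two defensible
readings.

### Module detection

Every distinct adjusted p-value up to the cap (default 0.1) is used in
turn as a threshold. At each threshold an undirected graph connects two
smCOGs when *either* kind is significant, and all maximal cliques with at
least `min_size = 3` members are collected (enumeration is delegated to
igraph's Bron–Kerbosch implementation; an exhaustive subset-enumeration
oracle checks it in the test suite). A module's identity is its smCOG
set: the same set found at many thresholds is one module with the
smallest emitting threshold recorded, while a set and its superset found
at different thresholds are two (nested) modules — nesting is an expected
biological signal, not an artefact to deduplicate.

A cluster *supports* a module when it contains every member smCOG at any
positions; contiguity is not required, since colocalization edges carry
no positional claim. Modules with fewer than `min_support = 2`
supporting clusters are discarded as likely artefacts of pairwise
assembly (all pairs can be significant without the full set ever
co-occurring).

## Prioritisation

Six metric families feed the MIB score: module size, supporting-cluster
count, curated-database hits among supporting clusters, strictest
threshold, compound-class count plus Shannon entropy
$SE = -\sum_i f_i \ln f_i$ (natural log; $f_i$ the fraction of supporting
clusters with predicted class $i$), and functional-category percentages.
High entropy means the module recurs across diverse chemistries — the
profile of a genuine functional unit rather than a lineage-specific
block, so entropy gets the largest default weight (15). Rank direction
for the threshold metric is *smaller is better*; all other weighted
metrics rank larger-is-better. Ties receive average fractional ranks, and
because only ranks enter, any strictly monotone rescaling of a metric
leaves the score unchanged. Weighted rank sums are mapped linearly onto
$[1, 100]$; when every module ties on every weighted metric (including
the single-module case) all scores are 100 — a degenerate input has no
least interesting member.

smCOG categories are derived from member genes with ordered rules on the
category shares: runner-up above 40% when the top category is the
catch-all "other"; otherwise top category above 60%; otherwise a double
category (e.g. `tailoring/core`) when top two together exceed 75%;
otherwise `mixed`. All comparisons are strict, as stated; exact ties are
broken by a fixed priority (core > tailoring > transport > regulator >
other) so annotation is deterministic. Double categories contribute half
a count to each named category in the percentage metrics.

The top-quartile enrichment test (`quartile_enrichment()`) is a one-sided
Fisher exact test on the selected-by-top-fraction 2×2 table, with the top
set defined as the $\lfloor qn \rfloor$ highest scores and value ties
broken by original order. The selection is passed as indices or a logical
mask rather than as raw scores, because score values need not be unique.

## Preprocessing defaults

* **Trimming threshold 0.1** on the per-gene domain probability: genes
  are removed from each cluster end, scanning strictly inward and
  stopping at the first gene at or above the threshold. Interior
  low-probability genes survive — trimming is a boundary correction, not
  a filter — and raising the threshold beyond 0.1 has little additional
  effect. Clusters lacking the probabilities are left untouched.
* **Minimum smCOG size 3**: an orthogroup needs at least three member
  genes for a pairwise count to be meaningful; smaller ones are
  relabelled `UNASSIGNED` *in place* so positions never shift.
* **Redundancy removal**: clusters with identical smCOG composition keep
  only the shortest representative. Composition is compared as a
  **multiset** (copy numbers matter): \{A,A,B\} and \{A,B\} are different
  compositions. The multiset reading is the stricter of the two possible
  ones and avoids merging genuinely different architectures. Equal-length
  ties keep the lexicographically smallest cluster id.

## Numerical choices

* **Exact tails.** For small placement spaces
  ($\binom{N_{tot}}{B_{tot}} \le 10^9$) the tail is a ratio of exact
  integers: binomial products are computed by iterative multiply/divide
  so every intermediate is an exact integer below $2^{53}$, and the
  division happens once at the end. Larger profiles switch to log-gamma
  (`lchoose`) summation with a log-sum-exp reduction. The test suite
  pins a crossover band where both paths must agree to $10^{-10}$
  relative error.
* **No cancellation.** The upper tail is always summed directly over the
  $i \ge i_{orig}$ region rather than as $1 - P(i < i_{orig})$, so
  p-values near 1 cannot suffer catastrophic cancellation; $i_{orig} = 0$
  short-circuits to exactly 1.
* **Big integers.** The search-space count overflows doubles at
  $\sim 10^{16}$, so the package carries a minimal base-$10^7$
  digit-vector integer type (add, multiply-by-small, exact
  divide-by-small) sufficient for binomial sums.
* **Determinism.** Module ids are assigned after sorting by (strictest
  threshold, size, member key); clique members and supporting clusters
  are sorted before serialisation; reruns are byte-identical. The
  synthetic generator saves and restores the caller's RNG state.

## The synthetic benchmark

`generate_clusters()` emulates the *structure* of a real collection:
clusters of varying length (default 100 clusters of 5–15 genes), a
background of 30 smCOGs drawn uniformly with replacement at rate 0.7
(duplicates therefore occur and exercise the collapse), unassigned
positions, per-smCOG "home" functional categories inherited by members
with probability 0.8, and compound classes drawn from 6 labels. Planted
modules — fixed sets of 3–6 smCOGs — are inserted into a chosen fraction
of clusters, as a contiguous block (producing adjacency signal) or
scattered (colocalization signal only). These sizes keep a full pipeline
run around two seconds, so the test suite can afford 20-seed recovery and
null-control experiments.

What passing the benchmark shows: the pipeline recovers a 3-smCOG module
planted in 30% of 100 clusters in at least 18 of 20 seeds, and invents at
most one module at adjusted $p \le 0.01$ across 20 background-only seeds.
What it does not show: robustness to phylogenetic redundancy (near-copies
of whole clusters from related genomes), which the generator does not
model — its clusters are independent by construction. On real data such
redundancy produces real, but uninteresting, modules; the entropy weight
in the MIB score down-ranks them, and `correlate_classes = TRUE` lets one
reproduce that failure mode synthetically. Real collections also have
heavy-tailed smCOG abundances and length distributions the generator
does not attempt to match.

## Known limitations

* The null model fixes one smCOG exactly and randomises the other
  globally; it does not condition on per-cluster gene counts, so clusters
  with many genes are slightly over-weighted as landing sites.
* P-values of overlapping pairs are dependent; BY correction bounds the
  FDR but the module-level error rate is not formally controlled beyond
  the two-cluster support filter.
* Maximal-clique enumeration is exponential in the worst case; the
  `max_steps` ladder knob subsamples thresholds for very large inputs at
  the cost of deviating from the full iterative scheme (default: full
  ladder).
* GenBank input requires a user-supplied gene-to-smCOG mapping; the
  package deliberately performs no sequence-level computation.
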
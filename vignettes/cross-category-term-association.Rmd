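---
title: "Scoring cross-category GO term associations with crogo2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cross-category GO term associations with crogo2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crogo2)
```

## The problem

The three Gene Ontology categories — biological process (BP), molecular
function (MF) and cellular component (CC) — are separate DAGs with no
structural edges between them, so the classical semantic-similarity
measures (Resnik, Lin, Wang, ...) cannot relate, say, an MF term to the BP
term whose process it drives.  Yet such cross-category links are exactly
what a biologist reasons with: an enzyme activity term and the
biosynthetic process it catalyses are "about" the same biology.

`crogo2` scores the relatedness of a cross-category term pair from three
ingredients: the two terms' *propagated annotation gene sets*, a weighted
*gene co-function network*, and the terms' *depth* in their own
categories.  The central idea is that two terms are related when the genes
annotated to one are strongly associated — directly or through
intermediate genes — with the genes annotated to the other.

## The score, step by step

### Step 1: diffused gene–gene association

Let $E = (e_{ij})$ be the weighted adjacency of the co-function network.
Two matrices are derived from it:

* $U$, the row-normalized adjacency, $u_{ij} = e_{ij} / \sum_k e_{ik}$
  (each row a weighted average over neighbours; all-zero rows for isolated
  genes);
* $O$, the "original relations" matrix: $E$ rescaled by its maximum
  weight so every entry lies in $[0,1]$.

The association matrix $R$ is the fixed point of the iterative ranking
recurrence

$$R^{(t+1)} = \alpha\, O + (1-\alpha)\, U R^{(t)}, \qquad R^{(0)} = O,$$

a restart-weighted random walk: at every step a gene keeps a fraction
$\alpha$ of its original direct relations and diffuses the rest through
its neighbours.  Iteration stops when
$\theta = \max_j \sum_i |(R^{(t+1)} - R^{(t)})_{ij}|$ (maximum absolute
column sum) drops below a threshold.  Because $U$ is row-(sub)stochastic
and $O \in [0,1]$, every iterate stays in $[0,1]$ — the implementation
asserts that its final clamping is a numerical no-op.  After convergence
$R$ is symmetrized (association is undirected; the row normalization alone
would make it directional) and the diagonal is overwritten with 1: a gene
is maximally associated with itself.  That convention is not cosmetic — it
is what makes the soft set difference of identical sets exactly zero
below.

The fixed point solves the linear system
$(I - (1-\alpha)U)\,R = \alpha O$, which the test suite uses as an
independent closed-form oracle: the iterated and directly solved matrices
agree entrywise to $10^{-8}$ on random networks of up to 200 nodes.

### Step 2: soft set difference between annotation sets

For gene sets $G_1, G_2$ (the propagated annotations of $t_1, t_2$), the
usual set difference is replaced by a network-soft count

$$|G_1 - G_2| = |G_1| - \sum_{g_i \in G_1}
  \Bigl(1 - \prod_{g_j \in G_2} (1 - r_{ij})\Bigr),$$

i.e. each gene of $G_1$ is discounted to the extent that it is associated
with at least one gene of $G_2$ (reading $r_{ij}$ as independent
association probabilities).  The network similarity is then the
Jaccard-style ratio

$$\mathrm{Sim}_{net}(t_1,t_2) =
  \frac{|G_1 \cup G_2| - |G_1 - G_2| - |G_2 - G_1|}{|G_1 \cup G_2|}$$

with a crisp union count in the denominator.  Shared genes contribute zero
to either difference (their product term contains the factor
$1 - r_{ii} = 0$), so identical sets give $\mathrm{Sim}_{net} = 1$;
disjoint sets with no network association give 0; and with $R = I$ the
whole construction collapses to the crisp overlap formula.  Under these
conventions $\mathrm{Sim}_{net}$ is confined to $[0,1]$; the code asserts
the upper bound and flags any negative value as an upstream invariant
violation.

### Step 3: shallow-annotation correction

After true-path propagation a near-root term annotates almost every gene
in its category, so term pairs near the two roots would score high on any
overlap measure regardless of biology.  The depth weight

$$\mathrm{Sim}_{GO} = \sqrt{\Bigl(1 - \tfrac{|G_1|}{|G_{C_1}|}\Bigr)
                            \Bigl(1 - \tfrac{|G_2|}{|G_{C_2}|}\Bigr)}$$

(with $|G_{C}|$ the category's annotated gene universe) vanishes for a
category root and approaches 1 for specific terms.  The final score is the
product $\mathrm{Sim} = \mathrm{Sim}_{net} \cdot \mathrm{Sim}_{GO}$.  It
is symmetric in the two terms; direction enters only at the network-
building stage.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.1 | restart weight; small values emphasise indirect paths. 0.1 is the setting at which the method performed best in its original yeast evaluation, and the default here. |
| `theta_threshold` | 1e-6 | stopping gap on the max-column-sum norm; far below any difference that affects a ranking. Tests that compare against the closed form tighten it to 1e-12. |
| `max_iter` | 1000 | cap; non-convergence returns a flagged result with a warning rather than an error. |
| `fdr` | 0.05 | q-value cutoff for edges of the association network. |
| `n_null` | 10000 | null-sample size for the empirical FDR; at least 100. |
| `dense_limit` | 6000 | above this many genes the adjacency is held sparse; both paths give identical results. |

Annotation evidence codes are *not* filtered by default (an
`exclude_evidence` argument and `--exclude-evidence` flag allow dropping
e.g. IEA).  Gene identifiers are compared as bare case-sensitive strings;
identifier mapping is dataset-specific and out of scope.  Propagation
follows `is_a` and `part_of` (the GO true-path convention);
regulates-type relations are ignored, and cross-namespace parent edges are
dropped at parse time.

## Design choices where the design was open

* **Scaling of $O$.**  "Original relations" are taken as the raw weights
  rescaled by the global maximum.  The products in the soft difference
  require $r_{ij} \in [0,1]$, and this scaling is the least informative
  transformation that guarantees it for every iterate.  One consequence,
  exercised in the tests: raising an edge weight *past* the current
  maximum rescales all other entries of $O$, so the monotone
  "stronger edge, stronger association" property is only promised for
  changes below the maximum.
* **Initialisation.**  $R^{(0)} = O$, so the $\alpha \to 1$ limit is exact
  already at the first iterate.
* **Genes absent from the network** keep zero association with every
  other gene and unit self-association — the conservative choice.
* **Direction rule.**  After filtering, each significant pair contributes
  both directed edges; for a term $t_1$ with cross-category neighbour set
  $T_2$, the edge $t_1 \to t_2$ is deleted whenever another neighbour
  $t_3 \in T_2$ is a descendant of $t_2$.  The rule is applied from both
  endpoints in a single pass over the original neighbour sets (deletions
  do not shrink $T_2$ mid-pass), and deletion removes the directed edge
  itself, which keeps edges pointing at the most specific related terms.
  Mutually non-ancestral neighbours are all kept.
* **Empirical FDR.**  P-values come from scoring `n_null` uniformly
  sampled random cross-category pairs — the same negative model the ROC
  evaluation uses — via $p = (1 + \#\{null \ge s\})/(1 + n_{null})$, then
  Benjamini–Hochberg.  A structural caveat follows directly from this
  choice: when *all* pairs of a small instance are scored, the null
  sample is drawn from the very population being tested, so
  $p \approx \mathrm{rank}/N$ and every BH q-value sits near 1.  The
  procedure is therefore extremely conservative at benchmark scale — the
  calibration test below passes by a wide margin, and the FDR-filtered
  network of a toy instance is typically empty.  For exploratory use
  `build_assoc_network(sim_threshold = )` filters on the score itself,
  which matches the user-defined-threshold filtering step of the
  direction-assignment procedure; q-values are still attached for
  reporting.
* **Whole-universe terms** (e.g. roots) are retained in the output with
  score 0 rather than dropped, keeping the output shape predictable;
  terms with *empty* propagated sets are excluded, since the similarity
  ratio is undefined for them.

## What the synthetic benchmark emulates — and what it does not

`synthetic_spec()` builds two complete $b$-ary term trees (categories
`category_a` / `category_b`), annotates each leaf with a disjoint block of
genes, propagates upward, and wires a gene network in which the blocks of
each *planted* cross-category leaf pair are densely interconnected
(probability 0.8, weights uniform on $[0.5, 1]$) over a sparse background
(probability 0.01).  The default instance uses 40 terms per category, 400
genes, blocks of 5 and 8 planted pairs — sized so a full pipeline run
takes seconds.  Because planted pairs share *no* genes, any signal the
score finds travels through the network pathway, which is precisely the
method's novel component.  The `indirect` preset goes further and removes
all direct edges between the paired blocks, connecting both to a small
shared hub set instead: only a method that sees length-2 paths can relate
them, and the tests verify that the diffused score does while the
raw-adjacency degenerate mode (`direct_association()`) does not.  The
`null` preset plants nothing and is used for FDR calibration.

Real annotation corpora are not like this in several respects: term sizes
are heavy-tailed rather than uniform, annotations overlap heavily between
categories, co-function networks have hubs and degree heterogeneity that
the flat background probability does not imitate, and true relatedness is
graded rather than planted/not-planted.  Passing the benchmark therefore
demonstrates that the machinery recovers network-encoded relatedness under
controlled conditions, not that any particular biological pair will score
highly.

## Numerical conventions and degenerate inputs

* Ties in the ROC sweep are grouped into a single step; the AUC is the
  trapezoidal integral, identical to the Mann–Whitney statistic with ties
  counted one half (verified against a brute-force oracle).  TPR-at-FPR is
  read at the largest achieved FPR not exceeding the target, without
  interpolation.
* Isolated network nodes get all-zero rows in $U$; empty annotation files,
  all-comment edge lists and cyclic "DAGs" are hard errors; obsolete
  terms parse but carry no annotations and appear in no score.
* Duplicate network pairs merge keeping the maximum weight; self-loops are
  dropped; both with warnings.
* All randomness (null sampling, edge deletion, benchmark generation) is
  seeded explicitly and restores the caller's RNG state, so pipeline
  outputs are byte-identical across runs with equal inputs and seeds.

## Problem sizes in the shipped tests

The suite exercises diffusion against the closed-form solve on networks up
to 200 nodes, benchmark recovery and robustness on the 400-gene default
instance over 5 seeds, and FDR calibration over 20 null-instance seeds at
`n_null = 300` — chosen as the smallest sizes at which each property is
meaningfully tested.  The same machinery scales to organism-size inputs
(thousands of genes, $10^5$ edges) through the sparse path; the all-pairs
scoring stage is then the dominant cost and grows with the product of the
two categories' term counts.

## Known limitations

* Applying the method to a real GO release requires the caller to supply
  the OBO file, annotations and co-function network; no downloads are
  performed, and reproducing published organism-scale term networks
  depends on the exact data vintage used there.
* The score relates *annotation sets*; two terms annotating the same
  genes for unrelated reasons are indistinguishable to it.
* The empirical-null FDR is population-conservative, as discussed above.
* Within-category similarity, alternative baselines (association-rule or
  vector-space scores) and GO-slim mapping are out of scope; externally
  computed score files can be compared through the same `evaluate`
  interface.
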
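---
title: "Cross-model network dynamics of protein aggregation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-model network dynamics of protein aggregation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`polyqnet` chains nine analysis stages into one reproducible pipeline. This
vignette is the package's own account of the statistics it computes, the
parameters that matter, the choices made where the design was genuinely
open, and what the synthetic-data tests do and do not demonstrate about
real data.

## The two-model design

The pipeline assumes a matched pair of experimental models of polyQ protein
aggregation sampled at three aggregation stages:

* a **cell model** with a single shared baseline (`D0`) and three induction
  time-points (`D2`, `D5`, `D10`), each compared against `D0`;
* a **mouse model** sampled at three ages (`W5`, `W12`, `W28`), each
  compared against its own age-matched control group.

The asymmetry is deliberate and mirrors how such experiments are actually
designed: cultured cells are compared to their pre-induction state, while
aging animals need contemporaneous controls. The stage matching
`D2↔W5`, `D5↔W12`, `D10↔W28` (early/middle/late) is a configuration table
(`stage_matching()`), not an assumption baked into any computation.

## Differential expression on FPKM

Expression arrives as FPKM, so no count modelling (dispersion estimation,
library-size normalization) is attempted; the unit of analysis is the
replicate-mean FPKM per condition. For each gene,

* `FC = (mean_case + c) / (mean_control + c)`, with pseudocount `c = 0.25`
  by default. The raw ratio is undefined at control FPKM = 0, a frequent
  event in real data and an unavoidable one in simulation; a fixed small
  pseudocount is the simplest rule that keeps `log2FC` finite while leaving
  well-expressed genes essentially untouched. `c` is exposed so that
  `c = 0` recovers the bare ratio.
* a two-sided two-sample t-test per gene. The default is Welch's
  unequal-variance form, the default of `t.test()` in R, which is the kind
  of environment where such an analysis is typically run; a pooled-variance
  Student's t is available via `test = "student"`. The statistic is computed
  vectorised across genes in closed form (verified against `t.test()` in
  the test suite) so that calibration experiments over hundreds of
  replicate simulations stay cheap. Genes with zero variance in both groups
  and equal means are reported at p = 1; zero variance with unequal means
  gives p = 0 (the limit of the statistic).
* DEG status: `|log2FC| > 0.5` and `p < 0.05`, both strict inequalities,
  applied exactly as stated — boundary values are not DEGs. No
  multiple-testing correction is applied at this stage; the DEG lists feed
  an over-representation analysis whose own p-values are what downstream
  selection acts on, and correcting twice would double-penalize.

## Ortholog mapping

Mouse results are translated into the human namespace through a rank-scored
ortholog table. "High rank" is exposed as `min_rank` (default: the top rank
class of the generated maps). Two deterministic rules remove all ambiguity:
a source gene keeps its highest-rank admissible target (ties:
lexicographically smallest target id), and when several sources land on one
target the higher-rank mapping wins (ties: smallest source id). Dropped and
collapsed rows are counted and reported, never silent.

## Over-representation and common pathways

Enrichment is the exact one-sided hypergeometric upper tail (the test
behind the standard web enrichment tools), computed with `phyper`. The
background universe is the intersection of the genes present in the
expression data with the genes appearing anywhere in the collection. This
choice is not the only defensible one — web tools often use their own
internal gene universe — but it is self-consistent, fully determined by the
inputs, and testable; set sizes `K` are restricted to the same background.
Over-representation only (no depletion) is tested.

A pathway is "common" at a stage when it is significant (`p < alpha`,
strict, default 0.05) in both models at the matched time-points. Pathways
common at every stage are flagged persistent, the pattern of interest for
processes engaged from aggregation onset onward.

For genes called DEG in at least one time-point in both models, each model
assigns a direction — the sign of the gene's largest-|log2FC| DEG call —
and agreement is tested with an exact two-sided binomial sign test against
0.5. A sign test is the weakest assumption available for "do the two models
move the same genes the same way"; it ignores magnitudes on purpose.

## Stage networks and the union

Member proteins of the common pathways at a stage induce a subgraph of the
supplied interactome (no neighbor expansion: the analysis is about the
pathway components themselves). Filters are inclusive: tissue-expression
score ≥ 4.8 (a nervous-system expression cutoff), interaction confidence
≥ 0.950. Degree-0 nodes are then deleted. The two filters commute, and
raising either threshold can only shrink the network — both properties are
asserted in the tests.

The union of the three stage networks keeps, per node, its exact stage
membership. Three patterns get the conventional names and colours — present
at all stages (yellow), middle-only (green), late-only (magenta) — and
every other pattern keeps a literal label such as `early+middle` rather
than being forced into a named group.

## Motif z-scores

Network structure is summarized by the counts of the six isomorphism
classes of connected 4-node induced subgraphs (path, star, cycle, triangle
with pendant, diamond, complete). The census is exact: non-induced copy
counts of each pattern are computed in closed form from the adjacency
matrix (degree and codegree statistics, per-edge triangle counts, clique
enumeration over edges) and converted to induced counts by
inclusion–exclusion over the containment lattice. An enumeration of all
4-subsets would give the same numbers — the test suite checks exactly that
on random graphs — but the algebraic route is what makes a
1000-replicate null ensemble affordable.

The null model is the field standard for motif statistics: attempted
double-edge swaps (10 per edge by default) that preserve the degree
sequence exactly and never create self-loops or multi-edges. Graphs with no
legal swap (stars, for instance) pass through unchanged — in that case all
null standard deviations are zero and the z-scores are reported as
undefined rather than fabricated. Per class, `z = (real − mean) / sd` over
the ensemble (default 1000 networks); the single-number summary is the
unweighted mean of the defined per-class z values. That aggregation is a
documented package choice: a per-network motif z is conventionally reported
as one number, but no standard defines the aggregate, so it is kept simple,
symmetric, and labelled for what it is.

## Centrality dynamics and prioritization

Three per-node centralities are computed on each stage network, unweighted:

* **DC**, the neighbor count;
* **BC**, the unnormalized betweenness — the sum over unordered node pairs
  (endpoints excluded) of the fraction of shortest paths through the node;
* **CC**, closeness. The classical closeness formula is a *farness* sum
  Σⱼ d(i, j), under which "highest centrality" would mean the smallest
  value; network-analysis tools instead report component-normalized inverse
  farness, `(n_c − 1) / farness` within the node's component of size `n_c`,
  where larger is more central. The package computes and reports **both**
  (`farness` and `cc`), and ranks by `cc`. This resolves the mismatch
  between the printed formula convention and tool convention explicitly
  instead of silently picking one.

For heatmaps and trajectory calls, each metric is min–max scaled to [0, 1]
across the nodes of each stage; constant columns map to 0.5. Trajectories
compare the earliest and latest stage where a node is present: increasing /
decreasing / stable with a dead band of 0.05 on the scaled axis (heatmap
classification is by eye in practice; 0.05 is a conservative floor for
"visibly changed"), and nodes absent from a stage are flagged
`absent-some-stages` — absence is never imputed as zero centrality.

Prioritization encodes the pharmacological reading of the dynamics: nodes
increasing in both DC and BC are accumulating control of the network
(inhibition candidates); nodes decreasing in BC and CC are losing their
broker role (stimulation candidates); nodes in the top CC quantile
(`cc_quantile`, default 0.9) at *every* stage are persistent central
anchors. Every candidate carries its evidence string.

## Drug overlay and BBB consensus

Drug–target interactions are restricted to the prioritized targets with an
inclusive score threshold of 0.5 (interpreted as a minimum interaction
confidence; the input table's own score semantics are preserved, not
recomputed). A drug is predicted brain-permeable only on a strict 8/8
consensus of the supplied predictor calls (ADABoost and SVM, each over
MACCS, Openbabel, Molprint and PubChem fingerprints). A missing or partial
call set yields `incomplete` — a drug can never become permeable through
missing evidence, and the rule is monotone under flipping calls to
negative. Predictor internals are out of scope by design: calls are inputs.

## The synthetic-data generator

The generator emulates the statistical structure of the two-model design so
that every stage of the pipeline can be tested against planted truth:

* baseline abundance is log-normal per gene (log2 mean 3, sd 1.5), the
  standard heavy-tailed shape of RNA-seq abundance; replicate noise is
  additive Gaussian on the log2 scale (sd 0.2 by default), which makes the
  t-test's assumptions controllable;
* three replicates per condition; the cell model has a single `D0` control,
  the mouse model paired per-age controls;
* planted pathway perturbations switch on at an onset stage and persist at
  all later stages, in both models when shared; per-gene effect signs are
  drawn once (70% down by default, matching the predominance of
  downregulation in aggregation models) and reused across models and
  stages, so shared genes are direction-concordant by construction;
* pathway memberships are drawn disjoint by default. Real pathway
  collections overlap heavily, but with overlapping modules "exactly the
  planted pathways recovered" is not a well-posed criterion — a background
  set sharing genes with a planted one can be legitimately enriched. The
  `overlap_pathways` switch restores overlapping draws for users who want
  the harder, fuzzier setting;
* the interactome is denser and more confident within pathways
  (P(edge) = 0.35, confidence ~ U(0.95, 1)) than in the background
  (P = 0.01, U(0.5, 0.97)); 90% of nodes pass the 4.8 tissue filter;
* the ortholog map is 1:1 at top rank for 90% of genes, with a low-rank
  second target for the rest, exercising the rank filter;
* each drug receives 1–3 targets and exactly 8 BBB calls; planted permeable
  drugs are 8/8 positive, all others carry at least one negative call.

Everything is bit-reproducible under the config seed; the interactome and
drug generators use fixed offsets of it so the three generators can be
re-run independently without correlation surprises.

**What passing tests do not show.** The generator's FPKM values are
Gaussian on the log scale with a gene-independent noise sd; real RNA-seq
has mean-variance coupling, batch structure, and correlated genes. Planted
effects are uniform within a pathway; real dysregulation is graded. Pathway
recovery on this generator therefore demonstrates the pipeline's logic
(thresholds, intersections, onset propagation), not its power on real
data. The variance structure of real FPKM data is deliberately not fitted —
the defaults are conventional, not estimated.

## Numerical choices and degenerate inputs

* Strict inequalities everywhere the decision rules state them; inclusive
  (≥) thresholds for the network and drug-score filters.
* Ties in rankings break lexicographically by identifier; all orderings are
  deterministic, and the whole pipeline is byte-reproducible under a fixed
  seed (asserted in the tests).
* Empty common-pathway sets produce empty stage networks and a valid
  report, not an error; `enrich` with zero overlap returns p = 1; an empty
  shared-gene set reports the concordance p as NA.
* Motif z-scores are undefined (NA) wherever the null sd is zero, and the
  aggregate is NA when no class is defined.
* Problem sizes used by the test suite and the acceptance script — 600
  genes, 10 pathways of 15–25 genes, 3 replicates, null ensembles of
  40–1000 — were chosen to make every property measurable in seconds to a
  few minutes while leaving the planted effects realistically sized
  (|log2FC| = 1, noise sd 0.15–0.2).

## Known limitations

* No count-level differential expression and no normalization beyond the
  FPKM given; systematic library effects must be handled upstream.
* Closeness dynamics across stages compare per-stage scaled values, so a
  node's trajectory is relative to its stage's network, not an absolute
  quantity.
* The motif aggregate z is not comparable across tools that aggregate
  differently; compare per-class z values when in doubt.
* The drug overlay trusts the supplied interaction scores and BBB calls;
  it adds set logic, not evidence.
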
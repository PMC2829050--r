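---
title: "Unbiased pathway models from perturbation metabolomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unbiased pathway models from perturbation metabolomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A physiologic perturbation — the motivating case is an oral glucose
tolerance test (OGTT), with plasma sampled before and two hours after a
glucose load — changes the abundance of dozens of metabolites at once.
Mapping those changes onto *predefined* pathway definitions often explains
little, because plasma metabolite levels are shaped as much by transport
between tissues as by the textbook pathway a metabolite belongs to. This
package implements an unbiased alternative: score every metabolite by the
statistical evidence that it changed, embed the scores in a genome-scale
metabolite reaction network, and search for *active modules* — connected
subnetworks whose aggregate evidence for change is maximal — without any
reference to pathway boundaries. The discovered modules are then
characterized after the fact with enrichment statistics, tissue-activity
scores, and correlation structure across individuals.

# The metabolite reaction network

Reactions are read from a tab-separated table (`read_reaction_table()`)
with compartmented participants written as `met[c]`, `met[e]`, etc. The
unipartite projection (`build_mrn()`) creates one node per metabolite per
cellular compartment and applies two undirected edge rules:

1. within each reaction, every reactant is joined to every product;
2. for each catalyst (enzyme or transporter), *all* of its substrates —
   reactants and products pooled across every reaction it catalyzes — are
   joined into a clique.

The clique rule is what encodes co-transport: two amino acids carried by
the same solute-carrier transporter become neighbours even if no reaction
interconverts them. Reversibility is ignored; the projection is
undirected.

Twenty-eight promiscuous or buffered currency metabolites (ATP, NAD,
water, protons, ...) are removed from reactions before edge formation —
they would otherwise bridge unrelated parts of metabolism — except in
reactions explicitly exempted because nucleotides are their primary
reactants and products (nucleotide biosynthesis and catabolism, NAD and
riboflavin metabolism). The exemption is supplied as an explicit reaction
list in configuration: there is no reliable machine rule for "primary",
and an explicit list is auditable.

Because only a fraction of the network is measured, the network is
restricted (`filter_to_measured()`) to measured nodes plus unmeasured
nodes lying on a *simple path* of length at most three between two
distinct measured nodes. We implement the simple-path form rather than
the cheaper distance-sum form (`d(m1,u) + d(u,m2) <= 3`): the two
criteria agree except for pendant nodes attached to a single measured
neighbour, which the distance-sum form would wrongly retain (the path it
counts doubles back through the same measured node).

A metabolite measured in plasma exists as several compartment twins; the
measurement must be attached to exactly one node. Both conventions are
produced in a full run: the extracellular network (EMRN) flags the `[e]`
twin and the cytoplasmic network (CMRN) the `[c]` twin, with fallback
preferred → the other of {e, c} → alphabetically first available node.
The paper's data cannot decide which convention is right, so downstream
results are always reported for both.

# From paired abundances to scores

Per metabolite, the paired statistic is the per-individual fractional
change `(post - pre) / pre`; the summary is its median and the test a
two-sided one-sample Wilcoxon signed-rank test against zero (exact null
up to 25 pairs, normal approximation with continuity correction beyond;
zeros dropped, ties midranked). Missing members of a pair drop that pair
only. The two-sided choice is deliberate: the module search looks for
*coordinated* change, not a direction.

Changed-metabolite calls use Storey q-values (`compute_qvalues()`), with
the null proportion estimated by the smoother method (cubic smoothing
spline over the lambda grid 0.05–0.95, read off at 0.95, clipped to
(0, 1]). The implementation is tested against an independent literal
transcription of the published algorithm.

The p-value distribution is then decomposed (`fit_bum()`) as a
beta-uniform mixture

$$f(x) = \pi + (1 - \pi)\, a\, x^{a-1}, \qquad 0 < a < 1,$$

a uniform noise floor of weight $\pi$ plus a Beta($a$, 1) signal spike at
zero. Maximum likelihood uses box-constrained L-BFGS-B from five fixed
starting points (both parameters bounded to [1e-5, 1 - 1e-5] to keep the
mixture proper); a fit with $a \ge 1$ means no enrichment near zero and
is rejected with a diagnostic. The mixture bounds the null proportion by
$\pi_{ub} = \pi + (1-\pi)a$, and the p-value threshold achieving a target
false discovery rate (default 0.01) has the closed form

$$\tau = \left(\frac{\pi_{ub} - \pi\,\mathrm{FDR}}
{\mathrm{FDR}\,(1-\pi)}\right)^{1/(a-1)},$$

verified in tests against a bisection solve of
$\mathrm{FDR}(\tau) = \pi_{ub}\tau / F(\tau)$. Scores are

$$S(p) = (a - 1)\,(\ln p - \ln \tau),$$

zero at $p = \tau$, positive below, negative above — so a module only
gains from nodes more significant than the FDR threshold, and pays for
every node less significant. P-values of exactly zero are floored at
1e-12 before the logarithm.

# Active modules

The maximum-weight connected subgraph problem is solved exactly
(`solve_mwcs()`). Two reductions come first: connected components of
positive-weight nodes are contracted (any optimum touching one contains
all of it) and non-positive leaves are pruned iteratively. The reduced
instance then goes to one of two exact engines, both in C++. With few
positive supernodes, a branch-and-bound search is used; its bound
charges every reachable positive its cheapest connection cost (Dijkstra
over node costs $\max(0, -w)$): for positives sorted by that cost $d_j$
with prefix weight sums $W_j$, any extension of the current set is worth
at most $\max_j (W_j - d_j)$, because a connector reaching a set of
positives costs at least the largest of their individual connection
costs. With many scattered positives — the regime produced by score
permutation, where branch-and-bound pruning degrades — the solver
switches to a Steiner dynamic program over terminal subsets
(Dreyfus–Wagner style, terminals = positive supernodes, cost
$\Theta(3^k n)$ for $k$ terminals), which is exact with predictable
runtime. Ties between equal-score optima break toward the
lexicographically smallest node-key set in the branch-and-bound engine,
so small instances are fully deterministic; with continuous scores ties
have probability zero. The engines arbitrate each other in the test
suite, and both are arbitrated by a brute-force enumeration of all
connected subsets on small random graphs. When every
score is negative the best single node is returned rather than the empty
set — one optimal solution is always reported — and a `heuristic` mode
(greedy connected growth with two-step lookahead) is available for
networks beyond exact reach (the exact mode refuses more than 30,000
nodes).

Unmeasured nodes have no p-value; asserting they did not change would be
overconfident. Instead each replicate draws their p-values from
Uniform(0, 1) — the distribution of unchanged metabolites — and scores
them with the fit obtained from the *measured* p-values
(`impute_unmeasured()`). One hundred replicates are run
(`run_replicates()`, per-replicate seed = base seed + index);
chromatographically ambiguous peaks (e.g. leucine/isoleucine) are
reassigned to a uniformly chosen candidate in every replicate. Nodes
appearing in at least 20% of replicate optima form the Active Module
Group (`build_amg()`).

Significance (`permute_and_solve()`) keeps the topology fixed, permutes
the measured scores among measured nodes, re-imputes unmeasured nodes,
and re-solves; the observed and null optimal-score distributions are
compared with a one-sided Mann–Whitney–Wilcoxon test
(`compare_score_distributions()`; when every value in both samples is
identical — possible in degenerate no-signal runs — the comparison
returns p = 1 with a warning).

# Enrichment and tissue activity

`hypergeom_enrich()` is the upper-tail cumulative hypergeometric test of
a query set against each predefined set, relative to a tested universe.
Multiple testing is adjusted by resampling (`adjust_by_resampling()`):
random query lists — optionally matched to the real query's composition
of measured and unmeasured nodes, which matters because AMGs mix both —
are drawn, the minimum p-value over sets retained per draw, and the
adjusted p-value is the fraction of draws at or below the set's raw p
(ties count, the conservative direction). Ordered mode
(`ordered_enrich()`) scans every rank-prefix cutoff of a ranked query
and adjusts jointly over sets and cutoffs, the conservative reading of
rank-optimized enrichment. Tissue activity (`tissue_enrich()`) sums
per-node activity calls in [-2, +2] (missing pairs count 0) per tissue
and compares against the *maximum* tissue score of each resampled set,
making the adjustment family-wise over tissues. Sets need at least three
members in the universe to be tested.

# Correlation structure and PCA

Metabolites significantly changed in either group (q < 0.05), plus a
configured always-include list, enter a metabolite-by-individual matrix
of fractional changes. Clustering uses the dissimilarity
$d = 1 - |\rho|$ with $\rho$ the pairwise-complete Spearman correlation
— the absolute value groups co-regulated metabolites regardless of
direction, which is what shared-transporter structure predicts.
Undefined correlations (constant rows) become distance 1 with a warning.
Linkage defaults to complete (the default of the clustering tool the
analysis is modelled on) and is configurable; labels are sorted before
clustering so ties break deterministically. PCA treats individuals as
observations, centers by default, does not scale by default (matching
`prcomp`), and median-imputes missing changes per metabolite with a log
message.

# The synthetic-data generator

`simulate_study()` writes a complete input bundle with known ground
truth: a connected random network (Erdős–Rényi by default, 200 base
metabolites, edge probability 0.02, 10% of metabolites duplicated into
[c]/[e] twins joined by a dedicated transporter), a planted connected
module chosen by random walk, paired abundances for 25 individuals
(log-normal baselines, planted fractional shift −0.3, block-correlated
changes through a shared per-individual latent factor), a GMT collection
whose first set is exactly the planted module plus random decoys, and a
tissue table with mostly ambiguous calls (score 0 with 60% probability,
±1 with 15% each, ±2 with 5% each — confident calls are rare in real
tissue-activity predictions) in which one tissue is shifted +1 on the
planted members. Fixed seeds give byte-identical files.

The generator emulates the *statistical* structure the pipeline consumes
— mixture-distributed p-values, a connected high-scoring subgraph,
correlated fractional changes, planted enrichment — and deliberately not
mass-spectrometric reality (peak shapes, ion suppression, batch effects,
contaminant chemistry). Passing tests therefore demonstrate that the
machinery recovers planted truth under its own model assumptions, not
that those assumptions hold for any particular platform.

## Signal strength in the recovery experiments

Planted signal p-values are drawn from Beta($a_s$, 1). Under the score
transform, a planted node's expected score is
$(1 - \hat a)(1/a_s + \ln \tau)$, which is positive only when
$a_s < -1/\ln \tau$. At the default scoring FDR of 0.01 the fitted
threshold on these simulations is $\tau \approx 5\times 10^{-4}$, so the
break-even signal shape is $a_s \approx 0.13$: a planted module drawn
with the generator's illustrative default $a_s = 0.2$ has *negative*
expected total score and no solver can be expected to return it. The
planted-module recovery and threshold-robustness experiments therefore
use the strong-signal regime $a_s = 0.05$ (expected planted score
$\approx +10$ per node), chosen from the break-even formula with margin.
This is a property of the score transform, not of the solver: recovery
experiments at any $a_s$ above the break-even point measure the
transform's deliberate refusal to reward weak evidence.

# Problem sizes and numerical choices

The shipped experiments use 200-node networks with 12-node planted
modules, 100 search replicates, and 20 simulations for recovery
averages; the observed-versus-null significance demonstration uses a
100-node network with 50 replicates and 50 permutations; the no-signal
calibration uses 400 scaled-down runs of 10 replicates and 10
permutations on 40-node networks. These sizes
give stable averages while keeping the full experiment battery
comfortably within a coffee break on one CPU; all of them are
configuration values, not constants.

Other numerical choices: p-value floors at 1e-12 (finite log-scores);
solver score comparisons at 1e-9 with independent post-hoc re-verification
of connectivity and of the reported total against the member sum;
mixture-density normalization checked to 1e-9 in tests; q-values clipped
to [0, 1] and monotonized; resampled adjusted p-values have resolution
1/n_resamples and a warning fires below 100 resamples.

# Known limitations

- The reaction TSV schema is a package convention; genome-scale
  reconstructions ship in SBML, and converting them is the user's step.
- The promiscuous-metabolite exemption list must be curated by hand.
- Edge formation ignores stoichiometry, directionality and flux
  feasibility; a module is a statistical object, not a flux mode.
- The composition-matched null treats all unmeasured nodes as
  exchangeable, ignoring degree structure; hub-heavy AMGs may look
  slightly more enriched than a degree-matched null would report.
- Ordered-mode enrichment is quadratic in the ranked-list length times
  resamples; it is meant for ranked lists of tens, not thousands.
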
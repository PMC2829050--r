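# metamodule

Unbiased pathway modelling of perturbation metabolomics in R.

When a physiologic perturbation (the motivating design is an oral
glucose tolerance test: plasma drawn before and after a glucose load)
shifts many metabolite levels at once, predefined pathway annotations
often explain the pattern poorly — plasma levels are governed as much by
inter-tissue *transport* as by the pathway a metabolite belongs to.
`metamodule` instead lets the data draw its own pathway model:

1. **Network.** A compartmented reaction table is projected onto a
   unipartite metabolite reaction network (MRN): nodes are
   `metabolite[compartment]`, edges join every reactant to every product
   of a reaction, and all substrates of each enzyme or transporter into
   a clique (co-transport becomes adjacency). Promiscuous currency
   metabolites (ATP, NAD, water, ...) are excluded.
2. **Scores.** Per-metabolite paired change is tested with a one-sample
   Wilcoxon signed-rank test on fractional changes `(post − pre)/pre`.
   The p-value distribution is decomposed as a beta-uniform mixture
   `f(x) = π + (1 − π) a x^(a−1)`; the threshold τ achieving a target
   FDR (default 0.01) is
   `τ = ((π_ub − π·FDR) / (FDR·(1 − π)))^(1/(a−1))`, `π_ub = π + (1−π)a`,
   and scores are `S(p) = (a − 1)(ln p − ln τ)` — positive exactly for
   `p < τ`.
3. **Active modules.** The maximum-weight connected subgraph of the
   scored network is found *exactly* (C++: branch-and-bound with a
   cheapest-connection bound, switching to a Steiner subset dynamic
   program when positive nodes are many and scattered). Unmeasured nodes
   get p ~ Uniform(0,1) per replicate; nodes in ≥ 20% of 100 replicate
   optima form the Active Module Group (AMG).
4. **Inference & characterization.** Significance by score permutation +
   one-sided Mann–Whitney; FuncAssociate-style hypergeometric enrichment
   with composition-matched resampling nulls; tissue-activity scoring;
   Spearman `1 − |ρ|` clustering and PCA of fractional changes.

A synthetic-data generator (`simulate_study()`) emits every input with
planted ground truth, so the whole pipeline is exercisable — and
falsifiable — without any external data.

## Worked example

```r
library(metamodule)

dir <- tempfile("study")
bundle <- simulate_study(dir, n_nodes = 120, module_size = 8,
                         a_signal = 0.05, measured_fraction = 0.35,
                         n_individuals = 25, effect = -0.3,
                         edge_param = 0.035, seed = 2026)
res <- run_pipeline(bundle$reactions, bundle$abundances, bundle$sets,
                    bundle$tissues, file.path(dir, "results"),
                    config = list(n_replicates = 50, n_permutations = 50,
                                  n_resamples = 500, seed = 11))

head(dplyr::arrange(res$change, q_value), 3)
#>   metabolite fractional_change     p_value n_pairs measured   q_value
#> 1 M074                  -0.249 0.000000834      25 TRUE     0.0000170
#> 2 M096                  -0.211 0.00000113       25 TRUE     0.0000170
#> 3 M114                  -0.181 0.000000596      25 TRUE     0.0000170

res$fit
#> Beta-uniform mixture fit (n = 45): pi = 0.720, a = 0.114
#>   tau = 0.00183 at FDR 0.01

res$placements$extracellular$amg
#> Active Module Group: 9 node(s) at frequency >= 0.20 over 50 solutions
res$placements$extracellular$significance_p
#> 3.53e-18
```

The simulated study planted an 8-metabolite connected module with a −30%
post-perturbation shift. The fitted mixture says 72% of measured
p-values are noise; at FDR 0.01 only p < 0.00183 earns a positive score.
The AMG contains exactly the eight planted metabolites (plus the
extracellular twin of one of them), and the permutation test says a
module this strong essentially never arises from scrambled scores
(p ≈ 4e-18). Characterization concurs:

```r
head(res$placements$extracellular$enrichment, 2)[, c("set_id", "overlap", "p_raw", "p_adj")]
#>   set_id      overlap p_raw    p_adj
#> 1 SET_PLANTED       8 3.79e-11 0.000   # the planted set, rank 1
#> 2 SET_D020          2 1.77e-01 0.874
head(res$placements$extracellular$tissue, 1)
#>   tissue activity_sum p_adj
#> 1 TIS01             8 0.020                # the planted tissue, rank 1
```

Each result type has `tidy()` / `glance()` methods and an `autoplot()`
(`bum_fit`, `amg`, `pca_changes`), so results drop straight into dplyr
and ggplot2 workflows.

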
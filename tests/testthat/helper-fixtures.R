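# A small planted-signal scored network used by module search and
# significance tests: strong signal so replicate optima are stable.
scored_net_fixture <- function(seed = 101, n = 60, measured = 15,
                               a_signal = 0.05, module = 6) {
  set.seed(seed)
  gen <- generate_network(n, "erdos_renyi", 0.06, 0.1)
  net <- gen$network
  pl <- plant_module_and_pvalues(net, module, a_signal,
                                 measured / igraph::vcount(net))
  fit <- set_fdr_threshold(fit_bum(pl$p_table$p_value), 0.01)
  keys <- igraph::V(net)$name
  igraph::V(net)$measured <- keys %in% pl$p_table$node
  sc <- rep(NA_real_, length(keys))
  sc[match(pl$p_table$node, keys)] <- score_pvalue(pl$p_table$p_value, fit)
  igraph::V(net)$score <- sc
  list(net = net, fit = fit, truth = pl$truth, p_table = pl$p_table)
}
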
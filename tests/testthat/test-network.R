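rx_from_lines <- function(...) read_reaction_table(toy_reaction_file(c(...)))

test_that("reactant-product and shared-substrate edge rules apply per reaction", {
  rx <- rx_from_lines("R1\tA[c]+B[c]\tC[c]\tE1\t1")
  net <- build_mrn(rx)
  ed <- mrn_edges(net)
  pair <- function(a, b) ed[ed$from == pmin(a, b) & ed$to == pmax(a, b), ]
  expect_equal(nrow(ed), 3)  # A-B, A-C, B-C
  expect_true(pair("A[c]", "C[c]")$reactant_product)
  expect_true(pair("B[c]", "C[c]")$reactant_product)
  expect_false(pair("A[c]", "B[c]")$reactant_product)  # co-reactants only via catalyst
  expect_true(all(ed$shared_substrate))
  expect_true(all(grepl("E1", ed$catalysts)))
})

test_that("promiscuous metabolites are removed before edges unless exempted", {
  rx <- rx_from_lines("R2\tA[c]+ATP[c]\tB[c]+ADP[c]\t\t1")
  net <- build_mrn(rx)
  expect_setequal(mrn_nodes(net)$node, c("A[c]", "B[c]"))
  expect_equal(nrow(mrn_edges(net)), 1)  # single A-B edge

  exempted <- build_mrn(rx, exempt_reactions = "R2")
  expect_equal(igraph::vcount(exempted), 4)
  expect_equal(nrow(mrn_edges(exempted)), 4)  # 2x2 reactant-product pairs

  all_prom <- rx_from_lines("R3\tATP[c]\tADP[c]\t\t1")
  expect_warning(net3 <- build_mrn(all_prom), "contribute nothing")
  expect_equal(igraph::vcount(net3), 0)
})

test_that("a transporter's substrates across reactions form a clique", {
  rx <- rx_from_lines("T1\tX[e]\tX[c]\tTR\t1",
                      "T2\tY[e]\tY[c]\tTR\t1")
  net <- build_mrn(rx)
  ed <- mrn_edges(net)
  expect_equal(igraph::vcount(net), 4)
  expect_equal(nrow(ed), choose(4, 2))  # all 6 pairs present
  ss <- ed[!(ed$reactant_product), ]
  expect_true(all(ss$shared_substrate))
  expect_true(all(grepl("TR", ed$catalysts)))
})

test_that("catalyst clique size is k(k-1)/2 and duplication is idempotent", {
  for (k in c(3, 5, 7)) {
    mets <- paste0("M", seq_len(k))
    line <- sprintf("R1\t%s\t%s\tE\t1",
                    paste0(mets[1], "[c]"),
                    paste(paste0(mets[-1], "[c]"), collapse = "+"))
    net <- build_mrn(read_reaction_table(toy_reaction_file(line)))
    expect_equal(nrow(mrn_edges(net)), k * (k - 1) / 2)
  }
  rx <- rx_from_lines("R1\tA[c]+B[c]\tC[c]\tE1\t1")
  rx_dup <- dplyr::bind_rows(rx, dplyr::mutate(rx, reaction_id = "R1b"))
  n1 <- build_mrn(rx)
  n2 <- build_mrn(rx_dup)
  expect_equal(mrn_edges(n2)[c("from", "to", "reactant_product", "shared_substrate")],
               mrn_edges(n1)[c("from", "to", "reactant_product", "shared_substrate")])
})

test_that("measured-compartment assignment follows placement and fallback", {
  rx <- rx_from_lines("T1\tglc[e]\tglc[c]\tTR\t1",
                      "R1\tglc[c]\tpyr[c]\t\t1",
                      "R2\tpyr[c]\tlac[m]\t\t1")
  net <- build_mrn(rx)
  emrn <- assign_measured_compartment(net, c("glc", "pyr"), "extracellular")
  meas <- mrn_nodes(emrn)[mrn_nodes(emrn)$measured, "node", drop = TRUE]
  expect_setequal(meas, c("glc[e]", "pyr[c]"))  # pyr falls back to [c]

  cmrn <- assign_measured_compartment(net, c("glc", "pyr"), "cytoplasmic")
  measc <- mrn_nodes(cmrn)[mrn_nodes(cmrn)$measured, "node", drop = TRUE]
  expect_setequal(measc, c("glc[c]", "pyr[c]"))

  expect_warning(assign_measured_compartment(net, c("glc", "ghost")),
                 "ghost")
  # exactly one node flagged per metabolite however many compartments
  rx5 <- rx_from_lines("R1\tm[c]\tm[e]\t\t1", "R2\tm[m]\tm[l]\t\t1",
                       "R3\tm[l]\tm[g]\t\t1")
  net5 <- build_mrn(rx5)
  out5 <- assign_measured_compartment(net5, "m", "extracellular")
  expect_equal(sum(mrn_nodes(out5)$measured), 1)
})

test_that("path filtering keeps bridges up to the length threshold only", {
  chain <- function(nodes) {
    lines <- sprintf("R%d\t%s[c]\t%s[c]\t\t1", seq_len(length(nodes) - 1),
                     head(nodes, -1), nodes[-1])
    build_mrn(read_reaction_table(toy_reaction_file(lines)))
  }
  # m1-u1-u2-m2: bridge of length 3, retained
  n1 <- chain(c("m1", "u1", "u2", "m2"))
  igraph::V(n1)$measured <- igraph::V(n1)$metabolite %in% c("m1", "m2")
  f1 <- filter_to_measured(n1, 3)
  expect_setequal(igraph::V(f1)$name, c("m1[c]", "u1[c]", "u2[c]", "m2[c]"))
  # m1-u1-u2-u3-m2: length 4, interior removed
  n2 <- chain(c("m1", "u1", "u2", "u3", "m2"))
  igraph::V(n2)$measured <- igraph::V(n2)$metabolite %in% c("m1", "m2")
  f2 <- filter_to_measured(n2, 3)
  expect_setequal(igraph::V(f2)$name, c("m1[c]", "m2[c]"))
  # pendant unmeasured node attached to one measured node only: removed
  n3 <- chain(c("u0", "m1", "m2"))
  igraph::V(n3)$measured <- igraph::V(n3)$metabolite %in% c("m1", "m2")
  f3 <- filter_to_measured(n3, 3)
  expect_setequal(igraph::V(f3)$name, c("m1[c]", "m2[c]"))
  expect_error(filter_to_measured(chain(c("a", "b"))),
               class = "metamodule_data_error")
})

test_that("path filtering preserves measured nodes and returns a subgraph", {
  set.seed(42)
  for (i in 1:5) {
    gen <- generate_network(40, "erdos_renyi", 0.08, 0.1)
    net <- gen$network
    keys <- igraph::V(net)$name
    igraph::V(net)$measured <- keys %in% sample(keys, 8)
    out <- filter_to_measured(net, 3)
    expect_true(all(keys[igraph::V(net)$measured] %in% igraph::V(out)$name))
    expect_true(all(igraph::V(out)$name %in% keys))
    eo <- mrn_edges(out)
    ei <- mrn_edges(net)
    expect_true(all(paste(eo$from, eo$to) %in% paste(ei$from, ei$to)))
  }
})
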
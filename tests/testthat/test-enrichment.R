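mk_sets <- function(...) {
  lst <- list(...)
  tibble::tibble(set_id = names(lst), description = names(lst),
                 members = unname(lst),
                 size = purrr::map_int(unname(lst), length))
}

test_that("hypergeometric tail matches exhaustive enumeration", {
  universe <- sprintf("U%02d", 1:20)
  sets <- mk_sets(S = universe[1:3])
  res <- hypergeom_enrich(universe[1:5], sets, universe)
  expect_equal(res$overlap, 3L)
  expect_equal(res$p_raw, 136 / 15504, tolerance = 1e-12)
  expect_equal(res$p_raw, oracle_hypergeom(20, 3, 5, 3), tolerance = 1e-12)
  # sweep of overlap configurations against the enumeration oracle
  for (cfg in list(c(12, 4, 5, 2), c(15, 6, 4, 1), c(10, 5, 5, 3))) {
    u <- sprintf("x%02d", seq_len(cfg[1]))
    s <- mk_sets(S = u[seq_len(cfg[2])])
    q <- c(u[seq_len(cfg[4])], rev(u)[seq_len(cfg[3] - cfg[4])])
    r <- hypergeom_enrich(q, s, u)
    expect_equal(r$overlap, cfg[4])
    expect_equal(r$p_raw, oracle_hypergeom(cfg[1], cfg[2], cfg[3], cfg[4]),
                 tolerance = 1e-12)
  }
})

test_that("hypergeometric degenerate cases behave", {
  universe <- sprintf("U%02d", 1:20)
  sets <- mk_sets(S = universe[1:3], ALL = universe)
  res <- hypergeom_enrich(universe[10:14], sets, universe)
  expect_equal(res$p_raw[res$set_id == "S"], 1)    # zero overlap: P(X >= 0) = 1
  expect_equal(res$p_raw[res$set_id == "ALL"], 1)  # set = universe: certain
  expect_error(hypergeom_enrich(character(0), sets, universe),
               class = "metamodule_data_error")
  expect_error(hypergeom_enrich("notin", sets, universe),
               class = "metamodule_data_error")
})

test_that("resampling adjustment is monotone and finds planted enrichment", {
  set.seed(17)
  universe <- sprintf("U%02d", 1:40)
  planted <- universe[1:6]
  query <- c(planted, universe[30:33])
  sets <- mk_sets(PL = planted, D1 = sample(universe, 8), D2 = sample(universe, 6),
                  D3 = sample(universe, 10), D4 = sample(universe, 5))
  res <- hypergeom_enrich(query, sets, universe)
  adj <- adjust_by_resampling(res, sets, universe, query, n_resamples = 400)
  # shared null: p_adj non-decreasing in p_raw
  expect_true(all(diff(adj$p_adj[order(adj$p_raw)]) >= -1e-12))
  expect_equal(adj$set_id[which.min(adj$p_adj)], "PL")
  expect_lt(adj$p_adj[adj$set_id == "PL"], 0.05)
  expect_warning(adjust_by_resampling(res, sets, universe, query,
                                      n_resamples = 50), "coarse")
})

test_that("planted sets rank first across repeated simulations", {
  set.seed(18)
  wins <- sapply(1:20, function(i) {
    universe <- sprintf("U%02d", 1:30)
    planted <- sample(universe, 6)
    query <- unique(c(planted, sample(universe, 3)))
    sets <- mk_sets(PL = planted,
                    D1 = sample(universe, 7), D2 = sample(universe, 7),
                    D3 = sample(universe, 7))
    adj <- adjust_by_resampling(hypergeom_enrich(query, sets, universe),
                                sets, universe, query, n_resamples = 150)
    adj$set_id[order(adj$p_adj, adj$p_raw)][1] == "PL"
  })
  expect_gte(sum(wins), 18)
})

test_that("composition matching constrains the null queries", {
  set.seed(19)
  universe <- sprintf("U%02d", 1:30)
  measured <- universe[1:10]
  query <- c(universe[1:4], universe[25:27])  # 4 measured, 3 unmeasured
  draws <- replicate(200, sample_matched_query(universe, measured, 4, 3),
                     simplify = FALSE)
  expect_true(all(purrr::map_int(draws, ~ length(intersect(.x, measured))) == 4))
  expect_true(all(purrr::map_int(draws, length) == 7))
  # all-measured query with matching equals the unmatched procedure's support
  sets <- mk_sets(S = universe[1:5])
  res <- hypergeom_enrich(universe[1:4], sets, universe[1:10])
  set.seed(5)
  a1 <- adjust_by_resampling(res, sets, universe[1:10], universe[1:4],
                             measured = universe[1:10],
                             match_composition = TRUE, n_resamples = 200)
  set.seed(5)
  a2 <- adjust_by_resampling(res, sets, universe[1:10], universe[1:4],
                             match_composition = FALSE, n_resamples = 200)
  expect_equal(a1$p_adj, a2$p_adj)
})

test_that("ordered mode finds the optimizing rank cutoff", {
  set.seed(23)
  universe <- sprintf("U%02d", 1:50)
  planted <- universe[1:5]
  ranked <- c(planted, sample(setdiff(universe, planted), 15))
  sets <- mk_sets(PL = planted, D = sample(universe[6:50], 8))
  res <- ordered_enrich(ranked, sets, universe, n_resamples = 60)
  expect_equal(res$best_rank_cutoff[res$set_id == "PL"], 5L)
  # the scan minimum equals a manual prefix scan
  manual <- min(sapply(1:20, function(k)
    hypergeom_enrich(ranked[1:k], sets, universe)$p_raw[
      hypergeom_enrich(ranked[1:k], sets, universe)$set_id == "PL"]))
  expect_equal(res$p_raw[res$set_id == "PL"], manual)
  # single-element list reduces to the plain test on that singleton
  res1 <- ordered_enrich(ranked[1], sets, universe, n_resamples = 40)
  plain <- hypergeom_enrich(ranked[1], sets, universe)
  expect_equal(res1$p_raw, plain$p_raw[match(res1$set_id, plain$set_id)])
  expect_error(ordered_enrich(c("a", "a"), sets, universe),
               class = "metamodule_data_error")
})

test_that("tissue activity sums and family-wise null behave", {
  universe <- sprintf("U%02d", 1:30)
  tt <- tidyr::expand_grid(node = universe, tissue = c("liver", "muscle")) |>
    dplyr::mutate(score = 0)
  tt$score[tt$node %in% universe[1:3] & tt$tissue == "liver"] <- c(2, 2, 1)
  set.seed(29)
  res <- tissue_enrich(universe[1:3], tt, universe, n_resamples = 200)
  expect_equal(res$activity_sum[res$tissue == "liver"], 5)
  expect_equal(res$activity_sum[res$tissue == "muscle"], 0)
  expect_lt(res$p_adj[res$tissue == "liver"],
            res$p_adj[res$tissue == "muscle"] + 1e-9)
  # empty query: all sums zero
  res0 <- tissue_enrich(character(0), tt, universe, n_resamples = 50)
  expect_true(all(res0$activity_sum == 0))
  # tissue with no scored node in the universe is excluded with a warning
  tt2 <- dplyr::bind_rows(tt, tibble::tibble(node = "ghost", tissue = "brain",
                                             score = 1))
  expect_warning(tissue_enrich(universe[1:3], tt2, universe, n_resamples = 20),
                 "brain")
})

test_that("a shifted tissue attains the smallest adjusted p across runs", {
  set.seed(31)
  wins <- sapply(1:20, function(i) {
    universe <- sprintf("U%02d", 1:40)
    query <- sample(universe, 8)
    st <- generate_sets_and_tissues(universe, query, n_decoy_sets = 2,
                                    n_tissues = 6)
    res <- tissue_enrich(query, st$tissues, universe, n_resamples = 150)
    res$tissue[order(res$p_adj, -res$activity_sum)][1] == st$planted_tissue
  })
  expect_gte(sum(wins), 18)
})

test_that("resampling procedures are bit-reproducible under a fixed seed", {
  universe <- sprintf("U%02d", 1:25)
  sets <- mk_sets(S1 = universe[1:5], S2 = universe[10:17])
  query <- universe[c(1:4, 20)]
  res <- hypergeom_enrich(query, sets, universe)
  set.seed(44)
  a <- adjust_by_resampling(res, sets, universe, query, n_resamples = 150)
  set.seed(44)
  b <- adjust_by_resampling(res, sets, universe, query, n_resamples = 150)
  expect_identical(a, b)
})
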
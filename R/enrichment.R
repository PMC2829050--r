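#' Hypergeometric set enrichment
#'
#' Upper-tail cumulative hypergeometric (one-sided Fisher) test of
#' overlap between a query node set and each predefined set, relative to
#' a tested universe: p = P(X >= overlap) with
#' X ~ Hypergeom(|universe|, |set in universe|, |query|).
#'
#' @param query Character vector of node ids, a subset of `universe`.
#' @param sets Set collection tibble (see [read_set_gmt()]).
#' @param universe Character vector of node ids.
#' @return Tibble `set_id`, `overlap`, `set_size_in_universe`,
#'   `query_size`, `universe_size`, `p_raw`.
#' @export
hypergeom_enrich <- function(query, sets, universe) {
  if (length(query) == 0) {
    abort("query is empty", class = "metamodule_data_error")
  }
  if (!all(query %in% universe)) {
    abort("query must be a subset of the universe",
          class = "metamodule_data_error")
  }
  N <- length(universe)
  n <- length(query)
  sets |>
    dplyr::transmute(
      .data$set_id,
      set_size_in_universe = purrr::map_int(.data$members,
                                            ~ length(intersect(.x, universe))),
      overlap = purrr::map_int(.data$members, ~ length(intersect(.x, query))),
      query_size = n, universe_size = N,
      p_raw = phyper(.data$overlap - 1L, .data$set_size_in_universe,
                     N - .data$set_size_in_universe, n, lower.tail = FALSE)
    ) |>
    dplyr::arrange(.data$p_raw, .data$set_id)
}

sample_matched_query <- function(universe, measured, n_measured, n_unmeasured) {
  meas_pool <- intersect(universe, measured)
  unmeas_pool <- setdiff(universe, measured)
  c(sample(meas_pool, n_measured), sample(unmeas_pool, n_unmeasured))
}

#' Resampling adjustment of enrichment p-values
#'
#' FuncAssociate-style multiple-testing correction: the hypergeometric
#' test is repeated for random query lists of the same size (optionally
#' matching the real query's composition of measured vs unmeasured
#' nodes), the minimum p-value over sets is retained per resample, and
#' p_adj(set) is the fraction of resamples whose minimum p-value is less
#' than or equal to the set's raw p-value.
#'
#' @param results Output of [hypergeom_enrich()] for the real query.
#' @param sets,universe As in [hypergeom_enrich()].
#' @param query The real query (used for its composition).
#' @param measured Character vector of measured node ids (required when
#'   `match_composition`).
#' @param match_composition Match measured/unmeasured counts in the null.
#' @param n_resamples Number of random query lists (default 1000).
#' @return `results` with a `p_adj` column (resolution 1/n_resamples).
#' @export
adjust_by_resampling <- function(results, sets, universe, query,
                                 measured = NULL, match_composition = FALSE,
                                 n_resamples = 1000L) {
  if (n_resamples < 100L) {
    warn("fewer than 100 resamples: adjusted p-values are coarse")
  }
  n <- length(query)
  if (match_composition) {
    if (is.null(measured)) {
      abort("match_composition requires `measured`",
            class = "metamodule_config_error")
    }
    n_meas <- length(intersect(query, measured))
    n_unmeas <- n - n_meas
  }
  min_p <- purrr::map_dbl(seq_len(n_resamples), function(i) {
    rq <- if (match_composition) {
      sample_matched_query(universe, measured, n_meas, n_unmeas)
    } else {
      sample(universe, n)
    }
    min(hypergeom_enrich(rq, sets, universe)$p_raw)
  })
  results |>
    dplyr::mutate(p_adj = purrr::map_dbl(.data$p_raw,
                                         ~ mean(min_p <= .x)))
}

#' Ordered-mode enrichment over a ranked query
#'
#' For a ranked node list (e.g. metabolites ranked by magnitude of
#' change), each set's raw p-value is minimized over all rank-prefix
#' cutoffs k = 1..length(list); the resampling null draws random ranked
#' lists of the same length from the universe and retains the minimum
#' p-value jointly over sets and cutoffs.
#'
#' @param ranked_query Ordered character vector without duplicates.
#' @param sets,universe As in [hypergeom_enrich()].
#' @param n_resamples Number of random ranked lists.
#' @return Tibble `set_id`, `p_raw`, `best_rank_cutoff`, `p_adj`.
#' @export
ordered_enrich <- function(ranked_query, sets, universe, n_resamples = 1000L) {
  if (anyDuplicated(ranked_query)) {
    abort("ranked query contains duplicates", class = "metamodule_data_error")
  }
  scan <- function(rq) {
    per_k <- purrr::map(seq_along(rq), function(k) {
      hypergeom_enrich(rq[seq_len(k)], sets, universe) |>
        dplyr::mutate(k = k)
    }) |> dplyr::bind_rows()
    per_k |>
      dplyr::group_by(.data$set_id) |>
      dplyr::arrange(.data$p_raw, .data$k, .by_group = TRUE) |>
      dplyr::summarise(p_raw = dplyr::first(.data$p_raw),
                       best_rank_cutoff = dplyr::first(.data$k),
                       .groups = "drop")
  }
  obs <- scan(ranked_query)
  min_p <- purrr::map_dbl(seq_len(n_resamples), function(i) {
    min(scan(sample(universe, length(ranked_query)))$p_raw)
  })
  obs |>
    dplyr::mutate(p_adj = purrr::map_dbl(.data$p_raw, ~ mean(min_p <= .x))) |>
    dplyr::arrange(.data$p_raw, .data$set_id)
}

#' Tissue-activity enrichment of a node set
#'
#' Each tissue's activity for the query is the sum of its per-node
#' activity scores (in \[-2, +2\]; missing node/tissue pairs count 0).
#' The null resamples composition-matched random node sets from the
#' universe and takes the highest tissue score per resample, making the
#' adjusted p-value family-wise over tissues:
#' p_adj(tissue) = fraction of resamples whose maximum tissue score is
#' at least the observed activity sum.
#'
#' @param query Character vector of node ids.
#' @param tissue_table Tibble `node`, `tissue`, `score`.
#' @param universe Character vector of node ids.
#' @param measured Measured node ids (for composition matching).
#' @param match_composition Match measured/unmeasured counts in the null.
#' @param n_resamples Number of random sets (default 1000).
#' @return Tibble `tissue`, `activity_sum`, `p_adj`.
#' @export
tissue_enrich <- function(query, tissue_table, universe, measured = NULL,
                          match_composition = !is.null(measured),
                          n_resamples = 1000L) {
  tt <- tissue_table |> dplyr::filter(.data$node %in% universe)
  empty <- setdiff(unique(tissue_table$tissue), unique(tt$tissue))
  if (length(empty) > 0) {
    warn(sprintf("tissue(s) with no scored nodes in universe excluded: %s",
                 paste(empty, collapse = ", ")))
  }
  tissues <- sort(unique(tt$tissue))
  sums_for <- function(q) {
    s <- tt |>
      dplyr::filter(.data$node %in% q) |>
      dplyr::group_by(.data$tissue) |>
      dplyr::summarise(activity_sum = sum(.data$score), .groups = "drop")
    out <- setNames(rep(0, length(tissues)), tissues)
    out[s$tissue] <- s$activity_sum
    out
  }
  obs <- sums_for(query)
  if (match_composition) {
    n_meas <- length(intersect(query, measured))
    n_unmeas <- length(query) - n_meas
  }
  null_max <- purrr::map_dbl(seq_len(n_resamples), function(i) {
    rq <- if (match_composition) {
      sample_matched_query(universe, measured, n_meas, n_unmeas)
    } else {
      sample(universe, length(query))
    }
    max(sums_for(rq))
  })
  tibble::tibble(tissue = tissues, activity_sum = unname(obs)) |>
    dplyr::mutate(p_adj = purrr::map_dbl(.data$activity_sum,
                                         ~ mean(null_max >= .x))) |>
    dplyr::arrange(.data$p_adj, dplyr::desc(.data$activity_sum), .data$tissue)
}
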